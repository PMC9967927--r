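#' Configure a synthetic genotype panel
#'
#' Defines the generative model for a multi-population co-dominant marker
#' panel: ancestral allele frequencies drawn uniformly on the simplex,
#' population frequencies drawn from the Balding-Nichols Dirichlet
#' `Dir(p * (1 - fst) / fst)` (with `fst = 0` meaning populations share the
#' ancestral frequencies exactly), and genotypes drawn with within-population
#' inbreeding `f`: `P(homozygote i) = p_i^2 + f p_i (1 - p_i)`,
#' `P(heterozygote ij) = 2 p_i p_j (1 - f)`.
#'
#' Defaults mirror the study design this package was built around: 12
#' populations of 15 individuals, 220 bi-allelic SNP and 8 SSR loci whose
#' visible allele counts and per-locus null-allele frequencies equal the
#' observed per-marker panel values.
#'
#' @param n_populations,n_per_population Number of populations and individuals
#'   per population.
#' @param n_snp,n_ssr Number of SNP and SSR loci.
#' @param fst Differentiation parameter in `[0, 1)`.
#' @param inbreeding_f Within-population inbreeding coefficient in `[-1, 1]`.
#' @param naf_per_ssr_locus Per-SSR-locus null allele frequencies in `[0, 1)`;
#'   recycled to `n_ssr`.
#' @param missing_rate Independent per-call missingness probability in `[0, 1)`.
#' @param ssr_allele_counts Per-SSR-locus count of visible alleles; recycled.
#' @param depth_mean Mean simulated read depth for called SNP genotypes
#'   (Poisson); `NULL` for no depths.
#' @param seed Integer RNG seed; the single stream driving all draws.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_populations = 12,
                              n_per_population = 15,
                              n_snp = 220,
                              n_ssr = 8,
                              fst = 0.05,
                              inbreeding_f = 0,
                              naf_per_ssr_locus = c(0.0341, 0.2875, 0.1495, 0.2875,
                                                    0.2917, 0.0970, 0.0390, 0.3361),
                              missing_rate = 0.02,
                              ssr_allele_counts = c(6, 5, 4, 9, 13, 5, 4, 4),
                              depth_mean = 30,
                              seed = 1L) {
  stopifnot(n_populations >= 1, n_per_population >= 1, n_snp >= 0, n_ssr >= 0)
  if (n_populations %% 1 != 0 || n_per_population %% 1 != 0 ||
      n_snp %% 1 != 0 || n_ssr %% 1 != 0 || n_snp < 0 || n_ssr < 0) {
    stop("counts must be non-negative integers")
  }
  if (fst < 0 || fst >= 1) stop("fst must lie in [0, 1)")
  if (inbreeding_f < -1 || inbreeding_f > 1) stop("inbreeding_f must lie in [-1, 1]")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must lie in [0, 1)")
  if (n_ssr > 0) {
    naf_per_ssr_locus <- rep_len(naf_per_ssr_locus, n_ssr)
    ssr_allele_counts <- rep_len(as.integer(ssr_allele_counts), n_ssr)
    if (any(naf_per_ssr_locus < 0 | naf_per_ssr_locus >= 1)) {
      stop("null allele frequencies must lie in [0, 1)")
    }
    if (any(ssr_allele_counts < 2)) stop("SSR loci need at least 2 visible alleles")
  } else {
    naf_per_ssr_locus <- numeric()
    ssr_allele_counts <- integer()
  }
  structure(
    list(n_populations = as.integer(n_populations),
         n_per_population = as.integer(n_per_population),
         n_snp = as.integer(n_snp), n_ssr = as.integer(n_ssr),
         fst = fst, inbreeding_f = inbreeding_f,
         naf_per_ssr_locus = naf_per_ssr_locus,
         missing_rate = missing_rate,
         ssr_allele_counts = ssr_allele_counts,
         depth_mean = depth_mean,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Table-2-style motif pool for SSR metadata and fragment-length steps
ssr_motif_pool <- c("AAC", "AG", "CTGCA", "T", "AT", "ATG")

study_population_codes <- c("CAM", "GHN", "SR", "NR", "CWK", "SK",
                            "NPM", "CPM", "SPM", "SS", "NS", "SBH")

runif_simplex <- function(k) {
  x <- stats::rexp(k)
  x / sum(x)
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) { # numerically degenerate concentration: fall back to mean
    x <- alpha
  }
  x / sum(x)
}

# genotype draw for one population x locus under inbreeding f
draw_genotypes <- function(p, f, n) {
  k <- length(p)
  idx <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  probs <- ifelse(idx[, 1] == idx[, 2],
                  p[idx[, 1]]^2 + f * p[idx[, 1]] * (1 - p[idx[, 1]]),
                  2 * p[idx[, 1]] * p[idx[, 2]] * (1 - f))
  probs <- pmax(probs, 0)
  g <- sample.int(nrow(idx), n, replace = TRUE, prob = probs)
  cbind(idx[g, 1], idx[g, 2])
}

#' Simulate a multi-population genotype panel
#'
#' Draws a complete panel under the model of [simulation_config()], then
#' overlays SSR null alleles ([apply_null_alleles()]) and random missingness
#' ([apply_missingness()]) as configured. Deterministic under the config seed.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `matrix` (a [geno_matrix()]), `popmap`
#'   (a [pop_map]) and `truth` (a `sim_truth`: ancestral and per-population
#'   allele frequencies plus the config echo).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    np <- config$n_populations
    nind <- config$n_per_population
    codes <- if (np <= length(study_population_codes)) {
      study_population_codes[seq_len(np)]
    } else {
      c(study_population_codes, sprintf("P%02d", seq_len(np - length(study_population_codes)) + 12))
    }
    popmap <- pop_map(tibble::tibble(
      individual = sprintf("%s_%02d", rep(codes, each = nind), rep(seq_len(nind), np)),
      population = rep(codes, each = nind)
    ))

    loci <- simulate_loci(config)
    anc <- lapply(loci$alleles, function(reg) {
      p <- runif_simplex(length(reg))
      stats::setNames(p, reg)
    })
    popfreq <- lapply(codes, function(code) {
      lapply(anc, function(p) {
        if (config$fst == 0) p else {
          stats::setNames(rdirichlet1(p * (1 - config$fst) / config$fst), names(p))
        }
      })
    })
    names(popfreq) <- codes

    calls <- draw_panel_calls(loci, popfreq, popmap, config$inbreeding_f, config$depth_mean)
    gm <- geno_matrix(calls, loci = loci, individuals = popmap$individual)

    truth <- structure(
      list(ancestral_frequencies = stats::setNames(anc, loci$locus),
           population_frequencies = lapply(popfreq, function(pf) stats::setNames(pf, loci$locus)),
           config = config),
      class = "sim_truth"
    )

    if (config$n_ssr > 0 && any(config$naf_per_ssr_locus > 0)) {
      gm <- apply_null_alleles(gm, truth, seed = NULL)
    }
    if (config$missing_rate > 0) {
      gm <- apply_missingness(gm, config$missing_rate, seed = NULL)
    }
    list(matrix = gm, popmap = popmap, truth = truth)
  })
}

simulate_loci <- function(config) {
  snp_loci <- if (config$n_snp > 0) {
    regs <- lapply(seq_len(config$n_snp), function(i) sort(sample(c("A", "C", "G", "T"), 2)))
    tibble::tibble(
      locus = sprintf("SNP%04d", seq_len(config$n_snp)),
      kind = "SNP", alleles = regs,
      motif = NA_character_, size_range = NA_character_, ta = NA_real_
    )
  } else NULL
  ssr_loci <- if (config$n_ssr > 0) {
    motifs <- rep_len(ssr_motif_pool, config$n_ssr)
    regs <- vector("list", config$n_ssr)
    ranges <- character(config$n_ssr)
    for (j in seq_len(config$n_ssr)) {
      step <- nchar(motifs[j])
      start <- sample(100:180, 1)
      lens <- start + step * (seq_len(config$ssr_allele_counts[j]) - 1)
      regs[[j]] <- as.character(lens)
      ranges[j] <- paste0(min(lens), "-", max(lens))
    }
    tibble::tibble(
      locus = sprintf("SSR%02d", seq_len(config$n_ssr)),
      kind = "SSR", alleles = regs,
      motif = motifs, size_range = ranges,
      ta = sample(c(54, 56, 58), config$n_ssr, replace = TRUE)
    )
  } else NULL
  dplyr::bind_rows(snp_loci, ssr_loci)
}

draw_panel_calls <- function(loci, popfreq, popmap, f, depth_mean) {
  codes <- names(popfreq)
  out <- vector("list", length(codes) * nrow(loci))
  k <- 0L
  for (code in codes) {
    ids <- popmap$individual[popmap$population == code]
    for (j in seq_len(nrow(loci))) {
      p <- popfreq[[code]][[j]]
      pair <- draw_genotypes(p, f, length(ids))
      reg <- loci$alleles[[j]]
      depth <- if (!is.null(depth_mean) && loci$kind[j] == "SNP") {
        as.integer(stats::rpois(length(ids), depth_mean))
      } else NA_integer_
      k <- k + 1L
      out[[k]] <- tibble::tibble(
        individual = ids, locus = loci$locus[j],
        a1 = reg[pair[, 1]], a2 = reg[pair[, 2]], depth = depth
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Overlay null alleles on simulated SSR loci
#'
#' Inserts a null (non-amplifying) allele at frequency `r` into the generative
#' frequencies of each SSR locus: visible frequencies are rescaled by
#' `1 - r`, and each individual's genotype is redrawn from the augmented
#' frequency vector under the configured inbreeding. Visible/visible pairs
#' keep ordinary coding, visible/null pairs are recorded as homozygotes for
#' the visible allele (the mis-scoring that inflates apparent homozygosity),
#' and null/null pairs become missing calls.
#'
#' @param matrix A [geno_matrix()] from [simulate_panel()].
#' @param truth The matching `sim_truth`.
#' @param naf Per-SSR-locus null allele frequencies; defaults to the config's.
#' @param seed Optional seed; `NULL` draws from the current RNG stream.
#' @return The modified [geno_matrix()].
#' @export
apply_null_alleles <- function(matrix, truth, naf = NULL, seed = NULL) {
  stopifnot(inherits(matrix, "geno_matrix"), inherits(truth, "sim_truth"))
  cfg <- truth$config
  ssr_idx <- which(matrix$loci$kind == "SSR")
  naf <- naf %||% cfg$naf_per_ssr_locus
  naf <- rep_len(naf, length(ssr_idx))
  if (any(naf >= 1 | naf < 0)) stop("null allele frequencies must lie in [0, 1)")
  run <- function() {
    cm <- matrix$calls
    for (k in seq_along(ssr_idx)) {
      r <- naf[k]
      if (r == 0) next
      j <- ssr_idx[k]
      loc <- matrix$loci$locus[j]
      for (code in names(truth$population_frequencies)) {
        p_vis <- truth$population_frequencies[[code]][[loc]]
        p_aug <- c(p_vis * (1 - r), stats::setNames(r, ".null."))
        rows <- which(cm$locus == loc &
                        cm$individual %in% truth_pop_ids(truth, matrix, code))
        pair <- draw_genotypes(p_aug, cfg$inbreeding_f, length(rows))
        lab <- names(p_aug)
        null_i <- length(p_aug)
        a1 <- lab[pair[, 1]]
        a2 <- lab[pair[, 2]]
        both_null <- pair[, 1] == null_i & pair[, 2] == null_i
        one_null <- xor(pair[, 1] == null_i, pair[, 2] == null_i)
        vis <- ifelse(pair[, 1] == null_i, a2, a1)
        a1[one_null] <- vis[one_null]
        a2[one_null] <- vis[one_null]
        a1[both_null] <- NA_character_
        a2[both_null] <- NA_character_
        cm$a1[rows] <- a1
        cm$a2[rows] <- a2
      }
    }
    geno_matrix(cm, loci = matrix$loci, individuals = matrix$individuals)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

truth_pop_ids <- function(truth, matrix, code) {
  nind <- truth$config$n_per_population
  # individuals are named <code>_<i> by simulate_panel
  ids <- matrix$individuals[startsWith(matrix$individuals, paste0(code, "_"))]
  if (length(ids)) ids else matrix$individuals
}

#' Overlay random missingness
#'
#' Each called genotype is independently set to missing with probability
#' `rate`; already-missing calls are untouched.
#'
#' @param matrix A [geno_matrix()].
#' @param rate Missingness probability in `[0, 1)`.
#' @param seed Optional seed; `NULL` draws from the current RNG stream.
#' @return The modified [geno_matrix()].
#' @export
apply_missingness <- function(matrix, rate, seed = NULL) {
  stopifnot(inherits(matrix, "geno_matrix"))
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  if (rate == 0) return(matrix)
  run <- function() {
    cm <- matrix$calls
    called <- which(!is.na(cm$a1))
    drop <- called[stats::runif(length(called)) < rate]
    cm$a1[drop] <- NA_character_
    cm$a2[drop] <- NA_character_
    cm$depth[drop] <- NA_integer_
    geno_matrix(cm, loci = matrix$loci, individuals = matrix$individuals)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate an introduction design: two native sources, derived populations
#'
#' Emulates a biological-introduction scenario: two strongly diverged native
#' populations, and `n_derived` populations founded from the first native
#' source with only mild drift. Useful for checking that distance-based
#' clustering attaches the derived populations to their true source.
#'
#' @param n_snp,n_ssr Locus counts.
#' @param n_per_population Individuals per population.
#' @param n_derived Number of derived (introduced) populations.
#' @param fst_native Differentiation between the native sources.
#' @param fst_derived Drift of each derived population from its source.
#' @param seed RNG seed.
#' @return As [simulate_panel()]: list with `matrix`, `popmap`, `truth`. The
#'   first native population is coded `CAM` (the source), the second `GHN`,
#'   derived populations `D01`, `D02`, ...
#' @export
simulate_introduction_panel <- function(n_snp = 200, n_ssr = 8,
                                        n_per_population = 15, n_derived = 10,
                                        fst_native = 0.3, fst_derived = 0.02,
                                        seed = 1L) {
  stopifnot(fst_native > 0, fst_native < 1, fst_derived > 0, fst_derived < 1)
  cfg <- simulation_config(
    n_populations = 2 + n_derived, n_per_population = n_per_population,
    n_snp = n_snp, n_ssr = n_ssr, fst = fst_native, inbreeding_f = 0,
    naf_per_ssr_locus = 0, missing_rate = 0, depth_mean = NULL, seed = seed
  )
  withr::with_seed(seed, {
    codes <- c("CAM", "GHN", sprintf("D%02d", seq_len(n_derived)))
    popmap <- pop_map(tibble::tibble(
      individual = sprintf("%s_%02d", rep(codes, each = n_per_population),
                           rep(seq_len(n_per_population), length(codes))),
      population = rep(codes, each = n_per_population)
    ))
    loci <- simulate_loci(cfg)
    anc <- lapply(loci$alleles, function(reg) stats::setNames(runif_simplex(length(reg)), reg))
    bn <- function(p, fst) stats::setNames(rdirichlet1(p * (1 - fst) / fst), names(p))
    native <- lapply(c("CAM", "GHN"), function(code) lapply(anc, bn, fst = fst_native))
    names(native) <- c("CAM", "GHN")
    popfreq <- native
    for (d in sprintf("D%02d", seq_len(n_derived))) {
      popfreq[[d]] <- lapply(native$CAM, bn, fst = fst_derived)
    }
    calls <- draw_panel_calls(loci, popfreq, popmap, f = 0, depth_mean = NULL)
    gm <- geno_matrix(calls, loci = loci, individuals = popmap$individual)
    truth <- structure(
      list(ancestral_frequencies = stats::setNames(anc, loci$locus),
           population_frequencies = lapply(popfreq, function(pf) stats::setNames(pf, loci$locus)),
           config = cfg),
      class = "sim_truth"
    )
    list(matrix = gm, popmap = popmap, truth = truth)
  })
}

#' Generate contig fixtures with planted SSR motifs
#'
#' Builds random-background contigs each carrying one perfect tandem repeat at
#' a recorded 1-based position. Backgrounds are constrained so that no
#' unplanted perfect repeat reaches three unit copies for any unit length
#' 1-6 nt, and the characters flanking the planted repeat cannot extend it;
#' the returned truth table is therefore exactly the set of reportable hits
#' under the default [scan_ssr_motifs()] thresholds.
#'
#' @param n Number of contigs.
#' @param planted A data frame (or list coercible to one) with columns
#'   `motif` (1-6 nt over ACGT), `repeats`, `left`, `right` (flank lengths in
#'   bases, `>= 0`); rows are recycled to length `n`.
#' @param seed RNG seed.
#' @return A list with `sequences` (named character vector) and `truth`
#'   (tibble: contig, motif, repeats, start, end, 1-based inclusive).
#' @export
make_contig_fixtures <- function(n, planted, seed = 1L) {
  stopifnot(n >= 0)
  if (n == 0) {
    return(list(sequences = stats::setNames(character(), character()),
                truth = tibble::tibble(contig = character(), motif = character(),
                                       repeats = integer(), start = integer(),
                                       end = integer())))
  }
  planted <- tibble::as_tibble(planted)
  stopifnot(all(c("motif", "repeats", "left", "right") %in% names(planted)))
  if (any(planted$left < 0 | planted$right < 0)) stop("flank lengths must be >= 0")
  if (any(!grepl("^[ACGT]{1,6}$", planted$motif))) {
    stop("motifs must be 1-6 nt over ACGT")
  }
  idx <- rep_len(seq_len(nrow(planted)), n)
  withr::with_seed(seed, {
    seqs <- character(n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      row <- planted[idx[i], ]
      motif <- row$motif
      k <- nchar(motif)
      block <- strrep(motif, row$repeats)
      left <- safe_background(row$left,
                              forbid_last = substr(motif, k, k))
      right <- safe_background(row$right,
                               forbid_first = substr(motif, 1, 1))
      seqs[i] <- paste0(left, block, right)
      truth[[i]] <- tibble::tibble(
        contig = sprintf("contig%04d", i), motif = motif,
        repeats = as.integer(row$repeats),
        start = nchar(left) + 1L,
        end = nchar(left) + nchar(block)
      )
    }
    names(seqs) <- sprintf("contig%04d", seq_len(n))
    list(sequences = seqs, truth = dplyr::bind_rows(truth))
  })
}

# random DNA with no perfect tandem run reaching 3 unit copies (units 1-6 nt)
safe_background <- function(len, forbid_first = NULL, forbid_last = NULL) {
  if (len == 0) return("")
  bases <- c("A", "C", "G", "T")
  s <- character(len)
  for (i in seq_len(len)) {
    ok <- bases
    if (i == 1 && !is.null(forbid_first)) ok <- setdiff(ok, forbid_first)
    if (i == len && !is.null(forbid_last)) ok <- setdiff(ok, forbid_last)
    repeat {
      c0 <- sample(ok, 1)
      s[i] <- c0
      if (!creates_repeat(s, i)) break
      ok <- setdiff(ok, c0)
      if (!length(ok)) { # cannot avoid: back off one position (rare)
        s[i] <- sample(bases, 1)
        break
      }
    }
  }
  paste(s, collapse = "")
}

# would position i complete a 3-copy perfect repeat of some unit 1..6?
creates_repeat <- function(s, i) {
  for (k in 1:6) {
    if (i < 3 * k) next
    seg <- s[(i - 3 * k + 1):i]
    if (all(seg[1:(2 * k)] == seg[(k + 1):(3 * k)])) return(TRUE)
  }
  FALSE
}
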