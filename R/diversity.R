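#' Allele frequencies at one or all loci
#'
#' Counts alleles over called genotypes only (missing calls are excluded
#' entirely) and divides by twice the number of called genotypes.
#'
#' @param x A [geno_matrix()].
#' @param locus Optional locus name; default returns all loci.
#' @param scope `"GLOBAL"` or a population code from `popmap`.
#' @param popmap A [pop_map], required for population scopes.
#' @return A tibble with columns `locus`, `scope`, `allele`, `count`, `freq`,
#'   `n_called`. Loci with no called genotypes appear with zero rows.
#' @export
allele_frequencies <- function(x, locus = NULL, scope = "GLOBAL", popmap = NULL) {
  ids <- scope_individuals(x, scope, popmap)
  cm <- x$calls[x$calls$individual %in% ids & !is.na(x$calls$a1), ]
  if (!is.null(locus)) {
    stopifnot(locus %in% x$loci$locus)
    cm <- cm[cm$locus == locus, ]
  }
  long <- tibble::tibble(locus = rep(cm$locus, 2L), allele = c(cm$a1, cm$a2))
  n_called <- dplyr::count(cm, .data$locus, name = "n_called")
  out <- dplyr::count(long, .data$locus, .data$allele, name = "count") |>
    dplyr::left_join(n_called, by = "locus") |>
    dplyr::mutate(freq = .data$count / (2 * .data$n_called), scope = scope) |>
    dplyr::select("locus", "scope", "allele", "count", "freq", "n_called")
  out
}

#' Polymorphism information content (Botstein)
#'
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`, a marker-informativeness
#' index in `[0, 1]`; its bi-allelic maximum is 0.375 at p = 0.5.
#'
#' @param frequencies Numeric vector of allele frequencies summing to 1.
#' @return PIC value.
#' @export
pic <- function(frequencies) {
  check_simplex(frequencies)
  s2 <- sum(frequencies^2)
  s4 <- sum(frequencies^4)
  1 - s2 - (s2^2 - s4)
}

#' Expected heterozygosity
#'
#' Gene diversity `He = 1 - sum(p_i^2)`, without small-sample correction (see
#' the methods vignette for the rationale).
#'
#' @inheritParams pic
#' @return He value.
#' @export
expected_heterozygosity <- function(frequencies) {
  check_simplex(frequencies)
  1 - sum(frequencies^2)
}

check_simplex <- function(p) {
  if (!length(p)) stop("empty frequency vector")
  if (any(p < -1e-12)) stop("negative allele frequency")
  if (abs(sum(p) - 1) > 1e-6) stop("allele frequencies must sum to 1")
  invisible(p)
}

#' Observed heterozygosity
#'
#' Fraction of called genotypes that are heterozygous; `NA` when no genotype
#' is called in scope.
#'
#' @inheritParams allele_frequencies
#' @param locus Locus name.
#' @return Proportion in `[0, 1]`, or `NA`.
#' @export
observed_heterozygosity <- function(x, locus, scope = "GLOBAL", popmap = NULL) {
  ids <- scope_individuals(x, scope, popmap)
  cm <- x$calls[x$calls$individual %in% ids & x$calls$locus == locus & !is.na(x$calls$a1), ]
  if (!nrow(cm)) return(NA_real_)
  mean(cm$a1 != cm$a2)
}

#' Wright's inbreeding coefficient
#'
#' `Fis = 1 - Ho / He`; positive values indicate a heterozygote deficit,
#' negative values an excess. Undefined (`NA`) at monomorphic loci (He = 0).
#'
#' @param he,ho Expected and observed heterozygosity.
#' @return Fis, or `NA` when `he` is 0.
#' @export
fis <- function(he, ho) {
  stopifnot(all(he >= 0, na.rm = TRUE))
  ifelse(is.na(he) | he == 0, NA_real_, 1 - ho / he)
}

#' Per-locus diversity summary
#'
#' Computes, per locus and scope, the standard marker-characterisation block:
#' number of called genotypes, major allele frequency (MAF), number of
#' observed alleles (N_A) and distinct genotypes (N_G), expected and observed
#' heterozygosity, PIC, and Fis (NA-flagged when He = 0).
#'
#' @inheritParams allele_frequencies
#' @return A tibble with one row per locus: `locus`, `kind`, `scope`,
#'   `n_called`, `maf`, `n_alleles`, `n_genotypes`, `he`, `ho`, `pic`, `fis`.
#'   Loci with no called genotypes carry `n_called = 0` and `NA` statistics.
#' @export
locus_summary <- function(x, locus = NULL, scope = "GLOBAL", popmap = NULL) {
  ids <- scope_individuals(x, scope, popmap)
  cm <- x$calls[x$calls$individual %in% ids, ]
  target <- if (is.null(locus)) x$loci$locus else {
    stopifnot(all(locus %in% x$loci$locus))
    locus
  }
  cm <- cm[cm$locus %in% target, ]
  called <- cm[!is.na(cm$a1), ]

  freq_stats <- if (nrow(called) == 0) {
    tibble::tibble(locus = character(), maf = numeric(), n_alleles = integer(),
                   he = numeric(), pic = numeric())
  } else {
    called |>
      tidyr::pivot_longer(c("a1", "a2"), values_to = "allele") |>
      dplyr::count(.data$locus, .data$allele) |>
      dplyr::group_by(.data$locus) |>
      dplyr::summarise(
        maf = max(.data$n) / sum(.data$n),
        n_alleles = dplyr::n_distinct(.data$allele),
        he = 1 - sum((.data$n / sum(.data$n))^2),
        pic = pic(.data$n / sum(.data$n))
      )
  }
  geno_stats <- called |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(
      n_called = dplyr::n(),
      n_genotypes = dplyr::n_distinct(paste(.data$a1, .data$a2)),
      ho = mean(.data$a1 != .data$a2)
    )
  out <- tibble::tibble(locus = target) |>
    dplyr::left_join(x$loci[c("locus", "kind")], by = "locus") |>
    dplyr::left_join(geno_stats, by = "locus") |>
    dplyr::left_join(freq_stats, by = "locus") |>
    dplyr::mutate(
      scope = scope,
      n_called = dplyr::coalesce(.data$n_called, 0L),
      fis = fis(.data$he, .data$ho)
    ) |>
    dplyr::select("locus", "kind", "scope", "n_called", "maf", "n_alleles",
                  "n_genotypes", "he", "ho", "pic", "fis")
  out
}

#' Per-population diversity summary table
#'
#' For each population: N individuals and the unweighted means over loci (with
#' at least one called genotype) of MAF, N_A, He, Ho and PIC; Fis is the
#' unweighted mean of defined per-locus Fis values (loci with He > 0), not the
#' ratio of mean Ho to mean He. With `adjust_null = TRUE`, an `adjusted_fis`
#' column re-estimates Fis after Brookfield-1 null-allele correction of each
#' locus within each population (see [adjusted_fis()]). A final `Mean` row
#' holds the unweighted column means over populations.
#'
#' @param x A [geno_matrix()].
#' @param popmap A [pop_map].
#' @param adjust_null Add the null-allele-adjusted Fis column?
#' @param mean_row Append the grand `Mean` row?
#' @return A tibble, one row per population (plus `Mean`): `population`, `n`,
#'   `maf`, `n_alleles`, `he`, `ho`, `pic`, `fis` (and `adjusted_fis`).
#' @export
population_summary_table <- function(x, popmap, adjust_null = FALSE, mean_row = TRUE) {
  codes <- intersect(population_codes(popmap), unique(popmap$population[popmap$individual %in% x$individuals]))
  rows <- purrr::map(codes, function(code) {
    ls <- locus_summary(x, scope = code, popmap = popmap)
    used <- ls[ls$n_called > 0, ]
    row <- tibble::tibble(
      population = code,
      n = length(scope_individuals(x, code, popmap)),
      maf = mean(used$maf),
      n_alleles = mean(used$n_alleles),
      he = mean(used$he),
      ho = mean(used$ho),
      pic = mean(used$pic),
      fis = mean(used$fis[!is.na(used$fis)])
    )
    if (adjust_null) {
      adj <- adjusted_fis(used$he, used$ho)
      row$adjusted_fis <- mean(adj$fis_adj[!is.na(adj$fis_adj)])
    }
    row
  })
  out <- dplyr::bind_rows(rows)
  if (mean_row && nrow(out) > 1) {
    m <- dplyr::summarise(out, dplyr::across(dplyr::where(is.numeric), mean))
    m$population <- "Mean"
    m$n <- NA_integer_
    out <- dplyr::bind_rows(out, m)
  }
  out
}

#' Monte-Carlo exact test for Hardy-Weinberg equilibrium
#'
#' Pools the `2n` called alleles at the locus and re-pairs them uniformly at
#' random `n_permutations` times; the statistic is the heterozygote count.
#' The two-sided p-value is `2 * min(tail fractions)` capped at 1, with the
#' observed panel counted in its own tail (add-one smoothing).
#'
#' @inheritParams observed_heterozygosity
#' @param n_permutations Number of random re-pairings.
#' @param seed Optional seed; `NULL` uses the current stream.
#' @return p-value, or `NA` when fewer than 2 genotypes are called or the
#'   locus is monomorphic in scope.
#' @export
hwe_test <- function(x, locus, scope = "GLOBAL", popmap = NULL,
                     n_permutations = 10000, seed = NULL) {
  ids <- scope_individuals(x, scope, popmap)
  cm <- x$calls[x$calls$individual %in% ids & x$calls$locus == locus & !is.na(x$calls$a1), ]
  n <- nrow(cm)
  if (n < 2) return(NA_real_)
  alleles <- c(cm$a1, cm$a2)
  if (length(unique(alleles)) < 2) return(NA_real_)
  obs <- sum(cm$a1 != cm$a2)
  run <- function() {
    het <- vapply(seq_len(n_permutations), function(i) {
      perm <- sample(alleles)
      sum(perm[seq_len(n)] != perm[n + seq_len(n)])
    }, numeric(1))
    lo <- (sum(het <= obs) + 1) / (n_permutations + 1)
    hi <- (sum(het >= obs) + 1) / (n_permutations + 1)
    min(1, 2 * min(lo, hi))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Linkage disequilibrium between two loci
#'
#' Each locus is collapsed to its major-allele dosage (0/1/2) over the
#' individuals called at both loci; `r^2` is the squared Pearson correlation
#' of the two dosage vectors. This single-number collapse is the convention
#' used for multi-allelic SSR pairs (logged per pair in pipeline reports).
#'
#' @inheritParams observed_heterozygosity
#' @param locus_a,locus_b Locus names.
#' @return `r^2` in `[0, 1]`, or `NA` when either dosage is constant or fewer
#'   than 2 individuals are called at both loci.
#' @export
ld_r2 <- function(x, locus_a, locus_b, scope = "GLOBAL", popmap = NULL) {
  ids <- scope_individuals(x, scope, popmap)
  da <- major_dosage(x, locus_a, ids)
  db <- major_dosage(x, locus_b, ids)
  both <- !is.na(da) & !is.na(db)
  if (sum(both) < 2) return(NA_real_)
  da <- da[both]; db <- db[both]
  if (stats::sd(da) == 0 || stats::sd(db) == 0) return(NA_real_)
  stats::cor(da, db)^2
}

major_dosage <- function(x, locus, ids) {
  cm <- x$calls[x$calls$individual %in% ids & x$calls$locus == locus, ]
  cm <- cm[match(ids, cm$individual), ]
  called <- !is.na(cm$a1)
  if (!any(called)) return(rep(NA_real_, length(ids)))
  tab <- sort(table(c(cm$a1[called], cm$a2[called])), decreasing = TRUE)
  major <- names(tab)[1]
  ifelse(called, (cm$a1 == major) + (cm$a2 == major), NA_real_)
}
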