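# Brute-force oracles and tiny fixture builders shared across tests.

# Naive per-locus statistics from a list of genotype pairs (each a character
# vector of length 2, or NULL for missing), computed by explicit loops.
bf_locus_stats <- function(genos) {
  called <- Filter(Negate(is.null), genos)
  n <- length(called)
  if (n == 0) {
    return(list(n_called = 0L, maf = NA, n_alleles = NA, n_genotypes = NA,
                he = NA, ho = NA, pic = NA, fis = NA))
  }
  alleles <- unlist(called)
  tab <- table(alleles)
  p <- as.numeric(tab) / sum(tab)
  het <- 0
  seen <- character()
  for (g in called) {
    gs <- paste(sort(g), collapse = "/")
    seen <- union(seen, gs)
    if (g[1] != g[2]) het <- het + 1
  }
  s <- 0
  for (i in seq_along(p)) {
    for (j in seq_along(p)) {
      if (i < j) s <- s + 2 * p[i]^2 * p[j]^2
    }
  }
  he <- 1 - sum(p^2)
  ho <- het / n
  list(
    n_called = n,
    maf = max(p),
    n_alleles = length(p),
    n_genotypes = length(seen),
    he = he,
    ho = ho,
    pic = 1 - sum(p^2) - s,
    fis = if (he == 0) NA else 1 - ho / he
  )
}

# genotype list for one locus/scope from a geno_matrix, for bf_locus_stats
genotype_list <- function(gm, locus, ids = individuals(gm)) {
  cm <- calls(gm)
  cm <- cm[cm$locus == locus & cm$individual %in% ids, ]
  lapply(seq_len(nrow(cm)), function(i) {
    if (is.na(cm$a1[i])) NULL else c(cm$a1[i], cm$a2[i])
  })
}

# Regular-expression SSR oracle: maximal perfect tandem repeats per unit
# length via greedy backreference matching, with the same reporting rules
# (primitive units only; containment suppression) applied independently.
regex_ssr_oracle <- function(s, min_repeats = c(`1` = 10, `2` = 5, `3` = 5,
                                                `4` = 4, `5` = 4, `6` = 4)) {
  hits <- list()
  for (k in as.integer(names(min_repeats))) {
    minrep <- min_repeats[[as.character(k)]]
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", k, minrep - 1)
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1) next
    lens <- attr(m, "match.length")
    for (i in seq_along(m)) {
      start <- m[i]
      motif <- substr(s, start, start + k - 1)
      primitive <- TRUE
      for (d in seq_len(k - 1)) {
        if (k %% d == 0 && strrep(substr(motif, 1, d), k / d) == motif) primitive <- FALSE
      }
      if (!primitive) next
      repeats <- lens[i] %/% k
      hits[[length(hits) + 1]] <- data.frame(
        motif = motif, repeats = repeats,
        start = start, end = start + repeats * k - 1
      )
    }
  }
  if (!length(hits)) {
    return(data.frame(motif = character(), repeats = integer(),
                      start = integer(), end = integer()))
  }
  res <- do.call(rbind, hits)
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    ki <- nchar(res$motif[i])
    if (any(nchar(res$motif) < ki & res$start <= res$start[i] & res$end >= res$end[i])) {
      keep[i] <- FALSE
    }
  }
  res <- res[keep, ]
  res[order(res$start, nchar(res$motif)), , drop = FALSE]
}

# A tiny mixed panel built by hand: 4 individuals, 1 SNP + 1 SSR locus.
toy_panel <- function() {
  calls <- tibble::tibble(
    individual = rep(c("w1", "w2", "w3", "w4"), times = 2),
    locus = rep(c("snp1", "ssr1"), each = 4),
    a1 = c("A", "A", "A", NA, "124", "124", "136", "124"),
    a2 = c("A", "T", "T", NA, "136", "124", "136", "124"),
    depth = c(20L, 9L, 30L, NA, NA, NA, NA, NA)
  )
  geno_matrix(calls)
}

expect_same_matrix <- function(a, b) {
  expect_identical(individuals(a), individuals(b))
  expect_identical(loci(a)$locus, loci(b)$locus)
  ca <- calls(a)[order(calls(a)$individual, calls(a)$locus), ]
  cb <- calls(b)[order(calls(b)$individual, calls(b)$locus), ]
  expect_identical(ca$a1, cb$a1)
  expect_identical(ca$a2, cb$a2)
}
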