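#' Brookfield-1 null allele frequency estimator
#'
#' `r = (He - Ho) / (1 + He)`, clamped at 0 when there is no heterozygote
#' deficit (`Ho >= He`): heterozygote excess is read as absence of
#' null-allele evidence, not as a negative frequency.
#'
#' @param he_obs,ho_obs Expected and observed heterozygosity over called
#'   genotypes, both in `[0, 1]`. Vectorised.
#' @return Estimated null allele frequency in `[0, 1)`.
#' @export
brookfield1 <- function(he_obs, ho_obs) {
  stopifnot(all(he_obs >= 0 & he_obs <= 1, na.rm = TRUE),
            all(ho_obs >= 0 & ho_obs <= 1, na.rm = TRUE))
  pmax(0, (he_obs - ho_obs) / (1 + he_obs))
}

#' Classify a null allele frequency
#'
#' Classes: negligible (`NAF < 0.05`), moderate (`0.05 <= NAF < 0.20`),
#' large (`NAF >= 0.20`).
#'
#' @param naf Null allele frequency (vectorised).
#' @return Factor with levels `negligible`, `moderate`, `large`.
#' @export
classify_naf <- function(naf) {
  stopifnot(all(naf >= 0 & naf < 1, na.rm = TRUE))
  cut(naf, breaks = c(-Inf, 0.05, 0.20, Inf),
      labels = c("negligible", "moderate", "large"), right = FALSE)
}

#' Correct visible allele frequencies for a null allele
#'
#' Rescales each visible allele frequency by `1 - r` and appends a `NULL`
#' pseudo-allele at frequency `r`; the result sums to 1.
#'
#' @param frequencies Named numeric vector of visible allele frequencies
#'   summing to 1.
#' @param naf Null allele frequency `r` in `[0, 1)`.
#' @return Named numeric vector including the `NULL` entry.
#' @export
adjust_frequencies <- function(frequencies, naf) {
  check_simplex(frequencies)
  if (naf < 0 || naf >= 1) stop("null allele frequency must lie in [0, 1)")
  out <- c(frequencies * (1 - naf), naf)
  names(out) <- c(names(frequencies) %||% as.character(seq_along(frequencies)), "NULL")
  out
}

#' Null-allele-adjusted heterozygosity and Fis
#'
#' From apparent (called-genotype) He and Ho, estimates the null allele
#' frequency `r` (Brookfield-1, unless supplied), then re-expresses both
#' heterozygosities on the all-individuals scale of the corrected frequency
#' spectrum:
#' \itemize{
#'   \item `he_adj = 1 - (1 - r)^2 (1 - he_obs) - r^2` (expected
#'     heterozygosity of the corrected spectrum: visible alleles rescaled by
#'     `1 - r` plus the null pseudo-allele),
#'   \item `ho_adj = ho_obs (1 - r^2) + 2 r (1 - r)` (rescales the
#'     called-genotype heterozygosity by the called fraction `1 - r^2` and
#'     restores the visible-by-null heterozygotes that were mis-scored as
#'     homozygotes),
#'   \item `fis_adj = 1 - ho_adj / he_adj`.
#' }
#' When the true `r` is supplied, the adjustment is exact for a
#' random-mating population: `fis_adj` is identically 0 (the algebraic
#' identity is property-tested). Under Brookfield-1 estimation the correction
#' is approximate and should be read as a bias reduction, not exact recovery.
#'
#' @inheritParams brookfield1
#' @param naf Optional known null allele frequency; default estimates it via
#'   [brookfield1()]. Vectorised.
#' @return A tibble with columns `naf`, `naf_class`, `he_adj`, `ho_adj`,
#'   `fis_adj` (`NA` where `he_adj` is 0 or inputs are `NA`).
#' @export
adjusted_fis <- function(he_obs, ho_obs, naf = NULL) {
  r <- if (is.null(naf)) brookfield1(he_obs, ho_obs) else {
    if (any(naf < 0 | naf >= 1, na.rm = TRUE)) stop("naf must lie in [0, 1)")
    rep_len(naf, length(he_obs))
  }
  he_adj <- 1 - (1 - r)^2 * (1 - he_obs) - r^2
  ho_adj <- ho_obs * (1 - r^2) + 2 * r * (1 - r)
  tibble::tibble(
    naf = r,
    naf_class = classify_naf(r),
    he_adj = he_adj,
    ho_adj = ho_adj,
    fis_adj = fis(he_adj, ho_adj)
  )
}

#' Per-locus null-allele estimates for a panel
#'
#' Runs the Brookfield-1 chain over every SSR locus of a genotype matrix at
#' one scope: apparent He/Ho over called genotypes, estimated NAF with class,
#' corrected frequency spectrum, and adjusted He/Ho/Fis.
#'
#' @inheritParams allele_frequencies
#' @return A tibble, one row per SSR locus: `locus`, `scope`, `he_obs`,
#'   `ho_obs`, `fis_raw`, `naf`, `naf_class`, `he_adj`, `ho_adj`, `fis_adj`,
#'   plus `adjusted_frequencies` (list column of named vectors including the
#'   `NULL` pseudo-allele).
#' @export
null_allele_table <- function(x, scope = "GLOBAL", popmap = NULL) {
  ssr <- x$loci$locus[x$loci$kind == "SSR"]
  if (!length(ssr)) stop("the panel has no SSR loci")
  ls <- locus_summary(x, locus = ssr, scope = scope, popmap = popmap)
  adj <- adjusted_fis(ls$he, ls$ho)
  freqs <- allele_frequencies(x, scope = scope, popmap = popmap)
  adj_freq <- purrr::map2(ls$locus, adj$naf, function(loc, r) {
    f <- freqs[freqs$locus == loc, ]
    if (!nrow(f) || is.na(r)) return(NULL)
    adjust_frequencies(stats::setNames(f$freq, f$allele), r)
  })
  tibble::tibble(
    locus = ls$locus, scope = scope,
    he_obs = ls$he, ho_obs = ls$ho, fis_raw = ls$fis,
    naf = adj$naf, naf_class = adj$naf_class,
    he_adj = adj$he_adj, ho_adj = adj$ho_adj, fis_adj = adj$fis_adj,
    adjusted_frequencies = adj_freq
  )
}
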