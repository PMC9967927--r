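#' Hard-filter variants by depth, minor allele frequency and call count
#'
#' The discovery-stage re-filter applied to freshly called variants, in two
#' stages. First, calls with read depth below `min_depth` are set to missing
#' (loci with no depth information skip this criterion, with a warning).
#' Then a locus is removed when its minor allele frequency is not strictly
#' above `min_maf` (the combined frequency of all non-major alleles, which
#' for a bi-allelic locus is the minor allele's frequency), or when fewer
#' than `min_called` of the `total` samples carry a called genotype.
#'
#' @param x A [geno_matrix()].
#' @param min_depth Minimum supporting reads per call (default 8).
#' @param min_maf Strict lower bound on minor allele frequency (default 0.05;
#'   a locus at exactly 0.05 is removed).
#' @param min_called Minimum number of called genotypes (default 32).
#' @param total Total sample count the call criterion refers to (default the
#'   number of individuals in `x`).
#' @return A list with `matrix` (the filtered [geno_matrix()]) and `report`
#'   (a `filter_report`).
#' @export
filter_variants <- function(x, min_depth = 8, min_maf = 0.05,
                            min_called = 32, total = n_individuals(x)) {
  if (min_called > total) stop("min_called (", min_called, ") exceeds total (", total, ")")
  cm <- x$calls
  has_depth <- !is.na(cm$depth)
  loci_with_depth <- unique(cm$locus[has_depth])
  no_depth <- setdiff(x$loci$locus, loci_with_depth)
  if (length(no_depth) && length(loci_with_depth)) {
    warning("no depth information for ", length(no_depth),
            " locus/loci; depth criterion skipped there")
  } else if (!length(loci_with_depth)) {
    warning("no depth information in panel; depth criterion skipped")
  }
  low <- has_depth & cm$depth < min_depth
  cm$a1[low] <- NA_character_
  cm$a2[low] <- NA_character_
  cm$depth[low] <- NA_integer_
  gm <- geno_matrix(cm, loci = x$loci, individuals = x$individuals)

  ls <- locus_summary(gm)
  # minor allele frequency from exact allele counts (avoids 1 - maf rounding)
  af <- allele_frequencies(gm)
  minor_tbl <- if (nrow(af) == 0) {
    tibble::tibble(locus = character(), minor = numeric())
  } else {
    dplyr::summarise(
      dplyr::group_by(af, .data$locus),
      minor = (sum(.data$count) - max(.data$count)) / sum(.data$count)
    )
  }
  minor <- minor_tbl$minor[match(ls$locus, minor_tbl$locus)]
  remove_maf <- !is.na(minor) & minor <= min_maf
  remove_maf[is.na(minor)] <- TRUE # nothing called: no allele passes
  remove_called <- ls$n_called < min_called
  removed <- remove_maf | remove_called
  reason <- dplyr::case_when(
    remove_maf & remove_called ~ "minor allele frequency and call count",
    remove_maf ~ paste0("minor allele frequency <= ", min_maf),
    remove_called ~ paste0("called in fewer than ", min_called, " of ", total, " samples"),
    TRUE ~ NA_character_
  )
  report <- filter_report("variant_hard_filter", ls$locus, removed, reason)
  keep <- ls$locus[!removed]
  out <- if (length(keep)) select_loci(gm, keep) else empty_panel(gm)
  list(matrix = out, report = report)
}

#' Retain loci above a call-rate threshold
#'
#' A locus is retained iff `called / total > threshold` (strict inequality:
#' at a 0.95 threshold, a locus called in exactly 95% of individuals is
#' removed). The limiting threshold 1 keeps only loci with no missing call.
#'
#' @param x A [geno_matrix()].
#' @param threshold Call-rate threshold in `(0, 1]`.
#' @return A list with `matrix` and `report`, as [filter_variants()].
#' @export
filter_call_rate <- function(x, threshold = 0.95) {
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  total <- n_individuals(x)
  ls <- locus_summary(x)
  rate <- ls$n_called / total
  removed <- if (threshold == 1) rate < 1 else !(rate > threshold)
  reason <- ifelse(removed,
                   sprintf("call rate %.4f <= %.4f", rate, threshold),
                   NA_character_)
  report <- filter_report(sprintf("call_rate_%.2f", threshold), ls$locus, removed, reason)
  keep <- ls$locus[!removed]
  out <- if (length(keep)) select_loci(x, keep) else empty_panel(x)
  list(matrix = out, report = report)
}

empty_panel <- function(x) {
  geno_matrix(x$calls[0, ], loci = x$loci[0, ], individuals = x$individuals)
}

filter_report <- function(stage, loci_in, removed, reason) {
  structure(
    list(stage = stage,
         n_in = length(loci_in),
         n_out = sum(!removed),
         removed = tibble::tibble(locus = loci_in[removed],
                                  reason = reason[removed])),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report> stage '", x$stage, "': ", x$n_in, " loci in, ",
      x$n_out, " retained, ", nrow(x$removed), " removed\n", sep = "")
  invisible(x)
}

#' Check flanking-sequence availability around a variant
#'
#' A variant on a sequencing tag is usable for probe design only when at
#' least `min_flank` bases flank it on both sides: true iff
#' `(snp_position - 1) >= min_flank` and
#' `(tag_length - snp_position) >= min_flank`. Vectorised; positions are
#' 1-based.
#'
#' @param tag_length Tag length in bases.
#' @param snp_position 1-based variant position on the tag.
#' @param min_flank Minimum flank length (default 75).
#' @return Logical.
#' @export
check_flanks <- function(tag_length, snp_position, min_flank = 75) {
  stopifnot(all(snp_position >= 1), all(snp_position <= tag_length))
  (snp_position - 1) >= min_flank & (tag_length - snp_position) >= min_flank
}

#' Scan sequences for perfect tandem repeats (SSR motifs)
#'
#' Finds all maximal perfect tandem repeats with unit length 1-6 nt meeting
#' a per-unit-length minimum copy number. Each run is reported once, under
#' its leftmost phase, with the span truncated to whole copies; runs whose
#' unit is itself periodic (e.g. `TT`, `ATAT`) are suppressed, as are hits
#' wholly contained in a longer reported hit with a shorter unit — so a
#' `(T)12` run is never additionally reported as `(TT)6`. `N` bases never
#' occur inside a reported repeat.
#'
#' @param sequence A named character vector of sequences over ACGTN (a single
#'   unnamed sequence is accepted).
#' @param min_repeats Named integer vector: minimum copies per unit length.
#' @return A tibble with columns `contig`, `motif`, `repeats`, `start`,
#'   `end` (1-based inclusive), `left_flank`, `right_flank` (distances to the
#'   sequence ends in bases).
#' @export
scan_ssr_motifs <- function(sequence,
                            min_repeats = c(`1` = 10, `2` = 5, `3` = 5,
                                            `4` = 4, `5` = 4, `6` = 4)) {
  if (is.null(names(sequence))) {
    names(sequence) <- if (length(sequence) == 1) "seq1" else
      paste0("seq", seq_along(sequence))
  }
  out <- purrr::imap(sequence, function(s, nm) {
    hits <- scan_one_sequence(toupper(s), min_repeats)
    if (nrow(hits)) hits$contig <- nm
    hits
  })
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) {
    return(tibble::tibble(contig = character(), motif = character(),
                          repeats = integer(), start = integer(), end = integer(),
                          left_flank = integer(), right_flank = integer()))
  }
  dplyr::select(res, "contig", "motif", "repeats", "start", "end",
                "left_flank", "right_flank")
}

scan_one_sequence <- function(s, min_repeats) {
  empty <- tibble::tibble(motif = character(), repeats = integer(),
                          start = integer(), end = integer(),
                          left_flank = integer(), right_flank = integer(),
                          contig = character())
  n <- nchar(s)
  if (n == 0) return(empty)
  if (grepl("[^ACGTN]", s)) stop("sequence contains characters outside ACGTN")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  hits <- list()
  for (k in as.integer(names(min_repeats))) {
    minrep <- min_repeats[[as.character(k)]]
    if (n < k * minrep) next
    eq <- chars[seq_len(n - k)] == chars[(k + 1):n] & chars[seq_len(n - k)] != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (ri in which(r$values)) {
      span <- r$lengths[ri] + k           # length of the periodic region
      start <- starts[ri]
      repeats <- span %/% k
      if (repeats < minrep) next
      motif <- substr(s, start, start + k - 1)
      if (is_periodic_unit(motif)) next   # covered by the shorter unit
      end <- start + repeats * k - 1
      hits[[length(hits) + 1]] <- tibble::tibble(
        motif = motif, repeats = as.integer(repeats),
        start = as.integer(start), end = as.integer(end)
      )
    }
  }
  if (!length(hits)) return(empty)
  res <- dplyr::bind_rows(hits)
  # suppress hits wholly inside a longer reported hit with a shorter unit
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    ki <- nchar(res$motif[i])
    inside <- which(nchar(res$motif) < ki &
                      res$start <= res$start[i] & res$end >= res$end[i])
    if (length(inside)) keep[i] <- FALSE
  }
  res <- res[keep, ]
  res$left_flank <- res$start - 1L
  res$right_flank <- n - res$end
  res$contig <- NA_character_
  res[order(res$start, nchar(res$motif)), ]
}

# is the unit itself a whole number of copies of a shorter unit?
is_periodic_unit <- function(motif) {
  k <- nchar(motif)
  if (k == 1) return(FALSE)
  for (d in seq_len(k - 1)) {
    if (k %% d == 0 && strrep(substr(motif, 1, d), k / d) == motif) return(TRUE)
  }
  FALSE
}

#' Melting temperature by the GC-fraction approximation
#'
#' `Tm = 64.9 + 41 (GC - 16.4) / length` in degrees C, where `GC` is the
#' G+C count. A deliberately simple, fixed formula used for reproducible
#' constraint screening; it is not a nearest-neighbour thermodynamic model
#' and is not expected to match commercial primer-design tools (see the
#' methods vignette).
#'
#' @param primer Primer sequence over ACGT (vectorised).
#' @return Tm in degrees C.
#' @export
primer_tm <- function(primer) {
  stopifnot(all(grepl("^[ACGT]+$", toupper(primer))))
  up <- toupper(primer)
  gc <- nchar(gsub("[AT]", "", up))
  len <- nchar(up)
  64.9 + 41 * (gc - 16.4) / len
}

#' Screen a primer pair against design constraints
#'
#' Checks each constraint independently and returns a one-row assessment:
#' primer lengths within `[18, 23]` nt, product length within `[100, 280]`
#' bp, each Tm within `[54, 60]` degrees C (by [primer_tm()]) and Tm
#' difference at most 0.5 degrees C — all ranges inclusive. The verdict is
#' `"fail"` iff any constraint is violated, and the violations are listed.
#'
#' @param forward,reverse Primer sequences over ACGT.
#' @param product_length Expected PCR product length in bp.
#' @param constraints Named list overriding the defaults: `len_min`,
#'   `len_max`, `product_min`, `product_max`, `tm_min`, `tm_max`,
#'   `tm_delta_max`.
#' @return A one-row tibble: `forward`, `reverse`, `len_forward`,
#'   `len_reverse`, `tm_forward`, `tm_reverse`, `tm_delta`, `product_length`,
#'   `verdict`, `violations` (list column of character).
#' @export
evaluate_primer_pair <- function(forward, reverse, product_length,
                                 constraints = list()) {
  cons <- utils::modifyList(
    list(len_min = 18, len_max = 23, product_min = 100, product_max = 280,
         tm_min = 54, tm_max = 60, tm_delta_max = 0.5),
    constraints
  )
  tm_f <- primer_tm(forward)
  tm_r <- primer_tm(reverse)
  len_f <- nchar(forward)
  len_r <- nchar(reverse)
  delta <- abs(tm_f - tm_r)
  viol <- character()
  if (len_f < cons$len_min || len_f > cons$len_max) {
    viol <- c(viol, sprintf("forward length %d outside [%d, %d]", len_f, cons$len_min, cons$len_max))
  }
  if (len_r < cons$len_min || len_r > cons$len_max) {
    viol <- c(viol, sprintf("reverse length %d outside [%d, %d]", len_r, cons$len_min, cons$len_max))
  }
  if (product_length < cons$product_min || product_length > cons$product_max) {
    viol <- c(viol, sprintf("product length %d outside [%d, %d]",
                            product_length, cons$product_min, cons$product_max))
  }
  if (tm_f < cons$tm_min || tm_f > cons$tm_max) {
    viol <- c(viol, sprintf("forward Tm %.2f outside [%.1f, %.1f]", tm_f, cons$tm_min, cons$tm_max))
  }
  if (tm_r < cons$tm_min || tm_r > cons$tm_max) {
    viol <- c(viol, sprintf("reverse Tm %.2f outside [%.1f, %.1f]", tm_r, cons$tm_min, cons$tm_max))
  }
  if (delta > cons$tm_delta_max) {
    viol <- c(viol, sprintf("Tm difference %.2f exceeds %.2f", delta, cons$tm_delta_max))
  }
  tibble::tibble(
    forward = forward, reverse = reverse,
    len_forward = len_f, len_reverse = len_r,
    tm_forward = tm_f, tm_reverse = tm_r, tm_delta = delta,
    product_length = as.integer(product_length),
    verdict = if (length(viol)) "fail" else "pass",
    violations = list(viol)
  )
}
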