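#' Construct a genotype matrix
#'
#' The central container of the package: a complete individuals-by-loci grid of
#' unordered co-dominant allele pairs. SNP alleles are single bases (A/C/G/T);
#' SSR (microsatellite) alleles are PCR fragment lengths in base pairs, stored
#' as integer-valued tokens. A missing genotype is atomic: either both alleles
#' are present or the call is missing, never a half call.
#'
#' @param calls A data frame with columns `individual`, `locus`, `a1`, `a2`
#'   (character allele labels, both `NA` for a missing call) and optionally
#'   `depth` (non-negative integer read depth, `NA` where unknown or missing).
#'   Cells absent from `calls` are filled in as missing so the grid is always
#'   complete.
#' @param loci Optional data frame describing loci: columns `locus`, `kind`
#'   (`"SNP"` or `"SSR"`), and optionally `alleles` (list column: the allele
#'   registry), `motif`, `size_range`, `ta` (annealing temperature, deg C).
#'   When omitted, loci are inferred from `calls` with registries equal to the
#'   observed alleles.
#' @param individuals Optional character vector fixing individual order;
#'   defaults to order of first appearance in `calls`.
#'
#' @return An object of class `geno_matrix`: a list with elements `calls`
#'   (tibble), `loci` (tibble) and `individuals` (character).
#'
#' @details Every allele observed in `calls` must appear in the locus registry
#' (registries are extended automatically when inferred). A SNP locus with more
#' than two registry alleles is accepted with a warning: the panels this
#' package targets are bi-allelic, but multi-allelic records are not an error.
#'
#' @examples
#' calls <- tibble::tibble(
#'   individual = c("w1", "w2"), locus = "L1",
#'   a1 = c("A", "A"), a2 = c("A", "T")
#' )
#' gm <- geno_matrix(calls)
#' n_individuals(gm)
#' @export
geno_matrix <- function(calls, loci = NULL, individuals = NULL) {
  calls <- tibble::as_tibble(calls)
  stopifnot(all(c("individual", "locus", "a1", "a2") %in% names(calls)))
  if (!"depth" %in% names(calls)) calls$depth <- NA_integer_
  calls$individual <- as.character(calls$individual)
  calls$locus <- as.character(calls$locus)
  calls$a1 <- as.character(calls$a1)
  calls$a2 <- as.character(calls$a2)
  calls$depth <- as.integer(calls$depth)

  half <- xor(is.na(calls$a1), is.na(calls$a2))
  if (any(half)) {
    stop("half calls are not allowed (rows ",
         paste(utils::head(which(half), 5), collapse = ", "),
         "): a genotype has both alleles or is missing")
  }
  if (any(calls$depth < 0, na.rm = TRUE)) stop("read depths must be non-negative")
  calls$depth[is.na(calls$a1)] <- NA_integer_ # depth only attaches to a call

  if (is.null(individuals)) individuals <- unique(calls$individual)
  individuals <- as.character(individuals)
  if (anyDuplicated(individuals)) stop("duplicate individual IDs")

  if (is.null(loci)) {
    loci <- tibble::tibble(locus = unique(calls$locus))
  } else {
    loci <- tibble::as_tibble(loci)
  }
  if (anyDuplicated(loci$locus)) stop("duplicate locus names")
  if (!"kind" %in% names(loci)) {
    # integer-valued labels are fragment lengths, hence SSR
    obs <- dplyr::summarise(
      dplyr::group_by(dplyr::filter(calls, !is.na(.data$a1)), .data$locus),
      ssr = all(grepl("^[0-9]+$", c(.data$a1, .data$a2)))
    )
    loci$kind <- ifelse(loci$locus %in% obs$locus[obs$ssr], "SSR", "SNP")
  }
  if (!all(loci$kind %in% c("SNP", "SSR"))) stop("locus kind must be 'SNP' or 'SSR'")
  for (col in c("motif", "size_range")) if (!col %in% names(loci)) loci[[col]] <- NA_character_
  if (!"ta" %in% names(loci)) loci$ta <- NA_real_

  extra_ind <- setdiff(calls$individual, individuals)
  if (length(extra_ind)) stop("calls reference unknown individuals: ",
                              paste(utils::head(extra_ind, 5), collapse = ", "))
  extra_loc <- setdiff(calls$locus, loci$locus)
  if (length(extra_loc)) stop("calls reference unknown loci: ",
                              paste(utils::head(extra_loc, 5), collapse = ", "))
  if (anyDuplicated(calls[c("individual", "locus")])) {
    stop("duplicate (individual, locus) cells in calls")
  }

  # canonical within-pair order (numeric for SSR labels, lexicographic else)
  calls <- canonicalise_pairs(calls)

  # registry: provided or observed; observed alleles must be registered
  observed <- allele_registry_observed(calls)
  if (!"alleles" %in% names(loci)) {
    loci$alleles <- lapply(loci$locus, function(l) observed[[l]] %||% character())
  } else {
    for (i in seq_len(nrow(loci))) {
      obs_l <- observed[[loci$locus[i]]]
      missing_alleles <- setdiff(obs_l, loci$alleles[[i]])
      if (length(missing_alleles)) {
        stop("locus ", loci$locus[i], ": observed allele(s) ",
             paste(missing_alleles, collapse = ", "), " not in registry")
      }
    }
  }
  wide_snp <- loci$kind == "SNP" & vapply(loci$alleles, length, 1L) > 2
  if (any(wide_snp)) {
    warning("SNP locus with more than two registry alleles: ",
            paste(loci$locus[wide_snp], collapse = ", "))
  }
  bad_snp <- loci$kind == "SNP" &
    !vapply(loci$alleles, function(a) all(a %in% c("A", "C", "G", "T")), TRUE)
  if (any(bad_snp)) stop("SNP alleles must be unambiguous bases (A/C/G/T)")
  bad_ssr <- loci$kind == "SSR" &
    !vapply(loci$alleles, function(a) all(grepl("^[0-9]+$", a)) && all(as.integer(a) > 0), TRUE)
  if (any(bad_ssr)) stop("SSR alleles must be positive integer fragment lengths")

  # complete the grid
  grid <- tidyr::expand_grid(individual = individuals, locus = loci$locus)
  calls <- dplyr::left_join(grid, calls, by = c("individual", "locus"))

  structure(
    list(calls = tibble::as_tibble(calls), loci = loci, individuals = individuals),
    class = "geno_matrix"
  )
}

canonicalise_pairs <- function(calls) {
  num <- grepl("^[0-9]+$", calls$a1) & grepl("^[0-9]+$", calls$a2)
  num[is.na(num)] <- FALSE
  swap <- !is.na(calls$a1) & calls$a1 > calls$a2
  swap[num] <- as.integer(calls$a1[num]) > as.integer(calls$a2[num])
  tmp <- calls$a1[swap]
  calls$a1[swap] <- calls$a2[swap]
  calls$a2[swap] <- tmp
  calls
}

allele_registry_observed <- function(calls) {
  called <- calls[!is.na(calls$a1), ]
  long <- tibble::tibble(
    locus = rep(called$locus, 2L),
    allele = c(called$a1, called$a2)
  )
  split(long$allele, long$locus) |> lapply(function(a) sort(unique(a)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.geno_matrix <- function(x, ...) {
  n_miss <- sum(is.na(x$calls$a1))
  cat("<geno_matrix> ", length(x$individuals), " individuals x ",
      nrow(x$loci), " loci (",
      sum(x$loci$kind == "SNP"), " SNP, ", sum(x$loci$kind == "SSR"), " SSR); ",
      sprintf("%.1f%%", 100 * n_miss / nrow(x$calls)), " missing calls\n", sep = "")
  invisible(x)
}

#' Dimensions and accessors for genotype matrices
#'
#' @param x A [geno_matrix()].
#' @return `n_individuals()`/`n_loci()` return counts; `calls()` the complete
#'   call grid as a tibble; `loci()` the locus table; `individuals()` the
#'   individual IDs.
#' @export
n_individuals <- function(x) length(x$individuals)

#' @rdname n_individuals
#' @export
n_loci <- function(x) nrow(x$loci)

#' @rdname n_individuals
#' @export
calls <- function(x) x$calls

#' @rdname n_individuals
#' @export
loci <- function(x) x$loci

#' @rdname n_individuals
#' @export
individuals <- function(x) x$individuals

#' Subset a genotype matrix
#'
#' @param x A [geno_matrix()].
#' @param keep Character vector of locus names (`select_loci`) or individual
#'   IDs (`select_individuals`) to retain, in the order given.
#' @return A new `geno_matrix`.
#' @export
select_loci <- function(x, keep) {
  keep <- as.character(keep)
  stopifnot(all(keep %in% x$loci$locus))
  loci2 <- x$loci[match(keep, x$loci$locus), ]
  calls2 <- x$calls[x$calls$locus %in% keep, ]
  geno_matrix(calls2, loci = loci2, individuals = x$individuals)
}

#' @rdname select_loci
#' @export
select_individuals <- function(x, keep) {
  keep <- as.character(keep)
  stopifnot(all(keep %in% x$individuals))
  calls2 <- x$calls[x$calls$individual %in% keep, ]
  geno_matrix(calls2, loci = x$loci, individuals = keep)
}

#' Keep loci of one marker kind
#'
#' @param x A [geno_matrix()].
#' @param kind `"SNP"` or `"SSR"`.
#' @return A `geno_matrix` restricted to loci of that kind.
#' @export
filter_kind <- function(x, kind = c("SNP", "SSR")) {
  kind <- match.arg(kind)
  select_loci(x, x$loci$locus[x$loci$kind == kind])
}

# individuals belonging to a scope ("GLOBAL" or a population code)
scope_individuals <- function(x, scope, popmap = NULL) {
  if (identical(scope, "GLOBAL")) return(x$individuals)
  if (is.null(popmap)) stop("a population map is required for scope '", scope, "'")
  ids <- popmap$individual[popmap$population == scope]
  if (!length(ids)) stop("no individuals in population '", scope, "'")
  intersect(x$individuals, ids)
}
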