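#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PCA result
#'
#' @param x A [pca()] result.
#' @param ... Unused.
#' @return `tidy()`: the scores tibble (`individual`, `population`, `PC1`,
#'   ...). `glance()`: a one-row tibble with `n_individuals`, `n_components`,
#'   `var_pc1`, `var_pc2` (explained-variance fractions) and `degenerate`.
#' @method tidy marker_pca
#' @export
tidy.marker_pca <- function(x, ...) x$scores

#' @rdname tidy.marker_pca
#' @method glance marker_pca
#' @export
glance.marker_pca <- function(x, ...) {
  ev <- x$explained_variance
  tibble::tibble(
    n_individuals = nrow(x$scores),
    n_components = length(ev),
    var_pc1 = ev[1],
    var_pc2 = if (length(ev) > 1) ev[2] else NA_real_,
    degenerate = x$degenerate
  )
}

#' Tidy a Nei distance matrix
#'
#' @param x A [distance_matrix()] result.
#' @param ... Unused.
#' @return `tidy()`: long tibble of unordered population pairs with their
#'   distance. `glance()`: one row with population count, the mean finite
#'   off-diagonal distance, and whether infinite distances were flagged.
#' @method tidy nei_dist
#' @export
tidy.nei_dist <- function(x, ...) {
  m <- x$values
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(
    pop_a = rownames(m)[idx[, 1]],
    pop_b = colnames(m)[idx[, 2]],
    distance = m[idx]
  )
}

#' @rdname tidy.nei_dist
#' @method glance nei_dist
#' @export
glance.nei_dist <- function(x, ...) {
  tibble::tibble(
    n_populations = length(x$labels),
    mean_distance = x$mean_off_diagonal,
    has_infinite = x$has_infinite
  )
}

#' Tidy a phenogram
#'
#' @param x A [upgma()] phenogram.
#' @param ... Unused.
#' @return `tidy()`: edge table with parent/child node ids, branch lengths
#'   and tip labels. `glance()`: one row with tip count and tree height.
#' @method tidy phenogram
#' @export
tidy.phenogram <- function(x, ...) {
  tibble::tibble(
    parent = x$edge[, 1],
    node = x$edge[, 2],
    branch_length = x$edge.length,
    label = ifelse(x$edge[, 2] <= length(x$tip.label),
                   x$tip.label[x$edge[, 2]], NA_character_)
  )
}

#' @rdname tidy.phenogram
#' @method glance phenogram
#' @export
glance.phenogram <- function(x, ...) {
  depths <- ape::node.depth.edgelength(x)
  tibble::tibble(
    n_tips = length(x$tip.label),
    height = max(depths[seq_along(x$tip.label)])
  )
}

#' Tidy simulation truth
#'
#' @param x A `sim_truth` from [simulate_panel()].
#' @param ... Unused.
#' @return Long tibble of generative allele frequencies: `scope`
#'   (`"ancestral"` or a population code), `locus`, `allele`, `freq`.
#' @method tidy sim_truth
#' @export
tidy.sim_truth <- function(x, ...) {
  one <- function(scope, freqs) {
    purrr::imap(freqs, function(p, loc) {
      tibble::tibble(scope = scope, locus = loc,
                     allele = names(p), freq = unname(p))
    }) |> dplyr::bind_rows()
  }
  dplyr::bind_rows(
    one("ancestral", x$ancestral_frequencies),
    purrr::imap(x$population_frequencies, one) |> dplyr::bind_rows()
  )
}
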