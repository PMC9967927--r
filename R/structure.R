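#' Nei's standard genetic distance between two populations
#'
#' Nei's (1972) standard distance from per-locus allele frequencies:
#' `Jx = mean_l sum_i x_li^2`, `Jy` likewise, `Jxy = mean_l sum_i x_li y_li`;
#' identity `I = Jxy / sqrt(Jx Jy)`; `D = -ln I`. The J terms are averaged
#' over loci before the ratio (the classical form), not per-locus ratios
#' averaged. Loci with no data in either population are dropped pairwise.
#'
#' @param freqs_a,freqs_b Named lists (by locus) of named numeric frequency
#'   vectors, e.g. built from [allele_frequencies()]. An empty or `NULL`
#'   element means no data at that locus.
#' @return Nei's D (`>= 0` up to floating error); `Inf` when the populations
#'   share no alleles (`I = 0`).
#' @export
nei_distance <- function(freqs_a, freqs_b) {
  shared <- intersect(names(freqs_a), names(freqs_b))
  usable <- shared[vapply(shared, function(l) {
    length(freqs_a[[l]]) > 0 && length(freqs_b[[l]]) > 0
  }, TRUE)]
  if (!length(usable)) stop("no locus with data in both populations")
  jx <- jy <- jxy <- numeric(length(usable))
  for (i in seq_along(usable)) {
    a <- freqs_a[[usable[i]]]
    b <- freqs_b[[usable[i]]]
    jx[i] <- sum(a^2)
    jy[i] <- sum(b^2)
    common <- intersect(names(a), names(b))
    jxy[i] <- sum(a[common] * b[common])
  }
  I <- mean(jxy) / sqrt(mean(jx) * mean(jy))
  if (I <= 0) return(Inf)
  max(0, -log(min(I, 1)))
}

# per-population per-locus frequency lists for a panel
population_frequency_lists <- function(x, popmap) {
  codes <- intersect(population_codes(popmap),
                     unique(popmap$population[popmap$individual %in% x$individuals]))
  out <- lapply(codes, function(code) {
    f <- allele_frequencies(x, scope = code, popmap = popmap)
    split_f <- split(f, f$locus)
    lapply(stats::setNames(as.list(x$loci$locus), x$loci$locus), function(l) {
      fl <- split_f[[l]]
      if (is.null(fl)) return(numeric())
      stats::setNames(fl$freq, fl$allele)
    })
  })
  stats::setNames(out, codes)
}

#' Pairwise Nei distance matrix among populations
#'
#' @param x A [geno_matrix()].
#' @param popmap A [pop_map].
#' @return An object of class `nei_dist`: list with `labels`, `values`
#'   (symmetric matrix, zero diagonal; `Inf` flags disjoint allele sets) and
#'   `mean_off_diagonal` (mean of the finite off-diagonal entries).
#' @export
distance_matrix <- function(x, popmap) {
  pf <- population_frequency_lists(x, popmap)
  codes <- names(pf)
  k <- length(codes)
  if (k < 2) stop("need at least two populations")
  d <- matrix(0, k, k, dimnames = list(codes, codes))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d[i, j] <- d[j, i] <- nei_distance(pf[[i]], pf[[j]])
    }
  }
  off <- d[upper.tri(d)]
  structure(
    list(labels = codes, values = d,
         mean_off_diagonal = mean(off[is.finite(off)]),
         has_infinite = any(!is.finite(off))),
    class = "nei_dist"
  )
}

#' @export
print.nei_dist <- function(x, ...) {
  cat("<nei_dist> ", length(x$labels), " populations; mean off-diagonal D = ",
      format(x$mean_off_diagonal, digits = 4), "\n", sep = "")
  print(round(x$values, 4))
  invisible(x)
}

#' UPGMA phenogram from a distance matrix
#'
#' Average-linkage agglomeration: at each step the closest pair of clusters
#' is merged at height `distance / 2`, and distances to the merged cluster
#' are the size-weighted arithmetic means of the member distances. Ties are
#' broken deterministically by smallest (row, column) position in the input
#' matrix. The result is ultrametric.
#'
#' Infinite entries (disjoint allele sets under Nei's D) are replaced by
#' `1 + max(finite D)` with a warning, preserving their "farthest" rank while
#' keeping the agglomeration finite.
#'
#' @param distances A [distance_matrix()] result, a symmetric matrix with
#'   dimnames, or a [stats::dist].
#' @return An [ape::phylo] tree of class `c("phenogram", "phylo")` with
#'   branch lengths; leaf labels are the input labels.
#' @export
upgma <- function(distances) {
  d <- if (inherits(distances, "nei_dist")) distances$values
       else if (inherits(distances, "dist")) as.matrix(distances)
       else as.matrix(distances)
  if (is.null(rownames(d))) stop("distance matrix must have labels")
  if (nrow(d) < 2) stop("need at least two taxa")
  if (any(!is.finite(d))) {
    repl <- 1 + max(d[is.finite(d)])
    warning("infinite distance(s) replaced by 1 + max finite D = ", format(repl))
    d[!is.finite(d)] <- repl
  }
  labels <- rownames(d)
  n <- nrow(d)
  sizes <- rep(1L, n)
  heights <- rep(0, n)
  newick <- labels
  active <- seq_len(n)
  dm <- d
  while (length(active) > 1) {
    sub <- dm[active, active, drop = FALSE]
    m <- min(sub[upper.tri(sub)])
    hit <- which(upper.tri(sub) & sub <= m + 0, arr.ind = TRUE)
    hit <- hit[sub[hit] == m, , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
    i <- active[hit[1]]
    j <- active[hit[2]]
    h <- m / 2
    newick_new <- paste0("(", newick[i], ":", format(h - heights[i], digits = 12),
                         ",", newick[j], ":", format(h - heights[j], digits = 12), ")")
    # size-weighted average distance to the merged cluster
    others <- setdiff(active, c(i, j))
    dnew <- (sizes[i] * dm[i, others] + sizes[j] * dm[j, others]) / (sizes[i] + sizes[j])
    dm <- rbind(cbind(dm, 0), 0)
    new_id <- nrow(dm)
    dm[new_id, others] <- dnew
    dm[others, new_id] <- dnew
    sizes <- c(sizes, sizes[i] + sizes[j])
    heights <- c(heights, h)
    newick <- c(newick, newick_new)
    active <- c(others, new_id)
  }
  tree <- ape::read.tree(text = paste0(newick[active], ";"))
  class(tree) <- c("phenogram", class(tree))
  tree
}

#' Allele-dosage design matrix for ordination
#'
#' One column per registry allele minus one per locus (the last registry
#' allele is dropped as redundant), entries the 0/1/2 count of that allele in
#' the genotype; missing calls as `NA`.
#'
#' @param x A [geno_matrix()].
#' @return Numeric matrix, individuals in rows.
#' @export
dosage_matrix <- function(x) {
  cols <- list()
  for (j in seq_len(nrow(x$loci))) {
    reg <- x$loci$alleles[[j]]
    if (length(reg) < 2) next
    loc <- x$loci$locus[j]
    cm <- x$calls[x$calls$locus == loc, ]
    cm <- cm[match(x$individuals, cm$individual), ]
    for (a in reg[-length(reg)]) {
      cols[[paste0(loc, ".", a)]] <-
        ifelse(is.na(cm$a1), NA_real_, (cm$a1 == a) + (cm$a2 == a))
    }
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- x$individuals
  mat
}

#' Principal component analysis of individual genotypes
#'
#' PCA of the centred allele-dosage design ([dosage_matrix()]); missing
#' dosages are mean-imputed per column and columns are centred but not scaled
#' (dosage columns share a scale). Components are ordered by variance.
#'
#' @param x A [geno_matrix()].
#' @param popmap Optional [pop_map]; population labels are carried into the
#'   scores for plotting.
#' @param n_components Number of components to retain (default all).
#' @return An object of class `marker_pca`: list with `scores` (tibble:
#'   `individual`, `population`, `PC1`, ...), `explained_variance`
#'   (non-increasing fractions summing to <= 1), `sdev`, and `degenerate`
#'   (TRUE when the design has zero variance).
#' @export
pca <- function(x, popmap = NULL, n_components = NULL) {
  if (n_individuals(x) < 2) stop("PCA needs at least two individuals")
  mat <- dosage_matrix(x)
  if (is.null(mat) || !ncol(mat)) stop("no polymorphic locus to ordinate")
  for (j in seq_len(ncol(mat))) {
    mj <- mat[, j]
    if (anyNA(mj)) {
      mu <- mean(mj, na.rm = TRUE)
      if (is.nan(mu)) mu <- 0
      mat[is.na(mj), j] <- mu
    }
  }
  vars <- apply(mat, 2, stats::var)
  degenerate <- all(vars == 0)
  if (degenerate) {
    warning("all dosage columns are constant: degenerate ordination")
    scores_mat <- matrix(0, nrow(mat), 1, dimnames = list(rownames(mat), "PC1"))
    ev <- 0
    sdev <- 0
  } else {
    fit <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
    keep <- seq_len(min(n_components %||% length(fit$sdev), length(fit$sdev)))
    scores_mat <- fit$x[, keep, drop = FALSE]
    ev <- (fit$sdev^2 / sum(fit$sdev^2))[keep]
    sdev <- fit$sdev[keep]
  }
  scores <- tibble::as_tibble(scores_mat)
  scores <- dplyr::bind_cols(tibble::tibble(individual = rownames(mat)), scores)
  scores$population <- if (!is.null(popmap)) {
    popmap$population[match(scores$individual, popmap$individual)]
  } else NA_character_
  scores <- dplyr::relocate(scores, "population", .after = "individual")
  structure(
    list(scores = scores, explained_variance = ev, sdev = sdev,
         degenerate = degenerate),
    class = "marker_pca"
  )
}

#' @export
print.marker_pca <- function(x, ...) {
  cat("<marker_pca> ", nrow(x$scores), " individuals, ",
      length(x$explained_variance), " components; PC1 explains ",
      sprintf("%.1f%%", 100 * x$explained_variance[1]), "\n", sep = "")
  invisible(x)
}

#' Nearest-centroid assignment accuracy on leading components
#'
#' Assigns each individual to the population whose centroid (over the first
#' `n_components` PCs) is nearest, and reports the agreement with the true
#' labels — a simple separation score for simulated designs.
#'
#' @param ord A [pca()] result with population labels.
#' @param n_components Number of leading components to use.
#' @return Fraction of individuals assigned to their true population.
#' @export
centroid_accuracy <- function(ord, n_components = 2) {
  stopifnot(inherits(ord, "marker_pca"))
  sc <- ord$scores
  if (all(is.na(sc$population))) stop("scores carry no population labels")
  pcs <- as.matrix(sc[, grep("^PC", names(sc))[seq_len(n_components)], drop = FALSE])
  cent <- rowsum(pcs, sc$population) / as.vector(table(sc$population)[sort(unique(sc$population))])
  cent <- cent[sort(unique(sc$population)), , drop = FALSE]
  d2 <- outer(rowSums(pcs^2), rep(1, nrow(cent))) -
    2 * pcs %*% t(cent) + outer(rep(1, nrow(pcs)), rowSums(cent^2))
  assigned <- rownames(cent)[max.col(-d2)]
  mean(assigned == sc$population)
}
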