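#' Unit-maximum normalization of a profile matrix
#'
#' Divides each protein row by its maximum intensity so profiles become
#' comparable shapes on a 0-1 scale.  All-zero rows carry no shape and are
#' dropped (listed in the `dropped` attribute).  Idempotent.
#'
#' @param matrix Proteins-by-fractions numeric matrix with rownames.
#' @return The normalized matrix, `normalization` attribute `"unit_max"`.
#' @export
normalize_unit_max <- function(matrix) {
  mx <- apply(matrix, 1L, max)
  dropped <- rownames(matrix)[mx == 0]
  m <- matrix[mx > 0, , drop = FALSE] / mx[mx > 0]
  attr(m, "dropped") <- dropped
  attr(m, "normalization") <- "unit_max"
  m
}

#' Cross-replicate fraction correlation matrix
#'
#' Entry (i, j) is the Pearson correlation, over the proteins shared by the
#' two replicates, between the intensities of fraction i in replicate 1 and
#' fraction j in replicate 2.  In a reproducible experiment the maxima line
#' up along the diagonal: each fraction correlates best with the same
#' fraction of the other replicate.
#'
#' @param matrix_rep1,matrix_rep2 Proteins-by-fractions matrices with
#'   protein rownames; rows are inner-joined on protein id.
#' @return Fractions-by-fractions correlation matrix.
#' @export
fraction_correlation <- function(matrix_rep1, matrix_rep2) {
  stopifnot(ncol(matrix_rep1) == ncol(matrix_rep2))
  shared <- intersect(rownames(matrix_rep1), rownames(matrix_rep2))
  if (length(shared) < 3L)
    stop("need at least 3 shared proteins, got ", length(shared))
  stats::cor(matrix_rep1[shared, , drop = FALSE],
             matrix_rep2[shared, , drop = FALSE])
}

#' Reconstruct model profiles from fitted peaks
#'
#' Evaluates each protein's accepted Gaussian components on the fraction
#' grid, producing the denoised profile matrix used for clustering.
#' Global-max entries (no parametric width) are reconstructed with a
#' default width so every protein contributes a comparable shape.
#'
#' @param fits Named list of `peakfit` objects (names are protein ids).
#' @param fractions Evaluation grid.
#' @param default_sigma Width used for peaks without a fitted sigma.
#' @return Proteins-by-fractions matrix.
#' @export
reconstruct_profiles <- function(fits, fractions, default_sigma = 1.5) {
  rows <- vapply(fits, function(ft) {
    if (ft$n_peaks == 0L) return(numeric(length(fractions)))
    pk <- ft$peaks
    pk$sigma[is.na(pk$sigma)] <- default_sigma
    gauss_mix(as.numeric(t(pk[, c("amplitude", "center", "sigma")])),
              fractions)
  }, numeric(length(fractions)))
  t(matrix(rows, nrow = length(fractions),
           dimnames = list(NULL, names(fits))))
}

#' Hierarchical clustering of elution profiles
#'
#' Agglomerative clustering of unit-max normalized profiles with
#' correlation distance (1 - Pearson between profile rows) and average
#' linkage.  Deterministic for a given input; the leaf order follows the
#' standard dendrogram convention.
#'
#' @param matrix Proteins-by-fractions matrix (normalized with
#'   [normalize_unit_max()] if not already).
#' @return An object of class `hclust`; protein ids are the labels.
#' @export
cluster_profiles <- function(matrix) {
  if (!identical(attr(matrix, "normalization"), "unit_max"))
    matrix <- normalize_unit_max(matrix)
  d <- stats::as.dist(1 - stats::cor(t(matrix)))
  d[d < 0] <- 0   # guard tiny negative rounding
  stats::hclust(d, method = "average")
}

#' Export a profile dendrogram in Newick format
#'
#' @param hc An `hclust` object from [cluster_profiles()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
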