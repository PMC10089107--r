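#' Nonpathological-variance (NPV) basis via subject-space PCA
#'
#' Principal components of an independent control sample, computed through
#' the small n-by-n matrix of centered-row inner products (the Gram trick)
#' rather than the voxel-by-voxel covariance matrix, which is intractable
#' at typical voxel counts. Components are mapped back to voxel space and
#' normalized to unit length, so removing component `c` from an image `p`
#' is the orthogonal projection update `p - (p . c) c`.
#'
#' @param controls [image_matrix] of the PCA control sample (>= 3 subjects).
#' @param k Optional number of components to retain (at most n - 1).
#' @return Object of class `npv_basis`: list with `components` (K x J
#'   matrix, unit-norm rows, eigenvalue order), `eigenvalues` (variances
#'   along each component, nonincreasing), `center` (column means removed
#'   before decomposition) and `n_source`.
#' @export
fast_pca <- function(controls, k = NULL) {
  stopifnot(inherits(controls, "image_matrix"))
  x <- controls$values
  n <- nrow(x)
  if (n < 3) stop("PCA needs >= 3 subjects", call. = FALSE)
  if (!is.null(k) && (k < 1 || k > n - 1)) {
    stop("k must be in [1, n - 1]", call. = FALSE)
  }
  center <- colMeans(x)
  xc <- x - rep(center, each = n)
  g <- tcrossprod(xc)                 # n x n Gram matrix of centered rows
  eg <- eigen(g, symmetric = TRUE)
  evals <- eg$values / (n - 1)        # variances along components
  if (max(evals) <= 0) {
    stop("all-constant input: no variance to decompose", call. = FALSE)
  }
  keep <- which(evals > 1e-10 * max(evals))
  keep <- keep[seq_len(min(length(keep), n - 1))]
  if (!is.null(k)) keep <- keep[seq_len(min(k, length(keep)))]
  # map subject-space eigenvectors to voxel space, then unit-normalize
  comp <- crossprod(eg$vectors[, keep, drop = FALSE], xc)
  comp <- comp / sqrt(rowSums(comp^2))
  # sign convention: largest-|loading| voxel positive, for reproducibility
  flip <- apply(comp, 1L, function(r) sign(r[which.max(abs(r))]))
  comp <- comp * flip
  structure(
    list(components = comp, eigenvalues = evals[keep], center = center,
         n_source = n),
    class = "npv_basis"
  )
}

#' @export
print.npv_basis <- function(x, ...) {
  cat(sprintf("npv_basis: %d components x %d voxels (from %d subjects)\n",
              nrow(x$components), ncol(x$components), x$n_source))
  ev <- utils::head(x$eigenvalues, 5)
  cat("  leading eigenvalues:", paste(signif(ev, 4), collapse = ", "),
      if (length(x$eigenvalues) > 5) "..." else "", "\n")
  invisible(x)
}

#' Truncate an NPV basis to its leading components
#'
#' @param basis An [fast_pca()] result.
#' @param k Number of leading components to keep.
#' @return An `npv_basis` with `k` components.
#' @export
truncate_basis <- function(basis, k) {
  stopifnot(inherits(basis, "npv_basis"))
  k <- min(k, nrow(basis$components))
  basis$components <- basis$components[seq_len(k), , drop = FALSE]
  basis$eigenvalues <- basis$eigenvalues[seq_len(k)]
  basis
}

#' Voxelwise covariate pattern (e.g. an aging pattern)
#'
#' Ordinary least-squares slope and intercept of voxel intensity on a
#' per-subject covariate, fitted independently at every voxel. Removing
#' the fitted pattern from the PCA sample before [fast_pca()] forces all
#' NPV components to be orthogonal to the covariate direction within that
#' sample — the rescue used when a disease pattern is nearly collinear
#' with, say, age-related atrophy.
#'
#' @param controls [image_matrix].
#' @param covariate Numeric vector, one value per subject, nonconstant.
#' @return Object of class `covariate_pattern`: list with `slope`
#'   (intensity per covariate unit), `intercept`, `covariate_name`.
#' @export
covariate_pattern <- function(controls, covariate,
                              covariate_name = "covariate") {
  stopifnot(inherits(controls, "image_matrix"))
  covariate <- as.numeric(covariate)
  n <- nrow(controls$values)
  if (length(covariate) != n) {
    stop("one covariate value per subject required", call. = FALSE)
  }
  sxx <- sum((covariate - mean(covariate))^2)
  if (sxx == 0) stop("constant covariate: slope undefined", call. = FALSE)
  xc <- covariate - mean(covariate)
  slope <- as.numeric(crossprod(xc, controls$values)) / sxx
  intercept <- colMeans(controls$values) - slope * mean(covariate)
  structure(
    list(slope = slope, intercept = intercept,
         covariate_name = covariate_name),
    class = "covariate_pattern"
  )
}

#' Remove a fitted covariate pattern from images
#'
#' Subtracts each subject's fitted value (`intercept + slope * covariate`)
#' voxelwise, leaving OLS residuals.
#'
#' @param controls [image_matrix].
#' @param pattern A [covariate_pattern()] fit.
#' @param covariate Numeric vector, one value per subject.
#' @return [image_matrix] of residual images.
#' @export
remove_covariate <- function(controls, pattern, covariate) {
  stopifnot(inherits(controls, "image_matrix"),
            inherits(pattern, "covariate_pattern"))
  check_same_space(controls$values[1, ], pattern$slope,
                   "images and covariate pattern")
  covariate <- as.numeric(covariate)
  if (length(covariate) != nrow(controls$values)) {
    stop("one covariate value per subject required", call. = FALSE)
  }
  fitted <- outer(covariate, pattern$slope) +
    rep(pattern$intercept, each = length(covariate))
  image_matrix(controls$values - fitted, controls$subject_ids,
               controls$labels, controls$mask_ref)
}
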