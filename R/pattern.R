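#' Read-out pattern with its uncertainty
#'
#' Builds the read-out pattern `b` as the difference of group mean images
#' (patients minus controls) and attaches its uncertainty estimators: the
#' squared standard error SE2 (expected squared Euclidean distance between
#' `b` and the unknown true pattern) and the noise component estimator
#' NCe = SE2 / ||b||^2, the fraction of the pattern's squared length
#' attributable to sampling noise.
#'
#' @param patients,controls [image_matrix] objects sharing a column space,
#'   each with at least 2 subjects.
#' @return An object of class `readout_pattern`: list with fields `b`
#'   (voxel vector), `n_patients`, `n_controls`, `se2`, `nce`, `norm2`,
#'   and `degenerate` (`TRUE` when NCe >= 1, i.e. the pattern is
#'   statistically indistinguishable from noise).
#' @seealso [squared_standard_error()], [nce()], [pes()]
#' @export
readout_pattern <- function(patients, controls) {
  stopifnot(inherits(patients, "image_matrix"),
            inherits(controls, "image_matrix"))
  check_same_space(patients, controls, "patients and controls")
  b <- colMeans(patients$values) - colMeans(controls$values)
  se2 <- squared_standard_error(patients, controls)
  norm2 <- sum(b^2)
  nce_val <- if (norm2 > 0) se2 / norm2 else NA_real_
  structure(
    list(b = b,
         n_patients = nrow(patients$values),
         n_controls = nrow(controls$values),
         se2 = se2, nce = nce_val, norm2 = norm2,
         degenerate = isTRUE(nce_val >= 1)),
    class = "readout_pattern"
  )
}

#' @export
print.readout_pattern <- function(x, ...) {
  cat(sprintf(
    "readout_pattern: %d voxels (n = %d patients vs %d controls)\n",
    length(x$b), x$n_patients, x$n_controls))
  cat(sprintf("  ||b||^2 = %.6g   SE2 = %.6g   NCe = %.1f%%%s\n",
              x$norm2, x$se2, 100 * x$nce,
              if (isTRUE(x$degenerate)) "  [degenerate: NCe >= 1]" else ""))
  invisible(x)
}

#' Squared standard error of a group-difference pattern
#'
#' The expected squared Euclidean distance between the read-out pattern and
#' the population mean difference, computed from unbiased per-voxel group
#' variances:
#' \deqn{SE^2 = \frac{1}{N_P}\sum_j Var_P(j) + \frac{1}{N_H}\sum_j Var_H(j)}
#'
#' @inheritParams readout_pattern
#' @return Nonnegative scalar.
#' @export
squared_standard_error <- function(patients, controls) {
  stopifnot(inherits(patients, "image_matrix"),
            inherits(controls, "image_matrix"))
  check_same_space(patients, controls, "patients and controls")
  np <- nrow(patients$values)
  nh <- nrow(controls$values)
  if (np < 2 || nh < 2) {
    stop("each group needs >= 2 subjects (variance undefined otherwise)",
         call. = FALSE)
  }
  sum(col_vars(patients$values)) / np + sum(col_vars(controls$values)) / nh
}

#' Noise component estimator of a pattern
#'
#' NCe = SE2 / ||b||^2. Values >= 1 mean the pattern's squared length is no
#' larger than its expected noise content; such patterns are returned with
#' a warning rather than clamped, so downstream feasibility checks
#' (weighted denoising requires NCe < 1) can act on them.
#'
#' @param pattern A [readout_pattern].
#' @return Scalar NCe.
#' @export
nce <- function(pattern) {
  stopifnot(inherits(pattern, "readout_pattern"))
  if (!(pattern$norm2 > 0)) {
    stop("nce undefined: pattern has zero norm", call. = FALSE)
  }
  val <- pattern$se2 / pattern$norm2
  if (val >= 1) {
    warning("NCe >= 1: pattern indistinguishable from noise", call. = FALSE)
  }
  val
}

#' Pattern expression score
#'
#' PES of an image `p` with respect to read-out pattern `b` is the
#' normalized dot product `(p . b) / ||b||^2`; under the linear pathology
#' model it estimates the subject's pathology-specific score.
#'
#' @param image A voxel vector, a numeric matrix (rows = subjects) or an
#'   [image_matrix].
#' @param pattern A [readout_pattern], or a raw voxel vector. When a raw
#'   vector is given its own squared norm is the denominator.
#' @param norm2 Optional denominator override; used by the denoising
#'   shortcut where scores against a denoised pattern keep `||b_d||^2`.
#' @return Numeric vector of one score per input image.
#' @export
pes <- function(image, pattern, norm2 = NULL) {
  b <- if (inherits(pattern, "readout_pattern")) pattern$b else
    as.numeric(pattern)
  if (is.null(norm2)) {
    norm2 <- if (inherits(pattern, "readout_pattern")) pattern$norm2 else
      sum(b^2)
  }
  if (!(norm2 > 0)) {
    stop("pes undefined: zero-norm pattern", call. = FALSE)
  }
  p <- if (inherits(image, "image_matrix")) image$values else image
  if (is.matrix(p)) {
    check_same_space(p[1, ], b, "image and pattern")
    as.numeric(p %*% b) / norm2
  } else {
    check_same_space(p, b, "image and pattern")
    sum(p * b) / norm2
  }
}

#' Per-subject score set
#'
#' @param scores Numeric vector of pattern expression scores.
#' @param labels Matching group labels (`"patient"` / `"control"`).
#' @param variant `"raw"` or `"denoised"`.
#' @return Object of class `score_set`.
#' @export
score_set <- function(scores, labels, variant = c("raw", "denoised")) {
  variant <- match.arg(variant)
  scores <- as.numeric(scores)
  if (!all(is.finite(scores))) stop("non-finite scores", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != length(scores)) {
    stop("one label per score required", call. = FALSE)
  }
  structure(list(scores = scores, labels = labels, variant = variant),
            class = "score_set")
}

#' Standard deviation of the PES estimation error
#'
#' Estimates the spread of the error made when PES is used to read out the
#' pathology-specific score: the sd over residual subjects of
#' `(r . b) / ((1 - NCe) ||b||^2)`. Residual images are the control images
#' used for pattern calculation, centered on their own mean.
#'
#' @param residuals [image_matrix] (or plain matrix) of residual-source
#'   images; rows are centered internally.
#' @param pattern_used Voxel vector (or [readout_pattern]) the scores are
#'   computed with; for weighted denoising this is `b_w`.
#' @param nce_term NCe entering the uncertainty correction (for denoised
#'   patterns, the NCe of the v-companion pattern). Defaults to the
#'   pattern's own NCe when a [readout_pattern] is supplied.
#' @param norm2_term Squared-norm denominator (for weighted denoising,
#'   `||b_v||^2`).
#' @return Nonnegative scalar \eqn{\sigma_{\hat\epsilon}}.
#' @export
estimation_error_sd <- function(residuals, pattern_used,
                                nce_term = NULL, norm2_term = NULL) {
  if (inherits(pattern_used, "readout_pattern")) {
    if (is.null(nce_term)) nce_term <- pattern_used$nce
    if (is.null(norm2_term)) norm2_term <- pattern_used$norm2
    bvec <- pattern_used$b
  } else {
    bvec <- as.numeric(pattern_used)
    if (is.null(norm2_term)) norm2_term <- sum(bvec^2)
    if (is.null(nce_term)) {
      stop("nce_term must be given for a raw pattern vector", call. = FALSE)
    }
  }
  if (nce_term >= 1) {
    stop("pattern dominated by noise (NCe >= 1): error estimate undefined",
         call. = FALSE)
  }
  r <- if (inherits(residuals, "image_matrix")) residuals$values else
    as.matrix(residuals)
  check_same_space(r[1, ], bvec, "residuals and pattern")
  rc <- r - rep(colMeans(r), each = nrow(r))
  stats::sd(as.numeric(rc %*% bvec)) / ((1 - nce_term) * norm2_term)
}

# sd of centered residual projections onto a direction: sigma(R b^T)
residual_proj_sd <- function(residuals, bvec) {
  r <- if (inherits(residuals, "image_matrix")) residuals$values else
    as.matrix(residuals)
  rc <- r - rep(colMeans(r), each = nrow(r))
  stats::sd(as.numeric(rc %*% bvec))
}
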