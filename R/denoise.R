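# Controls-based denoising (CODE): weighted removal of NPV components from
# read-out patterns and images, the NRe/SRe/NBe estimators, and the 1-D
# denoising-weight optimization.

# coefficients of x (vector or matrix rows) on the basis components
basis_coef <- function(x, basis) {
  if (is.matrix(x)) x %*% t(basis$components) else
    as.numeric(basis$components %*% x)
}

#' Weighted denoising of a read-out pattern
#'
#' Removes weight-`w` times the projection of the pattern onto every
#' retained NPV component: `b_w = b - w * sum_k (b . c_k) c_k`. `w = 1`
#' is standard CODE (full projection removal); `w = 0` is a no-op.
#'
#' @param pattern A [readout_pattern] or raw voxel vector.
#' @param basis An [fast_pca()] basis in the same column space.
#' @param w Scalar weight in `[0, 1]`.
#' @return The denoised voxel vector.
#' @export
denoise_pattern <- function(pattern, basis, w) {
  stopifnot(inherits(basis, "npv_basis"))
  check_w(w)
  b <- if (inherits(pattern, "readout_pattern")) pattern$b else
    as.numeric(pattern)
  if (nrow(basis$components) == 0L) return(b)  # empty basis: identity
  check_same_space(b, basis$components[1, ], "pattern and basis")
  b - w * as.numeric(crossprod(basis$components, basis_coef(b, basis)))
}

#' Weighted denoising of image data
#'
#' Applies `p - w * sum_k (p . c_k) c_k` to every row.
#'
#' @param images An [image_matrix].
#' @inheritParams denoise_pattern
#' @return An [image_matrix] of denoised rows.
#' @export
denoise_images <- function(images, basis, w) {
  stopifnot(inherits(images, "image_matrix"), inherits(basis, "npv_basis"))
  check_w(w)
  if (nrow(basis$components) == 0L) return(images)  # empty basis: identity
  check_same_space(images$values[1, ], basis$components[1, ],
                   "images and basis")
  vals <- images$values -
    w * basis_coef(images$values, basis) %*% basis$components
  image_matrix(vals, images$subject_ids, images$labels, images$mask_ref)
}

check_w <- function(w) {
  if (!is.numeric(w) || length(w) != 1 || !is.finite(w) || w < 0 || w > 1) {
    stop("denoising weight must be a scalar in [0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Companion weight v of a denoising weight w
#'
#' For weighted denoising the identity `b . b_w = ||b_v||^2` holds with
#' `v` and `w` connected via `1 - w = (1 - v)^2`: writing `b_C` for the
#' in-span part of `b`, `b . b_w = ||b_perp||^2 + (1 - w)||b_C||^2` while
#' `||b_v||^2 = ||b_perp||^2 + (1 - v)^2 ||b_C||^2`. The v-companion
#' pattern `b_v` carries the signal terms of SRe and of the optimization
#' objective: `(1 - NCe_v) ||b_v||^2` is the unbiased estimate of the true
#' signal coefficient in w-denoised scores, because the noise
#' self-projection in `b . b_w` retains a `(1 - w)` in-span share and the
#' squared standard error of v-denoised data retains `(1 - v)^2` of it.
#'
#' @param w Scalar in `[0, 1]`.
#' @return `v = 1 - sqrt(1 - w)`.
#' @export
v_from_w <- function(w) {
  check_w(w)
  1 - sqrt(1 - w)
}

#' Noise reduction estimator
#'
#' Fractional reduction of the residual-projection spread caused by
#' denoising: `NRe = 1 - sd(R b_w) / sd(R b)`, residual rows centered on
#' their own mean. Internally a fraction; conventionally reported in %.
#'
#' @param residuals [image_matrix] (or matrix) of residual-source images.
#' @param b Raw pattern voxel vector.
#' @param b_w Denoised pattern voxel vector.
#' @return Scalar `<= 1`.
#' @export
nre <- function(residuals, b, b_w) {
  base_sd <- residual_proj_sd(residuals, b)
  if (!(base_sd > 0)) {
    stop("residual projections on b have zero spread", call. = FALSE)
  }
  1 - residual_proj_sd(residuals, b_w) / base_sd
}

#' Signal reduction estimator
#'
#' Fractional reduction of the uncertainty-corrected squared pattern
#' length: `SRe = 1 - ((1 - NCe_d) ||b_v||^2) / ((1 - NCe) ||b||^2)`,
#' where `b_v` is the v-companion denoised pattern and `NCe_d` its noise
#' component recomputed from v-denoised data.
#'
#' @param pattern The raw [readout_pattern] (NCe must be < 1).
#' @param b_v v-companion denoised pattern vector.
#' @param nce_d NCe of the denoised pattern.
#' @return Scalar `<= 1`.
#' @export
sre <- function(pattern, b_v, nce_d) {
  stopifnot(inherits(pattern, "readout_pattern"))
  if (pattern$nce >= 1) {
    stop("raw pattern has NCe >= 1: signal reduction undefined",
         call. = FALSE)
  }
  1 - ((1 - nce_d) * sum(b_v^2)) / ((1 - pattern$nce) * pattern$norm2)
}

#' Net benefit estimator
#'
#' Predicted factor by which the signal-to-noise ratio of pattern
#' expression scores improves under denoising:
#' `NBe = (1 - SRe) / (1 - NRe)`. Equals the ratio of estimation-error
#' sds before and after denoising. Values > 1 predict benefit, < 1 harm.
#'
#' @param nre_val,sre_val Noise / signal reduction fractions (`nre_val < 1`).
#' @return Positive scalar.
#' @export
nbe <- function(nre_val, sre_val) {
  if (nre_val >= 1) {
    stop("NRe = 1: all residual spread removed, NBe undefined",
         call. = FALSE)
  }
  (1 - sre_val) / (1 - nre_val)
}

#' NCe of a denoised pattern, recomputed from denoised data
#'
#' Applies weight-`v` denoising to both groups' images, rebuilds the
#' pattern and re-evaluates SE2 and NCe on the denoised data, making the
#' denoised-error estimate structurally identical to the raw one.
#'
#' @inheritParams readout_pattern
#' @param basis An [fast_pca()] basis.
#' @param v Denoising weight applied to the image data (the v-companion
#'   of a pattern weight `w`; see [v_from_w()]).
#' @return Scalar NCe of the denoised pattern (never negative).
#' @export
nce_denoised <- function(patients, controls, basis, v) {
  dp <- denoise_images(patients, basis, v)
  dh <- denoise_images(controls, basis, v)
  p <- suppressWarnings(readout_pattern(dp, dh))
  p$nce
}

#' Denoising result at a fixed weight
#'
#' Evaluates weighted CODE at a given `w`: the denoised patterns `b_w`
#' (used for scoring and in noise terms) and `b_v` (signal terms), the
#' NRe/SRe/NBe estimators, the denoised-pattern NCe, and the predicted
#' estimation-error sd before and after denoising.
#'
#' @param pattern Raw [readout_pattern] (NCe < 1 required for the signal
#'   terms).
#' @param basis [fast_pca()] basis.
#' @param patients,controls The [image_matrix] groups the pattern was
#'   built from; the controls double as the residual matrix R.
#' @param w Scalar weight in `[0, 1]`.
#' @return Object of class `denoise_result` with fields `b_w`, `b_v`,
#'   `w`, `v`, `nre`, `sre`, `nbe`, `nce_d`, `sigma_eps`, `sigma_eps_d`.
#' @export
code_denoise <- function(pattern, basis, patients, controls, w) {
  stopifnot(inherits(pattern, "readout_pattern"),
            inherits(basis, "npv_basis"))
  check_w(w)
  v <- v_from_w(w)
  b_w <- denoise_pattern(pattern, basis, w)
  b_v <- denoise_pattern(pattern, basis, v)
  nce_d <- nce_denoised(patients, controls, basis, v)
  nre_val <- nre(controls, pattern$b, b_w)
  sre_val <- sre(pattern, b_v, nce_d)
  sigma_eps <- estimation_error_sd(controls, pattern)
  sigma_eps_d <- if (nce_d < 1) {
    estimation_error_sd(controls, b_w, nce_term = nce_d,
                        norm2_term = sum(b_v^2))
  } else NA_real_
  structure(
    list(b_w = b_w, b_v = b_v, w = w, v = v,
         nre = nre_val, sre = sre_val, nbe = nbe(nre_val, sre_val),
         nce_d = nce_d, sigma_eps = sigma_eps, sigma_eps_d = sigma_eps_d),
    class = "denoise_result"
  )
}

#' @export
print.denoise_result <- function(x, ...) {
  cat("denoise_result (weighted CODE)\n")
  cat(sprintf("  w = %.4f  (v = %.4f)\n", x$w, x$v))
  cat(sprintf("  NRe = %.1f%%   SRe = %.1f%%   NBe = %.3g\n",
              100 * x$nre, 100 * x$sre, x$nbe))
  cat(sprintf("  NCe of denoised pattern = %.1f%%\n", 100 * x$nce_d))
  invisible(x)
}

# Eq.-13 objective: predicted estimation-error sd after w-denoising.
# Inf when the NCe_v^d < 1 feasibility constraint is violated.
denoise_objective <- function(w, pattern, basis, patients, controls) {
  v <- v_from_w(w)
  b_w <- denoise_pattern(pattern, basis, w)
  b_v <- denoise_pattern(pattern, basis, v)
  nce_d <- nce_denoised(patients, controls, basis, v)
  if (!(nce_d < 1)) return(Inf)
  residual_proj_sd(controls, b_w) / ((1 - nce_d) * sum(b_v^2))
}

#' Optimize the denoising weight
#'
#' Minimizes the predicted estimation-error sd after denoising,
#' `sd(R b_w) / ((1 - NCe_v^d) ||b_v||^2)`, over `w` in `[0, 1]` subject
#' to `NCe_v^d < 1`. The problem is one-dimensional, so a deterministic
#' 21-point grid with local refinement around the best grid point is used;
#' ties break toward smaller `w`. Because `w = 0` (no denoising) is always
#' a candidate, the optimized objective never exceeds the un-denoised one:
#' denoising is never predicted to hurt.
#'
#' @inheritParams code_denoise
#' @return A [code_denoise()] result at the optimal weight `w*`.
#' @export
optimize_weight <- function(pattern, basis, patients, controls) {
  stopifnot(inherits(pattern, "readout_pattern"))
  if (pattern$nce >= 1) {
    stop("raw pattern has NCe >= 1: optimization undefined", call. = FALSE)
  }
  obj <- function(w) denoise_objective(w, pattern, basis, patients, controls)
  grid <- seq(0, 1, length.out = 21L)
  vals <- vapply(grid, obj, numeric(1))
  if (all(!is.finite(vals))) {
    warning("NCe constraint infeasible over [0, 1]; returning w = 0",
            call. = FALSE)
    return(code_denoise(pattern, basis, patients, controls, 0))
  }
  # ties toward smaller w (which.min keeps the first of equal minima)
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  w_star <- grid[i]
  f_star <- vals[i]
  if (hi > lo) {
    ref <- stats::optimize(obj, c(lo, hi), tol = 1e-6)
    if (ref$objective < f_star - 1e-12 * max(1, abs(f_star))) {
      w_star <- ref$minimum
      f_star <- ref$objective
    }
  }
  # numerical guard: refinement must never end above the w = 0 objective
  if (is.finite(vals[1]) && f_star > vals[1]) w_star <- 0
  code_denoise(pattern, basis, patients, controls, w_star)
}
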