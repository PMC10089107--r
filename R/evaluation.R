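# Classification evaluation: leave-one-pair-out scoring, t-ratio, ROC/AUC
# with Youden cut-point, and the one-sided DeLong comparison of paired AUCs.

split_by_label <- function(scores) {
  stopifnot(inherits(scores, "score_set"))
  list(patient = scores$scores[scores$labels == "patient"],
       control = scores$scores[scores$labels == "control"])
}

# equal-variance two-sample t statistic, patients minus controls
two_sample_t <- function(scores) {
  g <- split_by_label(scores)
  unname(stats::t.test(g$patient, g$control, var.equal = TRUE)$statistic)
}

#' Random one-to-one patient-control pairing
#'
#' @param patient_ids,control_ids Equal-length id vectors.
#' @param seed Integer seed; the pairing is reproducible under it.
#' @return data.frame with columns `patient`, `control`, one row per pair.
#' @export
lopo_pairs <- function(patient_ids, control_ids, seed) {
  if (length(patient_ids) != length(control_ids)) {
    stop("groups must have equal size; truncate before pairing",
         call. = FALSE)
  }
  if (missing(seed)) stop("a pairing seed is required", call. = FALSE)
  perm <- with_seed(seed, sample.int(length(control_ids)))
  data.frame(patient = as.character(patient_ids),
             control = as.character(control_ids)[perm],
             stringsAsFactors = FALSE)
}

#' ROC area, Youden cut-point, sensitivity and specificity
#'
#' AUC by the midrank (Mann-Whitney) formula, ties counted with weight
#' 0.5 — identical to the trapezoid under the empirical ROC curve. The
#' operating point maximizes Youden's J = sens + spec - 1 over thresholds
#' of the rule `score >= t` calls patient; ties in J break toward higher
#' specificity.
#'
#' @param scores A [score_set] containing both classes.
#' @return List with `auc`, `sens`, `spec`, `threshold`.
#' @export
roc_auc_youden <- function(scores) {
  g <- split_by_label(scores)
  m <- length(g$patient); n <- length(g$control)
  if (m == 0 || n == 0) {
    stop("both classes must be present for ROC analysis", call. = FALSE)
  }
  r <- rank(c(g$patient, g$control))   # midranks handle ties at 0.5
  auc <- (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  cand <- sort(unique(c(g$patient, g$control)), decreasing = TRUE)
  sens <- vapply(cand, function(t) mean(g$patient >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(g$control < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[which.max(spec[best])]  # tie-break toward specificity
  list(auc = auc, sens = sens[best], spec = spec[best],
       threshold = cand[best])
}

# placement values of the midrank (Sun & Xu) DeLong formulation
delong_placements <- function(x, y) {
  psi <- outer(x, y, ">") + 0.5 * outer(x, y, "==")
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' One-sided DeLong test for paired AUCs
#'
#' Tests whether the AUC of `scores_b` exceeds that of `scores_a` on the
#' same subjects, using the midrank formulation of the DeLong
#' covariance estimate for paired ROC curves.
#'
#' @param scores_a,scores_b [score_set]s over identical subjects and
#'   labels (e.g. before and after denoising).
#' @return One-sided p-value for `AUC_b > AUC_a`. When the variance of
#'   the AUC difference is zero: 0.5 if the AUCs are equal, otherwise 0
#'   or 1 with a degeneracy warning.
#' @export
delong_one_sided <- function(scores_a, scores_b) {
  if (!identical(scores_a$labels, scores_b$labels)) {
    stop("score sets must cover the same subjects and labels",
         call. = FALSE)
  }
  ga <- split_by_label(scores_a)
  gb <- split_by_label(scores_b)
  m <- length(ga$patient); n <- length(ga$control)
  pa <- delong_placements(ga$patient, ga$control)
  pb <- delong_placements(gb$patient, gb$control)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pb$auc - pa$auc
  if (var_diff <= 0) {
    if (d == 0) return(0.5)
    warning("zero DeLong variance with unequal AUCs: degenerate contrast",
            call. = FALSE)
    return(if (d > 0) 0 else 1)
  }
  stats::pnorm(d / sqrt(var_diff), lower.tail = FALSE)
}

#' Ratio of two-sample t statistics after vs before denoising
#'
#' The empirical counterpart of the net benefit estimator: the
#' equal-variance two-sample t of patient-vs-control scores after CODE,
#' divided by the same statistic before CODE.
#'
#' @param before,after [score_set]s on identical subjects.
#' @return Scalar ratio; `NaN`/`Inf` with a warning when the baseline t
#'   is zero.
#' @export
t_ratio <- function(before, after) {
  if (!identical(before$labels, after$labels)) {
    stop("score sets must cover the same subjects", call. = FALSE)
  }
  tb <- two_sample_t(before)
  ta <- two_sample_t(after)
  if (tb == 0) {
    warning("t before denoising is zero: ratio undefined", call. = FALSE)
  }
  ta / tb
}

#' Leave-one-pair-out evaluation of CODE
#'
#' For each randomly matched patient-control pair: the pair is held out,
#' the read-out pattern is rebuilt from the remaining subjects, the
#' denoising weight is re-optimized (or a fixed `w` applied), and the two
#' held-out subjects are scored with the raw and the denoised pattern.
#' Scores are aggregated over folds into a classification report. The NPV
#' basis comes from a separate control sample and is reused across folds.
#'
#' @param patients,controls [image_matrix] groups of equal size (>= 3).
#' @param basis [fast_pca()] NPV basis from an independent sample.
#' @param config List with `seed` (required, drives the pairing) and
#'   optionally `w` (fixed denoising weight; `NULL` re-optimizes per fold).
#' @return Object of class `eval_report`: t before/after, t-ratio, AUCs,
#'   one-sided DeLong p (after > before), Youden sensitivity/specificity
#'   of the denoised scores, mean optimized `w`, per-subject score sets,
#'   and the number of skipped folds.
#' @export
run_lopo <- function(patients, controls, basis, config) {
  stopifnot(inherits(patients, "image_matrix"),
            inherits(controls, "image_matrix"))
  if (is.null(config$seed)) stop("config$seed is required", call. = FALSE)
  np <- nrow(patients$values)
  if (np < 3 || nrow(controls$values) != np) {
    stop("run_lopo needs equal groups of size >= 3", call. = FALSE)
  }
  pairs <- lopo_pairs(patients$subject_ids, controls$subject_ids,
                      config$seed)
  fixed_w <- config$w
  sc_raw <- sc_den <- labs <- character(0)
  raw <- den <- ws <- numeric(0)
  skipped <- 0L
  for (f in seq_len(nrow(pairs))) {
    tr_p <- im_subset(patients, setdiff(patients$subject_ids,
                                        pairs$patient[f]))
    tr_h <- im_subset(controls, setdiff(controls$subject_ids,
                                        pairs$control[f]))
    res <- tryCatch({
      pat <- readout_pattern(tr_p, tr_h)
      if (!(pat$norm2 > 0)) stop("degenerate fold pattern")
      dres <- if (is.null(fixed_w)) {
        optimize_weight(pat, basis, tr_p, tr_h)
      } else {
        code_denoise(pat, basis, tr_p, tr_h, fixed_w)
      }
      ho_p <- im_subset(patients, pairs$patient[f])$values[1, ]
      ho_h <- im_subset(controls, pairs$control[f])$values[1, ]
      norm2_d <- sum(dres$b_v^2)
      list(raw = c(pes(ho_p, pat), pes(ho_h, pat)),
           den = c(pes(ho_p, dres$b_w, norm2 = norm2_d),
                   pes(ho_h, dres$b_w, norm2 = norm2_d)),
           w = dres$w)
    }, error = function(e) {
      warning(sprintf("fold %d skipped: %s", f, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) { skipped <- skipped + 1L; next }
    raw <- c(raw, res$raw)
    den <- c(den, res$den)
    labs <- c(labs, "patient", "control")
    ws <- c(ws, res$w)
  }
  if (skipped > 0.2 * nrow(pairs)) {
    stop("more than 20% of LOPO folds degenerate: run rejected",
         call. = FALSE)
  }
  before <- score_set(raw, labs, "raw")
  after <- score_set(den, labs, "denoised")
  roc_b <- roc_auc_youden(before)
  roc_a <- roc_auc_youden(after)
  tb <- two_sample_t(before)
  ta <- two_sample_t(after)
  structure(
    list(t_before = tb, t_after = ta, t_ratio = ta / tb,
         auc_before = roc_b$auc, auc_after = roc_a$auc,
         delong_p_one_sided = delong_one_sided(before, after),
         sens = roc_a$sens, spec = roc_a$spec,
         mean_w = mean(ws), fold_w = ws,
         scores_before = before, scores_after = after,
         n_folds = nrow(pairs), n_skipped = skipped),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report (leave-one-pair-out)\n")
  cat(sprintf("  folds: %d (skipped %d)   mean w = %.4f\n",
              x$n_folds, x$n_skipped, x$mean_w))
  cat(sprintf("  t before / after = %.2f / %.2f  (t-ratio %.2f)\n",
              x$t_before, x$t_after, x$t_ratio))
  cat(sprintf(
    "  AUC before / after = %.3f / %.3f  (one-sided DeLong p = %.3g)\n",
    x$auc_before, x$auc_after, x$delong_p_one_sided))
  cat(sprintf("  denoised Youden point: sens %.2f, spec %.2f\n",
              x$sens, x$spec))
  invisible(x)
}

#' Weight sweep: predicted vs observed benefit
#'
#' Evaluates NBe (predicted improvement) and the t-ratio (observed
#' improvement on an independent test cohort) over a grid of denoising
#' weights, the experiment behind "does the predictor find the best w".
#'
#' @inheritParams code_denoise
#' @param test_patients,test_controls Held-out [image_matrix] groups used
#'   only for scoring.
#' @param w_grid Weights to evaluate (default 0, 0.1, ..., 1).
#' @return data.frame with columns `w`, `nre`, `sre`, `nbe`, `t_value`,
#'   `t_ratio`.
#' @export
weight_sweep <- function(pattern, basis, patients, controls,
                         test_patients, test_controls,
                         w_grid = seq(0, 1, by = 0.1)) {
  labs <- c(rep("patient", nrow(test_patients$values)),
            rep("control", nrow(test_controls$values)))
  t_at_w <- function(b_w, b_v) {
    s <- c(pes(test_patients, b_w, norm2 = sum(b_v^2)),
           pes(test_controls, b_w, norm2 = sum(b_v^2)))
    two_sample_t(score_set(s, labs))
  }
  t0 <- t_at_w(pattern$b, pattern$b)
  rows <- lapply(w_grid, function(w) {
    dres <- code_denoise(pattern, basis, patients, controls, w)
    tw <- t_at_w(dres$b_w, dres$b_v)
    data.frame(w = w, nre = dres$nre, sre = dres$sre, nbe = dres$nbe,
               t_value = tw, t_ratio = tw / t0)
  })
  do.call(rbind, rows)
}
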