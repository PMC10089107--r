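# Scaled-down simulation experiments: Monte-Carlo validation of the
# squared standard error, exact-identity checks, predicted-vs-observed
# benefit sweeps, the collinear-pattern failure mode and its
# covariate-removal rescue, and the PCA-sample-size trend.

#' Monte-Carlo validation of the squared standard error
#'
#' Repeatedly draws cohorts from one truth, measures the squared Euclidean
#' distance between each read-out pattern and the expected pattern
#' `pss_mean * mu`, and compares the average distance with the average
#' analytic SE2. Their ratio should be 1 up to Monte-Carlo error.
#'
#' @param seed Integer seed.
#' @param n_reps Number of simulated cohorts.
#' @param n_patients,n_controls Group sizes per cohort.
#' @param truth Optional [make_truth()] object (default: 2000 voxels,
#'   10 NPV directions, no overlap).
#' @return List with `ratio` (mean distance^2 / mean SE2), `mean_dist2`,
#'   `mean_se2`, `n_reps`.
#' @export
mc_se2_experiment <- function(seed, n_reps = 2000, n_patients = 30,
                              n_controls = 30, truth = NULL) {
  if (is.null(truth)) truth <- make_truth(2000, 10, 0, child_seed(seed, 0))
  mu_eff <- truth$pss_mean * truth$mu
  d2 <- se2 <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    co <- sample_cohort(truth, n_patients, n_controls,
                        seed = child_seed(seed, r))
    p <- im_group(co$images, "patient")
    h <- im_group(co$images, "control")
    b <- colMeans(p$values) - colMeans(h$values)
    d2[r] <- sum((b - mu_eff)^2)
    se2[r] <- squared_standard_error(p, h)
  }
  list(ratio = mean(d2) / mean(se2), mean_dist2 = mean(d2),
       mean_se2 = mean(se2), n_reps = n_reps)
}

#' Exact formula identities on random instances
#'
#' On random small cohorts and bases checks, per instance: (i) the two
#' notations of the net benefit estimator (error-sd ratio vs
#' `(1-SRe)/(1-NRe)`) agree; (ii) `b . b_w = ||b_v||^2`; (iii) the scoring
#' shortcut `p_denoised . b = p . b_denoised`.
#'
#' @param seed Integer seed.
#' @param n_instances Number of random instances.
#' @return List of maxima of absolute errors: `nbe`, `vw`, `shortcut`.
#' @export
identity_experiment <- function(seed, n_instances = 50) {
  errs <- matrix(NA_real_, n_instances, 3,
                 dimnames = list(NULL, c("nbe", "vw", "shortcut")))
  for (i in seq_len(n_instances)) {
    s0 <- child_seed(seed, 100 + i)
    truth <- make_truth(60, 4, overlap = (i %% 5) / 5, seed = s0,
                        noise_sd = 0.05)
    co <- sample_cohort(truth, 8, 8, seed = child_seed(s0, 1))
    pca <- sample_cohort(truth, 2, 12, seed = child_seed(s0, 2))
    basis <- fast_pca(im_group(pca$images, "control"))
    p <- im_group(co$images, "patient")
    h <- im_group(co$images, "control")
    pat <- readout_pattern(p, h)
    w <- with_seed(child_seed(s0, 3), stats::runif(1))
    dres <- code_denoise(pat, basis, p, h, w)
    # (i) NBe via the error-sd ratio vs via (1 - SRe)/(1 - NRe)
    errs[i, "nbe"] <- abs(dres$sigma_eps / dres$sigma_eps_d - dres$nbe)
    # (ii) b . b_w = ||b_v||^2
    errs[i, "vw"] <- abs(sum(pat$b * dres$b_w) - sum(dres$b_v^2))
    # (iii) shortcut: scores from denoised images against the raw
    # pattern direction equal scores from raw images against b_w
    img_d <- denoise_images(p, basis, w)
    lhs <- as.numeric(img_d$values %*% pat$b)
    rhs <- as.numeric(p$values %*% dres$b_w)
    errs[i, "shortcut"] <- max(abs(lhs - rhs))
  }
  list(nbe = max(errs[, "nbe"]), vw = max(errs[, "vw"]),
       shortcut = max(errs[, "shortcut"]), n_instances = n_instances)
}

# direct voxel-space covariance PCA; independent oracle for the Gram trick
direct_pca <- function(x) {
  e <- eigen(stats::cov(x), symmetric = TRUE)
  keep <- which(e$values > 1e-10 * max(e$values))
  keep <- keep[seq_len(min(length(keep), nrow(x) - 1))]
  list(components = t(e$vectors[, keep, drop = FALSE]),
       eigenvalues = e$values[keep])
}

#' Gram-trick PCA vs direct covariance PCA
#'
#' Compares [fast_pca()] against an eigendecomposition of the voxel-space
#' covariance matrix on small random instances of increasing size.
#'
#' @param seed Integer seed.
#' @return List with `min_abs_cosine` (worst per-component agreement,
#'   1 = identical up to sign), `max_eval_relerr`, `n_instances`.
#' @export
pca_agreement_experiment <- function(seed) {
  shapes <- list(c(5, 8), c(8, 12), c(12, 30), c(20, 50))
  min_cos <- 1
  max_ev <- 0
  for (i in seq_along(shapes)) {
    n <- shapes[[i]][1]; j <- shapes[[i]][2]
    x <- with_seed(child_seed(seed, 200 + i),
                   matrix(stats::rnorm(n * j), n, j))
    im <- image_matrix(x)
    fp <- fast_pca(im)
    dp <- direct_pca(x)
    kk <- min(nrow(fp$components), nrow(dp$components))
    cs <- abs(rowSums(fp$components[seq_len(kk), , drop = FALSE] *
                        dp$components[seq_len(kk), , drop = FALSE]))
    min_cos <- min(min_cos, cs)
    max_ev <- max(max_ev, abs(fp$eigenvalues[seq_len(kk)] -
                                dp$eigenvalues[seq_len(kk)]) /
                    dp$eigenvalues[seq_len(kk)])
  }
  list(min_abs_cosine = min_cos, max_eval_relerr = max_ev,
       n_instances = length(shapes))
}

sign_tol <- function(x, tol = 1e-12) {
  ifelse(abs(x) < tol, 0, sign(x))
}

#' Predicted vs observed benefit across denoising weights
#'
#' Runs the weight-sweep experiment: (a) `n_runs` independent repetitions
#' of the orthogonal-NPV scenario, comparing the location of the maxima
#' of NBe(w) and of the t-ratio(w) measured on an independent test
#' cohort; (b) one sweep per scenario of the [scenario_suite()],
#' comparing the sign of NBe - 1 with the sign of t-ratio - 1 cell by
#' cell.
#'
#' @param seed Integer seed.
#' @param n_runs Repetitions for the argmax comparison.
#' @param n_test Per-group test-cohort size.
#' @return List with `argmax_agreement` (fraction of runs with
#'   |argmax NBe - argmax t-ratio| <= 0.1), `sign_match` (fraction of
#'   (scenario, w) cells with matching benefit sign), `argmax_diffs`,
#'   `sweeps`.
#' @export
benefit_sweep_experiment <- function(seed, n_runs = 20, n_test = 300) {
  w_grid <- seq(0, 1, by = 0.1)
  diffs <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    scn <- scenario_suite(child_seed(seed, 300 + r))$ad_like
    inst <- scenario_instance(scn, child_seed(seed, 400 + r),
                              n_test = n_test)
    sw <- weight_sweep(inst$pattern, inst$basis, inst$patients,
                       inst$controls, inst$test_patients,
                       inst$test_controls, w_grid)
    diffs[r] <- abs(sw$w[which.max(sw$nbe)] - sw$w[which.max(sw$t_ratio)])
  }
  scns <- scenario_suite(child_seed(seed, 500))
  sweeps <- lapply(scns, function(scn) {
    inst <- scenario_instance(scn, child_seed(seed, 501), n_test = n_test)
    sw <- weight_sweep(inst$pattern, inst$basis, inst$patients,
                       inst$controls, inst$test_patients,
                       inst$test_controls, w_grid)
    sw$scenario <- scn$name
    sw
  })
  cells <- do.call(rbind, sweeps)
  match_ok <- sign_tol(cells$nbe - 1, 1e-6) ==
    sign_tol(cells$t_ratio - 1, 1e-6)
  list(argmax_agreement = mean(diffs <= 0.1 + 1e-9),
       sign_match = mean(match_ok),
       argmax_diffs = diffs, sweeps = cells, n_runs = n_runs)
}

#' Collinear-pattern failure mode and covariate-removal rescue
#'
#' In the scenario whose pathology pattern is nearly collinear with an
#' age-driven NPV direction: weight optimization should refuse to denoise
#' (w* near 0) and NBe at w = 1 should predict harm. After regressing the
#' age pattern out of the PCA sample and rebuilding the basis, full
#' denoising no longer removes the signal: SRe collapses and NBe returns
#' to about 1.
#'
#' @param seed Integer seed.
#' @return List with `w_star`, `nbe_w1`, `sre_w1`, `sre_rescued`,
#'   `nbe_rescued`, `nce`.
#' @export
pd_rescue_experiment <- function(seed) {
  scn <- scenario_suite(seed)$pd_like
  inst <- scenario_instance(scn, child_seed(seed, 600))
  opt <- optimize_weight(inst$pattern, inst$basis, inst$patients,
                         inst$controls)
  d1 <- code_denoise(inst$pattern, inst$basis, inst$patients,
                     inst$controls, 1)
  age_pat <- covariate_pattern(inst$pca_sample, inst$pca_ages, "age")
  cleaned <- remove_covariate(inst$pca_sample, age_pat, inst$pca_ages)
  basis2 <- truncate_basis(fast_pca(cleaned), scn$k_basis)
  d2 <- code_denoise(inst$pattern, basis2, inst$patients,
                     inst$controls, 1)
  list(w_star = opt$w, nbe_w1 = d1$nbe, sre_w1 = d1$sre,
       sre_rescued = d2$sre, nbe_rescued = d2$nbe, nce = inst$pattern$nce)
}

#' Optimizer never predicts harm
#'
#' For every scenario in the suite, the predicted estimation-error sd at
#' the optimized weight must not exceed the un-denoised one (w = 0 is
#' always a feasible candidate).
#'
#' @param seed Integer seed.
#' @return data.frame with one row per scenario: `w_star`, `sigma_raw`,
#'   `sigma_opt`, `ratio`.
#' @export
optimizer_safety_experiment <- function(seed) {
  scns <- scenario_suite(seed)
  rows <- lapply(scns, function(scn) {
    inst <- scenario_instance(scn, child_seed(seed, 700))
    opt <- optimize_weight(inst$pattern, inst$basis, inst$patients,
                           inst$controls)
    data.frame(scenario = scn$name, w_star = opt$w,
               sigma_raw = opt$sigma_eps, sigma_opt = opt$sigma_eps_d,
               ratio = opt$sigma_eps_d / opt$sigma_eps)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' NBe as a function of PCA sample size and components removed
#'
#' The read-out cohort is held fixed while the PCA control sample is
#' redrawn at each size; NBe of full denoising is evaluated with all
#' available components and with the leading half. Larger PCA samples
#' yield more generalizable components, so NBe should grow with sample
#' size while being insensitive to removing 50% vs 100% of components.
#'
#' @param seed Integer seed.
#' @param sizes PCA sample sizes to compare.
#' @param n_reps Repetitions (fresh PCA sample) per size.
#' @return List with `summary` (per size: mean NBe with all and with half
#'   the components, mean relative difference) and `runs`.
#' @export
pca_size_experiment <- function(seed, sizes = c(20, 40, 100),
                                n_reps = 10) {
  truth <- make_truth(2000, 10, 0, child_seed(seed, 800))
  co <- sample_cohort(truth, 50, 50, seed = child_seed(seed, 801))
  p <- im_group(co$images, "patient")
  h <- im_group(co$images, "control")
  pat <- readout_pattern(p, h)
  runs <- list()
  for (s in sizes) {
    for (r in seq_len(n_reps)) {
      pca <- sample_cohort(truth, 2, s,
                           seed = child_seed(seed, 810 + 37 * s + r))
      basis <- fast_pca(im_group(pca$images, "control"))
      k_all <- nrow(basis$components)
      d_all <- code_denoise(pat, basis, p, h, 1)
      d_half <- code_denoise(pat, truncate_basis(basis, floor(k_all / 2)),
                             p, h, 1)
      runs[[length(runs) + 1]] <-
        data.frame(size = s, rep = r, k = k_all,
                   nbe_all = d_all$nbe, nbe_half = d_half$nbe)
    }
  }
  runs <- do.call(rbind, runs)
  summ <- do.call(rbind, lapply(split(runs, runs$size), function(d) {
    data.frame(size = d$size[1], nbe_all = mean(d$nbe_all),
               nbe_half = mean(d$nbe_half),
               rel_diff = mean(abs(d$nbe_all - d$nbe_half) / d$nbe_all))
  }))
  summ <- summ[order(summ$size), ]
  rownames(summ) <- NULL
  list(summary = summ, runs = runs)
}

#' ROC oracle agreement
#'
#' AUC from the midrank formula vs brute-force counting over all
#' patient-control pairs (ties at half weight) on random instances, and
#' the DeLong p-value for two identical score sets.
#'
#' @param seed Integer seed.
#' @param n_instances Number of random score sets.
#' @return List with `max_auc_err`, `delong_equal_p`.
#' @export
roc_oracle_experiment <- function(seed, n_instances = 50) {
  max_err <- 0
  for (i in seq_len(n_instances)) {
    ss <- with_seed(child_seed(seed, 900 + i), {
      m <- sample(3:12, 1); n <- sample(3:12, 1)
      # coarse grid scores so ties actually occur
      score_set(sample(seq(0, 2, by = 0.25), m + n, replace = TRUE) +
                  c(rep(0.4, m), rep(0, n)),
                rep(c("patient", "control"), c(m, n)))
    })
    g <- split_by_label(ss)
    brute <- mean(outer(g$patient, g$control,
                        function(a, b) (a > b) + 0.5 * (a == b)))
    max_err <- max(max_err, abs(roc_auc_youden(ss)$auc - brute))
  }
  ss <- with_seed(child_seed(seed, 999),
                  score_set(stats::rnorm(20),
                            rep(c("patient", "control"), 10)))
  list(max_auc_err = max_err, delong_equal_p = delong_one_sided(ss, ss),
       n_instances = n_instances)
}
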