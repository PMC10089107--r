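# Synthetic cohorts under the linear pathology model
#   p_i = PSS_i * mu + sum_k a_ik c_k + eps_i
# Patients carry PSS_i ~ N(pss_mean, pss_sd); controls have PSS = 0. NPV
# loadings a_ik are Gaussian, optionally with an age-driven deterministic
# part; eps is iid per-voxel Gaussian. This is the fixture generator for
# every estimator and for the scaled-down trend experiments.

#' Ground truth for the linear pathology model
#'
#' Draws a random unit pathology pattern `mu` and a random orthonormal set
#' of NPV directions, rotating the first NPV direction toward `mu` so that
#' `cos(c_1, mu) = overlap`. All draws are reproducible under `seed`.
#'
#' @param n_voxels Number of voxels J.
#' @param k_npv Number of true NPV directions K (`< n_voxels`).
#' @param overlap Cosine similarity injected between `mu` and the first
#'   NPV direction, in `[0, 1]`. High overlap is the regime where
#'   denoising removes pathology signal along with nuisance variance.
#' @param seed Integer seed.
#' @param npv_sd Per-direction sd of the random NPV loadings (recycled to
#'   length `k_npv`). Default `0.6 / sqrt(1:K)`: a few strong modes of
#'   physiological variance and a decaying tail.
#' @param noise_sd Per-voxel sd of the unstructured residual.
#' @param pss_mean,pss_sd Patient pathology-specific score distribution.
#' @param age_beta Optional per-direction slope of the loading on age
#'   (loading units per year); default all zero (no age coupling).
#' @param age_range Age range (years) subjects are drawn from uniformly
#'   when a cohort is sampled with ages.
#' @return Object of class `ground_truth`.
#' @export
make_truth <- function(n_voxels = 2000, k_npv = 10, overlap = 0, seed,
                       npv_sd = 0.6 / sqrt(seq_len(k_npv)),
                       noise_sd = 0.02, pss_mean = 1, pss_sd = 0.25,
                       age_beta = rep(0, k_npv), age_range = c(45, 75)) {
  if (k_npv >= n_voxels) stop("k_npv must be < n_voxels", call. = FALSE)
  if (overlap < 0 || overlap > 1) {
    stop("overlap must be in [0, 1]", call. = FALSE)
  }
  npv_sd <- rep_len(npv_sd, k_npv)
  age_beta <- rep_len(age_beta, k_npv)
  stopifnot(all(npv_sd >= 0), noise_sd > 0, pss_sd >= 0)
  with_seed(seed, {
    mu <- rnorm(n_voxels)
    mu <- mu / sqrt(sum(mu^2))
    raw <- matrix(rnorm(n_voxels * k_npv), n_voxels, k_npv)
    # orthonormalize, then rotate c_1 toward mu in the plane they span
    q <- qr.Q(qr(raw))
    u <- q[, 1] - sum(q[, 1] * mu) * mu
    u <- u / sqrt(sum(u^2))
    c1 <- overlap * mu + sqrt(1 - overlap^2) * u
    if (k_npv > 1) {
      rest <- q[, -1, drop = FALSE]
      rest <- rest - outer(c1, as.numeric(crossprod(rest, c1)))
      rest <- qr.Q(qr(rest))                 # re-orthonormalize, all | c1
      comps <- t(cbind(c1, rest))
    } else {
      comps <- matrix(c1, 1)
    }
    structure(
      list(mu = mu, npv_patterns = comps, npv_sd = npv_sd,
           noise_sd = noise_sd, pss_mean = pss_mean, pss_sd = pss_sd,
           overlap = overlap, age_beta = age_beta, age_range = age_range,
           age_center = mean(age_range)),
      class = "ground_truth"
    )
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "ground_truth: %d voxels, %d NPV directions (overlap %.2f)\n",
    length(x$mu), nrow(x$npv_patterns), x$overlap))
  cat(sprintf("  PSS ~ N(%.3g, %.3g), noise sd %.3g, NPV sd %s\n",
              x$pss_mean, x$pss_sd, x$noise_sd,
              paste(signif(utils::head(x$npv_sd, 4), 3), collapse = ", ")))
  if (any(x$age_beta != 0)) {
    cat("  age-coupled loadings on directions:",
        paste(which(x$age_beta != 0), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Sample a patient/control cohort from a ground truth
#'
#' Patient image = `PSS_i mu + sum_k a_ik c_k + eps_i`; controls are
#' identical with PSS = 0. When any NPV direction is age-coupled and no
#' ages are supplied, subject ages are drawn uniformly from the truth's
#' `age_range` so that the coupled loading variance is realized.
#'
#' @param truth A [make_truth()] object.
#' @param n_patients,n_controls Group sizes (>= 2).
#' @param seed Integer seed.
#' @param ages Optional numeric vector of length
#'   `n_patients + n_controls` (patients first).
#' @return List with `images` (one [image_matrix], patients first, labels
#'   set), `pss` (true per-subject scores) and `ages` (or `NULL`).
#' @export
sample_cohort <- function(truth, n_patients, n_controls, seed,
                          ages = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (n_patients < 2 || n_controls < 2) {
    stop("each group needs >= 2 subjects", call. = FALSE)
  }
  n <- n_patients + n_controls
  j <- length(truth$mu)
  k <- nrow(truth$npv_patterns)
  with_seed(seed, {
    if (is.null(ages) && any(truth$age_beta != 0)) {
      ages <- stats::runif(n, truth$age_range[1], truth$age_range[2])
    }
    pss <- c(rnorm(n_patients, truth$pss_mean, truth$pss_sd),
             rep(0, n_controls))
    load <- matrix(rnorm(n * k), n, k) %*% diag(truth$npv_sd, k)
    if (!is.null(ages)) {
      if (length(ages) != n) {
        stop("'ages' must have one entry per subject", call. = FALSE)
      }
      load <- load + outer(ages - truth$age_center, truth$age_beta)
    }
    vals <- outer(pss, truth$mu) + load %*% truth$npv_patterns +
      matrix(rnorm(n * j, sd = truth$noise_sd), n, j)
    im <- image_matrix(vals,
                       labels = rep(c("patient", "control"),
                                    c(n_patients, n_controls)),
                       mask_ref = "simulated")
    list(images = im, pss = pss, ages = ages)
  })
}

#' Canonical simulation scenarios
#'
#' Reproducible named scenarios spanning the regimes the framework has to
#' distinguish. Each scenario holds a `truth`, read-out cohort sizes, the
#' PCA-sample size and the number of NPV components its pipeline retains:
#'
#' * `ad_like` — large effect, NPV orthogonal to the pathology pattern,
#'   moderate uncertainty: denoising should clearly help.
#' * `scz_like` — large effect with strong NPV variance: the largest
#'   predicted benefit.
#' * `mdd_like` — weak effect, high pattern uncertainty (NCe near 1):
#'   scores are barely discriminative before denoising.
#' * `pd_like` — weak effect whose pattern is nearly collinear
#'   (cosine 0.95) with a strong, purely age-driven NPV direction:
#'   denoising removes the signal itself, the failure mode the net
#'   benefit estimator has to flag in advance.
#'
#' @param seed Integer seed; truths are derived reproducibly from it.
#' @return Named list of scenarios, each a list with `name`, `truth`,
#'   `n_patients`, `n_controls`, `n_pca`, `k_basis` (`NULL` = all
#'   components).
#' @export
scenario_suite <- function(seed) {
  k <- 10
  list(
    ad_like = list(
      name = "ad_like",
      truth = make_truth(2000, k, overlap = 0, seed = child_seed(seed, 1)),
      n_patients = 30, n_controls = 30, n_pca = 300, k_basis = NULL),
    scz_like = list(
      name = "scz_like",
      truth = make_truth(2000, k, overlap = 0, seed = child_seed(seed, 2),
                         npv_sd = 1.2 / sqrt(seq_len(k))),
      n_patients = 30, n_controls = 30, n_pca = 300, k_basis = NULL),
    mdd_like = list(
      name = "mdd_like",
      truth = make_truth(2000, k, overlap = 0, seed = child_seed(seed, 3),
                         pss_mean = 0.25, pss_sd = 0.05),
      n_patients = 40, n_controls = 40, n_pca = 300, k_basis = NULL),
    pd_like = list(
      name = "pd_like",
      truth = make_truth(2000, k, overlap = 0.95,
                         seed = child_seed(seed, 4),
                         npv_sd = c(0.02, rep(0.08, k - 1)),
                         noise_sd = 0.07, pss_mean = 0.35, pss_sd = 0.1,
                         age_beta = c(0.0323, rep(0, k - 1))),
      n_patients = 30, n_controls = 30, n_pca = 1000, k_basis = k)
  )
}

#' Sample the standard pieces of a scenario
#'
#' Draws the read-out cohort, an independent PCA control sample with its
#' NPV basis, and (optionally) an independent test cohort, all from the
#' scenario's truth.
#'
#' @param scn One element of [scenario_suite()].
#' @param seed Integer seed.
#' @param n_test Per-group size of an independent test cohort (0 = none).
#' @return List with `patients`, `controls`, `pattern`, `basis`,
#'   `pca_sample`, and optionally `test_patients`, `test_controls`.
#' @export
scenario_instance <- function(scn, seed, n_test = 0) {
  co <- sample_cohort(scn$truth, scn$n_patients, scn$n_controls,
                      seed = child_seed(seed, 11))
  pca <- sample_cohort(scn$truth, 2, scn$n_pca,
                       seed = child_seed(seed, 12))
  pca_controls <- im_group(pca$images, "control")
  basis <- fast_pca(pca_controls)
  if (!is.null(scn$k_basis)) basis <- truncate_basis(basis, scn$k_basis)
  patients <- im_group(co$images, "patient")
  controls <- im_group(co$images, "control")
  out <- list(patients = patients, controls = controls,
              pattern = readout_pattern(patients, controls),
              basis = basis, pca_sample = pca_controls,
              pca_ages = if (is.null(pca$ages)) NULL else
                pca$ages[pca$images$labels == "control"])
  if (n_test > 0) {
    te <- sample_cohort(scn$truth, n_test, n_test,
                        seed = child_seed(seed, 13))
    out$test_patients <- im_group(te$images, "patient")
    out$test_controls <- im_group(te$images, "control")
  }
  out
}
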