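test_that("random pairing is a seeded bijection over equal groups", {
  p1 <- lopo_pairs(c("p1", "p2", "p3"), c("h1", "h2", "h3"), seed = 5)
  p2 <- lopo_pairs(c("p1", "p2", "p3"), c("h1", "h2", "h3"), seed = 5)
  expect_identical(p1, p2)
  expect_setequal(p1$control, c("h1", "h2", "h3"))
  expect_setequal(p1$patient, c("p1", "p2", "p3"))
  expect_equal(nrow(lopo_pairs("p", "h", seed = 1)), 1L)
  expect_error(lopo_pairs(c("a", "b"), "h", seed = 1), "equal size")
  expect_error(lopo_pairs("a", "h"), "seed")
})

test_that("AUC equals brute-force pair counting, ties at half weight", {
  ss <- score_set(c(2, 3, 0, 1), rep(c("patient", "control"), each = 2))
  r <- roc_auc_youden(ss)
  expect_equal(r$auc, 1)
  expect_equal(r$sens, 1)
  expect_equal(r$spec, 1)

  flat <- score_set(rep(1, 6), rep(c("patient", "control"), 3))
  expect_equal(roc_auc_youden(flat)$auc, 0.5)

  for (s in 1:20) {
    sc <- with_seed_ns(200 + s, {
      m <- sample(3:10, 1); n <- sample(3:10, 1)
      score_set(sample(seq(0, 1, 0.2), m + n, TRUE) +
                  c(rep(0.3, m), rep(0, n)),
                rep(c("patient", "control"), c(m, n)))
    })
    pat <- sc$scores[sc$labels == "patient"]
    ctl <- sc$scores[sc$labels == "control"]
    brute <- mean(outer(pat, ctl, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(roc_auc_youden(sc)$auc, brute, tolerance = 1e-12)
    # Mann-Whitney U equivalence through the base wilcox statistic
    u <- suppressWarnings(wilcox.test(pat, ctl)$statistic)
    expect_equal(roc_auc_youden(sc)$auc, unname(u) / (length(pat) *
                                                        length(ctl)))
  }
  expect_error(roc_auc_youden(score_set(1:3, rep("patient", 3))),
               "both classes")
})

test_that("Youden cut-point maximizes sens + spec - 1 (6-subject toy)", {
  # one overlapping patient score below two control scores
  ss <- score_set(c(5, 4, 1.5, 2, 1, 0),
                  rep(c("patient", "control"), each = 3))
  r <- roc_auc_youden(ss)
  expect_equal(r$auc, 8 / 9)
  expect_equal(r$threshold, 4)  # ties in J broken toward specificity
  expect_equal(r$sens, 2 / 3)
  expect_equal(r$spec, 1)
})

test_that("DeLong test agrees with pROC and a jackknife oracle", {
  labs <- rep(c("patient", "control"), c(10, 10))
  a <- with_seed_ns(210, score_set(rnorm(20) + c(rep(1, 10), rep(0, 10)),
                                   labs))
  b <- score_set(a$scores + with_seed_ns(211, rnorm(20, sd = 0.6)), labs)

  p_ours <- delong_one_sided(a, b)
  roc_a <- pROC::roc(labs, a$scores, levels = c("control", "patient"),
                     direction = "<", quiet = TRUE)
  roc_b <- pROC::roc(labs, b$scores, levels = c("control", "patient"),
                     direction = "<", quiet = TRUE)
  p_ref <- pROC::roc.test(roc_a, roc_b, method = "delong", paired = TRUE,
                          alternative = "less")$p.value
  expect_equal(p_ours, p_ref, tolerance = 1e-8)

  # jackknife oracle for the variance of the AUC difference
  auc_of <- function(sc) roc_auc_youden(sc)$auc
  d_full <- auc_of(b) - auc_of(a)
  drop_subject <- function(ss, i) score_set(ss$scores[-i], ss$labels[-i])
  ip <- which(labs == "patient"); ic <- which(labs == "control")
  d_p <- sapply(ip, function(i) auc_of(drop_subject(b, i)) -
                  auc_of(drop_subject(a, i)))
  d_c <- sapply(ic, function(i) auc_of(drop_subject(b, i)) -
                  auc_of(drop_subject(a, i)))
  var_jack <- (length(ip) - 1) / length(ip) * sum((d_p - mean(d_p))^2) +
    (length(ic) - 1) / length(ic) * sum((d_c - mean(d_c))^2)
  z <- qnorm(p_ours, lower.tail = FALSE)
  var_delong <- (d_full / z)^2
  expect_equal(var_delong, var_jack, tolerance = 0.1)
})

test_that("DeLong p is 0.5 for identical sets and symmetric otherwise", {
  labs <- rep(c("patient", "control"), 8)
  a <- with_seed_ns(212, score_set(rnorm(16) +
                                     rep(c(0.8, 0), 8), labs))
  expect_equal(delong_one_sided(a, a), 0.5)

  b <- with_seed_ns(213, score_set(rnorm(16) + rep(c(1.6, 0), 8), labs))
  expect_equal(delong_one_sided(a, b) + delong_one_sided(b, a), 1,
               tolerance = 1e-12)
  # invariance under strictly monotone transforms (rank statistic)
  b_mono <- score_set(exp(3 * b$scores), labs)
  expect_equal(delong_one_sided(a, b_mono), delong_one_sided(a, b),
               tolerance = 1e-12)
})

test_that("t-ratio behaves as a ratio of equal-variance t statistics", {
  labs <- rep(c("patient", "control"), c(6, 6))
  sc <- with_seed_ns(214, score_set(rnorm(12) + rep(c(1, 0), c(6, 6)),
                                    labs))
  expect_equal(t_ratio(sc, sc), 1)
  doubled <- score_set(2 * sc$scores, labs)
  expect_equal(t_ratio(sc, doubled), 1, tolerance = 1e-12)
  flat <- score_set(c(1, -1, 0, 0), rep(c("patient", "control"), each = 2))
  after <- score_set(c(2, 0, 0, 0), rep(c("patient", "control"), each = 2))
  expect_warning(t_ratio(flat, after), "zero")
})

test_that("LOPO evaluation: separable data and fixed w = 0 edge cases", {
  truth <- make_truth(120, 3, 0, seed = 220, noise_sd = 0.02,
                      pss_mean = 5, pss_sd = 0.2)
  co <- sample_cohort(truth, 8, 8, seed = 221)
  basis <- fast_pca(im_group(sample_cohort(truth, 2, 20, 222)$images,
                             "control"))
  p <- im_group(co$images, "patient")
  h <- im_group(co$images, "control")

  rep0 <- run_lopo(p, h, basis, list(seed = 7, w = 0))
  expect_equal(rep0$scores_before$scores, rep0$scores_after$scores)
  expect_equal(rep0$mean_w, 0)

  rep1 <- run_lopo(p, h, basis, list(seed = 7))
  expect_equal(rep1$auc_before, 1)   # huge effect: separable either way
  expect_equal(rep1$auc_after, 1)
  expect_equal(rep1$n_skipped, 0L)
})

test_that("LOPO improves classification in an NPV-noise scenario", {
  truth <- make_truth(300, 5, 0, seed = 230, noise_sd = 0.05,
                      npv_sd = 1.5 / sqrt(1:5), pss_mean = 0.8,
                      pss_sd = 0.2)
  co <- sample_cohort(truth, 12, 12, seed = 231)
  basis <- fast_pca(im_group(sample_cohort(truth, 2, 60, 232)$images,
                             "control"))
  p <- im_group(co$images, "patient")
  h <- im_group(co$images, "control")
  rep <- run_lopo(p, h, basis, list(seed = 11))
  d <- code_denoise(readout_pattern(p, h), basis, p, h, rep$mean_w)
  expect_gt(rep$auc_after, rep$auc_before)
  expect_gt(d$nbe, 1)
  # per-fold optimized weights vary little when the truth is fixed
  expect_lt(sd(rep$fold_w), 0.02)
})
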