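test_that("read-out pattern is the difference of group means", {
  pats <- mk_im(c(2, 0), c(2, 0))
  ctls <- mk_im(c(0, 0), c(0, 0))
  p <- readout_pattern(pats, ctls)
  expect_equal(p$b, c(2, 0))
  expect_equal(p$se2, 0)        # zero within-group variance
  expect_equal(p$nce, 0)
  expect_false(p$degenerate)
})

test_that("SE2 matches hand-computed per-voxel variances", {
  # patient voxel-1 values {0, 2}: unbiased variance 2, divided by N_P = 2
  pats <- mk_im(c(0, 0), c(2, 0))
  ctls <- mk_im(c(0, 0), c(0, 0))
  p <- readout_pattern(pats, ctls)
  expect_equal(p$b, c(1, 0))
  expect_equal(p$se2, 1)
  expect_equal(p$nce, 1)        # pattern indistinguishable from noise
  expect_true(p$degenerate)

  # cross-check against an independent scalar variance routine
  se2_scalar <- sum(apply(pats$values, 2, var)) / 2 +
    sum(apply(ctls$values, 2, var)) / 2
  expect_equal(squared_standard_error(pats, ctls), se2_scalar)

  expect_error(squared_standard_error(mk_im(c(1, 1)), ctls), ">= 2")
  expect_error(readout_pattern(pats, mk_im(c(0, 0, 0), c(0, 0, 0))),
               "column space")
})

test_that("swapping groups negates b and leaves SE2 unchanged", {
  a <- rand_im(5, 7, seed = 1)
  b <- rand_im(6, 7, seed = 2)
  p1 <- readout_pattern(a, b)
  p2 <- readout_pattern(b, a)
  expect_equal(p1$b, -p2$b)
  expect_equal(p1$se2, p2$se2)
  expect_equal(p1$nce, p2$nce)
})

test_that("NCe is scale invariant and flags noise-dominated patterns", {
  a <- rand_im(6, 9, seed = 3)
  b <- rand_im(6, 9, seed = 4)
  p <- readout_pattern(a, b)
  sc <- readout_pattern(image_matrix(a$values * 3),
                        image_matrix(b$values * 3))
  expect_equal(nce(sc), nce(p), tolerance = 1e-12)

  deg <- readout_pattern(mk_im(c(0, 0), c(2, 0)), mk_im(c(0, 0), c(0, 0)))
  expect_warning(v <- nce(deg), "indistinguishable")
  expect_equal(v, 1)
  zero <- readout_pattern(mk_im(c(1, 1), c(1, 1)), mk_im(c(1, 1), c(1, 1)))
  expect_error(nce(zero), "zero norm")
})

test_that("pattern expression score is the normalized dot product", {
  p <- readout_pattern(mk_im(c(1, 0), c(1, 0)), mk_im(c(0, 0), c(0, 0)))
  expect_equal(pes(p$b, p), 1)            # self-expression
  expect_equal(pes(c(0, 5), p), 0)        # orthogonal image
  expect_equal(pes(c(2, 0), p), 2)
  expect_error(pes(c(1, 1), c(0, 0)), "zero-norm")

  # linearity over images
  x1 <- with_seed_ns(8, rnorm(7))
  x2 <- with_seed_ns(9, rnorm(7))
  pt <- readout_pattern(rand_im(4, 7, 5), rand_im(4, 7, 6))
  expect_equal(pes(2 * x1 - 3 * x2, pt),
               2 * pes(x1, pt) - 3 * pes(x2, pt), tolerance = 1e-12)

  # matrix input gives one score per row
  m <- rbind(x1, x2)
  expect_equal(pes(m, pt), c(pes(x1, pt), pes(x2, pt)))
})

test_that("under the noiseless linear model PES recovers PSS exactly", {
  j <- 50
  mu <- with_seed_ns(11, rnorm(j))
  pss <- c(1.3, 0.2, 2.5, 0.9)
  pats <- image_matrix(outer(pss, mu))
  ctls <- image_matrix(matrix(0, 3, j))
  p <- readout_pattern(pats, ctls)   # b = mean(pss) * mu
  expect_equal(pes(pats, p) * mean(pss), pss, tolerance = 1e-12)
})

test_that("estimation error sd follows the uncertainty-corrected form", {
  bvec <- c(1, 0, 0)
  res <- mk_im(c(0, 1, 0), c(0, 0, 1), c(0, -1, -1))  # orthogonal to b
  expect_equal(estimation_error_sd(res, bvec, nce_term = 0.3), 0)

  res2 <- rand_im(6, 3, seed = 7)
  base <- estimation_error_sd(res2, bvec, nce_term = 0)
  rc <- scale(res2$values, scale = FALSE)
  expect_equal(base, sd(rc %*% bvec) / sum(bvec^2))   # nce = 0 limit
  # halving (1 - nce) doubles the estimate
  expect_equal(estimation_error_sd(res2, bvec, nce_term = 0.5), 2 * base)
  expect_error(estimation_error_sd(res2, bvec, nce_term = 1),
               "dominated by noise")
})

test_that("NCe shrinks in expectation as group sizes grow", {
  truth <- make_truth(200, 4, 0, seed = 21, noise_sd = 0.05)
  mean_nce <- sapply(c(10, 30, 100), function(n) {
    mean(sapply(1:30, function(r) {
      co <- sample_cohort(truth, n, n, seed = 1000 * n + r)
      readout_pattern(im_group(co$images, "patient"),
                      im_group(co$images, "control"))$nce
    }))
  })
  expect_true(all(diff(mean_nce) < 0))
})
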