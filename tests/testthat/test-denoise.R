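test_that("pattern denoising removes weighted projections", {
  basis <- mk_basis(c(1, 0))
  expect_equal(denoise_pattern(c(1, 1), basis, 1), c(0, 1))
  expect_equal(denoise_pattern(c(1, 1), basis, 0.5), c(0.5, 1))
  expect_equal(denoise_pattern(c(0, 2), basis, 0.8), c(0, 2))  # orthogonal
  expect_error(denoise_pattern(c(1, 1), basis, 1.2), "\\[0, 1\\]")
})

test_that("image denoising is rowwise and exact at the w limits", {
  basis <- mk_basis(rbind(c(1, 0, 0), c(0, 1, 0)))
  im <- mk_im(c(1, 2, 3), c(-1, 0, 2))
  expect_equal(denoise_images(im, basis, 0)$values, im$values)
  d1 <- denoise_images(im, basis, 1)
  expect_equal(d1$values, rbind(c(0, 0, 3), c(0, 0, 2)),
               ignore_attr = TRUE)
  span_only <- mk_im(c(2, -1, 0), c(0.5, 3, 0))
  expect_equal(denoise_images(span_only, basis, 1)$values,
               matrix(0, 2, 3), ignore_attr = TRUE)
})

test_that("the v-companion weight satisfies the dot-product identity", {
  expect_equal(v_from_w(0), 0)
  expect_equal(v_from_w(1), 1)
  expect_equal(v_from_w(0.5), 1 - sqrt(0.5))
  expect_error(v_from_w(-0.1), "\\[0, 1\\]")

  # b . b_w = ||b_v||^2 and, at w = 1, b . b_d = ||b_d||^2
  basis <- mk_basis(rbind(c(1, 0, 0, 0), c(0, 1 / sqrt(2), 1 / sqrt(2), 0)))
  b <- with_seed_ns(41, rnorm(4))
  for (w in c(0, 0.17, 0.5, 0.83, 1)) {
    b_w <- denoise_pattern(b, basis, w)
    b_v <- denoise_pattern(b, basis, v_from_w(w))
    expect_equal(sum(b * b_w), sum(b_v^2), tolerance = 1e-12)
  }
  b1 <- denoise_pattern(b, basis, 1)
  expect_equal(sum(b * b1), sum(b1^2), tolerance = 1e-12)
})

test_that("scoring shortcut: denoised images vs denoised pattern", {
  truth <- make_truth(40, 3, 0.4, seed = 42, noise_sd = 0.05)
  co <- sample_cohort(truth, 5, 5, seed = 43)
  basis <- fast_pca(im_group(sample_cohort(truth, 2, 10, 44)$images,
                             "control"))
  p <- im_group(co$images, "patient")
  for (w in c(0.3, 1)) {
    lhs <- denoise_images(p, basis, w)$values %*%
      readout_pattern(p, im_group(co$images, "control"))$b
    rhs <- p$values %*%
      denoise_pattern(readout_pattern(p, im_group(co$images, "control")),
                      basis, w)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("noise reduction estimator matches a hand-computed sd ratio", {
  basis <- mk_basis(c(1, 0, 0))
  res <- mk_im(c(1, 2, 0), c(3, 0, 1), c(-2, 1, 1), c(0, -1, 2))
  b <- c(1, 1, 0)
  b_w <- denoise_pattern(b, basis, 1)
  rc <- scale(res$values, scale = FALSE)
  expect_equal(nre(res, b, b_w),
               1 - sd(rc %*% b_w) / sd(rc %*% b))
  expect_equal(nre(res, b, b), 0)

  # residuals entirely inside the removed span: all noise goes away
  span_res <- mk_im(c(1, 0, 0), c(-2, 0, 0), c(0.5, 0, 0))
  expect_equal(nre(span_res, c(1, 0.2, 0),
                   denoise_pattern(c(1, 0.2, 0), basis, 1)), 1)
  expect_error(nre(mk_im(c(0, 1, 0), c(0, 2, 0)), c(1, 0, 0),
                   c(1, 0, 0)), "zero spread")
})

test_that("signal reduction is 0 at w = 0 and 1 for an in-span pattern", {
  pats <- with_seed_ns(45, image_matrix(matrix(rnorm(30, sd = 0.1), 5, 6) +
                                          rep(c(3, 1, 0, 0, 0, 0),
                                              each = 5)))
  pat <- readout_pattern(pats, rand_im(5, 6, 46, sd = 0.1))
  expect_equal(sre(pat, pat$b, pat$nce), 0)
  expect_equal(sre(pat, 0 * pat$b, 0), 1)
  deg <- readout_pattern(mk_im(c(0, 0), c(2, 0)), mk_im(c(0, 0), c(0, 0)))
  expect_error(sre(deg, deg$b, 0), "NCe >= 1")
})

test_that("net benefit combines the two reductions", {
  expect_equal(nbe(0, 0), 1)
  expect_equal(nbe(0.5, 0), 2)
  expect_error(nbe(1, 0.2), "NRe = 1")
})

test_that("denoised NCe reduces to the raw one at v = 0", {
  truth <- make_truth(60, 4, 0, seed = 47, noise_sd = 0.1)
  co <- sample_cohort(truth, 6, 6, seed = 48)
  basis <- fast_pca(im_group(sample_cohort(truth, 2, 9, 49)$images,
                             "control"))
  p <- im_group(co$images, "patient")
  h <- im_group(co$images, "control")
  raw <- readout_pattern(p, h)
  expect_equal(nce_denoised(p, h, basis, 0), raw$nce, tolerance = 1e-12)
  expect_gte(nce_denoised(p, h, basis, 1), 0)
})

test_that("code_denoise at w = 0 is a no-op with NBe = 1", {
  truth <- make_truth(60, 4, 0, seed = 50, noise_sd = 0.1)
  co <- sample_cohort(truth, 6, 6, seed = 51)
  basis <- fast_pca(im_group(sample_cohort(truth, 2, 9, 52)$images,
                             "control"))
  p <- im_group(co$images, "patient")
  h <- im_group(co$images, "control")
  pat <- readout_pattern(p, h)
  d0 <- code_denoise(pat, basis, p, h, 0)
  expect_equal(d0$b_w, pat$b)
  expect_equal(d0$nre, 0)
  expect_equal(d0$sre, 0)
  expect_equal(d0$nbe, 1)
  # empty basis: denoising is the identity
  empty <- truncate_basis(basis, 0)
  expect_equal(denoise_pattern(pat, empty, 1), pat$b)
  expect_equal(denoise_images(p, empty, 1)$values, p$values)
})

test_that("weight optimization is safe and flat landscapes give w = 0", {
  # basis orthogonal to both the pattern and all residual variation
  basis <- mk_basis(c(0, 0, 0, 1))
  pats <- mk_im(c(2, 0.1, 0, 0), c(2.2, -0.1, 0.1, 0),
                c(1.9, 0, -0.1, 0))
  ctls <- mk_im(c(0, 0.1, 0.1, 0), c(0.1, -0.2, 0, 0),
                c(-0.1, 0.1, -0.1, 0))
  opt <- optimize_weight(readout_pattern(pats, ctls), basis, pats, ctls)
  expect_equal(opt$w, 0)
  expect_equal(opt$nbe, 1)

  # random instances: predicted error never worse than no denoising
  for (s in 1:5) {
    truth <- make_truth(80, 4, s / 6, seed = 60 + s, noise_sd = 0.08)
    co <- sample_cohort(truth, 8, 8, seed = 70 + s)
    basis <- fast_pca(im_group(sample_cohort(truth, 2, 14,
                                             80 + s)$images, "control"))
    p <- im_group(co$images, "patient")
    h <- im_group(co$images, "control")
    pat <- readout_pattern(p, h)
    if (pat$nce >= 1) next
    opt <- optimize_weight(pat, basis, p, h)
    expect_lte(opt$sigma_eps_d, opt$sigma_eps * (1 + 1e-10))
  }
})
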