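mkvol <- function(a) cbct_volume(array(a, c(length(a), 1, 1)), 1)

test_that("affine windowing solves the least-squares intensity map", {
  x <- array(rnorm(4^3, 50, 10), c(4, 4, 4))
  vx <- cbct_volume(x, 1)
  w1 <- affine_window(vx, vx)
  expect_equal(attr(w1, "a"), 1)
  expect_equal(attr(w1, "b"), 0, tolerance = 1e-10)

  # x = 2 ref + 3  ->  a = 0.5, b = -1.5
  v2 <- cbct_volume(2 * x + 3, 1)
  w2 <- affine_window(v2, vx)
  expect_equal(attr(w2, "a"), 0.5)
  expect_equal(attr(w2, "b"), -1.5)
  expect_equal(w2$data, x, tolerance = 1e-10)

  cst <- cbct_volume(array(7, c(4, 4, 4)), 1)
  expect_warning(affine_window(cst, vx), "indeterminate")
})

test_that("windowing never increases the RMSE", {
  set.seed(42)
  for (i in 1:20) {
    x <- cbct_volume(array(rnorm(125, 10, 4), c(5, 5, 5)), 1)
    y <- cbct_volume(array(rnorm(125, -3, 2), c(5, 5, 5)), 1)
    expect_lte(rmse(x, y, window = TRUE), rmse(x, y, window = FALSE) + 1e-12)
  }
})

test_that("CNR matches its closed form and affine invariance", {
  # fg all 5, bg values {1, 2, 3}: (5 - 2) / sd({1,2,3}) = 3
  vals <- array(0, c(3, 3, 4))
  vals[, , 1:3] <- 5
  vals[2, 2, 4] <- 1; vals[1, 2, 4] <- 2; vals[3, 2, 4] <- 3
  vol <- cbct_volume(vals, 1)
  fg_roi <- list(lo = c(1, 1, 1), hi = c(3, 3, 3))
  bg_roi <- list(lo = c(1, 2, 4), hi = c(3, 2, 4))
  expect_equal(cnr(vol, fg_roi, bg_roi), 3)
  expect_equal(cnr(vol, bg_roi, bg_roi), 0)

  # global positive affine map leaves CNR unchanged
  v2 <- cbct_volume(4 * vol$data + 100, 1)
  expect_equal(cnr(v2, fg_roi, bg_roi), 3)

  # constant background is an error; out-of-grid box is non-computable
  cstv <- cbct_volume(array(1, c(3, 3, 4)), 1)
  expect_error(cnr(cstv, fg_roi, bg_roi), "undefined")
  expect_true(is.na(cnr(vol, fg_roi, list(lo = c(1, 1, 3), hi = c(3, 3, 7)))))
})

test_that("CNR recovers a known contrast-to-noise level", {
  set.seed(7)
  mu_liver <- 75; mu_lung <- -800; sigma <- 40
  fg <- array(rnorm(21^3, mu_liver, sigma), c(21, 21, 21))
  bg <- array(rnorm(21^3, mu_lung, sigma), c(21, 21, 21))
  vol <- cbct_volume(array(c(fg, bg), c(21, 21, 42)), 1)
  v <- cnr(vol, list(lo = c(1, 1, 1), hi = c(21, 21, 21)),
           list(lo = c(6, 6, 22), hi = c(16, 16, 32)))
  expect_equal(v, (mu_liver - mu_lung) / sigma, tolerance = 0.05)
})

test_that("interface sharpness recovers the logistic rate and its limits", {
  l <- 60
  z <- 1:l
  runs <- array(0, c(5, 5, l))
  for (i in 1:5) for (j in 1:5) runs[i, j, ] <- 1 / (1 + exp(-0.5 * (z - 30)))
  vol <- cbct_volume(runs, 1)
  roi <- list(lo = c(1, 1, 1), hi = c(5, 5, l))
  expect_equal(as.numeric(tis(vol, roi)), 0.5, tolerance = 0.01)
  expect_error(tis(vol, list(lo = c(1, 1, 1), hi = c(5, 5, 6))), "run length")
})

test_that("hard edges saturate TIS and noise runs are excluded", {
  l <- 40
  mk_run <- function(f) f(1:l)
  runs <- array(0, c(5, 5, l))
  for (i in 1:5) for (j in 1:5) runs[i, j, ] <- c(rep(0, 20), rep(1, 20))
  roi <- list(lo = c(1, 1, 1), hi = c(5, 5, l))
  expect_equal(as.numeric(tis(cbct_volume(runs, 1), roi, k_max = 10)), 10,
               tolerance = 1e-6)

  # one flat/noise run among edge runs is excluded from the mean
  set.seed(1)
  runs[3, 3, ] <- rnorm(l, 0.5, 0.01)
  v <- tis(cbct_volume(runs, 1), roi)
  expect_equal(attr(v, "n_valid"), 24)

  # descending (liver below, lung above) polarity is flipped before fitting
  desc <- array(0, c(5, 5, l))
  for (i in 1:5) for (j in 1:5) desc[i, j, ] <- 1 / (1 + exp(0.7 * ((1:l) - 18)))
  expect_equal(as.numeric(tis(cbct_volume(desc, 1), roi)), 0.7, tolerance = 0.01)
})

test_that("TIW converts sharpness to a physical 10-90% width", {
  expect_equal(tiw(1, 1), 2 * log(9), tolerance = 1e-12)
  expect_equal(tiw(0.4394, 1), 2 * log(9) / 0.4394)
  expect_error(tiw(0, 1), "TIS")

  # the 0.1/0.9 crossings of a k = 0.5 logistic sit exactly TIW apart
  k <- 0.5; w <- 1
  z10 <- -log(9) / k; z90 <- log(9) / k
  expect_equal((z90 - z10) * w, tiw(k, w))
  expect_equal(tiw(k, w), 8.789, tolerance = 1e-3)
})

test_that("RMSE matches hand values and a brute-force loop", {
  a <- mkvol(c(0, 0)); b <- mkvol(c(3, 4))
  expect_equal(rmse(b, a, window = FALSE), sqrt(25 / 2))
  expect_equal(rmse(a, a, window = FALSE), 0)

  set.seed(3)
  x <- cbct_volume(array(rnorm(60), c(5, 4, 3)), 1)
  y <- cbct_volume(array(rnorm(60), c(5, 4, 3)), 1)
  acc <- 0
  for (i in 1:5) for (j in 1:4) for (k in 1:3)
    acc <- acc + (x$data[i, j, k] - y$data[i, j, k])^2
  expect_equal(rmse(x, y, window = FALSE), sqrt(acc / 60), tolerance = 1e-10)
})

test_that("global SSIM follows its closed form and degrades with noise", {
  set.seed(11)
  x <- array(rnorm(6^3, 100, 30), c(6, 6, 6))
  vx <- cbct_volume(x, 1)
  expect_equal(ssim(vx, vx, window = FALSE), 1)

  y <- array(rnorm(6^3, 100, 30), c(6, 6, 6))
  vy <- cbct_volume(y, 1)
  # closed form recomputed independently
  L <- max(c(x, y)) - min(c(x, y))
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  expected <- (2 * mean(x) * mean(y) + c1) * (2 * cov(as.numeric(x), as.numeric(y)) + c2) /
    ((mean(x)^2 + mean(y)^2 + c1) * (var(as.numeric(x)) + var(as.numeric(y)) + c2))
  expect_equal(ssim(vx, vy, window = FALSE), expected, tolerance = 1e-12)

  # symmetry
  expect_equal(ssim(vx, vy, window = FALSE), ssim(vy, vx, window = FALSE))

  # anticorrelated input scores below 1 with the covariance's sign
  neg <- cbct_volume(-x + 200, 1)
  expect_lt(ssim(neg, vx, window = FALSE), 1)

  # monotone degradation with increasing noise
  base <- fix_gt4d()$phases[[1]]
  hu <- to_hu(base)
  L0 <- diff(range(hu$data))
  vals <- vapply(c(0.01, 0.02, 0.04), function(s) {
    set.seed(5)
    noisy <- cbct_volume(hu$data + rnorm(length(hu$data), 0, s * L0),
                         hu$spacing, hu$origin)
    ssim(noisy, hu, window = FALSE)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("TIW increases monotonically under Gaussian blur", {
  gt <- to_hu(fix_gt4d()$phases[[1]])
  rois <- auto_rois(fix_phantom(), fix_mini()$grid)
  vals <- vapply(c(0, 1, 2, 3), function(s) {
    b <- cbct_volume(blur3(gt$data, s), gt$spacing, gt$origin)
    tiw(tis(b, rois$tiw_box), gt$spacing[3])
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("phase averaging handles excluded phases", {
  expect_equal(as.numeric(phase_average(rep(4.2, 10))), 4.2)
  v <- phase_average(c(1, 2, NA, 3))
  expect_equal(as.numeric(v), 2)
  expect_equal(attr(v, "n_phases"), 3)
  expect_equal(as.numeric(phase_average(c(2, 4, 6, 8))), mean(c(2, 4, 6, 8)))
})

test_that("paired t-test matches the t distribution and errors on degenerate input", {
  a <- c(1.2, 3.4, 0.8, 2.2)
  b <- c(1.0, 2.9, 1.4, 1.7)
  d <- a - b
  tstat <- mean(d) / (sd(d) / sqrt(4))
  p_oracle <- 2 * pt(-abs(tstat), df = 3)
  expect_equal(paired_t_test(a, b), p_oracle, tolerance = 1e-6)

  expect_error(paired_t_test(c(1, 2, 3), c(0, 1, 2)), "zero variance")
  expect_error(paired_t_test(1:2, 3:4), "at least 3")
  expect_error(paired_t_test(1:4, 1:3), "equal length")

  # under the null, p-values are uniform: fraction below 0.05 is ~5%
  set.seed(99)
  hits <- mean(replicate(200, {
    x <- rnorm(8); paired_t_test(x + rnorm(8, 0, 0.5), x) < 0.05
  }))
  expect_gte(hits, 0.01)
  expect_lte(hits, 0.09)
})
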