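test_that("cosine preweight has its closed-form values", {
  g <- scan_geometry(sid = 500, sdd = 1000, detector_cols = 3L,
                     detector_rows = 1L, pixel_pitch = 1000)
  w <- preweight(matrix(1, 3, 1), g)
  expect_equal(w[2, 1], 1)                   # central pixel
  expect_equal(w[3, 1], 1 / sqrt(2))         # u = sdd
  # monotone decreasing in |u| (odd pixel counts center the grid exactly)
  g2 <- scan_geometry(detector_cols = 63, detector_rows = 51, pixel_pitch = 8)
  w2 <- preweight(matrix(1, 63, 51), g2)
  half <- w2[32:63, 26]
  expect_true(all(diff(half) < 0))
})

test_that("short-scan weights sum to one over conjugate ray pairs", {
  g <- fix_mini()$geometry
  nu <- g$detector_cols
  u_iso <- (seq_len(nu) - (nu + 1) / 2) * g$pixel_pitch * g$sid / g$sdd
  gam <- atan2(u_iso, g$sid) * 180 / pi
  # pick columns and a first angle such that the conjugate angle
  # beta2 = beta1 + 180 - 2 gamma stays inside the arc
  for (col in c(5, 20, 32, 45, 58)) {
    b1 <- 5
    b2 <- b1 + 180 - 2 * gam[col]
    w <- short_scan_weights(c(b1, b2), g)
    expect_equal(w[col, 1] + w[nu + 1 - col, 2], 1, tolerance = 1e-9)
  }
  # 360-degree arc: flat 0.5 weights
  g360 <- scan_geometry(detector_cols = 63, detector_rows = 50, pixel_pitch = 8,
                        arc_deg = 360)
  expect_true(all(short_scan_weights(c(0, 90, 180), g360) == 0.5))
  # arc below 180 + fan is insufficient
  g_small <- scan_geometry(detector_cols = 63, detector_rows = 50,
                           pixel_pitch = 8, arc_deg = 185)
  expect_error(short_scan_weights(c(0, 90), g_small), "insufficient")
})

test_that("ramp filter reproduces the Ram-Lak taps and kills DC", {
  du <- 2
  n <- 64
  imp <- numeric(n); imp[n / 2] <- 1
  f <- ramp_filter(imp, du = du)
  expect_equal(f[n / 2], 1 / (4 * du^2))
  expect_equal(f[n / 2 + 1], -1 / (pi * du)^2)
  expect_equal(f[n / 2 + 2], 0)
  expect_equal(f[n / 2 + 3], -1 / (3 * pi * du)^2)
  expect_equal(f[n / 2 - 1], -1 / (pi * du)^2)

  # constant row: (near) zero away from the edges
  # interior leakage is bounded by the truncated kernel's tail mass
  cst <- ramp_filter(rep(3, 256), du = 1)
  expect_lt(max(abs(cst[64:192])), 0.01)

  # symmetric input stays symmetric
  x <- exp(-((1:101) - 51)^2 / 50)
  fx <- ramp_filter(x, du = 1)
  expect_equal(fx, rev(fx), tolerance = 1e-10)
})

test_that("backprojection input contracts are enforced", {
  grid <- cbct_grid(c(5, 5, 5), 8)
  g <- fix_mini()$geometry
  expect_error(backproject(array(0, c(4, 4, 0)), numeric(0), g, grid), "no projections")
  vol <- backproject(array(0, c(63, 50, 3)), c(0, 90, 180), g, grid)
  expect_equal(max(abs(vol$data)), 0)
})

test_that("FDK recovers absolute attenuation of a static sphere from a short scan", {
  grid <- fix_mini()$grid
  geom <- fix_mini()$geometry
  ps <- simulate_scan(fix_sphere_v4(), geom, scan_protocol("rapid"))
  rec <- fdk3d(ps, grid)
  ctr <- round(grid$dim / 2)
  roi <- rec$data[(ctr[1] - 3):(ctr[1] + 3), (ctr[2] - 3):(ctr[2] + 3),
                  (ctr[3] - 3):(ctr[3] + 3)]
  expect_equal(mean(roi), 0.02, tolerance = 0.05)

  # short scan agrees with a full 360-degree scan
  geom360 <- scan_geometry(detector_cols = 63, detector_rows = 50,
                           pixel_pitch = 8, arc_deg = 360)
  rec360 <- fdk3d(simulate_scan(fix_sphere_v4(), geom360, scan_protocol("rapid")), grid)
  roi360 <- rec360$data[(ctr[1] - 3):(ctr[1] + 3), (ctr[2] - 3):(ctr[2] + 3),
                        (ctr[3] - 3):(ctr[3] + 3)]
  expect_equal(mean(roi), mean(roi360), tolerance = 0.03)
})

test_that("static-phantom reconstruction error decreases with projection count", {
  # few-view regime, where streak error is far above the discretization floor
  grid <- fix_mini()$grid
  geom <- fix_mini()$geometry
  truth <- fix_sphere_v4()$phases[[1]]$data
  ctr <- round(grid$dim / 2)
  sub <- function(a) a[(ctr[1] - 8):(ctr[1] + 8), (ctr[2] - 8):(ctr[2] + 8),
                       (ctr[3] - 8):(ctr[3] + 8)]
  errs <- vapply(c(15, 30, 60), function(np) {
    ps <- simulate_scan(fix_sphere_v4(), geom, scan_protocol("custom", np, 16.6, 16.1))
    sqrt(mean((sub(fdk3d(ps, grid)$data) - sub(truth))^2))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("phase-correlated FDK uses only each bin's projections", {
  grid <- fix_mini()$grid
  ps <- fix_rapid_ps()
  v4 <- suppressWarnings(fdk4d(ps, grid))
  expect_length(v4$phases, 10)
  # rapid bins have angular gaps beyond 30 degrees (sparse by design)
  expect_true(any(attr(v4, "max_gap_deg") > 30))

  # bin reconstruction equals fdk3d on the same subset
  idx <- which(ps$phase_bins == 3)
  expect_equal(v4$phases[[4]]$data, fdk3d(ps, grid, idx = idx)$data,
               tolerance = 1e-12)

  # an empty bin is an explicit error naming the bin
  ps2 <- ps
  ps2$phase_bins[ps2$phase_bins == 7] <- 6L
  expect_error(suppressWarnings(fdk4d(ps2, grid)), "bin 7")
})

test_that("zero-motion input makes all 4DFDK conventional-bin volumes consistent", {
  grid <- fix_mini()$grid
  geom <- fix_mini()$geometry
  ps <- simulate_scan(fix_sphere_v4(), geom, scan_protocol("conventional"))
  expect_equal(as.numeric(table(ps$phase_bins)), rep(132, 10))
  v4 <- suppressWarnings(fdk4d(ps, grid))
  ctr <- round(grid$dim / 2)
  sub <- function(v) v$data[(ctr[1] - 6):(ctr[1] + 6), (ctr[2] - 6):(ctr[2] + 6),
                            (ctr[3] - 6):(ctr[3] + 6)]
  for (p in 2:10)
    expect_equal(sub(v4$phases[[p]]), sub(v4$phases[[1]]), tolerance = 0.05)
  # and their mean approximates the all-projection reconstruction
  mv <- mean_volume(v4)
  r3 <- fdk3d(ps, grid)
  expect_lt(sqrt(mean((sub(mv) - sub(r3))^2)), 0.05 * 0.02)
})
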