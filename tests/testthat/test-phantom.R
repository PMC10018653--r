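test_that("phantom construction is deterministic and validates nesting", {
  a <- build_phantom(seed = 1, vary = TRUE)
  b <- build_phantom(seed = 1, vary = TRUE)
  expect_identical(a, b)

  # cohort mode: distinct anatomy per seed
  centers <- t(vapply(1:10, function(s) build_phantom(seed = s, vary = TRUE)$tumor_center,
                      numeric(3)))
  expect_equal(nrow(unique(round(centers, 6))), 10)

  # structures escaping the body are a configuration error
  expect_error(build_phantom(list(lungL_center = c(-140, 0, 28))), "nested")
  expect_error(build_phantom(list(tumor_center = c(-20, 0, 20))), "tumor")
  expect_error(build_phantom(list(diaphragm_amp = -1)), "amplitude")
})

test_that("diaphragm interface position tracks the motion amplitude", {
  for (amp in c(0, 5, 12, 20)) {
    ph <- build_phantom(list(diaphragm_amp = amp, tumor_amp = c(0, 0, 0)))
    z0 <- ph$diaphragm_z0
    # interface at peak exhale (w = 1) sits amp above the peak-inhale one
    expect_equal((z0 + ph$diaphragm_amp * resp_wave(0.5)) - z0, amp)
  }
})

test_that("voxelization gives innermost-structure attenuation at voxel centers", {
  ph <- fix_phantom()
  grid <- fix_mini()$grid
  v0 <- voxelize(ph, 0, grid)
  co <- grid_coords(grid)
  at <- function(vol, p) vol$data[which.min(abs(co$x - p[1])),
                                  which.min(abs(co$y - p[2])),
                                  which.min(abs(co$z - p[3]))]
  expect_equal(at(v0, c(0, -80, 120)), ph$mu_body)     # soft tissue, no overlap
  expect_equal(at(v0, c(-200, 0, 0)), 0)               # outside the body
  expect_equal(at(v0, ph$tumor_center), ph$mu_tumor)
  expect_equal(at(v0, c(70, 0, 80)), ph$mu_lung)       # upper right lung, peak inhale

  # tumor center moves by its amplitude between phase 0 and 0.5
  v5 <- voxelize(ph, 0.5, grid)
  expect_equal(at(v5, ph$tumor_center + ph$tumor_amp), ph$mu_tumor)

  # motion is cyclic: phase 0 and phase 1.0 identical bitwise
  expect_identical(v0$data, voxelize(ph, 1, grid)$data)

  # determinism
  expect_identical(v0$data, voxelize(ph, 0, grid)$data)
})

test_that("10-phase 4DCT flags a unique peak-inhale phase of maximal lung volume", {
  v4 <- fix_gt4d()
  expect_length(v4$phases, 10)
  expect_equal(v4$peak_inhale, 1L)   # zero waveform = diaphragm most inferior
  counts <- vapply(v4$phases, function(v) sum(v$data > 0.001 & v$data < 0.012),
                   numeric(1))
  # the flagged phase holds the maximal lung volume up to the sub-voxel
  # re-discretization jitter of the small moving structures
  expect_gte(counts[v4$peak_inhale], 0.995 * max(counts))

  # zero-amplitude phantom: all phases identical
  ph0 <- build_phantom(list(diaphragm_amp = 0, tumor_amp = c(0, 0, 0),
                            heart_amp = c(0, 0, 0), mu_lung_vent = 0))
  v40 <- generate_4dct(ph0, fix_mini()$grid)
  for (p in 2:10) expect_identical(v40$phases[[p]]$data, v40$phases[[1]]$data)
})

test_that("the time-averaged 3DCT blurs the diaphragm edge", {
  v4 <- fix_gt4d()
  gt3d <- mean_volume(v4)
  rois <- auto_rois(fix_phantom(), fix_mini()$grid)
  spread <- function(vol) {
    runs <- vol$data[rois$tiw_box$lo[1]:rois$tiw_box$hi[1],
                     rois$tiw_box$lo[2]:rois$tiw_box$hi[2],
                     rois$tiw_box$lo[3]:rois$tiw_box$hi[3]]
    pr <- apply(runs, 3, mean)
    pr <- (pr - min(pr)) / diff(range(pr))
    # 10-90% transition width of the mean SI profile (voxels)
    sum(pr > 0.1 & pr < 0.9)
  }
  expect_gte(spread(gt3d), spread(v4$phases[[1]]))
})

test_that("analytic DVFs vanish where they should and register phases", {
  ph <- fix_phantom()
  grid <- fix_mini()$grid
  expect_equal(max(abs(analytic_dvf(ph, 3, 3, grid)$data)), 0)
  ph0 <- build_phantom(list(diaphragm_amp = 0, tumor_amp = c(0, 0, 0),
                            heart_amp = c(0, 0, 0)))
  expect_equal(max(abs(analytic_dvf(ph0, 6, 1, grid)$data)), 0)

  # warping peak exhale to peak inhale beats not warping (lung/interface box)
  v4 <- fix_gt4d()
  dvf <- analytic_dvf(ph, 6, 1, grid)
  w <- warp(v4$phases[[6]], dvf)
  rois <- auto_rois(ph, grid)
  b <- rois$similarity_box
  sub <- function(v) v$data[b$lo[1]:b$hi[1], b$lo[2]:b$hi[2], b$lo[3]:b$hi[3]]
  ref <- sub(v4$phases[[1]])
  expect_lt(sqrt(mean((sub(w) - ref)^2)), sqrt(mean((sub(v4$phases[[6]]) - ref)^2)))
})

test_that("planning mismatch scales motion and drifts anatomy", {
  ph <- fix_phantom()
  expect_identical(unclass(mismatch(ph, 1, c(0, 0, 0))), unclass(ph))

  pl <- mismatch(ph, 1, c(5, -3, 2))
  expect_equal(pl$tumor_center - ph$tumor_center, c(5, -3, 2))
  expect_equal(pl$liver_center - ph$liver_center, c(5, -3, 2))
  expect_equal(pl$diaphragm_z0 - ph$diaphragm_z0, 2)

  # scaled planning motion scales the DVF at the diaphragm apex
  grid <- fix_mini()$grid
  pl7 <- mismatch(ph, 0.7, c(0, 0, 0))
  d1 <- analytic_dvf(ph, 6, 1, grid)
  d7 <- analytic_dvf(pl7, 6, 1, grid)
  co <- grid_coords(grid)
  i <- which.min(abs(co$x - 70)); j <- which.min(abs(co$y))
  k <- which.min(abs(co$z - ph$diaphragm_z0))
  expect_equal(d7$data[i, j, k, 3] / d1$data[i, j, k, 3], 0.7, tolerance = 1e-6)

  expect_error(mismatch(ph, 0), "amplitude_scale")
})

test_that("automatic ROIs land in the intended phantom regions", {
  ph <- fix_phantom()
  grid <- fix_mini()$grid
  rois <- auto_rois(ph, grid)
  expect_true(rois$cnr_ok && rois$tiw_ok)

  gt3d <- mean_volume(fix_gt4d())
  fg <- gt3d$data[rois$cnr_foreground$lo[1]:rois$cnr_foreground$hi[1],
                  rois$cnr_foreground$lo[2]:rois$cnr_foreground$hi[2],
                  rois$cnr_foreground$lo[3]:rois$cnr_foreground$hi[3]]
  expect_equal(as.numeric(fg), rep(ph$mu_liver, length(fg)),
               tolerance = 1e-12)             # homogeneous liver
  bg <- gt3d$data[rois$cnr_background$lo[1]:rois$cnr_background$hi[1],
                  rois$cnr_background$lo[2]:rois$cnr_background$hi[2],
                  rois$cnr_background$lo[3]:rois$cnr_background$hi[3]]
  expect_true(all(abs(bg - ph$mu_lung) < ph$mu_lung_vent + 1e-9))  # homogeneous lung

  # interface column spans lung value (superior) to liver value (inferior)
  tw <- voxelize(ph, 0, grid)$data[rois$tiw_box$lo[1]:rois$tiw_box$hi[1],
                                   rois$tiw_box$lo[2]:rois$tiw_box$hi[2],
                                   rois$tiw_box$lo[3]:rois$tiw_box$hi[3]]
  expect_equal(unique(as.numeric(tw[, , 1])), ph$mu_liver)
  expect_equal(unique(as.numeric(tw[, , dim(tw)[3]])), ph$mu_lung)

  # a field of view that excludes the diaphragm flags CNR/TIW non-computable
  small <- cbct_grid(c(30, 28, 20), 8, origin = c(-116, -108, 40))
  rois2 <- auto_rois(ph, small)
  expect_false(rois2$tiw_ok)
})
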