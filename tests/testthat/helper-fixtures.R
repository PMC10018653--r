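# Shared fixtures, built once per test run. Everything is generated in code;
# "mini" scale (8 mm voxels, 63x50 detector) keeps unit tests fast while
# preserving the protocols' angular/respiratory sampling structure.

.fix <- new.env()

fix_mini <- function() {
  if (is.null(.fix$mini)) .fix$mini <- study_preset("mini")
  .fix$mini
}

fix_phantom <- function() {
  if (is.null(.fix$phantom)) .fix$phantom <- build_phantom(seed = 1)
  .fix$phantom
}

fix_gt4d <- function() {
  if (is.null(.fix$gt4d))
    .fix$gt4d <- generate_4dct(fix_phantom(), fix_mini()$grid)
  .fix$gt4d
}

# static uniform sphere (r 60 mm, mu 0.02) on the mini grid, supersampled
fix_sphere_v4 <- function() {
  if (is.null(.fix$sphere)) {
    grid <- fix_mini()$grid
    co <- grid_coords(grid)
    acc <- array(0, grid$dim)
    for (ox in c(-0.25, 0.25)) for (oy in c(-0.25, 0.25)) for (oz in c(-0.25, 0.25)) {
      r2 <- outer(outer((co$x + ox * grid$spacing[1])^2,
                        (co$y + oy * grid$spacing[2])^2, "+"),
                  (co$z + oz * grid$spacing[3])^2, "+")
      acc <- acc + (r2 <= 60^2) * 0.02
    }
    vol <- cbct_volume(acc / 8, grid$spacing, grid$origin)
    .fix$sphere <- cbct_volume4d(rep(list(vol), 10), (0:9) / 10, 1L)
  }
  .fix$sphere
}

# rapid-protocol scan of the mini thorax phantom, reused across recon tests
fix_rapid_ps <- function() {
  if (is.null(.fix$rapid_ps))
    .fix$rapid_ps <- simulate_scan(fix_gt4d(), fix_mini()$geometry,
                                   scan_protocol("rapid"))
  .fix$rapid_ps
}

# separable 3D Gaussian blur used by metric-degradation property tests
blur3 <- function(a, sigma_vox) {
  if (sigma_vox <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-r):r)^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  pad_filter <- function(x) as.numeric(stats::filter(
    c(rep(x[1], r), x, rep(x[length(x)], r)), k, sides = 2))[(r + 1):(r + length(x))]
  a <- apply(a, c(2, 3), pad_filter)                 # along dim 1
  a <- aperm(apply(a, c(1, 3), pad_filter), c(2, 1, 3))  # along dim 2
  a <- aperm(apply(a, c(1, 2), pad_filter), c(2, 3, 1))  # along dim 3
  a
}
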