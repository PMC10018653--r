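## Parametric 4D thorax phantom.
##
## Anatomy: torso column (body ellipsoid strongly elongated in z, so the
## body extends axially past the imaged field of view like a real torso),
## two lung ellipsoids (low
## attenuation), a heart/mediastinum ellipsoid carved out between the lungs,
## a liver ellipsoid under the right lung and a stomach/spleen ellipsoid
## under the left lung, a moving diaphragm interface on both sides (the
## parts of the lungs below a superior-inferiorly translating plane are
## filled with the subdiaphragmatic tissue), and a spherical tumor in the
## left lung. Attenuation is linear (mm^-1): lung ~ -800 HU, soft tissue
## 0 HU, heart ~ +50 HU, liver ~ +75 HU, tumor ~ +30 HU at
## mu_water = 0.02 mm^-1.
##
## Motion: both hemidiaphragms translate superior-inferiorly (free-breathing
## excursion 10-20 mm), the heart follows with a smaller excursion
## (respiratory-induced cardiac displacement, ~6 mm SI), and the tumor moves
## with its own 3D amplitude.
##
## Motion: every moving structure follows the same smooth cyclic waveform
## w(p) = (1 - cos(2 pi (p - offset))) / 2, so phase 0 (w = 0) is peak inhale
## (diaphragm at its most inferior position, maximum lung volume) and
## phase 0.5 is peak exhale.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Respiratory displacement waveform
#'
#' `w(p) = (1 - cos(2 pi (p - offset))) / 2`: smooth, cyclic, zero at the
#' reference (peak-inhale) phase and one at peak exhale.
#'
#' @param phase phase fraction(s) in `[0, 1)`.
#' @param offset phase offset.
#' @return waveform value(s) in `[0, 1]`.
#' @export
resp_wave <- function(phase, offset = 0) (1 - cos(2 * pi * (phase - offset))) / 2

default_phantom_params <- function() {
  list(
    body_center  = c(0, 0, 0),     body_semi  = c(140, 95, 400), mu_body  = 0.0200,
    lungL_center = c(-70, 0, 28), lungL_semi = c(53, 59, 84),
    lungR_center = c(70, 0, 28),  lungR_semi = c(53, 59, 84),   mu_lung  = 0.0040,
    liver_center = c(68, 5, -55), liver_semi = c(48, 55, 58),   mu_liver = 0.0215,
    stomach_center = c(-68, 5, -55), stomach_semi = c(48, 55, 58), mu_stomach = 0.0208,
    heart_center = c(10, 25, 25),  heart_semi = c(45, 40, 45),   mu_heart = 0.0210,
    heart_amp = c(0, 2, 6),        # respiratory-induced cardiac excursion, mm
    diaphragm_z0 = -35,
    tumor_center = c(-70, 0, 20), tumor_radius = 12,            mu_tumor = 0.0206,
    diaphragm_amp = 15,            # superior excursion inhale -> exhale, mm
    tumor_amp = c(0, 2, 10),       # 3D tumor excursion, mm
    mu_lung_vent = 0.0012,         # ventilation: lung density swing inhale -> exhale
    bubble_radius = 14,            # stomach gas bubble under the left dome
    mu_bubble = 0,
    n_vessels = 14L,               # intrapulmonary vessel/nodule blobs
    vessel_radius = c(3.5, 7),     mu_vessel = 0.0185,
    phase_offset = 0,
    n_phases = 10L
  )
}

## blended unit displacement (per waveform step) at a single point, matching
## phantom_unit_fields(); used to move vessel blobs with the local field
point_unit_disp <- function(p, pt) {
  gz <- smooth_window(pt[3], p$diaphragm_z0 - 45, p$diaphragm_z0 + p$diaphragm_amp + 8, 40)
  rr <- function(lc, ls) sqrt(((pt[1] - lc[1]) / ls[1])^2 + ((pt[2] - lc[2]) / ls[2])^2)
  gxy <- min(smooth_window(rr(p$lungR_center, p$lungR_semi), 0, 1.05, 0.8) +
             smooth_window(rr(p$lungL_center, p$lungL_semi), 0, 1.05, 0.8), 1)
  g_dia <- gxy * gz
  hr <- sqrt(sum(((pt - p$heart_center) / p$heart_semi)^2))
  g_heart <- smooth_window(hr, 0, 1.1, 0.55)
  d_bg <- p$heart_amp * g_heart + (1 - g_heart) * c(0, 0, p$diaphragm_amp * g_dia)
  tr <- sqrt(sum((pt - p$tumor_center)^2))
  g_tum <- smooth_window(tr, 0, p$tumor_radius + 4, 25)
  p$tumor_amp * g_tum + (1 - g_tum) * d_bg
}

## deterministic vessel/nodule placement inside the lung interiors, kept
## clear of the metric ROIs (upper-right-lung background box, diaphragm
## interface column, tumor) and of the carved heart
draw_vessels <- function(p) {
  bg_c <- p$lungR_center + c(0, 0, 0.55 * p$lungR_semi[3])
  tiw_xy <- p$lungR_center[1:2]
  vessels <- list()
  for (side in c("lungL", "lungR")) {
    lc <- p[[paste0(side, "_center")]]
    ls <- p[[paste0(side, "_semi")]]
    n_target <- ceiling(p$n_vessels / 2)
    tries <- 0
    while (length(vessels) < ifelse(side == "lungL", n_target,
                                    p$n_vessels) && tries < 400) {
      tries <- tries + 1
      u <- runif(3, -1, 1)
      if (sum(u^2) > 1) next
      c0 <- lc + 0.72 * ls * u
      r <- runif(1, p$vessel_radius[1], p$vessel_radius[2])
      if (c0[3] - r < p$diaphragm_z0 + p$diaphragm_amp + 12) next
      if (sqrt(sum((c0 - bg_c)^2)) < 30) next
      if (sqrt(sum((c0[1:2] - tiw_xy)^2)) < 26 && side == "lungR") next
      if (sqrt(sum((c0 - p$tumor_center)^2)) < p$tumor_radius + r + 12) next
      if (sqrt(sum(((c0 - p$heart_center) / p$heart_semi)^2)) < 1.3) next
      vessels[[length(vessels) + 1L]] <-
        list(center = c0, radius = r, disp = point_unit_disp(p, c0))
    }
  }
  vessels
}

inside_ellipsoid <- function(p, center, semi) {
  sum(((p - center) / semi)^2) <= 1
}

## surface sample of ellipsoid `inner` fully inside ellipsoid `outer`?
nested_in <- function(center, semi, out_center, out_semi, n = 14) {
  th <- seq(0, pi, length.out = n)
  ph <- seq(0, 2 * pi, length.out = 2 * n)
  for (t in th) for (f in ph) {
    p <- center + semi * c(sin(t) * cos(f), sin(t) * sin(f), cos(t))
    if (!inside_ellipsoid(p, out_center, out_semi)) return(FALSE)
  }
  TRUE
}

#' Build a 4D thorax phantom
#'
#' Constructs the parametric phantom from defaults overridden by `config`.
#' With `vary = TRUE` (cohort mode) anatomy and motion are drawn from
#' physiologically plausible per-patient ranges (diaphragm excursion
#' 10-20 mm, tumor excursion 5-15 mm SI, tumor radius 9-15 mm, jittered
#' tumor position and diaphragm rest height), deterministically from `seed`.
#'
#' @param config named list overriding any default parameter
#'   (see `cbct4d:::default_phantom_params`).
#' @param seed integer; the phantom is deterministic given `config` + `seed`.
#' @param vary draw per-patient anatomy/motion variation (cohort mode).
#' @return A `cbct_phantom` object.
#' @export
build_phantom <- function(config = list(), seed = 1L, vary = FALSE) {
  p <- default_phantom_params()
  if (vary) {
    p <- with_seed(seed, {
      p$diaphragm_amp <- runif(1, 10, 20)
      p$tumor_amp <- c(0, runif(1, 0, 3), runif(1, 5, 15))
      p$tumor_radius <- runif(1, 9, 15)
      p$tumor_center <- p$tumor_center + c(runif(1, -10, 10), runif(1, -10, 10),
                                           runif(1, -10, 15))
      p$diaphragm_z0 <- runif(1, -40, -30)
      p$lungL_semi <- p$lungL_semi * runif(1, 0.95, 1.05)
      p$lungR_semi <- p$lungR_semi * runif(1, 0.95, 1.05)
      p$heart_amp <- c(0, runif(1, 0, 3), runif(1, 4, 10))
      p
    })
  }
  bad <- setdiff(names(config), names(p))
  if (length(bad)) stop("unknown phantom parameter(s): ", paste(bad, collapse = ", "))
  p[names(config)] <- config
  p$seed <- as.integer(seed)
  if (p$diaphragm_amp < 0 || any(p$tumor_amp^2 < 0)) stop("amplitudes must be >= 0")
  for (s in c("lungL", "lungR")) {
    if (!nested_in(p[[paste0(s, "_center")]], p[[paste0(s, "_semi")]],
                   p$body_center, p$body_semi))
      stop(s, " not nested inside body: configuration error")
  }
  ## tumor must stay inside its lung over the whole motion range
  for (w in c(0, 0.5, 1)) {
    tc <- p$tumor_center + p$tumor_amp * w
    if (!nested_in(tc, rep(p$tumor_radius, 3), p$lungL_center, p$lungL_semi))
      stop("tumor (incl. motion range) not inside left lung: configuration error")
  }
  for (s in c("liver", "stomach", "heart")) {
    if (!nested_in(p[[paste0(s, "_center")]], p[[paste0(s, "_semi")]],
                   p$body_center, p$body_semi))
      stop(s, " not nested inside body: configuration error")
  }
  ## tumor must stay above the highest diaphragm position
  if (p$tumor_center[3] - p$tumor_radius < p$diaphragm_z0 + p$diaphragm_amp)
    stop("tumor overlaps the diaphragm motion band: configuration error")
  p$bubble_center <- c(p$stomach_center[1] + 6, p$stomach_center[2] - 5,
                       p$diaphragm_z0 - 22)
  p$vessels <- with_seed(seed + 5000L, draw_vessels(p))
  structure(p, class = "cbct_phantom")
}

#' @export
print.cbct_phantom <- function(x, ...) {
  cat("<cbct_phantom> diaphragm amp ", signif(x$diaphragm_amp, 3),
      " mm, tumor amp (", paste(signif(x$tumor_amp, 3), collapse = ", "),
      ") mm, tumor r ", signif(x$tumor_radius, 3), " mm, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Planning-scan variant of a phantom (motion mismatch + setup drift)
#'
#' Emulates a planning 4DCT acquired on a different day: motion amplitudes are
#' scaled by `amplitude_scale` and the whole anatomy (all structure centers and
#' the diaphragm rest height) is rigidly offset by `drift_mm`. The original
#' (ground-truth) phantom is unchanged.
#'
#' @param phantom `cbct_phantom`.
#' @param amplitude_scale positive motion-amplitude scale factor.
#' @param drift_mm length-3 rigid setup offset (mm).
#' @return A new `cbct_phantom`.
#' @export
mismatch <- function(phantom, amplitude_scale = 1, drift_mm = c(0, 0, 0)) {
  if (amplitude_scale <= 0) stop("amplitude_scale must be > 0")
  p <- unclass(phantom)
  drift_mm <- as.numeric(drift_mm)
  p$diaphragm_amp <- p$diaphragm_amp * amplitude_scale
  p$tumor_amp <- p$tumor_amp * amplitude_scale
  p$heart_amp <- p$heart_amp * amplitude_scale
  for (f in c("body_center", "lungL_center", "lungR_center", "liver_center",
              "stomach_center", "heart_center", "tumor_center", "bubble_center"))
    p[[f]] <- p[[f]] + drift_mm
  p$diaphragm_z0 <- p$diaphragm_z0 + drift_mm[3]
  p$vessels <- lapply(p$vessels, function(v) {
    v$center <- v$center + drift_mm
    v$disp <- v$disp * amplitude_scale
    v
  })
  structure(p, class = "cbct_phantom")
}

## ellipsoid membership over the grid as a 3D logical array, built from
## separable quadratic terms (voxel-center membership)
ellipsoid_mask <- function(cx, cy, cz, center, semi) {
  qx <- ((cx - center[1]) / semi[1])^2
  qy <- ((cy - center[2]) / semi[2])^2
  qz <- ((cz - center[3]) / semi[3])^2
  outer(outer(qx, qy, "+"), qz, "+") <= 1
}

voxelize_at <- function(phantom, phase_fraction, grid, sub = c(0, 0, 0)) {
  p <- phantom
  co <- grid_coords(grid)
  cx <- co$x + sub[1]; cy <- co$y + sub[2]; cz <- co$z + sub[3]
  w <- resp_wave(phase_fraction, p$phase_offset)
  vol <- array(0, grid$dim)
  vol[ellipsoid_mask(cx, cy, cz, p$body_center, p$body_semi)] <- p$mu_body
  vol[ellipsoid_mask(cx, cy, cz, p$liver_center, p$liver_semi)] <- p$mu_liver
  vol[ellipsoid_mask(cx, cy, cz, p$stomach_center, p$stomach_semi)] <- p$mu_stomach
  lungL <- ellipsoid_mask(cx, cy, cz, p$lungL_center, p$lungL_semi)
  lungR <- ellipsoid_mask(cx, cy, cz, p$lungR_center, p$lungR_semi)
  ## ventilation: lung density rises from peak inhale (most air) to exhale
  vol[lungL | lungR] <- p$mu_lung + p$mu_lung_vent * w
  ## moving diaphragm: lung below the interface is subdiaphragmatic tissue
  zd <- p$diaphragm_z0 + p$diaphragm_amp * w
  below <- outer(array(TRUE, c(length(cx), length(cy))), cz < zd, "&")
  vol[lungR & below] <- p$mu_liver
  vol[lungL & below] <- p$mu_stomach
  ## stomach gas bubble rides the left hemidiaphragm
  bc <- p$bubble_center + c(0, 0, p$diaphragm_amp * w)
  vol[ellipsoid_mask(cx, cy, cz, bc, rep(p$bubble_radius, 3))] <- p$mu_bubble
  ## heart carves into the medial lungs and moves with respiration
  hc <- p$heart_center + p$heart_amp * w
  vol[ellipsoid_mask(cx, cy, cz, hc, p$heart_semi)] <- p$mu_heart
  ## vessel/nodule blobs advected by the local motion field
  for (v in p$vessels) {
    vc <- v$center + v$disp * w
    vol[ellipsoid_mask(cx, cy, cz, vc, rep(v$radius, 3))] <- p$mu_vessel
  }
  tc <- p$tumor_center + p$tumor_amp * w
  vol[ellipsoid_mask(cx, cy, cz, tc, rep(p$tumor_radius, 3))] <- p$mu_tumor
  vol
}

#' Voxelize the phantom at a respiratory phase
#'
#' Voxel value = attenuation of the innermost structure containing the voxel
#' center at that phase (exact, no partial volume). `supersample = 2` averages
#' a 2x2x2 sub-voxel sample instead, giving smoother (partial-volume) edges.
#'
#' @param phantom `cbct_phantom`.
#' @param phase_fraction phase in `[0, 1)` (values >= 1 wrap cyclically).
#' @param grid `cbct_grid`.
#' @param supersample 1 (voxel-center membership) or small integer s for
#'   s^3-point averaging.
#' @return `cbct_volume` of linear attenuation (mm^-1).
#' @export
voxelize <- function(phantom, phase_fraction, grid, supersample = 1L) {
  phase_fraction <- phase_fraction %% 1
  s <- as.integer(supersample)
  if (s <= 1L) {
    v <- voxelize_at(phantom, phase_fraction, grid)
  } else {
    off <- (seq_len(s) - (s + 1) / 2) / s
    v <- array(0, grid$dim)
    for (ox in off) for (oy in off) for (oz in off)
      v <- v + voxelize_at(phantom, phase_fraction, grid,
                           sub = c(ox, oy, oz) * grid$spacing)
    v <- v / s^3
  }
  cbct_volume(v, grid$spacing, grid$origin)
}

lung_voxel_count <- function(vol) {
  sum(vol$data > 0.001 & vol$data < 0.012)
}

#' Generate the 10-phase 4DCT of a phantom
#'
#' Voxelizes the phantom at phase fractions `k / n_phases`, `k = 0 ...
#' n_phases - 1`, and flags the peak-inhale phase: the phase of maximum lung
#' volume, which by construction of the motion model is the phase of minimum
#' waveform (the diaphragm at its most inferior position). Voxel counting on
#' coarse grids is a noisy estimator of lung volume (sub-voxel diaphragm
#' shifts are invisible while sphere re-discretization jitters counts), so
#' the flag is taken from the waveform; reconstructed volume sets, where only
#' images exist, are flagged by thresholded lung voxel counts instead.
#'
#' @inheritParams voxelize
#' @return `cbct_volume4d`.
#' @export
generate_4dct <- function(phantom, grid, supersample = 1L) {
  n <- phantom$n_phases
  fr <- (seq_len(n) - 1) / n
  phases <- lapply(fr, function(f) voxelize(phantom, f, grid, supersample))
  peak <- which.min(resp_wave(fr, phantom$phase_offset))
  cbct_volume4d(phases, fr, peak)
}

## smooth 0..1 window: 1 on [a, b], cosine rolloff to 0 over `fall` outside
smooth_window <- function(x, a, b, fall) {
  y <- numeric(length(x))
  y[x >= a & x <= b] <- 1
  lo <- x < a & x > a - fall
  y[lo] <- 0.5 * (1 + cos(pi * (a - x[lo]) / fall))
  hi <- x > b & x < b + fall
  y[hi] <- 0.5 * (1 + cos(pi * (x[hi] - b) / fall))
  y
}

## unit (per waveform step) displacement support fields, in reference coords.
## Falloff scales are chosen so the displacement Jacobian stays well below 1
## at the largest amplitudes (fixed-point invertibility).
phantom_unit_fields <- function(phantom, grid, w_ref = 0) {
  p <- phantom
  co <- grid_coords(grid)
  ## diaphragm: SI displacement inside both lung columns around the
  ## interface motion band, smooth falloff outside
  gz <- smooth_window(co$z, p$diaphragm_z0 - 45, p$diaphragm_z0 + p$diaphragm_amp + 8, 40)
  col_window <- function(lc, ls) {
    rx <- ((co$x - lc[1]) / ls[1])^2
    ry <- ((co$y - lc[2]) / ls[2])^2
    rr <- sqrt(outer(rx, ry, "+"))
    array(smooth_window(rr, 0, 1.05, 0.8), dim(rr))
  }
  gxy <- pmin(col_window(p$lungR_center, p$lungR_semi) +
              col_window(p$lungL_center, p$lungL_semi), 1)
  g_dia <- outer(gxy, gz, "*")
  ## tumor: 3D displacement near the reference-phase tumor position
  tc <- p$tumor_center + p$tumor_amp * w_ref
  dx2 <- (co$x - tc[1])^2
  dy2 <- (co$y - tc[2])^2
  dz2 <- (co$z - tc[3])^2
  r <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
  g_tum <- array(smooth_window(r, 0, p$tumor_radius + 4, 25), dim(r))
  ## heart: normalized-radius window around the reference-phase heart
  hc <- p$heart_center + p$heart_amp * w_ref
  hx <- ((co$x - hc[1]) / p$heart_semi[1])^2
  hy <- ((co$y - hc[2]) / p$heart_semi[2])^2
  hz <- ((co$z - hc[3]) / p$heart_semi[3])^2
  hr <- sqrt(outer(outer(hx, hy, "+"), hz, "+"))
  g_heart <- array(smooth_window(hr, 0, 1.1, 0.55), dim(hr))
  list(g_dia = g_dia, g_tum = g_tum, g_heart = g_heart)
}

#' Analytic deformation field between two phantom phases
#'
#' Returns the displacement field (pull convention) that maps reference-phase
#' coordinates to the coordinates of the same anatomy at `from_phase`:
#' `warp(voxelize(phantom, from), analytic_dvf(phantom, from, ref, grid))`
#' approximates `voxelize(phantom, ref)`. Displacements follow the phantom's
#' motion model exactly on the moving structures and fall off smoothly
#' (cosine windows) outside them.
#'
#' @param phantom `cbct_phantom`.
#' @param from_phase,reference_phase 1-based phase indices in `1..n_phases`.
#' @param grid `cbct_grid`.
#' @return `cbct_dvf`.
#' @export
analytic_dvf <- function(phantom, from_phase, reference_phase, grid) {
  n <- phantom$n_phases
  stopifnot(from_phase >= 1, from_phase <= n, reference_phase >= 1, reference_phase <= n)
  w_from <- resp_wave((from_phase - 1) / n, phantom$phase_offset)
  w_ref <- resp_wave((reference_phase - 1) / n, phantom$phase_offset)
  dw <- w_from - w_ref
  d <- array(0, c(grid$dim, 3L))
  if (abs(dw) > 0) {
    ## structure displacements are blended hierarchically (tumor dominates
    ## its own support, then heart, then diaphragm) so each moving structure
    ## follows its own motion exactly inside its support
    g <- phantom_unit_fields(phantom, grid, w_ref)
    for (a in 1:3) {
      bg <- phantom$heart_amp[a] * g$g_heart +
        (1 - g$g_heart) * (if (a == 3) phantom$diaphragm_amp * g$g_dia else 0)
      d[, , , a] <- dw * (phantom$tumor_amp[a] * g$g_tum + (1 - g$g_tum) * bg)
    }
  }
  cbct_dvf(d, grid$spacing, grid$origin, from_phase, reference_phase)
}

## ---- automatic ROI placement ------------------------------------------------

box_to_idx <- function(center, half_mm, grid) {
  ci <- round((center - grid$origin) / grid$spacing) + 1
  hv <- floor(half_mm / grid$spacing)
  lo <- as.integer(ci - hv)
  hi <- as.integer(ci + hv)
  list(lo = lo, hi = hi, center_mm = center, half_mm = half_mm,
       inside = all(lo >= 1L) && all(hi <= grid$dim))
}

#' Automatic metric-ROI placement from phantom geometry
#'
#' Places, by construction from the known phantom parameters, the subvolumes
#' used by the image-quality metrics: a contrast foreground box in homogeneous
#' liver (21 mm cube), a background box in homogeneous upper right lung
#' (11 mm cube), a 5x5-voxel column straddling the lung-liver diaphragm
#' interface in the superior-inferior direction (run length `tiw_l_mm`), and a
#' large thoracic similarity box for RMSE/SSIM kept inside the lateral and
#' cone-angle field of view. At 1 mm spacing the boxes reproduce 21^3, 11^3
#' and 5x5x60 voxel subvolumes.
#'
#' If the diaphragm column (including its motion range) leaves the grid, the
#' ROI set is flagged (`tiw_ok`/`cnr_ok = FALSE`) and CNR/TIW are treated as
#' non-computable for that case.
#'
#' @param phantom `cbct_phantom`.
#' @param grid `cbct_grid`.
#' @param tiw_l_mm physical run length of the interface column (mm).
#' @param sid,sdd,det_half_u,det_half_v scan geometry (mm) used to keep the
#'   similarity box inside the reconstructable field of view.
#' @return A `cbct_roi_set` list of boxes (1-based inclusive index ranges)
#'   with computability flags.
#' @export
auto_rois <- function(phantom, grid, tiw_l_mm = 60,
                      sid = 1000, sdd = 1536, det_half_u = 250, det_half_v = 200) {
  p <- phantom
  lung_bottom <- p$lungR_center[3] - p$lungR_semi[3]
  fg_c <- c(p$liver_center[1], p$liver_center[2],
            (lung_bottom + p$liver_center[3] - 0.55 * p$liver_semi[3]) / 2)
  fg <- box_to_idx(fg_c, rep(10.5, 3), grid)
  bg_c <- p$lungR_center + c(0, 0, 0.55 * p$lungR_semi[3])
  bg <- box_to_idx(bg_c, rep(5.5, 3), grid)
  ## diaphragm column: 5x5 voxels laterally, tiw_l_mm along z, centered on the
  ## mid-motion interface position
  tiw_c <- c(p$lungR_center[1], p$lungR_center[2],
             p$diaphragm_z0 + p$diaphragm_amp / 2)
  ci <- round((tiw_c - grid$origin) / grid$spacing) + 1
  l_vox <- max(8L, as.integer(round(tiw_l_mm / grid$spacing[3])))
  tiw <- list(lo = as.integer(c(ci[1] - 2, ci[2] - 2, ci[3] - floor((l_vox - 1) / 2))),
              center_mm = tiw_c, l_vox = l_vox)
  tiw$hi <- as.integer(c(ci[1] + 2, ci[2] + 2, tiw$lo[3] + l_vox - 1L))
  tiw$inside <- all(tiw$lo >= 1L) && all(tiw$hi <= grid$dim)
  ## the whole motion band must be inside the grid for TIW to make sense
  zr <- c(p$diaphragm_z0 - 5, p$diaphragm_z0 + p$diaphragm_amp + 5)
  zmax <- grid$origin[3] + (grid$dim[3] - 1) * grid$spacing[3]
  tiw_ok <- tiw$inside && zr[1] >= grid$origin[3] && zr[2] <= zmax
  ## similarity box: large thoracic region inscribed in the body cross
  ## section (no exterior air / body-surface edges) and inside the lateral
  ## field of view and the cone-angle coverage
  fov_r <- det_half_u * sid / sdd
  hx <- min(0.72 * p$body_semi[1], 0.95 * fov_r)
  hy <- min(0.63 * p$body_semi[2], 0.95 * fov_r)
  rbox <- sqrt(hx^2 + hy^2)
  hz <- min(0.62 * p$body_semi[3], det_half_v * (sid - rbox) / sdd - max(grid$spacing))
  sim_c <- p$body_center
  sim_half <- c(hx, hy, hz)
  sim <- box_to_idx(sim_c, sim_half, grid)
  sim$lo <- pmax(sim$lo, 1L); sim$hi <- pmin(sim$hi, grid$dim)
  structure(list(cnr_foreground = fg, cnr_background = bg, tiw_box = tiw,
                 similarity_box = sim,
                 cnr_ok = fg$inside && bg$inside, tiw_ok = tiw_ok),
            class = "cbct_roi_set")
}

roi_values <- function(vol, box) {
  vol$data[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3]]
}
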