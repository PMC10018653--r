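## Motion-compensated FDK: rigid alignment of the reconstruction to the
## planning frame, translation of the planning deformation fields into the
## treatment frame, pull-style warping, deformation-field inversion, and the
## warp-average-inverse-warp MCFDK pipeline.

#' Rigid translation registration (normalized cross-correlation)
#'
#' Finds the translation `t` (mm) maximizing the normalized cross-correlation
#' between `moving` sampled at `x + t` and `fixed(x)`: coarse integer-voxel
#' grid search over `+/- range_mm`, then two fine sub-voxel grid refinements.
#' Both images are pre-smoothed with a small binomial kernel so that the
#' implicit blur of fractional-offset resampling does not bias the similarity
#' surface (the well-known interpolation artifact, which otherwise puts NCC
#' maxima at half-voxel offsets). Translation only; NCC makes the result
#' invariant to global affine intensity maps of either image.
#'
#' @param moving,fixed `cbct_volume`s on the same grid.
#' @param range_mm search half-range (mm).
#' @param box optional ROI (list with `lo`, `hi` voxel indices) over which NCC
#'   is evaluated; defaults to the central 80% of the grid.
#' @param stride voxel stride for NCC evaluation (speed/accuracy trade-off).
#' @return numeric length-3 translation (mm), with attribute `ncc`.
#' @export
rigid_translate_register <- function(moving, fixed, range_mm = 15,
                                     box = NULL, stride = 2L) {
  if (!same_grid(moving, fixed)) stop("moving and fixed must share a grid")
  if (sd(moving$data) == 0 || sd(fixed$data) == 0)
    stop("flat image (zero variance): registration impossible")
  d <- dim(fixed$data)
  moving <- cbct_volume(smooth121(moving$data), moving$spacing, moving$origin)
  fixed <- cbct_volume(smooth121(fixed$data), fixed$spacing, fixed$origin)
  if (is.null(box)) {
    lo <- pmax(round(d * 0.1), 1)
    hi <- pmin(round(d * 0.9), d)
    box <- list(lo = lo, hi = hi)
  }
  eval_ncc <- function(offsets) {
    ncc_offsets_cpp(as.numeric(moving$data), as.numeric(fixed$data), d,
                    moving$spacing, as.integer(box$lo - 1L),
                    as.integer(box$hi - 1L), as.integer(stride), offsets)
  }
  grid_around <- function(center, half, step) {
    s <- lapply(1:3, function(a) center[a] + seq(-half, half, by = step))
    as.matrix(expand.grid(s[[1]], s[[2]], s[[3]]))
  }
  step0 <- max(moving$spacing)
  cand <- grid_around(c(0, 0, 0), ceiling(range_mm / step0) * step0, step0)
  ncc <- eval_ncc(cand)
  best <- cand[which.max(ncc), ]
  for (step in c(step0 / 2, step0 / 8)) {
    cand <- grid_around(best, 2 * step, step)
    ncc <- eval_ncc(cand)
    best <- cand[which.max(ncc), ]
  }
  structure(as.numeric(best), ncc = max(ncc, na.rm = TRUE))
}

## separable [1 2 1]/4 smoothing along each axis, edges clamped
smooth121 <- function(a) {
  d <- dim(a)
  for (ax in 1:3) {
    n <- d[ax]
    lo <- seq_len(n); lo <- c(1L, lo[-n])
    hi <- seq_len(n); hi <- c(hi[-1], n)
    if (ax == 1) a <- (a[lo, , , drop = FALSE] + 2 * a + a[hi, , , drop = FALSE]) / 4
    if (ax == 2) a <- (a[, lo, , drop = FALSE] + 2 * a + a[, hi, , drop = FALSE]) / 4
    if (ax == 3) a <- (a[, , lo, drop = FALSE] + 2 * a + a[, , hi, drop = FALSE]) / 4
  }
  a
}

#' Express a planning-frame deformation field in the treatment frame
#'
#' Given the translation `t` returned by [rigid_translate_register()] between
#' a treatment-frame reconstruction (moving) and the planning reference
#' (fixed), the planning DVF is conjugated with the frame offset:
#' map the treatment point into the planning frame, apply the planning
#' displacement, and map back. For a pure translation the composition reduces
#' to resampling the field, `d'(x) = d(x - t)`; the displacement vectors
#' themselves are frame-independent, so a zero field stays zero and the
#' compensated reconstruction remains in the treatment frame.
#'
#' @param dvf `cbct_dvf` defined in the planning frame.
#' @param t length-3 translation (mm) from [rigid_translate_register()].
#' @return `cbct_dvf` in the treatment frame.
#' @export
apply_translation_to_dvf <- function(dvf, t) {
  t <- as.numeric(t)
  if (all(t == 0)) return(dvf)
  d <- dvf$data
  dims <- dim(d)[1:3]
  out <- array(0, dim(d))
  for (k in 1:3) {
    out[, , , k] <- array(
      shift_sample_cpp(as.numeric(d[, , , k]), dims, dvf$spacing, -t), dims)
  }
  cbct_dvf(out, dvf$spacing, dvf$origin, dvf$from_phase, dvf$to_phase)
}

#' Warp a volume with a deformation field (pull convention)
#'
#' `out(x) = in(x + d(x))` with trilinear sampling; samples falling outside
#' the grid take the nearest edge value (clamp-to-edge, avoiding zero halos
#' inside the body). Consequence of the pull convention: a constant field `d`
#' translates the image content by `-d`.
#'
#' @param volume `cbct_volume`.
#' @param dvf `cbct_dvf` on the same grid.
#' @return `cbct_volume`.
#' @export
warp <- function(volume, dvf) {
  dims <- dim(volume$data)
  if (!all(dim(dvf$data)[1:3] == dims)) stop("DVF grid does not match volume")
  v <- warp_cpp(as.numeric(volume$data), as.numeric(dvf$data), dims,
                volume$spacing, volume$origin)
  cbct_volume(array(v, dims), volume$spacing, volume$origin)
}

#' Invert a deformation field by fixed-point iteration
#'
#' Iterates `d_inv(x) <- -d(x + d_inv(x))` until the update falls below
#' `tol_voxel` (in voxel units) or `max_iter` is reached, then reports the
#' maximum composition residual `|d_inv(x) + d(x + d_inv(x))|`. Assumes
#' diffeomorphic-scale displacements (Jacobian perturbation below 1).
#'
#' @param dvf `cbct_dvf`.
#' @param tol_voxel convergence tolerance for the per-iteration update, in
#'   voxels.
#' @param max_iter maximum fixed-point iterations.
#' @return `cbct_dvf` (from/to phases swapped) with attributes `residual_mm`
#'   and `iterations`.
#' @export
invert_dvf <- function(dvf, tol_voxel = 0.01, max_iter = 50L) {
  dims <- dim(dvf$data)[1:3]
  res <- invert_dvf_cpp(as.numeric(dvf$data), dims, dvf$spacing,
                        tol_voxel * min(dvf$spacing), as.integer(max_iter))
  if (res$iterations >= max_iter &&
      res$residual_mm > 0.5 * min(dvf$spacing)) {
    stop("DVF inversion did not converge within ", max_iter,
         " iterations (residual ", signif(res$residual_mm, 3), " mm)")
  }
  out <- cbct_dvf(array(res$dvf, c(dims, 3L)), dvf$spacing, dvf$origin,
                  dvf$to_phase, dvf$from_phase)
  attr(out, "residual_mm") <- res$residual_mm
  attr(out, "iterations") <- res$iterations
  out
}

#' Motion-compensated FDK (MCFDK) reconstruction
#'
#' Uses all projections in all respiratory phases: (1) respiratory-correlated
#' 4D FDK of the projection data; (2) rigid translation registration of the
#' 3D FDK reconstruction to the planning 3DCT (mean of the planning 4DCT);
#' (3) the translation is applied to the planning deformation fields;
#' (4) each phase volume is warped to the reference (peak-inhale) phase and
#' the warped volumes are averaged with equal weights into a single reference
#' MCFDK volume; (5) the inverse fields map the reference volume back to the
#' other nine phases.
#'
#' @param ps `projection_set`.
#' @param planning_dvfs list of `n_phases` `cbct_dvf`s mapping each planning
#'   phase to the reference phase (the reference entry is the zero field);
#'   all must share `to_phase`.
#' @param planning_3dct `cbct_volume`: mean of the planning 4DCT.
#' @param grid `cbct_grid`.
#' @param hann passed to the FDK steps.
#' @return `cbct_volume4d` with attributes `translation_mm` (the rigid
#'   registration result) and `max_gap_deg` (from the underlying 4D FDK).
#' @export
mcfdk <- function(ps, planning_dvfs, planning_3dct, grid, hann = FALSE) {
  nph <- ps$n_phases
  if (length(planning_dvfs) != nph)
    stop("need one planning DVF per phase (zero field for the reference)")
  ref <- unique(vapply(planning_dvfs, function(d) d$to_phase, integer(1)))
  if (length(ref) != 1L) stop("planning DVFs disagree on the reference phase")
  v4 <- suppressWarnings(fdk4d(ps, grid, hann = hann))
  rec3d <- fdk3d(ps, grid, hann = hann)
  t <- rigid_translate_register(rec3d, planning_3dct)
  dvfs <- lapply(planning_dvfs, apply_translation_to_dvf, t = t)
  acc <- array(0, grid$dim)
  for (p in seq_len(nph)) {
    w <- if (p == ref) v4$phases[[p]] else warp(v4$phases[[p]], dvfs[[p]])
    acc <- acc + w$data
  }
  ref_vol <- cbct_volume(acc / nph, grid$spacing, grid$origin)
  phases <- vector("list", nph)
  for (p in seq_len(nph)) {
    phases[[p]] <- if (p == ref) ref_vol else warp(ref_vol, invert_dvf(dvfs[[p]]))
  }
  out <- cbct_volume4d(phases, v4$phase_fractions, ref)
  attr(out, "translation_mm") <- as.numeric(t)
  attr(out, "max_gap_deg") <- attr(v4, "max_gap_deg")
  out
}

#' Planning deformation-field set from a phantom
#'
#' Analytic DVFs mapping every phantom phase to the peak-inhale reference
#' phase; the pluggable default DVF source for [mcfdk()] (user-supplied
#' fields read with [read_dvf()] may be used instead).
#'
#' @param phantom (planning) `cbct_phantom`.
#' @param grid `cbct_grid`.
#' @param reference 1-based reference phase; default the phantom's
#'   peak-inhale phase (phase of zero waveform).
#' @return list of `n_phases` `cbct_dvf`s.
#' @export
planning_dvfs_analytic <- function(phantom, grid, reference = NULL) {
  n <- phantom$n_phases
  if (is.null(reference)) {
    w <- resp_wave((seq_len(n) - 1) / n, phantom$phase_offset)
    reference <- which.min(w)
  }
  lapply(seq_len(n), function(p) analytic_dvf(phantom, p, reference, grid))
}
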