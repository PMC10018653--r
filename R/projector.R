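## CBCT acquisition simulation: full-fan circular cone-beam geometry,
## conventional / rapid protocols, regular respiration, ray-driven forward
## projection through the phase-resolved phantom.

#' Cone-beam scan geometry
#'
#' Full-fan circular geometry: the source rotates about the z (superior-
#' inferior) axis at distance `sid` from the isocenter; the flat-panel
#' detector, centered on the source-isocenter axis, sits at distance `sdd`
#' from the source. Defaults reproduce a fast-rotating ring-gantry system:
#' 1000 mm source-isocenter, 1536 mm source-detector, 500 x 400 detector
#' pixels of 1 mm, 200-degree arc.
#'
#' @param sid source-to-isocenter distance (mm).
#' @param sdd source-to-detector distance (mm), `> sid`.
#' @param detector_cols,detector_rows detector pixel counts (u = transaxial,
#'   v = axial).
#' @param pixel_pitch detector pixel size (mm).
#' @param arc_deg gantry arc in degrees, in `(0, 360]`.
#' @param start_angle_deg gantry angle of the first projection.
#' @return A `scan_geometry` object.
#' @export
scan_geometry <- function(sid = 1000, sdd = 1536, detector_cols = 500L,
                          detector_rows = 400L, pixel_pitch = 1,
                          arc_deg = 200, start_angle_deg = 0) {
  if (!(sdd > sid && sid > 0)) stop("need sdd > sid > 0")
  if (pixel_pitch <= 0) stop("pixel pitch must be > 0")
  if (arc_deg <= 0 || arc_deg > 360) stop("arc_deg must be in (0, 360]")
  structure(list(sid = sid, sdd = sdd, detector_cols = as.integer(detector_cols),
                 detector_rows = as.integer(detector_rows),
                 pixel_pitch = pixel_pitch, arc_deg = arc_deg,
                 start_angle_deg = start_angle_deg, fan_type = "full"),
            class = "scan_geometry")
}

#' Half fan angle of a geometry (degrees)
#' @param geometry `scan_geometry`.
#' @return half the full-fan opening angle, degrees.
#' @export
fan_half_angle <- function(geometry) {
  half_u <- geometry$detector_cols * geometry$pixel_pitch / 2
  atan2(half_u * geometry$sid / geometry$sdd, geometry$sid) * 180 / pi
}

#' Acquisition protocol
#'
#' The two study protocols: `"conventional"` (1320 projections in 240 s,
#' 16.5 breaths/min) and `"rapid"` (491 projections in 16.6 s,
#' 16.1 breaths/min). Breathing rates are chosen so the conventional scan
#' allocates an integer number of projections to each of the 10 phase bins.
#'
#' @param name `"conventional"`, `"rapid"`, or `"custom"`.
#' @param n_projections,duration_s,breathing_rate_bpm required for
#'   `"custom"`; ignored otherwise.
#' @return A `scan_protocol` object.
#' @export
scan_protocol <- function(name = c("conventional", "rapid", "custom"),
                          n_projections = NULL, duration_s = NULL,
                          breathing_rate_bpm = NULL) {
  name <- match.arg(name)
  p <- switch(name,
    conventional = list(n_projections = 1320L, duration_s = 240, breathing_rate_bpm = 16.5),
    rapid = list(n_projections = 491L, duration_s = 16.6, breathing_rate_bpm = 16.1),
    custom = list(n_projections = as.integer(n_projections), duration_s = duration_s,
                  breathing_rate_bpm = breathing_rate_bpm))
  if (is.null(p$n_projections) || p$n_projections < 1L) stop("n_projections must be >= 1")
  if (is.null(p$duration_s) || p$duration_s <= 0) stop("duration_s must be > 0")
  if (is.null(p$breathing_rate_bpm) || p$breathing_rate_bpm <= 0)
    stop("breathing_rate_bpm must be > 0")
  structure(c(list(name = name), p), class = "scan_protocol")
}

#' Respiratory phase at time t under regular breathing
#'
#' `phase = (t mod T) / T` with breathing period `T = 60 / rate_bpm`.
#'
#' @param t time(s) in seconds, `>= 0`.
#' @param rate_bpm breathing rate, breaths per minute, `> 0`.
#' @return phase fraction(s) in `[0, 1)`.
#' @export
respiratory_phase <- function(t, rate_bpm) {
  if (rate_bpm <= 0) stop("breathing rate must be > 0")
  if (any(t < 0)) stop("t must be >= 0")
  T <- 60 / rate_bpm
  ph <- (t %% T) / T
  ## times that are an exact multiple of the period must wrap to phase 0,
  ## not to 1 - epsilon
  ph[ph > 1 - 1e-9] <- 0
  ph
}

#' Phase bin (0-based) of a phase fraction
#' @param phase_fraction in `[0, 1)`. @param n_phases number of bins.
#' @return integer bin in `0 .. n_phases - 1`.
#' @export
phase_bin <- function(phase_fraction, n_phases = 10L) {
  ## small epsilon: protocols are constructed so samples land exactly on bin
  ## boundaries, and floating-point jitter must not flip them downward
  pmin(as.integer(floor(n_phases * phase_fraction + 1e-9)), n_phases - 1L)
}

#' Forward project a volume at one gantry angle
#'
#' Ray-driven line integrals: each detector pixel receives the integral of
#' attenuation along the source-pixel ray (dimensionless, mm^-1 x mm),
#' sampled with fixed steps (default half the smallest voxel spacing) and
#' trilinear interpolation.
#'
#' @param volume `cbct_volume`.
#' @param geometry `scan_geometry`.
#' @param angle_deg gantry angle (degrees).
#' @param step_mm sampling step; default `min(spacing) / 2`.
#' @return numeric matrix `detector_cols x detector_rows`.
#' @export
forward_project <- function(volume, geometry, angle_deg, step_mm = NULL) {
  if (is.null(step_mm)) step_mm <- min(volume$spacing) / 2
  ext <- sqrt(sum((dim(volume$data) * volume$spacing / 2)^2))
  if (ext >= geometry$sid) stop("degenerate geometry: source inside volume extent")
  forward_project_cpp(as.numeric(volume$data), dim(volume$data), volume$spacing,
                      volume$origin, geometry$sid, geometry$sdd,
                      geometry$detector_cols, geometry$detector_rows,
                      geometry$pixel_pitch, angle_deg, step_mm)
}

#' Simulate a CBCT acquisition from a 10-phase volume set
#'
#' Projection `i` (0-based) is taken at `t_i = i * duration / n_projections`
#' and gantry angle `start + i * arc / (n_projections - 1)`; the projected
#' volume is the phase whose bin matches the respiratory phase at `t_i`
#' (nearest-bin selection among the 10 discrete states). Noiseless.
#'
#' @param volume4d `cbct_volume4d` (the ground-truth 4DCT).
#' @param geometry `scan_geometry`.
#' @param protocol `scan_protocol`.
#' @param step_mm projector sampling step (mm); default half min voxel spacing.
#' @return A `projection_set`: array `nu x nv x n_projections` plus
#'   per-projection angles, timestamps, phase fractions and bins.
#' @export
simulate_scan <- function(volume4d, geometry, protocol, step_mm = NULL) {
  n <- protocol$n_projections
  nph <- length(volume4d$phases)
  t <- (seq_len(n) - 1) * protocol$duration_s / n
  ang <- geometry$start_angle_deg +
    (seq_len(n) - 1) * geometry$arc_deg / max(n - 1, 1)
  ph <- respiratory_phase(t, protocol$breathing_rate_bpm)
  bins <- phase_bin(ph, nph)
  if (is.null(step_mm)) step_mm <- min(volume4d$phases[[1]]$spacing) / 2
  nu <- geometry$detector_cols; nv <- geometry$detector_rows
  imgs <- array(0, c(nu, nv, n))
  for (i in seq_len(n)) {
    imgs[, , i] <- forward_project(volume4d$phases[[bins[i] + 1L]], geometry,
                                   ang[i], step_mm)
  }
  structure(list(images = imgs, angles_deg = ang, timestamps_s = t,
                 phase_fractions = ph, phase_bins = bins, geometry = geometry,
                 protocol = protocol, n_phases = nph),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  cat("<projection_set> ", dim(x$images)[3], " projections (",
      x$protocol$name, "), ", dim(x$images)[1], "x", dim(x$images)[2],
      " px, arc ", x$geometry$arc_deg, " deg\n", sep = "")
  invisible(x)
}

#' Write a projection set (NIfTI stack + JSON sidecar)
#' @param ps `projection_set`. @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_projections <- function(ps, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(RNifti::asNifti(ps$images), file.path(dir, "projections.nii.gz"))
  g <- ps$geometry; p <- ps$protocol
  jsonlite::write_json(
    list(angles_deg = ps$angles_deg, timestamps_s = ps$timestamps_s,
         phase_fractions = ps$phase_fractions, phase_bins = ps$phase_bins,
         n_phases = ps$n_phases, geometry = unclass(g), protocol = unclass(p)),
    file.path(dir, "projections.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a projection set written by [write_projections()]
#' @param dir directory. @return `projection_set`.
#' @export
read_projections <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "projections.json"), simplifyVector = TRUE)
  img <- RNifti::readNifti(file.path(dir, "projections.nii.gz"))
  g <- do.call(scan_geometry, side$geometry[setdiff(names(side$geometry), "fan_type")])
  pr <- side$protocol
  p <- scan_protocol(pr$name, pr$n_projections, pr$duration_s, pr$breathing_rate_bpm)
  structure(list(images = array(as.numeric(img), dim = dim(img)),
                 angles_deg = side$angles_deg, timestamps_s = side$timestamps_s,
                 phase_fractions = side$phase_fractions, phase_bins = side$phase_bins,
                 geometry = g, protocol = p, n_phases = side$n_phases),
            class = "projection_set")
}
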