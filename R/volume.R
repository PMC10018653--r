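#' Scalar 3D attenuation volume
#'
#' A `cbct_volume` holds a 3D grid of linear attenuation values (mm^-1)
#' together with its geometry: voxel spacing (mm per axis) and the world
#' coordinate (mm) of the *center* of voxel `[1, 1, 1]`. Axis order is
#' x = patient left-right, y = anterior-posterior, z = inferior-superior;
#' the gantry rotates about z.
#'
#' @param data numeric 3D array of attenuation values (mm^-1).
#' @param spacing numeric length-3, voxel spacing in mm (all > 0).
#' @param origin numeric length-3, world position (mm) of voxel `[1,1,1]`.
#' @return An object of class `cbct_volume`.
#' @export
cbct_volume <- function(data, spacing, origin = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) stop("voxel spacing must be positive")
  if (is.null(origin)) origin <- -spacing * (dim(data) - 1) / 2
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "cbct_volume")
}

#' Reconstruction / voxelization grid specification
#'
#' @param dim integer length-3 grid dimensions.
#' @param spacing numeric voxel spacing mm (scalar or length-3).
#' @param origin world position (mm) of the first voxel center; defaults to a
#'   grid centered on the isocenter.
#' @return A `cbct_grid` list with elements `dim`, `spacing`, `origin`.
#' @export
cbct_grid <- function(dim, spacing, origin = NULL) {
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 1L)) stop("grid dim must be 3 positive integers")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) stop("grid spacing must be positive")
  if (is.null(origin)) origin <- -spacing * (dim - 1) / 2
  structure(list(dim = dim, spacing = spacing, origin = as.numeric(origin)),
            class = "cbct_grid")
}

grid_of <- function(vol) cbct_grid(dim(vol$data), vol$spacing, vol$origin)

same_grid <- function(a, b, tol = 1e-9) {
  all(dim(a$data) == dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' World coordinates of voxel centers along each axis
#' @param grid a `cbct_grid` or `cbct_volume`.
#' @return list of numeric vectors `x`, `y`, `z` (mm).
#' @export
grid_coords <- function(grid) {
  if (inherits(grid, "cbct_volume")) grid <- grid_of(grid)
  list(x = grid$origin[1] + (seq_len(grid$dim[1]) - 1) * grid$spacing[1],
       y = grid$origin[2] + (seq_len(grid$dim[2]) - 1) * grid$spacing[2],
       z = grid$origin[3] + (seq_len(grid$dim[3]) - 1) * grid$spacing[3])
}

#' @export
print.cbct_volume <- function(x, ...) {
  cat("<cbct_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"),
      " mm, range [", signif(min(x$data), 4), ", ", signif(max(x$data), 4), "]\n",
      sep = "")
  invisible(x)
}

#' Ten-phase volume set
#'
#' Ordered set of phase volumes sharing one grid, with per-entry phase
#' fraction and the flagged peak-inhale phase (maximum lung volume).
#'
#' @param phases list of `cbct_volume`, all on the same grid.
#' @param phase_fractions numeric in `[0, 1)`, one per phase.
#' @param peak_inhale integer index (1-based) of the peak-inhale phase.
#' @return `cbct_volume4d` object.
#' @export
cbct_volume4d <- function(phases, phase_fractions, peak_inhale = 1L) {
  stopifnot(length(phases) == length(phase_fractions))
  for (p in phases[-1]) {
    if (!same_grid(phases[[1]], p)) stop("all phases must share grid geometry")
  }
  structure(list(phases = phases, phase_fractions = as.numeric(phase_fractions),
                 peak_inhale = as.integer(peak_inhale)),
            class = "cbct_volume4d")
}

#' @export
print.cbct_volume4d <- function(x, ...) {
  cat("<cbct_volume4d> ", length(x$phases), " phases, peak inhale = phase ",
      x$peak_inhale, "\n", sep = "")
  invisible(x)
}

#' Mean (time-averaged) volume of a phase set
#'
#' The per-voxel average of all phases; the motion-blurred "3DCT" companion of
#' a 10-phase scan, used as the rigid-registration prior and for ROI placement.
#'
#' @param v4 a `cbct_volume4d`.
#' @return `cbct_volume`.
#' @export
mean_volume <- function(v4) {
  acc <- v4$phases[[1]]$data
  for (i in seq_along(v4$phases)[-1]) acc <- acc + v4$phases[[i]]$data
  cbct_volume(acc / length(v4$phases), v4$phases[[1]]$spacing, v4$phases[[1]]$origin)
}

#' Deformation vector field
#'
#' Per-voxel displacement (mm) on the same grid as the volumes it warps.
#' Pull convention throughout the package: warping with field `d` produces
#' `out(x) = in(x + d(x))`, so `d` maps reference-phase coordinates to the
#' coordinates of the same anatomy in the source phase.
#'
#' @param data numeric 4D array `nx x ny x nz x 3` of displacements (mm).
#' @param spacing,origin grid geometry as for [cbct_volume()].
#' @param from_phase,to_phase 1-based phase indices (`to_phase` = reference).
#' @return `cbct_dvf` object.
#' @export
cbct_dvf <- function(data, spacing, origin = NULL, from_phase = NA_integer_,
                     to_phase = NA_integer_) {
  data <- as.array(data)
  d <- dim(data)
  if (length(d) != 4L || d[4] != 3L) stop("DVF data must be nx x ny x nz x 3")
  if (any(!is.finite(data))) stop("DVF must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (is.null(origin)) origin <- -spacing * (d[1:3] - 1) / 2
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin),
                 from_phase = as.integer(from_phase), to_phase = as.integer(to_phase)),
            class = "cbct_dvf")
}

#' @export
print.cbct_dvf <- function(x, ...) {
  mag <- sqrt(x$data[, , , 1]^2 + x$data[, , , 2]^2 + x$data[, , , 3]^2)
  cat("<cbct_dvf> phase ", x$from_phase, " -> ", x$to_phase, ", |d| max ",
      signif(max(mag), 4), " mm\n", sep = "")
  invisible(x)
}

#' Map linear attenuation to Hounsfield-like units
#'
#' Affine display map `HU = 1000 (mu - mu_water) / mu_water`. The package
#' computes internally in linear attenuation (mm^-1); this map is used for
#' display and for reporting image-quality metrics on a CT-like scale.
#'
#' @param vol `cbct_volume`.
#' @param mu_water water-equivalent attenuation (mm^-1).
#' @return `cbct_volume` in HU-like units.
#' @export
to_hu <- function(vol, mu_water = 0.02) {
  cbct_volume(1000 * (vol$data - mu_water) / mu_water, vol$spacing, vol$origin)
}

## ---- File I/O: NIfTI volumes + JSON sidecars --------------------------------

#' Write a volume to NIfTI
#' @param vol `cbct_volume`. @param path output file (`.nii` / `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#' @param path NIfTI file. @param origin optional origin override (mm).
#' @return `cbct_volume`.
#' @export
read_volume <- function(path, origin = NULL) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  cbct_volume(array(as.numeric(img), dim = dim(img)[1:3]), spacing, origin)
}

#' Write a 10-phase volume set as NIfTI files plus a JSON sidecar
#'
#' Writes `phase_00.nii.gz` ... and `volume4d.json` (phase fractions,
#' peak-inhale index, grid geometry) into `dir`.
#'
#' @param v4 `cbct_volume4d`. @param dir output directory.
#' @param extra named list merged into the sidecar (seed, motion parameters,
#'   ROI boxes, ...).
#' @return `dir`, invisibly.
#' @export
write_volume4d <- function(v4, dir, extra = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("phase_%02d.nii.gz", seq_along(v4$phases) - 1L)
  for (i in seq_along(v4$phases)) write_volume(v4$phases[[i]], file.path(dir, files[i]))
  side <- c(list(files = files, phase_fractions = v4$phase_fractions,
                 peak_inhale = v4$peak_inhale,
                 spacing = v4$phases[[1]]$spacing, origin = v4$phases[[1]]$origin,
                 dim = dim(v4$phases[[1]]$data)), extra)
  jsonlite::write_json(side, file.path(dir, "volume4d.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a 10-phase volume set written by [write_volume4d()]
#' @param dir directory containing `volume4d.json`.
#' @return `cbct_volume4d`.
#' @export
read_volume4d <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "volume4d.json"), simplifyVector = TRUE)
  phases <- lapply(side$files, function(f) read_volume(file.path(dir, f), origin = side$origin))
  cbct_volume4d(phases, side$phase_fractions, side$peak_inhale)
}

#' Write a deformation field (3-component NIfTI + JSON sidecar)
#' @param dvf `cbct_dvf`. @param path output NIfTI path.
#' @return `path`, invisibly.
#' @export
write_dvf <- function(dvf, path) {
  img <- RNifti::asNifti(dvf$data)
  RNifti::pixdim(img) <- c(dvf$spacing, 1)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(from_phase = dvf$from_phase, to_phase = dvf$to_phase,
                            spacing = dvf$spacing, origin = dvf$origin),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a deformation field written by [write_dvf()]
#' @param path NIfTI path (with `path.json` sidecar alongside).
#' @return `cbct_dvf`.
#' @export
read_dvf <- function(path) {
  img <- RNifti::readNifti(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cbct_dvf(array(as.numeric(img), dim = dim(img)), side$spacing, side$origin,
           side$from_phase, side$to_phase)
}
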