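## FDK filtered backprojection for the circular full-fan geometry:
## cosine preweighting, Parker-style short-scan redundancy weights, Ram-Lak
## ramp filtering (FFT convolution of the exact spatial-domain taps), and
## voxel-driven backprojection with the (sid/U)^2 distance weight.
##
## Weight convention: short-scan weights are normalized so conjugate-ray
## weights sum to 1 and a complete short scan reconstructs absolute
## attenuation; for a 360-degree arc every weight is 0.5.

#' FDK cosine preweighting
#'
#' Multiplies each detector pixel by `sdd / sqrt(sdd^2 + u^2 + v^2)`, the
#' cosine of the ray's angle to the central axis, with `(u, v)` the physical
#' detector coordinates of the pixel relative to the detector center.
#'
#' @param projection matrix `detector_cols x detector_rows`.
#' @param geometry `scan_geometry`.
#' @return weighted projection matrix.
#' @export
preweight <- function(projection, geometry) {
  projection * preweight_matrix(geometry)
}

preweight_matrix <- function(geometry) {
  nu <- geometry$detector_cols; nv <- geometry$detector_rows
  u <- (seq_len(nu) - (nu + 1) / 2) * geometry$pixel_pitch
  v <- (seq_len(nv) - (nv + 1) / 2) * geometry$pixel_pitch
  sdd <- geometry$sdd
  outer(u^2, v^2, function(a, b) sdd / sqrt(sdd^2 + a + b))
}

#' Short-scan (Parker) redundancy weights
#'
#' Smooth Parker-style weights for an arc of `pi + 2 gamma_m'`, taking
#' `gamma_m' = (arc - pi) / 2` so that over-scan beyond the minimal short-scan
#' arc is absorbed into the transition regions. Weights depend on the
#' projection angle within the arc and the detector-column fan angle; every
#' conjugate ray pair's weights sum to 1. For a (near) 360-degree arc all
#' weights are 0.5.
#'
#' @param angles_deg per-projection gantry angles (degrees).
#' @param geometry `scan_geometry` (defines arc, start angle and fan angle).
#' @return matrix `detector_cols x length(angles_deg)` of weights.
#' @export
short_scan_weights <- function(angles_deg, geometry) {
  nu <- geometry$detector_cols
  arc <- geometry$arc_deg * pi / 180
  if (geometry$arc_deg >= 359.99) {
    return(matrix(0.5, nu, length(angles_deg)))
  }
  fan <- 2 * fan_half_angle(geometry) * pi / 180
  if (arc < pi + fan) {
    stop("arc (", geometry$arc_deg, " deg) below short-scan minimum of 180 deg + fan (",
         round(180 + fan * 180 / pi, 1), " deg): insufficient data")
  }
  gm <- (arc - pi) / 2
  ## fan angle per detector column; sign matched to the gantry rotation
  ## direction so that the conjugate of (beta, gamma) is (beta + pi - 2 gamma,
  ## -gamma)
  u_iso <- (seq_len(nu) - (nu + 1) / 2) * geometry$pixel_pitch *
    geometry$sid / geometry$sdd
  gam <- atan2(u_iso, geometry$sid)
  beta <- (angles_deg - geometry$start_angle_deg) * pi / 180
  w <- matrix(1, nu, length(angles_deg))
  for (j in seq_along(beta)) {
    b <- beta[j]
    den1 <- pmax(gm + gam, 1e-6)
    den2 <- pmax(gm - gam, 1e-6)
    wj <- rep(1, nu)
    ## double-measured early rays ramp up; their conjugates at
    ## beta + pi - 2 gamma ramp down symmetrically
    r1 <- b < 2 * (gm + gam)
    wj[r1] <- sin(pi / 4 * b / den1[r1])^2
    r3 <- b > pi + 2 * gam
    wj[r3] <- sin(pi / 4 * (pi + 2 * gm - b) / den2[r3])^2
    wj[b < 0 | b > arc + 1e-9] <- 0
    w[, j] <- wj
  }
  w
}

#' Ram-Lak ramp filtering of detector rows
#'
#' Convolves each detector row (along the transaxial direction u) with the
#' band-limited ramp kernel defined by its exact spatial-domain taps
#' `h(0) = 1/(4 du^2)`, `h(n odd) = -1/(pi n du)^2`, `h(n even) = 0`,
#' implemented as FFT convolution zero-padded to the next power of two at
#' least twice the row length (no wraparound). The convolution is a plain
#' discrete sum: a unit impulse returns the taps themselves; the caller
#' multiplies by the sample spacing `du`.
#'
#' @param rows matrix `nu x n_rows` (filtering along the first dimension), or
#'   a vector.
#' @param du detector sample spacing (mm) defining the kernel scale.
#' @param hann apply a Hann apodization window (default off).
#' @return filtered matrix (or vector) of the same shape.
#' @export
ramp_filter <- function(rows, du = 1, hann = FALSE) {
  vec <- is.null(dim(rows))
  if (vec) rows <- matrix(rows, ncol = 1)
  nu <- nrow(rows)
  P <- 2^ceiling(log2(2 * nu))
  h <- numeric(P)
  n <- seq_len(nu - 1)
  h[1] <- 1 / (4 * du^2)
  odd <- n[n %% 2 == 1]
  h[1 + odd] <- -1 / (pi * odd * du)^2
  h[P + 1 - odd] <- -1 / (pi * odd * du)^2
  H <- Re(fft(h))
  if (hann) {
    f <- c(seq(0, P / 2), seq(P / 2 - 1, 1)) / (P / 2)
    H <- H * 0.5 * (1 + cos(pi * f))
  }
  pad <- matrix(0, P, ncol(rows))
  pad[seq_len(nu), ] <- rows
  out <- Re(mvfft(mvfft(pad) * H, inverse = TRUE)) / P
  out <- out[seq_len(nu), , drop = FALSE]
  if (vec) out[, 1] else out
}

## per-projection angular integration weights (radians) from local spacing:
## half the distance to each angular neighbour, end projections padded with
## the median spacing. Density compensation for non-uniform (phase-binned)
## angle sets; reduces to the uniform spacing for a full uniform scan.
## Weights are clamped at `cap_factor` times the set's mean spacing: a
## projection adjacent to a large unmeasured wedge must not extrapolate into
## it, so wedges beyond the cap are treated as missing data rather than
## over-weighted by their neighbours.
angular_weights <- function(angles_deg, cap_factor = 1) {
  n <- length(angles_deg)
  if (n == 1L) return(2 * pi / 360)  # lone projection: nominal 1-degree slab
  ord <- order(angles_deg)
  g <- diff(angles_deg[ord]) * pi / 180
  med <- stats::median(g)
  db <- (c(med, g) + c(g, med)) / 2
  cap <- cap_factor * diff(range(angles_deg)) * pi / 180 / n
  db <- pmin(db, pmax(cap, med))
  out <- numeric(n)
  out[ord] <- db
  out
}

## filter a subset of projections: cosine preweight, short-scan weight, ramp,
## times the iso-scaled sample spacing du'. Returns nu x nv x n array.
filter_projections <- function(ps, idx, hann = FALSE) {
  g <- ps$geometry
  nu <- g$detector_cols; nv <- g$detector_rows
  pw <- preweight_matrix(g)
  wss <- short_scan_weights(ps$angles_deg[idx], g)
  du_iso <- g$pixel_pitch * g$sid / g$sdd
  out <- array(0, c(nu, nv, length(idx)))
  for (k in seq_along(idx)) {
    img <- ps$images[, , idx[k]] * pw * wss[, k]
    out[, , k] <- ramp_filter(img, du = du_iso, hann = hann) * du_iso
  }
  out
}

#' Voxel-driven FDK backprojection
#'
#' Backprojects already-filtered projections onto a grid: each voxel is
#' projected onto the detector at every angle, the filtered projection is
#' bilinearly sampled, weighted by the FDK distance factor `(sid/U)^2`, and
#' accumulated with the per-projection angular weight (radians).
#'
#' @param filtered array `nu x nv x n` of filtered projections.
#' @param angles_deg,dbeta per-projection angles (degrees) and angular
#'   integration weights (radians); `dbeta` defaults to local-spacing weights.
#' @param geometry `scan_geometry`.
#' @param grid `cbct_grid`.
#' @return `cbct_volume`.
#' @export
backproject <- function(filtered, angles_deg, geometry, grid, dbeta = NULL) {
  if (length(dim(filtered)) != 3L) stop("filtered must be nu x nv x n")
  if (dim(filtered)[3] == 0L || length(angles_deg) == 0L)
    stop("no projections to backproject")
  if (is.null(dbeta)) dbeta <- angular_weights(angles_deg)
  v <- backproject_cpp(as.numeric(filtered), dim(filtered), angles_deg, dbeta,
                       geometry$sid, geometry$sdd, geometry$pixel_pitch,
                       grid$dim, grid$spacing, grid$origin)
  cbct_volume(array(v, grid$dim), grid$spacing, grid$origin)
}

#' 3D FDK reconstruction
#'
#' Standard FDK filtered backprojection using all projections (or the subset
#' `idx`): cosine preweight, short-scan redundancy weight, ramp filter,
#' voxel-driven backprojection.
#'
#' @param ps `projection_set`.
#' @param grid `cbct_grid`.
#' @param idx optional subset of projection indices.
#' @param hann apply Hann apodization in the ramp filter.
#' @return `cbct_volume`.
#' @export
fdk3d <- function(ps, grid, idx = NULL, hann = FALSE) {
  if (is.null(idx)) idx <- seq_len(dim(ps$images)[3])
  if (length(idx) == 0L) stop("no projections selected")
  filtered <- filter_projections(ps, idx, hann = hann)
  backproject(filtered, ps$angles_deg[idx], ps$geometry, grid)
}

## largest angular gap (degrees) within an angle set
max_angular_gap <- function(angles_deg) {
  if (length(angles_deg) < 2L) return(Inf)
  max(diff(sort(angles_deg)))
}

#' Respiratory-correlated 4D FDK reconstruction
#'
#' Reconstructs one volume per respiratory phase bin using only that bin's
#' projections (phase-correlated filtering and backprojection). Each bin uses
#' the short-scan weights of the full-arc geometry and density-compensated
#' angular weights from its own angle set; bins whose angular coverage is
#' below the short-scan minimum (sparse rapid-scan bins) are reconstructed
#' anyway — their streak-dominated quality is the scientific point — with a
#' warning.
#'
#' @param ps `projection_set`.
#' @param grid `cbct_grid`.
#' @param hann apply Hann apodization.
#' @return `cbct_volume4d` with an attribute `max_gap_deg` (per-bin largest
#'   angular gap) used to flag insufficient sampling downstream.
#' @export
fdk4d <- function(ps, grid, hann = FALSE) {
  nph <- ps$n_phases
  fan <- 2 * fan_half_angle(ps$geometry)
  vols <- vector("list", nph)
  gaps <- numeric(nph)
  sparse_bins <- integer(0)
  for (b in seq_len(nph) - 1L) {
    idx <- which(ps$phase_bins == b)
    if (length(idx) == 0L) stop("phase bin ", b, " has no projections")
    ang <- ps$angles_deg[idx]
    gaps[b + 1L] <- max_angular_gap(ang)
    if (diff(range(ang)) < 180 + fan) sparse_bins <- c(sparse_bins, b)
    vols[[b + 1L]] <- fdk3d(ps, grid, idx = idx, hann = hann)
  }
  if (length(sparse_bins)) {
    warning("phase bin(s) ", paste(sparse_bins, collapse = ", "),
            " cover less than the short-scan minimum; density-compensated ",
            "weighting used on sparse angle sets")
  }
  counts <- vapply(vols, lung_voxel_count, numeric(1))
  v4 <- cbct_volume4d(vols, (seq_len(nph) - 1) / nph, which.max(counts))
  attr(v4, "max_gap_deg") <- gaps
  v4
}
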