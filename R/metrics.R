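## Image-quality metrics: affine windowing, contrast-to-noise ratio (CNR),
## tissue interface sharpness / width (TIS / TIW), RMSE, global SSIM, phase
## averaging and paired t-tests. Conventions: sample (n-1) standard
## deviations throughout; SSIM is the single global statistic over the
## subvolume (not sliding-window); TIS is the mean fitted logistic rate
## parameter k (per voxel), which is the definition consistent with
## TIW = 2 w ln(9) / TIS.

#' Affine windowing of a volume against a reference
#'
#' Least-squares affine intensity map `a x + b` minimizing the difference to
#' `reference` over the ROI voxels, applied to the whole volume. Degenerate
#' input (constant over the ROI) returns the identity map with a warning.
#'
#' @param vol,reference `cbct_volume`s on the same grid.
#' @param roi box (list with `lo`, `hi` voxel index vectors); `NULL` = whole
#'   volume.
#' @return windowed `cbct_volume` with attributes `a`, `b`.
#' @export
affine_window <- function(vol, reference, roi = NULL) {
  x <- if (is.null(roi)) as.numeric(vol$data) else as.numeric(roi_values(vol, roi))
  y <- if (is.null(roi)) as.numeric(reference$data) else as.numeric(roi_values(reference, roi))
  vx <- stats::var(x)
  if (vx == 0) {
    warning("volume constant over ROI: affine window indeterminate, identity used")
    a <- 1; b <- 0
  } else {
    a <- (mean(x * y) - mean(x) * mean(y)) / (mean(x^2) - mean(x)^2)
    b <- mean(y) - a * mean(x)
  }
  out <- cbct_volume(a * vol$data + b, vol$spacing, vol$origin)
  attr(out, "a") <- a
  attr(out, "b") <- b
  out
}

#' Contrast-to-noise ratio
#'
#' `CNR = (mu_FG - mu_BG) / sigma_BG` with means over the foreground and
#' background boxes and the sample standard deviation of the background.
#'
#' @param vol `cbct_volume`.
#' @param fg_roi,bg_roi boxes (lists with `lo`, `hi`); out-of-grid boxes give
#'   `NA` (non-computable flag).
#' @return CNR value, or `NA` if a box leaves the grid.
#' @export
cnr <- function(vol, fg_roi, bg_roi) {
  d <- dim(vol$data)
  ok <- function(b) all(b$lo >= 1L) && all(b$hi <= d)
  if (!ok(fg_roi) || !ok(bg_roi)) return(NA_real_)
  fg <- roi_values(vol, fg_roi)
  bg <- roi_values(vol, bg_roi)
  s <- sd(bg)
  if (s == 0) stop("background standard deviation is zero: CNR undefined")
  (mean(fg) - mean(bg)) / s
}

## fit 1/(1 + exp(-k (z - z0))) to one normalized run; returns k or NA
fit_logistic_run <- function(y, k_max = 10) {
  l <- length(y)
  z <- seq_len(l)
  ## deterministic initialization: z0 from the 0.5 crossing, k from the
  ## 10-90% crossing distance
  z0_init <- z[which.min(abs(y - 0.5))]
  above <- which(y >= 0.9)
  below <- which(y <= 0.1)
  d1090 <- if (length(above) && length(below)) max(min(above) - max(below), 1) else l / 2
  k_init <- min(max(2 * log(9) / d1090, 0.05), k_max)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 1 / (1 + exp(-k * (z - z0))),
                      start = list(k = k_init, z0 = z0_init),
                      lower = c(k = 1e-3, z0 = -l), upper = c(k = k_max, z0 = 2 * l),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  r2 <- 1 - sum(stats::residuals(fit)^2) / max(sum((y - mean(y))^2), 1e-12)
  if (r2 < 0.5) return(NA_real_)
  unname(coef(fit)["k"])
}

#' Tissue interface sharpness (TIS)
#'
#' Extracts the `5 x 5` voxel runs of the interface box in the superior-
#' inferior direction, min-max normalizes each, orients them so intensity
#' increases from lung to tissue, fits a logistic
#' `1 / (1 + exp(-k (z - z0)))` to each by bounded least squares
#' (`0 < k <= k_max` per voxel), and returns the mean fitted rate `k` over
#' the runs. Runs with no edge (tiny dynamic range or a failed / poor fit)
#' are excluded; more than 50% excluded is an error.
#'
#' @param vol `cbct_volume`.
#' @param tiw_roi interface box from [auto_rois()] (`lo`, `hi` with the long
#'   axis along z; run length >= 8 voxels).
#' @param k_max upper bound for the fitted rate (per voxel).
#' @return TIS (per-voxel units) with attribute `n_valid`.
#' @export
tis <- function(vol, tiw_roi, k_max = 10) {
  d <- dim(vol$data)
  if (!(all(tiw_roi$lo >= 1L) && all(tiw_roi$hi <= d))) return(NA_real_)
  runs <- roi_values(vol, tiw_roi)
  l <- dim(runs)[3]
  if (l < 8) stop("TIS run length must be >= 8 voxels")
  full_range <- diff(range(runs))
  ks <- c()
  for (i in seq_len(dim(runs)[1])) for (j in seq_len(dim(runs)[2])) {
    y <- runs[i, j, ]
    rng <- diff(range(y))
    if (rng < 0.25 * full_range || rng == 0) { ks <- c(ks, NA_real_); next }
    y <- (y - min(y)) / rng
    if (mean(y[seq_len(ceiling(l / 3))]) > mean(y[(l - floor(l / 3) + 1):l])) y <- 1 - y
    ks <- c(ks, fit_logistic_run(y, k_max))
  }
  n_valid <- sum(!is.na(ks))
  if (n_valid < length(ks) / 2)
    stop("sigmoid fit failed on more than half of the interface runs")
  out <- mean(ks, na.rm = TRUE)
  attr(out, "n_valid") <- n_valid
  out
}

#' Tissue interface width (TIW)
#'
#' `TIW = 2 w ln(9) / TIS`: the physical distance over which the mean fitted
#' sigmoid rises from 0.1 to 0.9; smaller is sharper.
#'
#' @param tis_value TIS (logistic rate per voxel), `> 0`.
#' @param voxel_length_mm reconstructed voxel length along the run (mm).
#' @return TIW in mm.
#' @export
tiw <- function(tis_value, voxel_length_mm) {
  if (is.na(tis_value)) return(NA_real_)
  if (tis_value <= 0) stop("TIS must be > 0")
  2 * voxel_length_mm * log(9) / tis_value
}

#' Root-mean-square error over a subvolume
#'
#' `sqrt(mean((x_GT - x_r)^2))` over the ROI, by default after affine
#' windowing of the reconstruction to the ground truth over the same ROI.
#'
#' @param vol,gt `cbct_volume`s (reconstruction and ground truth).
#' @param roi box (`lo`, `hi`); `NULL` = whole volume.
#' @param window apply [affine_window()] first (default `TRUE`).
#' @return RMSE in the units of `gt`.
#' @export
rmse <- function(vol, gt, roi = NULL, window = TRUE) {
  if (window) vol <- affine_window(vol, gt, roi)
  x <- if (is.null(roi)) vol$data else roi_values(vol, roi)
  y <- if (is.null(roi)) gt$data else roi_values(gt, roi)
  sqrt(mean((y - x)^2))
}

#' Global structural similarity (SSIM) over a subvolume
#'
#' Single-statistic SSIM over all ROI voxels:
#' `(2 mu_x mu_y + c1)(2 cov + c2) / ((mu_x^2 + mu_y^2 + c1)(var_x + var_y + c2))`
#' with `c1 = (0.01 L)^2`, `c2 = (0.03 L)^2` and `L` the joint dynamic range
#' of the two subvolumes. Sample (n-1) variances and covariance. By default
#' the reconstruction is affine windowed to the ground truth first.
#'
#' @inheritParams rmse
#' @return SSIM value in `(-1, 1]`.
#' @export
ssim <- function(vol, gt, roi = NULL, window = TRUE) {
  if (window) vol <- affine_window(vol, gt, roi)
  x <- as.numeric(if (is.null(roi)) vol$data else roi_values(vol, roi))
  y <- as.numeric(if (is.null(roi)) gt$data else roi_values(gt, roi))
  L <- max(c(x, y)) - min(c(x, y))
  c1 <- (0.01 * L)^2
  c2 <- (0.03 * L)^2
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  cxy <- stats::cov(x, y)
  (2 * mx * my + c1) * (2 * cxy + c2) / ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

#' Phase-averaged metric
#'
#' Arithmetic mean over the computable (non-`NA`) phases; the count of phases
#' used is attached.
#'
#' @param values per-phase metric values.
#' @return mean with attribute `n_phases`.
#' @export
phase_average <- function(values) {
  out <- mean(values, na.rm = TRUE)
  attr(out, "n_phases") <- sum(!is.na(values))
  out
}

#' Two-sided paired-samples t-test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the paired differences with
#' `df = n - 1`.
#'
#' @param a,b paired cohort values (equal length `>= 3`).
#' @return two-sided p-value.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  if (length(a) < 3) stop("need at least 3 pairs")
  d <- a - b
  if (sd(d) == 0) stop("paired differences have zero variance: t undefined")
  t.test(a, b, paired = TRUE)$p.value
}
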