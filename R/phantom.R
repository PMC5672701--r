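# Synthetic phantom volumes with known ground truth.  The phantom emulates
# the data regime the slice-propagated segmentation assumes: a bright
# organ-like elliptical cross-section whose centre drifts smoothly across
# slices (adjacent slices are highly correlated), object and background
# intensities drawn from two Gaussians, and optionally a second, brighter
# confounder region touching the organ (the adjacent-heart failure mode).

#' Specify a synthetic phantom volume
#'
#' Slices are indexed `z = 1..nz`; the organ cross-section on slice z is an
#' ellipse whose centre drifts linearly away from the middle slice by
#' `drift` pixels per slice and whose semi-axes shrink toward the volume
#' ends by up to `radius_taper` (relative), mimicking an organ cap.
#'
#' @param dims Grid `c(ny, nx, nz)` (default `c(64, 64, 20)`).
#' @param center Organ centre `c(y, x)` on the middle slice.
#' @param radii Ellipse semi-axes `c(ry, rx)` on the middle slice
#'   (default `c(18, 14)`).
#' @param drift Per-slice centre drift `c(dy, dx)` in pixels (default
#'   `c(0.8, 1.2)`; adjacent-slice displacement stays well under 4 px).
#' @param radius_taper Relative shrink of the semi-axes at the outermost
#'   slices (default 0.25).
#' @param mu_obj,sigma_obj Object intensity Gaussian (default 150, 15).
#' @param mu_bg,sigma_bg Background intensity Gaussian (default 70, 15).
#' @param confounder `NULL`, or a list overriding any of `mu` (default
#'   230), `sigma` (15), `radii` (`c(12, 10)`), `z_frac` (`c(0.65, 1)`):
#'   a second bright ellipse placed immediately adjacent to (touching) the
#'   organ on the slices in the `z_frac` fraction of the volume.  The
#'   default emulates a heart-like structure abutting the organ toward one
#'   end of the volume, away from the mid-volume start slice an operator
#'   would pick.
#' @param noise_seed Integer RNG seed; generation is deterministic given
#'   the spec.
#' @return An `rw_phantom_spec` list.
#' @export
phantom_spec <- function(dims = c(64, 64, 20), center = NULL,
                         radii = c(18, 14), drift = c(0.8, 1.2),
                         radius_taper = 0.25,
                         mu_obj = 150, sigma_obj = 15,
                         mu_bg = 70, sigma_bg = 15,
                         confounder = NULL, noise_seed = 1L) {
  stopifnot(length(dims) == 3L, all(dims >= c(8, 8, 1)))
  if (is.null(center)) center <- c(dims[1] / 2, dims[2] / 2 - 4)
  if (!is.null(confounder)) {
    confounder <- utils::modifyList(
      list(mu = 230, sigma = 15, radii = c(12, 10), z_frac = c(0.65, 1)),
      confounder)
  }
  structure(list(dims = as.integer(dims), center = center, radii = radii,
                 drift = drift, radius_taper = radius_taper,
                 mu_obj = mu_obj, sigma_obj = sigma_obj,
                 mu_bg = mu_bg, sigma_bg = sigma_bg,
                 confounder = confounder,
                 noise_seed = as.integer(noise_seed)),
            class = "rw_phantom_spec")
}

phantom_geometry <- function(spec, z) {
  nz <- spec$dims[3]
  zmid <- (nz + 1) / 2
  off <- z - zmid
  taper <- 1 - spec$radius_taper * abs(off) / max(zmid - 1, 1)
  list(center = spec$center + spec$drift * off,
       radii = spec$radii * taper)
}

ellipse_mask <- function(dims2, center, radii) {
  Y <- matrix(seq_len(dims2[1]), dims2[1], dims2[2])
  X <- matrix(seq_len(dims2[2]), dims2[1], dims2[2], byrow = TRUE)
  ((Y - center[1]) / radii[1])^2 + ((X - center[2]) / radii[2])^2 <= 1
}

#' Generate a phantom volume with ground truth
#'
#' Deterministic given `spec$noise_seed`.  Background voxels are drawn from
#' `N(mu_bg, sigma_bg^2)`, organ voxels from `N(mu_obj, sigma_obj^2)`, and
#' confounder voxels (when configured) from the confounder Gaussian.  The
#' returned `truth` is the analytic organ region only — the confounder is
#' ground-truth background.
#'
#' @param spec An `rw_phantom_spec`.
#' @return A list: `volume` (numeric `[y, x, z]` array), `truth` (logical
#'   array), `confounder` (logical array or `NULL`), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "rw_phantom_spec"))
  d <- spec$dims
  truth <- array(FALSE, d)
  conf <- if (!is.null(spec$confounder)) array(FALSE, d) else NULL
  for (z in seq_len(d[3])) {
    geo <- phantom_geometry(spec, z)
    if (geo$center[1] - geo$radii[1] < 1 || geo$center[1] + geo$radii[1] > d[1] ||
        geo$center[2] - geo$radii[2] < 1 || geo$center[2] + geo$radii[2] > d[2])
      stop("invalid spec: organ exceeds the grid on slice ", z)
    truth[, , z] <- ellipse_mask(d[1:2], geo$center, geo$radii)
    if (!is.null(conf)) {
      zf <- spec$confounder$z_frac
      if (z >= 1 + (d[3] - 1) * zf[1] && z <= 1 + (d[3] - 1) * zf[2]) {
        cc <- geo$center + c(0, geo$radii[2] + spec$confounder$radii[2] - 1)
        cm <- ellipse_mask(d[1:2], cc, spec$confounder$radii)
        conf[, , z] <- cm & !truth[, , z]
      }
    }
  }
  vol <- withr::with_seed(spec$noise_seed, {
    v <- array(stats::rnorm(prod(d), spec$mu_bg, spec$sigma_bg), d)
    v[truth] <- stats::rnorm(sum(truth), spec$mu_obj, spec$sigma_obj)
    if (!is.null(conf))
      v[conf] <- stats::rnorm(sum(conf), spec$confounder$mu,
                              spec$confounder$sigma)
    v
  })
  list(volume = vol, truth = truth, confounder = conf, spec = spec)
}

#' Resample a volume along the slice (z) axis
#'
#' Linear interpolation between adjacent slices; `factor = 1` is the
#' identity.  Used to emulate acquisitions at different axial resolutions.
#'
#' @param vol 3D numeric array `[y, x, z]` (logical masks are resampled and
#'   re-thresholded at 0.5).
#' @param factor Positive scale factor for the number of slices.
#' @return A 3D array with `round(nz * factor)` slices (logical if the
#'   input was logical).
#' @export
resample_z <- function(vol, factor) {
  stopifnot(length(dim(vol)) == 3L, factor > 0)
  logical_in <- is.logical(vol)
  d <- dim(vol)
  nz_out <- as.integer(round(d[3] * factor))
  if (nz_out < 3L) stop("resampling would leave fewer than 3 slices")
  zi <- seq(1, d[3], length.out = nz_out)
  i0 <- pmin(floor(zi), d[3] - 1L)
  w <- zi - i0
  out <- array(0, c(d[1], d[2], nz_out))
  for (k in seq_len(nz_out)) {
    out[, , k] <- (1 - w[k]) * vol[, , i0[k]] + w[k] * vol[, , i0[k] + 1L]
  }
  if (logical_in) out > 0.5 else out
}

#' Deterministic start-slice seeds for a phantom
#'
#' Picks evenly spaced object seeds from the eroded truth mask of a slice
#' and background seeds from well outside the dilated truth mask — the kind
#' of interior/exterior strokes an operator would paint.  No randomness.
#'
#' @param truth Logical 3D truth array.
#' @param slice Slice index.
#' @param n_object,n_background Seed pixels per class (default 25; a
#'   painted stroke covers tens of pixels, and the intensity model's
#'   variance estimate needs that many samples to be stable).
#' @param margin Erosion/dilation radius separating seeds from the true
#'   boundary (default 3 inside, 6 outside).
#' @return Data frame with columns `label`, `y`, `x` (1-based).
#' @export
phantom_start_seeds <- function(truth, slice, n_object = 25,
                                n_background = 25, margin = 3) {
  sl <- truth[, , slice]
  if (!any(sl)) stop("truth slice ", slice, " is empty")
  core <- mask_erode(sl, margin)
  if (!any(core)) core <- sl
  outer <- !mask_dilate(sl, 2 * margin)
  pick <- function(idx, n) idx[unique(pmax(1L, round(seq(1, length(idx),
                                                         length.out = n))))]
  oi <- pick(which(core), n_object)
  bi <- pick(which(outer), n_background)
  ny <- nrow(sl)
  rbind(data.frame(label = 1L, y = (oi - 1L) %% ny + 1L,
                   x = (oi - 1L) %/% ny + 1L),
        data.frame(label = 2L, y = (bi - 1L) %% ny + 1L,
                   x = (bi - 1L) %/% ny + 1L))
}
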