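# Automatic seed generation for slice-to-slice propagation: morphological
# rough seeds from the previous mask (per connected component), and
# narrow-band intensity refinement of the object seeds.

#' Discrete Euclidean disk structuring element
#'
#' Pixel (dy, dx) belongs to the disk iff its centre distance satisfies
#' `dy^2 + dx^2 <= r^2`.
#'
#' @param r Nonnegative integer radius.
#' @return Integer (2r+1)-by-(2r+1) 0/1 matrix.
#' @export
disk_kernel <- function(r) {
  r <- as.integer(r)
  stopifnot(r >= 0L)
  d <- seq(-r, r)
  k <- outer(d^2, d^2, "+") <= r^2
  storage.mode(k) <- "integer"
  k
}

#' Binary dilation / erosion with a disk
#'
#' Minkowski dilation and erosion of a binary mask with [disk_kernel()].
#' Offsets that fall outside the image are ignored, so erosion does not eat
#' the mask at the image frame and dilation is clipped to the grid.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param r Disk radius in pixels; `r = 0` returns the mask unchanged.
#' @return Logical matrix.
#' @export
mask_dilate <- function(mask, r) {
  stopifnot(is.matrix(mask))
  m <- mask > 0
  if (r == 0 || !any(m)) return(m)
  storage.mode(m) <- "integer"
  EBImage::dilate(m, disk_kernel(r)) > 0
}

#' @rdname mask_dilate
#' @export
mask_erode <- function(mask, r) {
  stopifnot(is.matrix(mask))
  m <- mask > 0
  if (r == 0 || !any(m)) return(m)
  storage.mode(m) <- "integer"
  EBImage::erode(m, disk_kernel(r)) > 0
}

#' Rough object/background seeds from the previous slice's mask
#'
#' For each connected component of the previous mask, the rough object seeds
#' FS are the component eroded by a disk of radius `r_erode`, and the
#' background seeds BS form the annulus between the dilations by `r_dilate2`
#' and `r_dilate1` (strictly outside the organ boundary).  Components whose
#' erosion is empty are too thin to propagate and are dropped with a
#' message.  The returned background set additionally excludes the previous
#' mask itself, so FS and BS are disjoint by construction.
#'
#' @param prev_mask Logical matrix, nonempty.
#' @param r_erode Erosion radius for object seeds (default 8).
#' @param r_dilate1 Outer dilation radius of the background annulus
#'   (default 10).
#' @param r_dilate2 Inner dilation radius of the background annulus
#'   (default 8).
#' @return An `rw_seeds` object of linear pixel indices (possibly with an
#'   empty object set when every component was dropped; callers treat that
#'   as a propagation-termination signal).
#' @export
propagate_seeds <- function(prev_mask, r_erode = 8, r_dilate1 = 10,
                            r_dilate2 = 8) {
  stopifnot(is.matrix(prev_mask))
  prev_mask <- prev_mask > 0
  if (!any(prev_mask))
    stop("previous mask is empty: nothing to propagate")
  lab <- EBImage::bwlabel(prev_mask)
  fs <- matrix(FALSE, nrow(prev_mask), ncol(prev_mask))
  bs <- fs
  for (j in seq_len(max(lab))) {
    comp <- lab == j
    fs_j <- mask_erode(comp, r_erode)
    if (!any(fs_j)) {
      message("seed propagation: component ", j,
              " vanished under erosion (too thin); dropped")
      next
    }
    fs <- fs | fs_j
    bs <- bs | (mask_dilate(comp, r_dilate1) & !mask_dilate(comp, r_dilate2))
  }
  bs <- bs & !prev_mask & !fs
  seed_set(object = which(fs), background = which(bs),
           n = length(prev_mask))
}

#' Narrow-band intensity threshold around the object model mean
#'
#' The band is \eqn{[\mu - \beta\sigma,\ \mu + \beta\sigma]}; propagated
#' object seeds whose intensity falls outside it (for example bright
#' vessels) are discarded.  Useful `beta_nbt` values lie in \[0.05, 0.3\]
#' (low- to high-contrast data); values outside that range trigger a
#' warning but are accepted.
#'
#' @param gm_object An `rw_gaussian` for the object class (or an
#'   `rw_gaussian_model`, whose object component is used).
#' @param beta_nbt Positive band half-width in units of sigma.
#' @return An `rw_narrowband` list: `tl`, `th`, `beta_nbt`.
#' @examples
#' narrow_band(fit_gaussian(c(90, 100, 110)), beta_nbt = 0.2)
#' @export
narrow_band <- function(gm_object, beta_nbt) {
  if (inherits(gm_object, "rw_gaussian_model")) gm_object <- gm_object$object
  stopifnot(inherits(gm_object, "rw_gaussian"))
  if (!is.numeric(beta_nbt) || length(beta_nbt) != 1L || beta_nbt < 0)
    stop("`beta_nbt` must be a single nonnegative number")
  if (beta_nbt != 0 && (beta_nbt < 0.05 || beta_nbt > 0.3))
    warning("beta_nbt = ", beta_nbt,
            " is outside the recommended range [0.05, 0.3]")
  s <- sqrt(gm_object$sigma2)
  structure(list(tl = gm_object$mu - beta_nbt * s,
                 th = gm_object$mu + beta_nbt * s,
                 beta_nbt = beta_nbt),
            class = "rw_narrowband")
}

#' Refine propagated object seeds with the narrow band
#'
#' Keeps only the object seeds whose intensity lies in `[tl, th]`
#' (inclusive).  Background seeds pass through unchanged.  If the band
#' removes every object seed the unrefined set is kept with a warning (the
#' band can be too narrow on noisy data).
#'
#' @param seeds An `rw_seeds` with a nonempty object set.
#' @param img Numeric matrix of slice intensities.
#' @param band An `rw_narrowband`.
#' @return An `rw_seeds` with object seeds a subset of the input's.
#' @export
refine_object_seeds <- function(seeds, img, band) {
  seeds <- as_rw_seeds(seeds, length(img))
  stopifnot(is.matrix(img), inherits(band, "rw_narrowband"))
  if (length(seeds$object) == 0L)
    stop("object seed set is empty: nothing to refine")
  v <- img[seeds$object]
  keep <- seeds$object[v >= band$tl & v <= band$th]
  if (length(keep) == 0L) {
    warning("narrow band [", signif(band$tl, 4), ", ", signif(band$th, 4),
            "] removed every object seed; keeping the unrefined set")
    keep <- seeds$object
  }
  seed_set(object = keep, background = seeds$background, n = length(img))
}
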