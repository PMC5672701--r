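# Slice-by-slice segmentation pipeline: interactive start-slice
# segmentation with the classical random walker, automatic bidirectional
# propagation with the Bayes-extended walker, and final per-slice boundary
# smoothing.  Also the full-volume 3D classical-walker baseline.

#' Pipeline configuration
#'
#' Bundles every tunable constant of the segmentation pipeline.
#'
#' @param beta_weight Edge-weight contrast constant of the lattice graph
#'   (default 90; applied to intensities rescaled to \[0, 1\]).
#' @param beta_nbt Narrow-band half-width in units of sigma for object-seed
#'   refinement (default 0.2; useful range \[0.05, 0.3\]).
#' @param gamma Weight of the Bayes unary term (default 0.01).
#' @param keep_components Retained Fourier components for boundary
#'   smoothing (default 15).
#' @param r_dilate1 Outer dilation radius: background-seed annulus outer
#'   edge, shape-prior support and the restricted-graph region (default 10).
#' @param r_dilate2 Inner dilation radius of the background-seed annulus
#'   (default 8).
#' @param r_erode Erosion radius producing rough object seeds (default 8).
#' @param likelihood_threshold Candidate-pixel threshold on the normalised
#'   object likelihood (default 0.5).
#' @param min_mask_area Propagation stops in a direction when the new mask
#'   has fewer pixels than this (default 20).
#' @param shape_eps Probability floor of the binary shape prior
#'   (default 0.01).
#' @param sigma2_floor Variance floor of the Gaussian intensity models on
#'   \[0, 1\]-normalised intensities (default `1e-4`).
#' @param smooth Apply Fourier boundary smoothing to the output volume
#'   (default `TRUE`).
#' @return An `rw_config` list.
#' @export
rw_config <- function(beta_weight = 90, beta_nbt = 0.2, gamma = 0.01,
                      keep_components = 15, r_dilate1 = 10, r_dilate2 = 8,
                      r_erode = 8, likelihood_threshold = 0.5,
                      min_mask_area = 20, shape_eps = 0.01,
                      sigma2_floor = 1e-4, smooth = TRUE) {
  stopifnot(beta_weight > 0, beta_nbt >= 0, gamma >= 0,
            keep_components >= 1, r_dilate1 >= 1, r_dilate2 >= 0,
            r_erode >= 0, likelihood_threshold >= 0,
            likelihood_threshold <= 1, min_mask_area >= 0,
            shape_eps > 0, shape_eps < 0.5, sigma2_floor > 0)
  structure(list(beta_weight = beta_weight, beta_nbt = beta_nbt,
                 gamma = gamma, keep_components = keep_components,
                 r_dilate1 = r_dilate1, r_dilate2 = r_dilate2,
                 r_erode = r_erode,
                 likelihood_threshold = likelihood_threshold,
                 min_mask_area = min_mask_area, shape_eps = shape_eps,
                 sigma2_floor = sigma2_floor, smooth = smooth),
            class = "rw_config")
}

# Propagation-termination signal (organ has vanished / no usable seeds).
rw_terminate <- function(msg) {
  stop(structure(class = c("rw_termination", "error", "condition"),
                 list(message = msg, call = NULL)))
}

normalize01 <- function(x) {
  rng <- range(x)
  if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else x * 0
}

# Classical or Bayes solve on the subgraph induced by `region`: every pixel
# outside `region` is marked background, so the unknown set is restricted
# to the region's unmarked pixels.
solve_restricted <- function(img, region, object, background, cfg,
                             posterior = NULL) {
  outside <- which(!region)
  background_all <- sort(unique(c(background, setdiff(outside, object))))
  seeds <- seed_set(object = object, background = background_all,
                    n = length(img))
  g <- build_lattice_graph(img, beta_weight = cfg$beta_weight)
  lap <- build_laplacian(g, seeds)
  if (is.null(posterior)) {
    pf <- solve_classical_rw(lap)
  } else {
    pf <- solve_bayes_rw(lap, posterior, gamma = cfg$gamma,
                         renormalize = TRUE)
  }
  pf
}

#' Segment the interactively seeded start slice
#'
#' The four-step start-slice procedure: fit the two-class Gaussian
#' intensity model from the user's seed pixels, threshold the normalised
#' object likelihood into candidate pixels, then run the classical random
#' walker on the candidate-restricted subgraph (all pixels outside the
#' candidate support are treated as marked background).
#'
#' @param img Numeric slice matrix.
#' @param seeds An `rw_seeds` (linear indices) or a data frame of seed
#'   coordinates (`label`, `y`, `x`); at least one seed of each class.
#' @param cfg An [rw_config()].
#' @return A list: `mask` (logical matrix), `provenance` (fitted model
#'   parameters, seed counts, solver residual, unknown count).
#' @export
segment_start_slice <- function(img, seeds, cfg = rw_config()) {
  stopifnot(is.matrix(img), inherits(cfg, "rw_config"))
  if (is.data.frame(seeds)) seeds <- seeds_from_coords(seeds, dim(img))
  seeds <- as_rw_seeds(seeds, length(img))
  if (length(seeds$object) == 0L || length(seeds$background) == 0L)
    stop("start slice needs at least one object and one background seed")
  # a single seed still defines a degenerate model: mean = value,
  # variance = floor
  obj_samp <- img[seeds$object]
  bg_samp <- img[seeds$background]
  if (length(obj_samp) == 1L) obj_samp <- rep(obj_samp, 2L)
  if (length(bg_samp) == 1L) bg_samp <- rep(bg_samp, 2L)
  gm <- gaussian_model(obj_samp, bg_samp,
                       source = "start-slice-seeds",
                       sigma2_floor = cfg$sigma2_floor)
  lk <- likelihood_map(img, gm)
  cand <- candidate_pixels(lk, cfg$likelihood_threshold)
  if (!any(cand$mask))
    stop("start slice candidate mask is empty; check the seed placement")
  region <- cand$mask
  region[seeds$object] <- TRUE
  region[seeds$background] <- TRUE
  pf <- solve_restricted(img, region, seeds$object, seeds$background, cfg)
  mask <- labels_from_probabilities(pf)
  list(mask = mask,
       provenance = list(
         kind = "start", n_object_seeds = length(seeds$object),
         n_background_seeds = length(seeds$background),
         mu = c(object = gm$object$mu, background = gm$background$mu),
         sigma = c(object = sqrt(gm$object$sigma2),
                   background = sqrt(gm$background$sigma2)),
         gamma = NA_real_, beta_weight = cfg$beta_weight,
         beta_nbt = NA_real_, residual = pf$residual,
         n_unmarked = length(pf$marked) * 0 + (length(img) - length(pf$marked))))
}

#' Automatically segment a slice from its segmented neighbour
#'
#' One propagation step: (a) refit the Gaussian intensity model from the
#' current slice's pixels under the previous mask (object) and under the
#' background annulus (background); (b) generate rough seeds by
#' erosion/dilation of the previous mask; (c) refine the object seeds with
#' the narrow-band threshold; (d) build the restricted graph over the
#' dilated previous mask (everything outside is marked background), form
#' the Bayes posterior from the candidate-thresholded likelihood and the
#' dilated-mask shape prior, solve the Bayes-extended system and threshold
#' at 0.5.
#'
#' Raises an `rw_termination` condition when the previous mask is empty,
#' no usable seeds survive, or no candidate pixels remain — the signal that
#' the organ has vanished in this direction.
#'
#' @param img Numeric slice matrix (the slice to segment).
#' @param prev_mask Logical matrix: the adjacent slice's segmentation.
#' @param cfg An [rw_config()].
#' @return A list: `mask`, `provenance` (as in [segment_start_slice()]).
#' @export
segment_next_slice <- function(img, prev_mask, cfg = rw_config()) {
  stopifnot(is.matrix(img), is.matrix(prev_mask), inherits(cfg, "rw_config"))
  prev_mask <- prev_mask > 0
  if (!any(prev_mask)) rw_terminate("previous mask is empty")
  prev_mask <- EBImage::fillHull(prev_mask) > 0

  rough <- tryCatch(
    propagate_seeds(prev_mask, r_erode = cfg$r_erode,
                    r_dilate1 = cfg$r_dilate1, r_dilate2 = cfg$r_dilate2),
    error = function(e) rw_terminate(conditionMessage(e)))
  if (length(rough$object) == 0L)
    rw_terminate("no object seeds survive erosion: organ too thin")
  if (length(rough$background) < 2L)
    rw_terminate("background annulus is empty")

  gm <- gaussian_model(img[prev_mask], img[rough$background],
                       source = "previous-slice-mask",
                       sigma2_floor = cfg$sigma2_floor)
  band <- narrow_band(gm$object, cfg$beta_nbt)
  seeds <- refine_object_seeds(rough, img, band)

  lk <- likelihood_map(img, gm)
  cand <- candidate_pixels(lk, cfg$likelihood_threshold)
  region <- mask_dilate(prev_mask, cfg$r_dilate1)
  if (!any(cand$mask & region))
    rw_terminate("no candidate pixels remain in the propagation region")
  sp <- shape_prior(prev_mask, radius = cfg$r_dilate1, eps = cfg$shape_eps)
  post <- bayes_posterior(cand$likelihood, sp)

  pf <- solve_restricted(img, region, seeds$object, seeds$background, cfg,
                         posterior = posterior_matrix(post))
  mask <- labels_from_probabilities(pf)
  list(mask = mask,
       provenance = list(
         kind = "propagated", n_object_seeds = length(seeds$object),
         n_background_seeds = length(seeds$background),
         mu = c(object = gm$object$mu, background = gm$background$mu),
         sigma = c(object = sqrt(gm$object$sigma2),
                   background = sqrt(gm$background$sigma2)),
         gamma = cfg$gamma, beta_weight = cfg$beta_weight,
         beta_nbt = cfg$beta_nbt, narrow_band = c(band$tl, band$th),
         residual = pf$residual,
         n_unmarked = length(img) - length(pf$marked)))
}

#' Segment a whole volume slice-by-slice from one seeded start slice
#'
#' Segments the start slice with the classical walker, then propagates the
#' segmentation upward (`start_slice + 1 ... nz`) and downward
#' (`start_slice - 1 ... 1`), each slice automatically seeded from its
#' already-segmented neighbour and solved with the Bayes-extended walker.
#' A direction stops at a termination signal or when the new mask area
#' falls below `cfg$min_mask_area` (the organ has vanished); remaining
#' slices in that direction stay empty.  Finally every slice boundary is
#' smoothed with truncated Fourier descriptors (unless `cfg$smooth` is
#' `FALSE`).  The whole procedure is deterministic.
#'
#' Intensities are min-max normalised to \[0, 1\] over the whole volume
#' before any model fitting, so every configuration constant is
#' scale-free.
#'
#' @param vol 3D numeric array `[y, x, z]` or an `rw_volume` from
#'   [read_volume()].
#' @param start_slice Index of the interactively seeded slice.
#' @param seeds Seeds on the start slice: `rw_seeds` (linear indices in the
#'   slice) or a data frame (`label`, `y`, `x`).
#' @param cfg An [rw_config()].
#' @return An `rw_segmentation`: `masks` (logical array), `provenance`
#'   (per-slice parameter records), `start_slice`, `config`.
#' @export
segment_volume <- function(vol, start_slice, seeds, cfg = rw_config()) {
  if (inherits(vol, "rw_volume")) vol <- vol$data
  stopifnot(length(dim(vol)) == 3L, inherits(cfg, "rw_config"))
  d <- dim(vol)
  nz <- d[3]
  if (start_slice < 1L || start_slice > nz)
    stop("start_slice must be in 1..", nz)
  nvol <- normalize01(vol)

  masks <- array(FALSE, d)
  prov <- vector("list", nz)

  start <- segment_start_slice(nvol[, , start_slice], seeds, cfg)
  if (!any(start$mask))
    stop("start slice segmentation is empty; aborting (check seeds and ",
         "likelihood threshold)")
  masks[, , start_slice] <- start$mask
  prov[[start_slice]] <- c(start$provenance, list(slice = start_slice))

  propagate_dir <- function(zs) {
    prev <- masks[, , start_slice]
    for (z in zs) {
      res <- tryCatch(segment_next_slice(nvol[, , z], prev, cfg),
                      rw_termination = function(c) c)
      if (inherits(res, "rw_termination")) {
        message("propagation stopped at slice ", z, ": ",
                conditionMessage(res))
        break
      }
      if (sum(res$mask) < cfg$min_mask_area) {
        message("propagation stopped at slice ", z,
                ": mask area below min_mask_area")
        break
      }
      masks[, , z] <<- res$mask
      prov[[z]] <<- c(res$provenance, list(slice = z))
      prev <- res$mask
    }
  }
  if (start_slice < nz) propagate_dir((start_slice + 1L):nz)
  if (start_slice > 1L) propagate_dir((start_slice - 1L):1L)

  if (cfg$smooth) {
    for (z in seq_len(nz)) {
      if (any(masks[, , z]))
        masks[, , z] <- smooth_mask(masks[, , z], keep = cfg$keep_components)
    }
  }
  structure(list(masks = masks, provenance = prov,
                 start_slice = start_slice, config = cfg),
            class = "rw_segmentation")
}

#' @export
print.rw_segmentation <- function(x, ...) {
  seg <- which(vapply(seq_len(dim(x$masks)[3]),
                      function(z) any(x$masks[, , z]), logical(1)))
  cat(sprintf("rw_segmentation: %s volume, start slice %d, %d segmented slice(s) [%s], %d object voxels\n",
              paste(dim(x$masks), collapse = "x"), x$start_slice,
              length(seg),
              if (length(seg)) paste(range(seg), collapse = "-") else "-",
              sum(x$masks)))
  invisible(x)
}

#' Classical 3D random-walker baseline on the full volume
#'
#' The unmodified seeded random walker applied to the whole 6-connected
#' voxel lattice in one solve — the comparison baseline for the
#' slice-propagated method.  No intensity model, shape prior, automatic
#' seeding or smoothing is involved.
#'
#' @param vol 3D numeric array or `rw_volume`.
#' @param seeds `rw_seeds` of linear voxel indices, or a data frame with
#'   columns `label`, `y`, `x`, `z`.
#' @param beta_weight Edge-weight constant (default 90).
#' @return An `rw_segmentation` with a single provenance record.
#' @export
segment_volume_rw3d <- function(vol, seeds, beta_weight = 90) {
  if (inherits(vol, "rw_volume")) vol <- vol$data
  stopifnot(length(dim(vol)) == 3L)
  if (is.data.frame(seeds)) seeds <- seeds_from_coords(seeds, dim(vol))
  seeds <- as_rw_seeds(seeds, length(vol))
  g <- build_lattice_graph(vol, beta_weight = beta_weight,
                           connectivity = "6")
  lap <- build_laplacian(g, seeds)
  pf <- solve_classical_rw(lap)
  masks <- labels_from_probabilities(pf)
  structure(list(masks = masks,
                 provenance = list(list(
                   kind = "rw3d-baseline",
                   n_object_seeds = length(seeds$object),
                   n_background_seeds = length(seeds$background),
                   beta_weight = beta_weight, residual = pf$residual,
                   n_unmarked = length(vol) - length(pf$marked))),
                 start_slice = NA_integer_,
                 config = NULL),
            class = "rw_segmentation")
}
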