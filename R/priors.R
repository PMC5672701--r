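# Per-class Gaussian intensity models, likelihood maps, candidate-pixel
# thresholding, the dilated-mask shape prior, and the Bayes posterior that
# feeds the extended random-walker system.

#' Fit a single-class Gaussian intensity model
#'
#' Maximum-likelihood fit: `mu` is the sample mean and `sigma2` the
#' population variance (divisor n), floored at `sigma2_floor` so that
#' degenerate constant regions still give a proper density.
#'
#' @param samples Numeric vector of at least 2 intensities.
#' @param sigma2_floor Lower bound on the fitted variance (default `1e-4`,
#'   appropriate for intensities normalised to \[0, 1\]).
#' @return An `rw_gaussian` list: `mu`, `sigma2`, `n`.
#' @examples
#' fit_gaussian(c(1, 2, 3))  # mu 2, sigma2 2/3
#' @export
fit_gaussian <- function(samples, sigma2_floor = 1e-4) {
  samples <- as.numeric(samples)
  samples <- samples[is.finite(samples)]
  if (length(samples) < 2L)
    stop("insufficient data: at least 2 intensity samples are required")
  mu <- mean(samples)
  sigma2 <- max(mean((samples - mu)^2), sigma2_floor)
  structure(list(mu = mu, sigma2 = sigma2, n = length(samples)),
            class = "rw_gaussian")
}

#' Fit the two-class (object/background) Gaussian model
#'
#' @param object_samples,background_samples Intensity samples per class.
#' @param source Where the samples came from: seeds on the start slice or
#'   the previous slice's segmentation.
#' @inheritParams fit_gaussian
#' @return An `rw_gaussian_model` list with `object` and `background`
#'   `rw_gaussian` components and the `source` tag.
#' @export
gaussian_model <- function(object_samples, background_samples,
                           source = c("start-slice-seeds", "previous-slice-mask"),
                           sigma2_floor = 1e-4) {
  source <- match.arg(source)
  structure(list(object = fit_gaussian(object_samples, sigma2_floor),
                 background = fit_gaussian(background_samples, sigma2_floor),
                 source = source),
            class = "rw_gaussian_model")
}

#' @export
print.rw_gaussian_model <- function(x, ...) {
  cat(sprintf("rw_gaussian_model (%s): object N(%.4g, %.4g^2) n=%d; background N(%.4g, %.4g^2) n=%d\n",
              x$source, x$object$mu, sqrt(x$object$sigma2), x$object$n,
              x$background$mu, sqrt(x$background$sigma2), x$background$n))
  invisible(x)
}

#' Normalised two-class likelihood map
#'
#' Evaluates the Gaussian density of each class at every pixel and
#' normalises across the two classes:
#' \eqn{p(I_i \mid s) / \sum_q p(I_i \mid q)}.  Pixels where both raw
#' densities underflow to zero are assigned 0.5/0.5.
#'
#' @param img Numeric matrix (slice).
#' @param gm An `rw_gaussian_model`.
#' @return An `rw_likelihood` list with matrices `object` and `background`
#'   (each in (0, 1), summing to 1 pixelwise) and the grid `dims`.
#' @export
likelihood_map <- function(img, gm) {
  stopifnot(is.matrix(img), inherits(gm, "rw_gaussian_model"))
  p1 <- stats::dnorm(img, gm$object$mu, sqrt(gm$object$sigma2))
  p2 <- stats::dnorm(img, gm$background$mu, sqrt(gm$background$sigma2))
  den <- p1 + p2
  zero <- den == 0
  o <- ifelse(zero, 0.5, p1 / den)
  b <- ifelse(zero, 0.5, p2 / den)
  structure(list(object = o, background = b, dims = dim(img)),
            class = "rw_likelihood")
}

#' Threshold the object likelihood into candidate pixels
#'
#' The object-class likelihood is set to 0 wherever it falls below the
#' threshold; the surviving support is the candidate-pixel mask on which
#' the solver operates.  Background likelihoods pass through unmodified.
#' Values exactly at the threshold are kept.
#'
#' @param lk An `rw_likelihood`.
#' @param threshold Discard object likelihoods below this value (default 0.5).
#' @return A list: `mask` (logical candidate matrix) and `likelihood`
#'   (the thresholded `rw_likelihood`).
#' @export
candidate_pixels <- function(lk, threshold = 0.5) {
  stopifnot(inherits(lk, "rw_likelihood"))
  mask <- lk$object >= threshold
  out <- lk
  out$object <- ifelse(mask, lk$object, 0)
  list(mask = mask, likelihood = out)
}

#' Shape prior from the previous slice's segmentation
#'
#' Dilates the previous organ mask with a discrete disk and assigns the
#' object prior \eqn{p(s{=}1) = 1 - \epsilon} inside the dilated support and
#' \eqn{\epsilon} outside; the background prior is the complement.  The
#' small \eqn{\epsilon} keeps the Bayes-extended linear system well posed
#' everywhere.
#'
#' @param prev_mask Logical matrix: the adjacent slice's organ mask
#'   (nonempty).
#' @param radius Dilation disk radius in pixels (default 10).
#' @param eps Probability floor outside/inside the support (default 0.01).
#' @return An `rw_shapeprior` list: `mask` (dilated support), `p_object`,
#'   `p_background`, `radius`, `eps`.
#' @export
shape_prior <- function(prev_mask, radius = 10, eps = 0.01) {
  stopifnot(is.matrix(prev_mask))
  prev_mask <- prev_mask > 0
  if (!any(prev_mask))
    stop("previous mask is empty: propagation should have terminated upstream")
  m <- mask_dilate(prev_mask, radius)
  p1 <- ifelse(m, 1 - eps, eps)
  structure(list(mask = m, p_object = p1, p_background = 1 - p1,
                 radius = radius, eps = eps),
            class = "rw_shapeprior")
}

#' Bayes posterior combining intensity likelihood and shape prior
#'
#' Per pixel, \eqn{p(s \mid I_i) = p(I_i \mid s)\, p(s) / \sum_q p(I_i \mid q)\, p(q)}.
#' With `sp = NULL` both labels are taken as equally likely a priori, so the
#' posterior is just the renormalised likelihood (the start-slice case with
#' no previous mask).  Pixels where both numerators vanish get 0.5/0.5 with
#' a warning.
#'
#' @param lk An `rw_likelihood` (possibly candidate-thresholded).
#' @param sp An `rw_shapeprior`, or `NULL` for equal priors.
#' @return An `rw_posterior` list with matrices `object`, `background`
#'   summing to 1 pixelwise.
#' @export
bayes_posterior <- function(lk, sp = NULL) {
  stopifnot(inherits(lk, "rw_likelihood"))
  if (is.null(sp)) {
    p1 <- 0.5; p2 <- 0.5
  } else {
    stopifnot(inherits(sp, "rw_shapeprior"))
    if (!identical(dim(sp$p_object), lk$dims))
      stop("likelihoods and shape prior must share the same grid")
    p1 <- sp$p_object; p2 <- sp$p_background
  }
  n1 <- lk$object * p1
  n2 <- lk$background * p2
  den <- n1 + n2
  zero <- den == 0
  if (any(zero)) {
    warning(sum(zero), " pixel(s) with zero posterior denominator; assigned 0.5/0.5")
    n1[zero] <- 0.5; n2[zero] <- 0.5; den[zero] <- 1
  }
  structure(list(object = n1 / den, background = n2 / den, dims = lk$dims),
            class = "rw_posterior")
}

#' Flatten a posterior into the n-by-2 matrix used by the solver
#'
#' @param post An `rw_posterior`.
#' @return Numeric matrix with columns (object, background).
#' @export
posterior_matrix <- function(post) {
  stopifnot(inherits(post, "rw_posterior"))
  cbind(as.numeric(post$object), as.numeric(post$background))
}
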