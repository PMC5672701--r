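# Random-walker linear-system solves: the classical seeded system and the
# Bayes-extended system with a diagonal unary (posterior) term.

new_probfield <- function(probs, dims, lap, residual) {
  colnames(probs) <- c("object", "background")
  structure(list(probs = probs, dims = dims,
                 marked = lap$marked, object = lap$object,
                 background = lap$background, residual = residual),
            class = "rw_probfield")
}

#' @export
print.rw_probfield <- function(x, ...) {
  cat(sprintf("rw_probfield: %d pixels (%s), %d marked, residual %.2e\n",
              nrow(x$probs), paste(x$dims, collapse = "x"),
              length(x$marked), x$residual))
  invisible(x)
}

solve_spd <- function(A, rhs) {
  x <- tryCatch(Matrix::solve(A, rhs),
                error = function(e)
                  stop("random-walker system is singular or not positive ",
                       "definite (an unmarked region is disconnected from ",
                       "every seed): ", conditionMessage(e), call. = FALSE))
  as.numeric(x)
}

rel_residual <- function(A, x, rhs) {
  r <- sqrt(sum((as.numeric(A %*% x) - rhs)^2))
  r / max(1, sqrt(sum(rhs^2)))
}

#' Solve the classical seeded random-walker system
#'
#' Computes, for every unmarked pixel, the probability that a random walk
#' started there reaches an object seed before a background seed, by solving
#' the reduced Laplacian system \eqn{L_U x_U^1 = -B^\top x_M^1} where
#' \eqn{x_M^1} is 1 on object seeds and 0 on background seeds.  The
#' background probability is recovered as the complement
#' \eqn{x^2 = 1 - x^1}.
#'
#' @param lap An `rw_laplacian` built with a nonempty seed set
#'   (see [build_laplacian()]).
#' @param tol Maximum accepted relative residual of the solve (default `1e-8`).
#' @return An `rw_probfield`: `probs` is an n-by-2 matrix of per-pixel
#'   probabilities for (object, background) summing to 1, with marked pixels
#'   set exactly to their label indicator.
#' @examples
#' img <- matrix(0, 1, 5)
#' g <- build_lattice_graph(img, beta_weight = 90)
#' lap <- build_laplacian(g, seed_set(object = 1, background = 5))
#' solve_classical_rw(lap)$probs[, "object"]
#' @export
solve_classical_rw <- function(lap, tol = 1e-8) {
  stopifnot(inherits(lap, "rw_laplacian"))
  if (length(lap$object) == 0L || length(lap$background) == 0L)
    stop("both object and background seed sets must be nonempty")
  xM <- as.numeric(lap$marked %in% lap$object)
  rhs <- -as.numeric(Matrix::crossprod(lap$B, xM))
  xu <- solve_spd(lap$LU, rhs)
  res <- rel_residual(lap$LU, xu, rhs)
  if (res > tol)
    stop(sprintf("solver residual %.3e exceeds tolerance %.1e", res, tol))
  x1 <- numeric(lap$n)
  x1[lap$unmarked] <- xu
  x1[lap$object] <- 1
  x1[lap$background] <- 0
  new_probfield(cbind(x1, 1 - x1), lap$dims, lap, res)
}

#' Solve the Bayes-extended random-walker system
#'
#' Adds a unary energy that pulls each pixel's probability toward a Bayes
#' posterior \eqn{p(s \mid I_i)}: the reduced system becomes
#' \deqn{(L_U + \gamma \sum_q \Lambda^q)\, x_U^s = \gamma\, p(s \mid I_U) - B^\top x_M^s,}
#' where \eqn{\Lambda^q} is the diagonal matrix of posterior values for label
#' q.  Both labels are solved independently and the per-pixel sum
#' \eqn{\sum_s x_i^s = 1} is a derived conservation property (checked, and
#' optionally renormalised).  With `gamma = 0` and nonempty seeds the system
#' reduces to the classical random walker.  With an empty marked set the
#' unreduced form \eqn{(L + \gamma \sum_q \Lambda^q) x^s = \gamma p(s \mid I)}
#' is solved instead (it is nonsingular for `gamma > 0`); in the large-gamma
#' limit the solution approaches the posterior itself.
#'
#' @param lap An `rw_laplacian`; may have an empty marked set (build with
#'   `allow_empty = TRUE`) when `gamma > 0`.
#' @param posterior n-by-2 matrix of per-pixel posterior probabilities for
#'   (object, background); rows should sum to 1.
#' @param gamma Nonnegative weight of the Bayes term (default 0.01).
#' @param renormalize If `TRUE`, rescale each pixel's two probabilities to
#'   sum to exactly 1 when the conservation defect exceeds `1e-6`.
#' @param tol Maximum accepted relative residual (default `1e-8`).
#' @return An `rw_probfield` (see [solve_classical_rw()]).
#' @export
solve_bayes_rw <- function(lap, posterior, gamma = 0.01, renormalize = FALSE,
                           tol = 1e-8) {
  stopifnot(inherits(lap, "rw_laplacian"))
  posterior <- as.matrix(posterior)
  if (nrow(posterior) != lap$n || ncol(posterior) != 2L)
    stop("`posterior` must be an n-by-2 matrix over all pixels")
  if (any(!is.finite(posterior)) || any(posterior < 0))
    stop("`posterior` must be finite and nonnegative")
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0)
    stop("invalid input: `gamma` must be a single nonnegative number")
  seedless <- length(lap$marked) == 0L
  if (seedless && gamma == 0)
    stop("gamma = 0 with an empty seed set: the system is singular")

  lam <- rowSums(posterior)          # diagonal of sum_q Lambda^q
  if (seedless) {
    A <- lap$L + gamma * Matrix::Diagonal(x = lam)
    X <- vapply(1:2, function(s) {
      rhs <- gamma * posterior[, s]
      x <- solve_spd(A, rhs)
      res <- rel_residual(A, x, rhs)
      if (res > tol)
        stop(sprintf("solver residual %.3e exceeds tolerance %.1e", res, tol))
      x
    }, numeric(lap$n))
    res <- NA_real_
  } else {
    A <- lap$LU + gamma * Matrix::Diagonal(x = lam[lap$unmarked])
    res <- 0
    X <- matrix(0, lap$n, 2L)
    for (s in 1:2) {
      own <- if (s == 1L) lap$object else lap$background
      xM <- as.numeric(lap$marked %in% own)
      rhs <- gamma * posterior[lap$unmarked, s] -
        as.numeric(Matrix::crossprod(lap$B, xM))
      xu <- solve_spd(A, rhs)
      res <- max(res, rel_residual(A, xu, rhs))
      X[lap$unmarked, s] <- xu
      X[own, s] <- 1
    }
    if (res > tol)
      stop(sprintf("solver residual %.3e exceeds tolerance %.1e", res, tol))
  }
  defect <- max(abs(rowSums(X) - 1))
  if (renormalize && defect > 1e-6) X <- X / rowSums(X)
  pf <- new_probfield(X, lap$dims, lap, res)
  pf$conservation_defect <- defect
  pf
}

#' Threshold a probability field into a binary label mask
#'
#' A pixel is labelled object iff its object probability is at least 0.5;
#' exact ties go to the object label.
#'
#' @param pf An `rw_probfield`.
#' @return A logical array with the field's grid dimensions (`TRUE` =
#'   object).
#' @export
labels_from_probabilities <- function(pf) {
  stopifnot(inherits(pf, "rw_probfield"))
  array(pf$probs[, "object"] >= 0.5, dim = pf$dims)
}
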