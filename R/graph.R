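# Lattice graph construction and graph Laplacian for random-walker solves.
#
# Node indexing follows R's native array linearisation (column-major):
# for a 2D slice stored as a matrix `img[y, x]` the node index of pixel
# (y, x) is (x - 1) * nrow + y; for a 3D volume `vol[y, x, z]` it is
# (z - 1) * ny * nx + (x - 1) * ny + y.  Seed sets, probability fields and
# masks all use these linear indices, so `mask[idx]` works directly.

#' Build a weighted lattice graph over an image
#'
#' Every pixel (voxel) is a node; edges connect 4-neighbours in 2D and
#' 6-neighbours in 3D.  The edge weight between neighbouring pixels i, j is
#' the Gaussian similarity \eqn{w_{ij} = \exp(-\beta (\hat I_i - \hat I_j)^2)},
#' where \eqn{\hat I} is the image min-max rescaled to \[0, 1\] so that
#' `beta_weight` is independent of the input intensity scale.  A small
#' positive floor is added to every weight so the graph stays numerically
#' connected even for very large `beta_weight`.
#'
#' @param img Numeric matrix (2D slice) or 3D array of finite intensities,
#'   with at least 2 pixels.
#' @param beta_weight Positive contrast-sensitivity constant (default 90).
#' @param connectivity `"4"` (2D) or `"6"` (3D); defaults to the minimal
#'   lattice connectivity matching `dim(img)`.
#' @param weight_floor Additive floor on every edge weight (default `1e-6`).
#' @return An object of class `rw_graph`: a list with `n` (node count),
#'   `dims`, `connectivity`, `edges` (data frame `i`, `j`, `w` with `i < j`),
#'   and `degrees` (\eqn{d_i = \sum_j w_{ij}}).
#' @examples
#' g <- build_lattice_graph(matrix(c(0, 1), 1, 2), beta_weight = 90)
#' g$edges
#' @export
build_lattice_graph <- function(img, beta_weight = 90, connectivity = NULL,
                                weight_floor = 1e-6) {
  if (!is.numeric(img)) stop("`img` must be a numeric matrix or 3D array")
  d <- dim(img)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop("`img` must be a 2D matrix or a 3D array")
  if (length(img) < 2L)
    stop("invalid input: image must contain at least 2 pixels")
  if (any(!is.finite(img)))
    stop("invalid input: image intensities must be finite")
  if (!is.numeric(beta_weight) || length(beta_weight) != 1L || beta_weight <= 0)
    stop("`beta_weight` must be a single positive number")
  default_conn <- if (length(d) == 2L) "4" else "6"
  connectivity <- if (is.null(connectivity)) default_conn else as.character(connectivity)
  connectivity <- match.arg(connectivity, c("4", "6"))
  if (connectivity == "4" && length(d) != 2L)
    stop("4-connectivity requires a 2D image")
  if (connectivity == "6" && length(d) != 3L)
    stop("6-connectivity requires a 3D volume")

  rng <- range(img)
  nimg <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) else array(0, d)

  n <- length(img)
  idx <- array(seq_len(n), d)
  if (length(d) == 2L) {
    a <- c(if (d[1] > 1L) idx[-d[1], , drop = FALSE],
           if (d[2] > 1L) idx[, -d[2], drop = FALSE])
    b <- c(if (d[1] > 1L) idx[-1L, , drop = FALSE],
           if (d[2] > 1L) idx[, -1L, drop = FALSE])
  } else {
    a <- c(if (d[1] > 1L) idx[-d[1], , , drop = FALSE],
           if (d[2] > 1L) idx[, -d[2], , drop = FALSE],
           if (d[3] > 1L) idx[, , -d[3], drop = FALSE])
    b <- c(if (d[1] > 1L) idx[-1L, , , drop = FALSE],
           if (d[2] > 1L) idx[, -1L, , drop = FALSE],
           if (d[3] > 1L) idx[, , -1L, drop = FALSE])
  }
  a <- as.integer(a); b <- as.integer(b)
  w <- exp(-beta_weight * (nimg[a] - nimg[b])^2) + weight_floor

  deg <- numeric(n)
  acc <- rowsum(c(w, w), group = c(a, b))
  deg[as.integer(rownames(acc))] <- acc[, 1L]

  structure(list(n = n, dims = d, connectivity = connectivity,
                 edges = data.frame(i = a, j = b, w = w),
                 degrees = deg, beta_weight = beta_weight,
                 weight_floor = weight_floor),
            class = "rw_graph")
}

#' @export
print.rw_graph <- function(x, ...) {
  cat(sprintf("rw_graph: %d nodes (%s), %d edges, %s-connected, beta = %g\n",
              x$n, paste(x$dims, collapse = "x"), nrow(x$edges),
              x$connectivity, x$beta_weight))
  invisible(x)
}

#' Assemble the graph Laplacian and its seed partition
#'
#' Builds the sparse combinatorial Laplacian \eqn{L} (degree minus weighted
#' adjacency) and partitions it by the marked/unmarked node split into the
#' blocks \eqn{L_M}, \eqn{B} and \eqn{L_U} used by the random-walker linear
#' system \eqn{L_U x_U = -B^\top x_M}.
#'
#' @param g An `rw_graph`.
#' @param seeds An `rw_seeds` object (see [seed_set()]).
#' @param allow_empty Permit an empty marked set (needed only for the
#'   seedless Bayes solve of the unreduced system); default `FALSE`.
#' @return An object of class `rw_laplacian`: sparse `L`, the blocks `LU`
#'   and `B`, index vectors `marked`/`unmarked`/`object`/`background`, and
#'   the grid `dims`.
#' @export
build_laplacian <- function(g, seeds, allow_empty = FALSE) {
  stopifnot(inherits(g, "rw_graph"))
  seeds <- as_rw_seeds(seeds, g$n)
  marked <- sort(c(seeds$object, seeds$background))
  if (length(marked) == 0L && !allow_empty)
    stop("marked set is empty: the reduced random-walker system is singular")

  W <- Matrix::sparseMatrix(i = c(g$edges$i, g$edges$j),
                            j = c(g$edges$j, g$edges$i),
                            x = c(g$edges$w, g$edges$w),
                            dims = c(g$n, g$n))
  L <- Matrix::Diagonal(x = g$degrees) - W
  L <- methods::as(Matrix::forceSymmetric(L), "CsparseMatrix")

  unmarked <- if (length(marked)) seq_len(g$n)[-marked] else seq_len(g$n)
  structure(list(L = L,
                 LU = L[unmarked, unmarked, drop = FALSE],
                 B = L[marked, unmarked, drop = FALSE],
                 marked = marked, unmarked = unmarked,
                 object = seeds$object, background = seeds$background,
                 n = g$n, dims = g$dims),
            class = "rw_laplacian")
}

#' Construct a validated seed set
#'
#' @param object Integer vector of linear node indices pre-labelled object
#'   (foreground, label 1).
#' @param background Integer vector of node indices pre-labelled background
#'   (label 2).
#' @param n Optional node count for bounds checking.
#' @return An `rw_seeds` list with sorted unique `object` and `background`.
#' @export
seed_set <- function(object = integer(), background = integer(), n = NULL) {
  object <- sort(unique(as.integer(object)))
  background <- sort(unique(as.integer(background)))
  if (anyNA(object) || anyNA(background))
    stop("seed indices must not contain NA")
  both <- intersect(object, background)
  if (length(both))
    stop("conflict: node(s) ", paste(utils::head(both, 5L), collapse = ", "),
         " marked with both labels")
  if (!is.null(n) && length(c(object, background)) &&
      (min(c(object, background)) < 1L || max(c(object, background)) > n))
    stop("seed index out of range 1..", n)
  structure(list(object = object, background = background), class = "rw_seeds")
}

as_rw_seeds <- function(seeds, n = NULL) {
  if (inherits(seeds, "rw_seeds")) {
    if (!is.null(n)) seed_set(seeds$object, seeds$background, n) else seeds
  } else if (is.list(seeds) && all(c("object", "background") %in% names(seeds))) {
    seed_set(seeds$object, seeds$background, n)
  } else {
    stop("`seeds` must be an rw_seeds object or a list with $object/$background")
  }
}

#' Convert seed pixel coordinates to a seed set of linear indices
#'
#' Coordinates are 1-based `(y, x)` pairs (plus `z` for volumes), matching R
#' matrix indexing: `y` is the row, `x` the column.
#'
#' @param coords Data frame with columns `label` (1/2 or
#'   `"object"`/`"background"`), `y`, `x` and optionally `z`.
#' @param dims Grid dimensions `c(ny, nx)` or `c(ny, nx, nz)`.
#' @return An `rw_seeds` object.
#' @export
seeds_from_coords <- function(coords, dims) {
  stopifnot(is.data.frame(coords), all(c("label", "y", "x") %in% names(coords)))
  lab <- coords$label
  if (is.character(lab) || is.factor(lab)) {
    lab <- match(as.character(lab), c("object", "background"))
    if (anyNA(lab)) stop("seed labels must be 1/2 or 'object'/'background'")
  }
  if (!all(lab %in% c(1, 2))) stop("seed labels must be 1 (object) or 2 (background)")
  y <- as.integer(coords$y); x <- as.integer(coords$x)
  z <- if ("z" %in% names(coords)) as.integer(coords$z) else rep(1L, nrow(coords))
  ny <- dims[1]; nx <- dims[2]; nz <- if (length(dims) > 2L) dims[3] else 1L
  bad <- which(y < 1L | y > ny | x < 1L | x > nx | z < 1L | z > nz)
  if (length(bad))
    stop("seed coordinate out of bounds at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  idx <- (z - 1L) * ny * nx + (x - 1L) * ny + y
  dup <- idx[duplicated(idx)]
  if (length(dup)) {
    for (p in unique(dup)) {
      if (length(unique(lab[idx == p])) > 1L)
        stop("conflict: pixel listed with both labels (linear index ", p, ")")
    }
  }
  seed_set(idx[lab == 1], idx[lab == 2], n = ny * nx * nz)
}
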