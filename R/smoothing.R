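# Boundary extraction, truncated-Fourier-descriptor smoothing, and
# rasterization back to a mask.
#
# A contour is an ordered closed sequence of boundary pixel coordinates,
# stored as an N x 2 matrix with columns (y, x), 1-based; the first point
# implicitly connects back to the last.

#' Trace the outer boundary of each connected component
#'
#' 8-connected ordered boundary tracing of every connected component of a
#' binary mask.  Components with fewer than 3 boundary pixels are skipped
#' with a message.
#'
#' @param mask Logical (or 0/1) matrix, nonempty.
#' @return A list of contours, each an N-by-2 matrix with columns `y`, `x`.
#' @export
trace_boundary <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- mask > 0
  if (!any(m)) stop("mask is empty: no boundary to trace")
  lab <- EBImage::bwlabel(m)
  oc <- EBImage::ocontour(lab)
  out <- list()
  for (k in seq_along(oc)) {
    pts <- oc[[k]] + 1L                      # 0-based -> 1-based
    colnames(pts) <- c("y", "x")
    # drop consecutive duplicates (incl. a repeated closing point)
    if (nrow(pts) > 1L) {
      dup <- c(FALSE, rowSums(abs(diff(pts))) == 0)
      pts <- pts[!dup, , drop = FALSE]
      if (nrow(pts) > 1L && all(pts[1L, ] == pts[nrow(pts), ]))
        pts <- pts[-nrow(pts), , drop = FALSE]
    }
    if (nrow(pts) < 3L) {
      message("trace_boundary: component ", k,
              " has fewer than 3 boundary points; skipped")
      next
    }
    out[[length(out) + 1L]] <- pts
  }
  out
}

#' Low-pass smooth a closed contour with truncated Fourier descriptors
#'
#' Each coordinate sequence is transformed with the discrete Fourier
#' transform; only the `keep` lowest absolute frequencies are retained
#' (the DC term plus `keep - 1` harmonics, each together with its conjugate
#' partner so the inverse transform is real), and the inverse transform
#' gives the smoothed closed curve.  Truncating the high frequencies
#' removes jagged, pixel-scale detail while preserving the coarse shape;
#' because the DC term is always kept, the contour centroid is unchanged.
#'
#' @param contour N-by-2 matrix (columns `y`, `x`) with `N > 2 * keep`;
#'   shorter contours are returned unchanged with a warning (boundaries are
#'   typically longer than 100 points).
#' @param keep Number of retained frequency components per coordinate
#'   (default 15).
#' @return A smoothed N-by-2 real contour (no longer integer pixel
#'   coordinates).
#' @export
fourier_smooth <- function(contour, keep = 15) {
  stopifnot(is.matrix(contour), ncol(contour) == 2L)
  n <- nrow(contour)
  keep <- as.integer(keep)
  stopifnot(keep >= 1L)
  if (n <= 2L * keep) {
    warning("contour has ", n, " points, too few for keep = ", keep,
            "; returned unchanged")
    return(contour)
  }
  sel <- logical(n)
  sel[seq_len(keep)] <- TRUE                        # frequencies 0 .. keep-1
  if (keep > 1L) sel[n - seq_len(keep - 1L) + 1L] <- TRUE  # conjugate partners
  out <- apply(contour, 2L, function(v) {
    f <- stats::fft(v)
    f[!sel] <- 0
    Re(stats::fft(f, inverse = TRUE)) / n
  })
  colnames(out) <- colnames(contour)
  out
}

# Offset a closed contour along its outward normals.  Traced contours
# connect boundary-pixel centres; the underlying region boundary runs half
# a pixel outside them, so smoothing operates on the offset curve.
offset_contour <- function(contour, by = 0.5) {
  n <- nrow(contour)
  if (n < 3L || by == 0) return(contour)
  nxt <- contour[c(2:n, 1L), , drop = FALSE]
  prv <- contour[c(n, 1:(n - 1L)), , drop = FALSE]
  tg <- nxt - prv                               # central-difference tangent
  nrm <- cbind(tg[, 2L], -tg[, 1L])             # rotate: candidate normal
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  # orientation from the signed area decides which rotation points outward
  y <- contour[, 1L]; x <- contour[, 2L]
  signed <- sum(x * nxt[, 1L] - nxt[, 2L] * y) / 2
  if (signed > 0) nrm <- -nrm
  contour + by * nrm
}

contour_area <- function(contour) {
  y <- contour[, 1L]; x <- contour[, 2L]
  yn <- c(y[-1L], y[1L]); xn <- c(x[-1L], x[1L])
  abs(sum(x * yn - xn * y)) / 2
}

#' Rasterize a closed contour into a filled binary mask
#'
#' Fills the polygon bounded by the contour on the given grid (pixel
#' centres at integer coordinates), clipping any part that falls outside.
#' A pixel belongs to the mask iff its centre is strictly inside the
#' polygon or lies exactly on it (so a traced pixel boundary rasterizes
#' back to the same pixels, while a smoothed curve passing between pixel
#' centres never recruits pixels beyond it).
#'
#' @param contour N-by-2 matrix (columns `y`, `x`), treated as a closed
#'   polygon.
#' @param shape Grid dimensions `c(ny, nx)`.
#' @return Logical ny-by-nx matrix.
#' @export
rasterize_contour <- function(contour, shape) {
  stopifnot(is.matrix(contour), ncol(contour) == 2L, length(shape) == 2L)
  ny <- shape[1L]; nx <- shape[2L]
  out <- matrix(FALSE, ny, nx)
  if (nrow(contour) < 3L || contour_area(contour) == 0) {
    warning("degenerate (zero-area) contour: empty mask returned")
    return(out)
  }
  bnd <- rbind(contour, contour[1L, ])
  pts <- cbind(y = as.numeric(rep(seq_len(ny), nx)),
               x = as.numeric(rep(seq_len(nx), each = ny)))
  inside <- mgcv::in.out(bnd, pts)
  out[inside] <- TRUE
  # pixel centres lying exactly on the polygon: densify each edge at
  # half-pixel steps (so integer centres on integer edges are sampled
  # exactly) and keep only points that coincide with a centre
  dens <- do.call(rbind, lapply(seq_len(nrow(contour)), function(k) {
    p <- contour[k, ]; q <- bnd[k + 1L, ]
    steps <- max(2L, 2L * ceiling(max(abs(q - p))) + 1L)
    cbind(seq(p[1L], q[1L], length.out = steps),
          seq(p[2L], q[2L], length.out = steps))
  }))
  ry <- round(dens[, 1L]); rx <- round(dens[, 2L])
  on_centre <- abs(dens[, 1L] - ry) < 1e-6 & abs(dens[, 2L] - rx) < 1e-6
  ok <- on_centre & ry >= 1 & ry <= ny & rx >= 1 & rx <= nx
  out[cbind(ry[ok], rx[ok])] <- TRUE
  out
}

#' Smooth every component of a mask via Fourier descriptors
#'
#' Traces each connected component's boundary, low-pass filters it with
#' [fourier_smooth()], rasterizes the result and unions the components.
#' Components too small to trace are kept unchanged.  Filling the smoothed
#' closed boundary also closes any interior holes.
#'
#' @param mask Logical matrix.
#' @param keep Retained Fourier components (default 15).
#' @return Logical matrix of the same shape.
#' @export
smooth_mask <- function(mask, keep = 15) {
  stopifnot(is.matrix(mask))
  m <- mask > 0
  if (!any(m)) return(m)
  lab <- EBImage::bwlabel(m)
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (j in seq_len(max(lab))) {
    comp <- lab == j
    cont <- suppressMessages(trace_boundary(comp))
    if (length(cont) == 0L) { out <- out | comp; next }
    sm <- suppressWarnings(fourier_smooth(offset_contour(cont[[1L]], 0.5),
                                          keep = keep))
    r <- rasterize_contour(sm, dim(m))
    if (!any(r)) r <- comp
    out <- out | r
  }
  out
}
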