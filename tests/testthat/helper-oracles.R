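# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths: dense enumeration,
# absorbing-Markov-chain fundamental-matrix solves, exhaustive
# structuring-element scans and direct O(N^2) DFT summation.

# Dense Laplacian by exhaustive pixel-pair enumeration (4-neighbour 2D).
dense_laplacian_oracle <- function(img, beta, floor = 1e-6) {
  d <- dim(img)
  rng <- range(img)
  nimg <- if (rng[2] > rng[1]) (img - rng[1]) / diff(rng) else img * 0
  n <- length(img)
  coord <- cbind(y = (seq_len(n) - 1L) %% d[1] + 1L,
                 x = (seq_len(n) - 1L) %/% d[1] + 1L)
  L <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && sum(abs(coord[i, ] - coord[j, ])) == 1L) {
      L[i, j] <- -(exp(-beta * (nimg[i] - nimg[j])^2) + floor)
    }
  }
  diag(L) <- -rowSums(L)
  L
}

# Absorbing-Markov-chain oracle: first-arrival probabilities at object
# seeds via the fundamental matrix (I - Q)^{-1} R of the walk with
# transition P_ij = w_ij / d_i.
absorbing_chain_oracle <- function(g, seeds) {
  n <- g$n
  W <- matrix(0, n, n)
  for (k in seq_len(nrow(g$edges))) {
    i <- g$edges$i[k]; j <- g$edges$j[k]; w <- g$edges$w[k]
    W[i, j] <- W[i, j] + w
    W[j, i] <- W[j, i] + w
  }
  P <- W / rowSums(W)
  marked <- sort(c(seeds$object, seeds$background))
  um <- setdiff(seq_len(n), marked)
  Q <- P[um, um, drop = FALSE]
  R <- P[um, marked, drop = FALSE]
  A <- solve(diag(length(um)) - Q, R)   # absorption probabilities
  x1 <- numeric(n)
  x1[um] <- A %*% as.numeric(marked %in% seeds$object)
  x1[seeds$object] <- 1
  x1
}

# Exhaustive-scan binary morphology with a discrete Euclidean disk.
# Offsets that fall outside the image are ignored (the package's stated
# border rule).
brute_morph <- function(mask, r, op = c("erode", "dilate")) {
  op <- match.arg(op)
  d <- dim(mask)
  offs <- which(disk_kernel(r) == 1L, arr.ind = TRUE) - (r + 1L)
  out <- matrix(FALSE, d[1], d[2])
  for (y in seq_len(d[1])) for (x in seq_len(d[2])) {
    yy <- y + offs[, 1]; xx <- x + offs[, 2]
    ok <- yy >= 1 & yy <= d[1] & xx >= 1 & xx <= d[2]
    vals <- mask[cbind(yy[ok], xx[ok])]
    out[y, x] <- if (op == "erode") all(vals) else any(vals)
  }
  out
}

# Direct O(N^2) DFT: F[k] = sum_j v[j] exp(-2*pi*1i*(j-1)*(k-1)/N).
direct_dft <- function(v) {
  n <- length(v)
  vapply(seq_len(n), function(k) {
    sum(v * exp(-2i * pi * (seq_len(n) - 1) * (k - 1) / n))
  }, complex(1))
}

# Monte-Carlo walker oracle: per-start first-arrival frequencies at object
# seeds, simulating `n_walks` independent discrete walks per unmarked
# pixel (step to neighbour j with probability w_ij / d_i) by multinomial
# count propagation.
mc_walker_oracle <- function(g, seeds, n_walks = 2e5) {
  n <- g$n
  W <- matrix(0, n, n)
  for (k in seq_len(nrow(g$edges))) {
    i <- g$edges$i[k]; j <- g$edges$j[k]; w <- g$edges$w[k]
    W[i, j] <- W[i, j] + w
    W[j, i] <- W[j, i] + w
  }
  P <- W / rowSums(W)
  marked <- sort(c(seeds$object, seeds$background))
  um <- setdiff(seq_len(n), marked)
  freq <- numeric(n)
  for (s in um) {
    counts <- numeric(n)
    counts[s] <- n_walks
    absorbed_obj <- 0
    repeat {
      active <- which(counts > 0)
      active <- setdiff(active, marked)
      if (length(active) == 0L) break
      newc <- numeric(n)
      for (j in active) {
        newc <- newc + as.numeric(stats::rmultinom(1, counts[j], P[j, ]))
      }
      counts[um] <- newc[um]
      absorbed_obj <- absorbed_obj + sum(newc[seeds$object])
      counts[marked] <- 0
    }
    freq[s] <- absorbed_obj / n_walks
  }
  freq[seeds$object] <- 1
  freq
}

# Analytic ellipse mask (duplicates the phantom's geometry independently).
ellipse_mask_for_test <- function(dims2, center, radii) {
  Y <- matrix(seq_len(dims2[1]), dims2[1], dims2[2])
  X <- matrix(seq_len(dims2[2]), dims2[1], dims2[2], byrow = TRUE)
  ((Y - center[1]) / radii[1])^2 + ((X - center[2]) / radii[2])^2 <= 1
}

# Small random test image with reproducible content.
random_img <- function(ny, nx, seed = 1) {
  withr::with_seed(seed, matrix(runif(ny * nx), ny, nx))
}

# A valid random two-class posterior matrix.
random_posterior <- function(n, seed = 1) {
  withr::with_seed(seed, {
    p <- runif(n, 0.001, 0.999)
    cbind(p, 1 - p)
  })
}

# Cached standard phantoms so several test files can reuse one generation.
.phantom_cache <- new.env(parent = emptyenv())
std_segmentation <- function() {
  if (is.null(.phantom_cache$seg)) {
    ph <- std_phantom()
    .phantom_cache$seg <- suppressMessages(
      segment_volume(ph$volume, 10, phantom_start_seeds(ph$truth, 10)))
  }
  .phantom_cache$seg
}
std_phantom <- function(confounder = FALSE, noise_seed = 7) {
  key <- paste0("ph_", confounder, "_", noise_seed)
  if (is.null(.phantom_cache[[key]])) {
    spec <- phantom_spec(confounder = if (confounder) list() else NULL,
                         noise_seed = noise_seed)
    .phantom_cache[[key]] <- generate_phantom(spec)
  }
  .phantom_cache[[key]]
}
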