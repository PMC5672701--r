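test_that("a filled 3x3 square traces to its 8-pixel boundary ring", {
  m <- matrix(FALSE, 5, 5); m[2:4, 2:4] <- TRUE
  cont <- trace_boundary(m)
  expect_length(cont, 1)
  pts <- cont[[1]]
  expect_equal(nrow(pts), 8)
  ring <- m; ring[3, 3] <- FALSE
  expect_setequal(paste(pts[, 1], pts[, 2]),
                  paste(which(ring, arr.ind = TRUE)[, 1],
                        which(ring, arr.ind = TRUE)[, 2]))
})

test_that("each connected component yields one contour of mask-boundary pixels", {
  m <- matrix(FALSE, 20, 20)
  m[3:8, 3:8] <- TRUE
  m[12:18, 11:17] <- TRUE
  cont <- trace_boundary(m)
  expect_length(cont, 2)
  blob <- mask_dilate(withr::with_seed(83, matrix(runif(144) > 0.85, 12, 12)), 2)
  for (pts in trace_boundary(blob)) {
    for (r in seq_len(nrow(pts))) {
      y <- pts[r, 1]; x <- pts[r, 2]
      expect_true(blob[y, x])
      nb <- expand.grid(y = y + (-1:1), x = x + (-1:1))
      nb <- nb[nb$y >= 1 & nb$y <= 12 & nb$x >= 1 & nb$x <= 12, ]
      on_frame <- y == 1 || y == 12 || x == 1 || x == 12
      expect_true(on_frame || any(!blob[cbind(nb$y, nb$x)]))
    }
  }
})

test_that("band-limited contours are fixed points of the smoother", {
  t <- seq(0, 2 * pi, length.out = 129)[-129]
  ell <- cbind(y = 30 + 10 * sin(t), x = 40 + 20 * cos(t))
  sm <- fourier_smooth(ell, keep = 15)
  expect_lt(max(abs(sm - ell)), 1e-6)
})

test_that("keeping the whole band reconstructs the contour exactly", {
  withr::with_seed(89, {
    pts <- cbind(y = cumsum(rnorm(11)), x = cumsum(rnorm(11)))
  })
  # keep >= N/2 spans the full spectrum: the contour must come back intact
  expect_warning(out <- fourier_smooth(pts, keep = nrow(pts)), "too few")
  expect_equal(out, pts)
  # a signal whose energy lies entirely in the retained band is also intact
  t <- seq(0, 2 * pi, length.out = 33)[-33]
  band <- cbind(y = 3 * cos(2 * t) + sin(3 * t), x = cos(t))
  expect_equal(fourier_smooth(band, keep = 5), band, tolerance = 1e-9)
})

test_that("retained spectrum matches a direct O(N^2) DFT and Parseval holds", {
  n <- 128
  t <- seq_len(n)
  sq_y <- c(rep(1, 32), 1:32, rep(33, 32), 33:2)      # 128-point square
  sq_x <- c(1:32, rep(33, 32), 33:2, rep(1, 32))
  cont <- cbind(y = sq_y, x = sq_x)
  keep <- 15
  sm <- fourier_smooth(cont, keep = keep)
  for (c in 1:2) {
    Fd <- direct_dft(cont[, c])
    expect_equal(as.complex(fft(cont[, c])), Fd, tolerance = 1e-8)
    sel <- c(seq_len(keep), n - seq_len(keep - 1) + 1)
    # output spectrum: retained coefficients preserved, the rest exactly 0
    Fs <- direct_dft(sm[, c])
    expect_equal(Fs[sel], Fd[sel], tolerance = 1e-6)
    expect_lt(max(Mod(Fs[-sel])), 1e-8)
    # Parseval: retained-coefficient energy equals total output energy
    expect_equal(sum(Mod(Fd[sel])^2) / n, sum(sm[, c]^2), tolerance = 1e-8)
  }
})

test_that("smoothing is idempotent and preserves the centroid", {
  withr::with_seed(97, {
    t <- seq(0, 2 * pi, length.out = 101)[-101]
    r <- 15 + 3 * sin(5 * t) + rnorm(100, 0, 0.5)
    cont <- cbind(y = 25 + r * sin(t), x = 25 + r * cos(t))
  })
  s1 <- fourier_smooth(cont, keep = 15)
  s2 <- fourier_smooth(s1, keep = 15)
  expect_lt(max(abs(s2 - s1)), 1e-9)
  expect_equal(colMeans(s1), colMeans(cont), tolerance = 1e-9)
})

test_that("rasterization fills rectangles and clips off-grid contours", {
  rect <- cbind(y = c(3, 3, 8, 8), x = c(4, 10, 10, 4))
  m <- rasterize_contour(rect, c(12, 12))
  expect_equal(sum(m), 6 * 7)
  expect_true(all(m[3:8, 4:10]))
  off <- cbind(y = c(-3, -3, 5, 5), x = c(2, 6, 6, 2))
  expect_silent(mo <- rasterize_contour(off, c(8, 8)))
  expect_true(all(which(mo, arr.ind = TRUE)[, 1] >= 1))
  expect_warning(md <- rasterize_contour(cbind(y = c(1, 2, 3), x = c(1, 2, 3)),
                                         c(5, 5)), "degenerate")
  expect_false(any(md))
})

test_that("trace-then-rasterize round-trips a convex blob", {
  m <- ellipse_mask_for_test(c(40, 40), c(20, 19), c(14, 11))
  cont <- trace_boundary(m)[[1]]
  back <- rasterize_contour(cont, dim(m))
  expect_gte(dice(m, back), 99)
})

test_that("mask smoothing removes jagged high-frequency boundary noise", {
  m <- ellipse_mask_for_test(c(48, 48), c(24, 24), c(15, 12))
  rough <- m
  withr::with_seed(101, {
    bnd <- trace_boundary(m)[[1]]
    jig <- bnd[sample(nrow(bnd), 15), ]
    rough[cbind(pmin(48, jig[, 1] + 1), jig[, 2])] <- TRUE
  })
  sm <- smooth_mask(rough, keep = 15)
  expect_gte(dice(m, sm), 97)
  # hole filling: an interior hole disappears
  holed <- m; holed[24, 24] <- FALSE
  expect_true(smooth_mask(holed, keep = 15)[24, 24])
})
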