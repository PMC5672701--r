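test_that("uniform path has the electrical-network closed-form solution", {
  img <- matrix(0, 1, 5)
  g <- build_lattice_graph(img)
  lap <- build_laplacian(g, seed_set(object = 1, background = 5))
  pf <- solve_classical_rw(lap)
  expect_equal(pf$probs[, "object"], c(1, 0.75, 0.5, 0.25, 0),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(rowSums(pf$probs), rep(1, 5), ignore_attr = TRUE)
})

test_that("marked pixels carry their label probability exactly", {
  img <- random_img(4, 4, seed = 5)
  g <- build_lattice_graph(img)
  lap <- build_laplacian(g, seed_set(object = c(1, 7), background = 16))
  pf <- solve_classical_rw(lap)
  expect_identical(unname(pf$probs[c(1, 7), "object"]), c(1, 1))
  expect_identical(unname(pf$probs[16, "object"]), 0)
})

test_that("classical RW matches the absorbing-chain oracle on varied grids", {
  sizes <- list(c(2, 3), c(2, 5), c(3, 3), c(1, 8), c(5, 4), c(8, 8))
  for (k in seq_along(sizes)) {
    d <- sizes[[k]]
    img <- random_img(d[1], d[2], seed = 100 + k)
    g <- build_lattice_graph(img, beta_weight = 90)
    seeds <- withr::with_seed(200 + k, {
      pick <- sample(g$n, 4)
      seed_set(object = pick[1:2], background = pick[3:4])
    })
    lap <- build_laplacian(g, seeds)
    pf <- solve_classical_rw(lap)
    oracle <- absorbing_chain_oracle(g, seeds)
    expect_equal(pf$probs[, "object"], oracle, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("unmarked probabilities obey the maximum principle", {
  img <- random_img(6, 6, seed = 8)
  g <- build_lattice_graph(img)
  lap <- build_laplacian(g, seed_set(object = c(1, 2), background = c(35, 36)))
  pf <- solve_classical_rw(lap)
  x <- pf$probs[lap$unmarked, "object"]
  expect_true(all(x > 0 & x < 1))
})

test_that("Bayes RW with gamma = 0 reproduces the classical solution", {
  img <- random_img(5, 5, seed = 13)
  g <- build_lattice_graph(img)
  seeds <- seed_set(object = c(3, 13), background = c(20, 25))
  lap <- build_laplacian(g, seeds)
  post <- random_posterior(g$n, seed = 31)
  pf0 <- solve_bayes_rw(lap, post, gamma = 0)
  pfc <- solve_classical_rw(lap)
  expect_equal(pf0$probs, pfc$probs, tolerance = 1e-8)
})

test_that("seedless Bayes RW approaches the posterior in the large-gamma limit", {
  img <- random_img(5, 5, seed = 17)
  g <- build_lattice_graph(img)
  lap <- build_laplacian(g, seed_set(), allow_empty = TRUE)
  post <- random_posterior(g$n, seed = 19)
  pf <- solve_bayes_rw(lap, post, gamma = 1e6)
  expect_lt(max(abs(pf$probs - post)), 1e-4)
})

test_that("label probabilities sum to one for all gamma", {
  img <- random_img(6, 6, seed = 23)
  g <- build_lattice_graph(img)
  seeds <- seed_set(object = c(1, 22), background = c(18, 36))
  lap <- build_laplacian(g, seeds)
  post <- random_posterior(g$n, seed = 29)
  for (gamma in c(0.01, 0.1, 1, 10, 100)) {
    pf <- solve_bayes_rw(lap, post, gamma = gamma)
    expect_lt(max(abs(rowSums(pf$probs) - 1)), 1e-6)
  }
})

test_that("the solution moves monotonically toward the prior as gamma grows", {
  img <- random_img(6, 6, seed = 37)
  g <- build_lattice_graph(img)
  seeds <- seed_set(object = 15, background = 36)
  lap <- build_laplacian(g, seeds)
  post <- random_posterior(g$n, seed = 41)
  dev <- vapply(c(0.01, 0.1, 1, 10, 100), function(gamma) {
    pf <- solve_bayes_rw(lap, post, gamma = gamma)
    max(abs(pf$probs[lap$unmarked, 1] - post[lap$unmarked, 1]))
  }, numeric(1))
  expect_true(all(diff(dev) <= 1e-9))
})

test_that("Bayes RW agrees with a dense direct solve of the full system", {
  img <- random_img(6, 6, seed = 43)
  g <- build_lattice_graph(img, beta_weight = 90)
  seeds <- withr::with_seed(47, {
    pick <- sample(g$n, 4)
    seed_set(object = pick[1:2], background = pick[3:4])
  })
  lap <- build_laplacian(g, seeds)
  post <- random_posterior(g$n, seed = 53)
  gamma <- 0.01
  pf <- solve_bayes_rw(lap, post, gamma = gamma)

  Ld <- dense_laplacian_oracle(img, beta = 90)
  um <- lap$unmarked; mk <- lap$marked
  A <- Ld[um, um] + gamma * diag(rowSums(post)[um])
  for (s in 1:2) {
    own <- if (s == 1) seeds$object else seeds$background
    xM <- as.numeric(mk %in% own)
    rhs <- gamma * post[um, s] - t(Ld[mk, um]) %*% xM
    expect_equal(pf$probs[um, s], drop(solve(A, rhs)), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("invalid solver inputs are rejected", {
  img <- random_img(3, 3)
  g <- build_lattice_graph(img)
  lap <- build_laplacian(g, seed_set(object = 1, background = 9))
  post <- random_posterior(9)
  expect_error(solve_bayes_rw(lap, post, gamma = -1), "nonnegative")
  lap0 <- build_laplacian(g, seed_set(), allow_empty = TRUE)
  expect_error(solve_bayes_rw(lap0, post, gamma = 0), "singular")
  expect_error(solve_classical_rw(build_laplacian(g, seed_set(object = 1))),
               "nonempty")
})

test_that("thresholding assigns ties to the object label and recounts match", {
  img <- random_img(4, 5, seed = 59)
  g <- build_lattice_graph(img)
  lap <- build_laplacian(g, seed_set(object = 1, background = 20))
  pf <- solve_classical_rw(lap)
  pf$probs[3, ] <- c(0.5, 0.5)     # forced tie
  mask <- labels_from_probabilities(pf)
  expect_true(mask[3])
  expect_true(mask[1]); expect_false(mask[20])
  expect_equal(sum(mask), sum(pf$probs[, 1] >= 0.5))
})
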