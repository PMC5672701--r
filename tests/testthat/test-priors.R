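test_that("Gaussian fits use the population variance convention with a floor", {
  g1 <- fit_gaussian(c(5, 5, 5))
  expect_equal(g1$mu, 5)
  expect_equal(g1$sigma2, 1e-4)          # degenerate constant region
  g2 <- fit_gaussian(c(1, 2, 3))
  expect_equal(g2$mu, 2)
  expect_equal(g2$sigma2, 2 / 3)
  expect_error(fit_gaussian(c(1)), "insufficient")
})

test_that("Gaussian parameters are recovered from simulated samples", {
  x <- withr::with_seed(61, rnorm(1e4, 100, 15))
  gm <- fit_gaussian(x)
  expect_lt(abs(gm$mu - 100), 1)
  expect_lt(abs(sqrt(gm$sigma2) - 15), 1)
})

test_that("likelihood maps match pointwise density evaluation and normalise", {
  img <- random_img(6, 6, seed = 67) * 100
  gm <- gaussian_model(c(60, 70, 80), c(20, 25, 30))
  lk <- likelihood_map(img, gm)
  d1 <- dnorm(img, gm$object$mu, sqrt(gm$object$sigma2))
  d2 <- dnorm(img, gm$background$mu, sqrt(gm$background$sigma2))
  expect_equal(lk$object, d1 / (d1 + d2), tolerance = 1e-12)
  expect_equal(lk$object + lk$background, matrix(1, 6, 6), tolerance = 1e-12)
  # bounds are closed at double precision (one density can underflow
  # relative to the other)
  expect_true(all(lk$object >= 0 & lk$object <= 1))
})

test_that("likelihood map favours the nearer class mean and is symmetric", {
  gm <- gaussian_model(c(99, 100, 101), c(49, 50, 51))
  img <- matrix(c(gm$object$mu, 75), 1, 2)  # at mu_1, and equidistant
  lk <- likelihood_map(img, gm)
  expect_gt(lk$object[1, 1], 0.5)
  expect_equal(lk$object[1, 2], 0.5, tolerance = 1e-9)
  # exchanging the classes swaps the maps
  gm_sw <- gaussian_model(c(49, 50, 51), c(99, 100, 101))
  lk_sw <- likelihood_map(img, gm_sw)
  expect_equal(lk_sw$object, lk$background, tolerance = 1e-12)
})

test_that("candidate thresholding keeps the boundary value and recounts match", {
  lk <- structure(list(object = matrix(c(0.9, 0.5, 0.49, 0.1), 2, 2),
                       background = matrix(0.5, 2, 2), dims = c(2L, 2L)),
                  class = "rw_likelihood")
  cand <- candidate_pixels(lk)
  expect_identical(cand$mask, matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  expect_equal(cand$likelihood$object[1, 2], 0)      # zeroed below threshold
  expect_equal(cand$likelihood$background, lk$background)  # passed through
  img <- random_img(8, 8, seed = 71)
  lk2 <- likelihood_map(img, gaussian_model(c(0.6, 0.7), c(0.2, 0.3)))
  cand2 <- candidate_pixels(lk2)
  expect_equal(sum(cand2$mask), sum(lk2$object >= 0.5))
})

test_that("all-object likelihood gives a full candidate mask", {
  lk <- structure(list(object = matrix(0.9, 3, 3),
                       background = matrix(0.1, 3, 3), dims = c(3L, 3L)),
                  class = "rw_likelihood")
  expect_true(all(candidate_pixels(lk)$mask))
})

test_that("shape prior support follows brute-force dilation and sums to one", {
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  sp <- shape_prior(m, radius = 3)
  expect_identical(sp$mask, brute_morph(m, 3, "dilate"))
  expect_equal(sp$p_object + sp$p_background, matrix(1, 9, 9))
  expect_equal(unique(as.numeric(sp$p_object)), c(0.01, 0.99))
  # radius 0: support equals the previous mask exactly
  sp0 <- shape_prior(m, radius = 0)
  expect_identical(sp0$mask, m)
  expect_error(shape_prior(matrix(FALSE, 4, 4)), "empty")
})

test_that("Bayes posterior equals the likelihood-prior quotient pointwise", {
  img <- random_img(7, 7, seed = 73) * 50
  gm <- gaussian_model(c(30, 35, 40), c(5, 10, 15))
  lk <- likelihood_map(img, gm)
  m <- matrix(FALSE, 7, 7); m[3:5, 3:5] <- TRUE
  sp <- shape_prior(m, radius = 1)
  post <- bayes_posterior(lk, sp)
  num1 <- lk$object * sp$p_object
  num2 <- lk$background * sp$p_background
  expect_equal(post$object, num1 / (num1 + num2), tolerance = 1e-12)
  expect_equal(post$object + post$background, matrix(1, 7, 7),
               tolerance = 1e-12)
  # uniform prior: posterior reduces to the normalised likelihood
  post_u <- bayes_posterior(lk, NULL)
  expect_equal(post_u$object, lk$object, tolerance = 1e-12)
})

test_that("outside the shape support the posterior is prior-dominated", {
  lk <- structure(list(object = matrix(0.9, 5, 5),
                       background = matrix(0.1, 5, 5), dims = c(5L, 5L)),
                  class = "rw_likelihood")
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  sp <- shape_prior(m, radius = 0, eps = 0.01)
  post <- bayes_posterior(lk, sp)
  expect_lt(post$object[1, 1], 0.5)    # bright pixel, but outside the prior
  expect_gt(post$object[3, 3], 0.99)
})

test_that("zero posterior denominators fall back to one half with a warning", {
  lk <- structure(list(object = matrix(c(0, 1), 1, 2),
                       background = matrix(c(0, 0), 1, 2), dims = c(1L, 2L)),
                  class = "rw_likelihood")
  m <- matrix(c(TRUE, TRUE), 1, 2)
  sp <- shape_prior(m, radius = 0)
  expect_warning(post <- bayes_posterior(lk, sp), "zero posterior")
  expect_equal(post$object[1, 1], 0.5)
})

test_that("well-separated classes give near-complete candidate recovery", {
  ph <- std_phantom()
  sl <- 10
  img <- ph$volume[, , sl]
  truth <- ph$truth[, , sl]
  gm <- gaussian_model(img[truth], img[!truth])
  cand <- candidate_pixels(likelihood_map(img, gm))
  expect_gte(sum(cand$mask & truth) / sum(truth), 0.99)
})
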