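test_that("EM recovers the generating parameters of a clean phantom", {
  ph <- clean_phantom(shape = 32, seed = 30)
  fit <- fit_gmm(ph$volume)
  expect_equal(fit$params$mu, c(0.2, 0.5, 0.8), tolerance = 0.01)
  fracs <- tabulate(ph$labels$labels, 3) / sum(ph$volume$mask)
  expect_true(all(abs(fit$params$pi - fracs) < 0.05))
  expect_true(all(diff(fit$params$mu) > 0))
  expect_true(fit$report$converged)
})

test_that("K = 1 EM reduces to the closed-form maximum-likelihood fit", {
  v <- with_test_seed(4, rnorm(5000, 0.4, 0.07))
  fit <- fit_gmm(vec_volume(v), K = 1)
  expect_equal(fit$params$mu, mean(v), tolerance = 1e-6)
  expect_equal(fit$params$var, mean((v - mean(v))^2), tolerance = 1e-6)
  expect_equal(fit$params$pi, 1)
})

test_that("the fitted mixture density is a proper density and the EM trace is monotone", {
  ph <- clean_phantom(shape = 24, seed = 31)
  fit <- fit_gmm(ph$volume)
  p <- fit$params
  mixture <- function(x) {
    rowSums(vapply(1:p$K, function(k) p$pi[k] * dnorm(x, p$mu[k], sqrt(p$var[k])),
                   numeric(length(x))))
  }
  expect_equal(integrate(mixture, -Inf, Inf)$value, 1, tolerance = 1e-6)
  expect_true(all(diff(fit$report$ll_trace) >= -1e-8))
})

test_that("kmeans initialization reaches the same well-separated solution", {
  ph <- clean_phantom(shape = 24, seed = 32)
  fq <- fit_gmm(ph$volume, init = "quantile")
  fk <- fit_gmm(ph$volume, init = "kmeans", seed = 99)
  expect_equal(fk$params$mu, fq$params$mu, tolerance = 1e-3)
})

test_that("EM agrees with an independent mixture fitter on the same sample", {
  v <- with_test_seed(6, c(rnorm(3000, 0.2, 0.02), rnorm(3000, 0.5, 0.02),
                           rnorm(3000, 0.8, 0.02)))
  fit <- fit_gmm(vec_volume(v), K = 3)
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller's scope
  mc <- mclust::Mclust(v, G = 3, modelNames = "V", verbose = FALSE)
  expect_equal(fit$params$mu, sort(as.numeric(mc$parameters$mean)), tolerance = 1e-3)
})

test_that("degenerate inputs to fit_gmm are rejected", {
  expect_error(fit_gmm(vec_volume(rep(c(0.2, 0.5), 50)), K = 3), "distinct")
  expect_error(fit_gmm(vec_volume(runif(10)), K = 3), "mask too small")
})

test_that("posteriors match symmetry, dominance and a brute-force Bayes oracle", {
  p2 <- mixture_params(c(0.5, 0.5), c(0.2, 0.8), c(0.01, 0.01))
  post <- posteriors(vec_volume(0.5), p2)
  expect_equal(as.numeric(post$probs), c(0.5, 0.5))
  p2b <- mixture_params(c(0.5, 0.5), c(0.2, 0.8), c(1e-4, 1e-4))
  post_b <- posteriors(vec_volume(0.2), p2b)
  expect_equal(post_b$probs[1, 1], 1, tolerance = 1e-12)

  prm <- with_test_seed(13, mixture_params(
    pi = (function(w) w / sum(w))(runif(3, 0.2, 1)),
    mu = sort(runif(3)), var = runif(3, 1e-4, 0.02)))
  v <- with_test_seed(14, runif(100))
  post_r <- posteriors(vec_volume(v), prm)$probs
  dens <- sapply(1:3, function(k) {
    prm$pi[k] * exp(-(v - prm$mu[k])^2 / (2 * prm$var[k])) / sqrt(2 * pi * prm$var[k])
  })
  expect_lt(max(abs(post_r - dens / rowSums(dens))), 1e-10)
  expect_lt(max(abs(rowSums(post_r) - 1)), 1e-6)
})

test_that("class_map takes the argmax with low-index tie-breaking", {
  pf <- structure(list(probs = rbind(c(1, 0, 0), c(0.5, 0.5, 0), c(0.1, 0.2, 0.7)),
                       mask = array(c(TRUE, TRUE, TRUE, FALSE), c(4, 1, 1)),
                       dim = c(4L, 1L, 1L), labels = c("CSF", "GM", "WM")),
                  class = "posterior_field")
  lab <- class_map(pf)
  expect_identical(as.integer(lab$labels), c(1L, 1L, 3L, 0L))
})

test_that("hard classification of a clean phantom reproduces the ground truth", {
  ph <- clean_phantom(shape = 32, seed = 33)
  fit <- fit_gmm(ph$volume)
  cmap <- class_map(posteriors(ph$volume, fit$params))
  for (k in 1:3) expect_gte(dice(cmap, ph$labels, k), 0.99)
})

test_that("dice implements the overlap formula including the empty-set convention", {
  a <- labeled_volume(array(c(1L, 1L, 0L, 0L), c(4, 1, 1)))
  b <- labeled_volume(array(c(1L, 0L, 1L, 0L), c(4, 1, 1)))
  expect_equal(dice(a, a, 1), 1)
  expect_equal(dice(a, b, 1), 0.5)
  disj <- labeled_volume(array(c(0L, 0L, 1L, 1L), c(4, 1, 1)))
  expect_equal(dice(a, disj, 1), 0)
  expect_equal(dice(a, b, 7), 1)  # class absent from both
})

test_that("mixture_params enforces its invariants and ascending-mean order", {
  expect_error(mixture_params(c(0.6, 0.6), c(0, 1), c(1, 1)), "sum to 1")
  expect_error(mixture_params(c(0.5, 0.5), c(0, 1), c(0, 1)), "> 0")
  p <- mixture_params(c(0.3, 0.7), c(0.8, 0.2), c(0.02, 0.01))
  expect_equal(p$mu, c(0.2, 0.8))
  expect_equal(p$pi, c(0.7, 0.3))
})
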