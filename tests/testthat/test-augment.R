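ref_params <- mixture_params(c(0.3, 0.4, 0.3), c(0.2, 0.5, 0.8),
                             c(0.01, 0.02, 0.015))

test_that("perturbation sampling respects the uniform support and its moments", {
  zero <- variation_ranges(rep(0, 3), rep(0, 3))
  q0 <- sample_perturbation(zero, ref_params, seed = 1)
  expect_identical(q0$q_mu, rep(0, 3))
  expect_identical(q0$q_var, rep(0, 3))

  r <- variation_ranges(c(0.06, 0, 0), c(0.001, 0, 0))
  n <- 2e4
  draws <- vapply(seq_len(n), function(i) {
    sample_perturbation(r, ref_params, seed = i)$q_mu[1]
  }, 0)
  expect_gt(min(draws), -0.06)
  expect_lt(max(draws), 0.06)
  sd_u <- 0.06 / sqrt(3)
  expect_lt(abs(mean(draws)), 3 * sd_u / sqrt(n))
  expect_lt(abs(sd(draws) - sd_u), 3 * sd_u / sqrt(2 * n))
})

test_that("perturbation sampling is deterministic given the seed", {
  r <- default_ranges()
  a <- sample_perturbation(r, ref_params, seed = 77)
  b <- sample_perturbation(r, ref_params, seed = 77)
  expect_identical(a$q_mu, b$q_mu)
  expect_identical(a$q_var, b$q_var)
  expect_false(identical(a$q_mu, sample_perturbation(r, ref_params, seed = 78)$q_mu))
})

test_that("variance offsets never push a component below the floor", {
  tiny <- mixture_params(c(0.5, 0.5), c(0.2, 0.8), c(2e-6, 0.01))
  r <- variation_ranges(c(0, 0), c(0.01, 0.01))
  for (s in 1:50) {
    q <- sample_perturbation(r, tiny, seed = s)
    expect_true(all(tiny$var + q$q_var >= 1e-6))
  }
})

test_that("perturb_params adds offsets componentwise, keeps pi and identity order", {
  q <- structure(list(q_mu = c(0.03, -0.06, 0.08), q_var = c(0, 0, 0), seed = NULL),
                 class = "perturbation_sample")
  p2 <- perturb_params(ref_params, q)
  expect_equal(p2$mu, c(0.23, 0.44, 0.88))
  expect_equal(p2$pi, ref_params$pi)
  expect_equal(p2$var, ref_params$var)
  # identity under zero perturbation
  q0 <- structure(list(q_mu = rep(0, 3), q_var = rep(0, 3), seed = NULL),
                  class = "perturbation_sample")
  expect_equal(perturb_params(ref_params, q0)[c("pi", "mu", "var")],
               ref_params[c("pi", "mu", "var")])
  # floor policy
  qneg <- structure(list(q_mu = rep(0, 3), q_var = c(-0.02, 0, 0), seed = NULL),
                    class = "perturbation_sample")
  expect_equal(perturb_params(ref_params, qneg)$var[1], 1e-6)
})

test_that("reconstruction reproduces the hand-computable special cases", {
  # no-op: new params equal old params
  ph <- clean_phantom(shape = 20, seed = 100)
  pv <- prepare_for_gmm(ph$volume)
  fit <- fit_gmm(pv)
  post <- posteriors(pv, fit$params)
  same <- reconstruct(pv, fit$params, fit$params, post)
  expect_lt(max(abs(same$data - pv$data)), 1e-9)

  # K = 1 closed form: v = 0.6, d = 1, mu' = 0.3, sigma' = 0.05 -> 0.35
  p1 <- mixture_params(1, 0.5, 0.01)
  p1b <- mixture_params(1, 0.3, 0.0025)
  v1 <- vec_volume(0.6)
  out1 <- reconstruct(v1, p1, p1b, posteriors(v1, p1))
  expect_equal(out1$data[1, 1, 1], 0.35)

  # symmetric cancellation: posteriors (0.5, 0.5), shift means inward
  p2 <- mixture_params(c(0.5, 0.5), c(0.2, 0.8), c(0.01, 0.01))
  p2b <- mixture_params(c(0.5, 0.5), c(0.3, 0.7), c(0.01, 0.01), sort = FALSE)
  v2 <- vec_volume(0.5)
  out2 <- reconstruct(v2, p2, p2b, posteriors(v2, p2))
  expect_equal(out2$data[1, 1, 1], 0.5)

  # zero variance in the original fit leaves the distance undefined
  expect_error(reconstruct(v1, structure(list(K = 1L, pi = 1, mu = 0.5, var = 0,
                                              labels = "a", component_order = 1L),
                                         class = "mixture_params"),
                           p1b, posteriors(v1, p1)), "variance")
})

test_that("vectorized remap matches the per-voxel scalar oracle", {
  prm <- with_test_seed(23, mixture_params(
    pi = (function(w) w / sum(w))(runif(3, 0.2, 1)),
    mu = sort(runif(3)), var = runif(3, 1e-3, 0.02)))
  q <- sample_perturbation(default_ranges(), prm, seed = 24)
  prm2 <- perturb_params(prm, q)
  v <- with_test_seed(25, runif(500))
  vol <- vec_volume(v)
  got <- reconstruct(vol, prm, prm2, posteriors(vol, prm))
  want <- scalar_remap_oracle(v, prm$pi, prm$mu, prm$var, prm2$mu, prm2$var)
  expect_lt(max(abs(got$data[got$mask] - want)), 1e-10)
})

test_that("pure voxels keep their Mahalanobis distance under augmentation", {
  ph <- clean_phantom(shape = 24, seed = 101)
  pv <- prepare_for_gmm(ph$volume)
  fit <- fit_gmm(pv)
  post <- posteriors(pv, fit$params)
  v <- pv$data[pv$mask]
  for (s in 1:5) {
    q <- sample_perturbation(default_ranges(), fit$params, seed = s)
    np <- perturb_params(fit$params, q)
    out <- reconstruct(pv, fit$params, np, post)
    vp <- out$data[out$mask]
    for (k in 1:3) {
      pure <- post$probs[, k] >= 1 - 1e-6
      if (!any(pure)) next
      d_old <- (v[pure] - fit$params$mu[k]) / sqrt(fit$params$var[k])
      d_new <- (vp[pure] - np$mu[k]) / sqrt(np$var[k])
      expect_lt(max(abs(d_new - d_old)), 1e-6)
    }
  }
})

test_that("augment with zero ranges reproduces the preprocessed input", {
  ph <- clean_phantom(shape = 24, seed = 102)
  aug <- augment(ph$volume, variation_ranges(rep(0, 3), rep(0, 3)),
                 seed = 5, n_variants = 2)
  for (v in aug$variants) expect_lt(max(abs(v$data - aug$input$data)), 1e-9)
})

test_that("refitting an augmented variant recovers the perturbed parameters", {
  ph <- clean_phantom(shape = 32, seed = 103)
  aug <- augment(ph$volume, default_ranges(), seed = 11)
  refit <- fit_gmm(aug$variants[[1]], K = 3)
  target <- sort(aug$new_params[[1]]$mu)
  expect_lt(max(abs(refit$params$mu - target)), 0.015)
})

test_that("augmentation is deterministic and per-variant seeds are stable", {
  ph <- clean_phantom(shape = 20, seed = 104)
  a <- augment(ph$volume, default_ranges(), seed = 9, n_variants = 5)
  b <- augment(ph$volume, default_ranges(), seed = 9, n_variants = 5)
  for (i in 1:5) expect_identical(a$variants[[i]]$data, b$variants[[i]]$data)
  expect_gt(length(unique(lapply(a$variants, function(v) v$data))), 4)
  # requesting fewer variants leaves earlier ones unchanged
  c2 <- augment(ph$volume, default_ranges(), seed = 9, n_variants = 2)
  expect_identical(c2$variants[[2]]$data, a$variants[[2]]$data)
})

test_that("with K = 1 the remap is exactly affine with slope sigma'/sigma", {
  v <- with_test_seed(31, runif(200, 0.2, 0.8))
  vol <- vec_volume(v)
  p <- mixture_params(1, 0.5, 0.01)
  p2 <- mixture_params(1, 0.42, 0.0036)
  out <- reconstruct(vol, p, p2, posteriors(vol, p))
  slope <- sqrt(0.0036 / 0.01)
  expect_equal(out$data[out$mask], 0.42 + slope * (v - 0.5), tolerance = 1e-12)
})

test_that("class structure survives default-range perturbations", {
  ph <- clean_phantom(shape = 32, seed = 105)
  pv <- prepare_for_gmm(ph$volume)
  fit <- fit_gmm(pv)
  before <- class_map(posteriors(pv, fit$params))
  for (s in 1:5) {
    q <- sample_perturbation(default_ranges(), fit$params, seed = s)
    np <- perturb_params(fit$params, q)
    out <- reconstruct(pv, fit$params, np, posteriors(pv, fit$params))
    refit <- fit_gmm(out)
    after <- class_map(posteriors(out, refit$params))
    for (k in 1:3) expect_gte(dice(before, after, k), 0.98)
  }
})

test_that("the augmentation iterator cycles, caches fits and replays streams", {
  empty <- augmenting_iterator(list(), default_ranges(), seed = 1)
  expect_null(empty$nxt())

  ph1 <- clean_phantom(shape = 20, seed = 106)
  ph2 <- clean_phantom(shape = 20, seed = 107, means = c(0.25, 0.5, 0.75))
  it <- augmenting_iterator(list(ph1$volume, ph2$volume), default_ranges(), seed = 3)
  stream <- lapply(1:10, function(i) it$nxt())
  expect_equal(it$fit_count(), 2)
  expect_equal(vapply(stream, `[[`, 0L, "source"), rep(c(1L, 2L), 5))

  it2 <- augmenting_iterator(list(ph1$volume, ph2$volume), default_ranges(), seed = 3)
  stream2 <- lapply(1:10, function(i) it2$nxt())
  for (i in 1:10) {
    expect_identical(stream2[[i]]$volume$data, stream[[i]]$volume$data)
  }
})
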