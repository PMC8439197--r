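# All fixtures are built in code; nothing is read from disk.

# Well-separated three-class phantom, noiseless corruption-wise.
clean_phantom <- function(shape = 32, seed = 1, means = c(0.2, 0.5, 0.8),
                          stds = c(0.02, 0.02, 0.02), ...) {
  generate_phantom(phantom_spec(grid_shape = rep(shape, 3L),
                                class_means = means, class_stds = stds,
                                seed = seed, ...))
}

# Wrap a numeric vector into a fully-masked 3-D volume (n x 1 x 1).
vec_volume <- function(values) {
  intensity_volume(array(values, c(length(values), 1L, 1L)),
                   mask = array(TRUE, c(length(values), 1L, 1L)))
}

# Collection of phantoms whose true class means are dispersed between
# images: m_k + delta_k, delta_k ~ N(0, dispersion^2), per image.
dispersed_phantoms <- function(n, dispersion = 0.05, shape = 32, seed = 100,
                               base_means = c(0.2, 0.5, 0.8), stds = rep(0.02, 3)) {
  vols <- vector("list", n)
  true_mu <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    m <- with_test_seed(seed + i, sort(stats::rnorm(3, base_means, dispersion)))
    true_mu[i, ] <- m
    vols[[i]] <- generate_phantom(phantom_spec(grid_shape = rep(shape, 3L),
                                               class_means = m, class_stds = stds,
                                               seed = seed * 1000L + i))$volume
  }
  list(volumes = vols, true_mu = true_mu)
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Scalar-loop oracle for the posterior + distance-preserving remap: plain
# per-voxel arithmetic, independent of the vectorized implementation.
scalar_remap_oracle <- function(v, pi, mu, var, mu2, var2) {
  K <- length(pi)
  out <- numeric(length(v))
  for (n in seq_along(v)) {
    dens <- numeric(K)
    for (k in seq_len(K)) {
      dens[k] <- pi[k] * exp(-(v[n] - mu[k])^2 / (2 * var[k])) / sqrt(2 * pi_const * var[k])
    }
    post <- dens / sum(dens)
    vn <- 0
    for (k in seq_len(K)) {
      d <- (v[n] - mu[k]) / sqrt(var[k])
      vn <- vn + post[k] * (mu2[k] + d * sqrt(var2[k]))
    }
    out[n] <- vn
  }
  out
}
pi_const <- base::pi
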