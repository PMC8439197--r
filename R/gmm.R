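#' Mixture parameters
#'
#' Container for the parameters of a K-component univariate Gaussian
#' mixture over tissue intensities: mixing coefficients `pi`, component
#' means `mu` and variances `var`. Components are stored in ascending-mean
#' order; for K = 3 they are labeled CSF, GM, WM following the T1w
#' convention that CSF is darkest and WM brightest.
#'
#' @param pi mixing coefficients (> 0, summing to 1).
#' @param mu component means, normalized intensity units.
#' @param var component variances (> 0).
#' @param labels optional component labels; default CSF/GM/WM when K = 3.
#' @param sort sort components by ascending mean (default). Perturbed
#'   parameter sets keep their component identity and may be constructed
#'   unsorted.
#' @return An object of class `mixture_params`.
#' @export
mixture_params <- function(pi, mu, var, labels = NULL, sort = TRUE) {
  K <- length(mu)
  if (length(pi) != K || length(var) != K) stop_gmmaug("pi, mu, var lengths differ")
  if (any(!is.finite(c(pi, mu, var)))) stop_gmmaug("non-finite mixture parameters")
  if (abs(sum(pi) - 1) > 1e-9) stop_gmmaug("mixing coefficients must sum to 1")
  if (any(pi <= 0)) stop_gmmaug("all mixing coefficients must be > 0")
  if (any(var <= 0)) stop_gmmaug("all variances must be > 0")
  ord <- if (sort) order(mu) else seq_len(K)
  if (is.null(labels)) {
    labels <- if (K == 3L) c("CSF", "GM", "WM") else paste0("comp", seq_len(K))
  } else {
    labels <- labels[ord]
  }
  structure(list(K = K, pi = as.numeric(pi[ord]), mu = as.numeric(mu[ord]),
                 var = as.numeric(var[ord]), labels = labels,
                 component_order = ord),
            class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, digits = 4, ...) {
  cat(sprintf("<mixture_params> K = %d\n", x$K))
  m <- rbind(pi = x$pi, mu = x$mu, var = x$var, sigma = sqrt(x$var))
  colnames(m) <- x$labels
  print(round(m, digits))
  invisible(x)
}

# log pi_k + log N(v | mu_k, var_k) for all voxels x components
log_weighted_dens <- function(v, params) {
  K <- params$K
  ld <- matrix(0, length(v), K)
  for (k in seq_len(K)) {
    ld[, k] <- log(params$pi[k]) +
      stats::dnorm(v, params$mu[k], sqrt(params$var[k]), log = TRUE)
  }
  ld
}

#' Fit a Gaussian mixture to masked voxel intensities
#'
#' Maximum-likelihood EM fit of a K-component univariate Gaussian mixture
#' to the masked intensities of a volume prepared by [prepare_for_gmm()].
#' Initialization is deterministic by default: component k's mean starts at
#' the (2k-1)/(2K) quantile of the masked intensities, all variances at the
#' total variance, and mixing coefficients uniform, so repeated fits of the
#' same volume are identical without any seed. A seeded k-means
#' initialization is available for parity with common library defaults.
#' Convergence is declared when the relative change in mean log-likelihood
#' stays below `tol` for three consecutive iterations: EM for closely
#' spaced components can cross a near-flat ridge where the per-iteration
#' change transiently dips before accelerating again, and a single-shot
#' threshold stops there with the two brightest classes still merged. A
#' variance floor guards against component collapse. Components are
#' returned sorted by ascending mean.
#'
#' @param vol an [intensity_volume()] with masked values in `[0, 1]`.
#' @param K number of components (default 3: CSF, GM, WM).
#' @param init `"quantile"` (deterministic, default) or `"kmeans"`.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param seed seed for `init = "kmeans"`; ignored otherwise.
#' @param var_floor lower bound applied to component variances.
#' @return A list with elements `params` (a [mixture_params()]) and
#'   `report`: `log_likelihood` (final mean log-likelihood per voxel),
#'   `n_iterations`, `converged`, and the per-iteration `ll_trace`.
#' @export
fit_gmm <- function(vol, K = 3L, init = c("quantile", "kmeans"),
                    tol = 1e-6, max_iter = 500L, seed = NULL,
                    var_floor = 1e-6) {
  stopifnot(inherits(vol, "intensity_volume"))
  init <- match.arg(init)
  v <- vol$data[vol$mask]
  n <- length(v)
  if (any(!is.finite(v))) stop_gmmaug("non-finite intensities within the mask")
  if (n < 10L * K) stop_gmmaug("mask too small: %d voxels for K = %d (need >= %d)", n, K, 10L * K)
  if (length(unique(v)) < K) stop_gmmaug("fewer distinct intensities than components")

  if (init == "quantile") {
    mu <- stats::quantile(v, (2 * seq_len(K) - 1) / (2 * K), names = FALSE, type = 7)
    var <- rep(max(stats::var(v), var_floor), K)
    pi <- rep(1 / K, K)
  } else {
    km <- with_preserved_seed(seed %||% 1L,
                              stats::kmeans(v, centers = K, nstart = 3L))
    ord <- order(km$centers)
    mu <- as.numeric(km$centers)[ord]
    cl <- match(km$cluster, ord)
    var <- pmax(tapply(v, cl, stats::var), var_floor)
    var[is.na(var)] <- var_floor
    pi <- tabulate(cl, K) / n
    pi <- pmax(pi, 1e-8); pi <- pi / sum(pi)
  }

  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  stable <- 0L
  iter <- 0L
  resp <- NULL
  params <- mixture_params(pi, mu, var, sort = FALSE)
  while (iter < max_iter) {
    iter <- iter + 1L
    ld <- log_weighted_dens(v, params)
    lse <- row_logsumexp(ld)
    ll <- mean(lse)
    ll_trace <- c(ll_trace, ll)
    resp <- exp(ld - lse)
    if (is.finite(ll_prev) && abs(ll - ll_prev) <= tol * max(abs(ll_prev), 1)) {
      stable <- stable + 1L
      if (stable >= 3L) {
        converged <- TRUE
        break
      }
    } else {
      stable <- 0L
    }
    ll_prev <- ll
    nk <- colSums(resp)
    pi <- nk / n
    mu <- colSums(resp * v) / nk
    var <- vapply(seq_len(K), function(k) sum(resp[, k] * (v - mu[k])^2) / nk[k], 0)
    var <- pmax(var, var_floor)
    params <- mixture_params(pi, mu, var, sort = FALSE)
  }
  params <- mixture_params(params$pi, params$mu, params$var, sort = TRUE)
  list(params = params,
       report = list(log_likelihood = ll_trace[length(ll_trace)],
                     n_iterations = iter, converged = converged,
                     ll_trace = ll_trace))
}

#' Per-voxel class posterior probabilities
#'
#' Bayes posteriors p(C = k | v) for every masked voxel: the
#' posterior-weighted component densities normalized across components,
#' computed in log space with log-sum-exp so extreme likelihood ratios
#' never underflow.
#'
#' @param vol an [intensity_volume()].
#' @param params a [mixture_params()].
#' @return An object of class `posterior_field`: list with `probs` (matrix,
#'   masked voxels x K, rows summing to 1), `mask`, `dim` and component
#'   `labels`.
#' @export
posteriors <- function(vol, params) {
  stopifnot(inherits(vol, "intensity_volume"), inherits(params, "mixture_params"))
  v <- vol$data[vol$mask]
  if (any(!is.finite(v))) stop_gmmaug("non-finite intensities within the mask")
  ld <- log_weighted_dens(v, params)
  probs <- exp(ld - row_logsumexp(ld))
  structure(list(probs = probs, mask = vol$mask, dim = dim(vol$data),
                 labels = params$labels),
            class = "posterior_field")
}

#' @export
print.posterior_field <- function(x, ...) {
  cat(sprintf("<posterior_field> %d voxels x %d components (%s)\n",
              nrow(x$probs), ncol(x$probs), paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Hard class assignment from posteriors
#'
#' Maps each masked voxel to the component with the largest posterior
#' probability; ties break toward the lowest component index. Background
#' voxels keep label 0.
#'
#' @param post a [posteriors()] result.
#' @return A [labeled_volume()].
#' @export
class_map <- function(post) {
  stopifnot(inherits(post, "posterior_field"))
  lab <- array(0L, post$dim)
  lab[post$mask] <- max.col(post$probs, ties.method = "first")
  labeled_volume(lab)
}

#' Dice overlap for one label class
#'
#' `2|A n B| / (|A| + |B|)` between the voxel sets carrying label `k` in
#' two label volumes; returns 1 when both sets are empty.
#'
#' @param a,b [labeled_volume()]s of identical shape.
#' @param k the label to compare.
#' @return Dice score in `[0, 1]`.
#' @export
dice <- function(a, b, k) {
  stopifnot(inherits(a, "labeled_volume"), inherits(b, "labeled_volume"))
  if (!identical(dim(a), dim(b))) stop_gmmaug("label volumes have different shapes")
  A <- a$labels == k
  B <- b$labels == k
  sa <- sum(A); sb <- sum(B)
  if (sa + sb == 0L) return(1)
  2 * sum(A & B) / (sa + sb)
}
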