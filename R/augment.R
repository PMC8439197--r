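#' Sample a perturbation of the mixture parameters
#'
#' Draws one additive offset per component for the means and the variances,
#' uniformly from `U(-s_mu[k], s_mu[k])` and `U(-s_var[k], s_var[k])`. A
#' variance offset that would push a component variance below the floor is
#' resampled (up to 100 tries) and finally clamped, so the perturbed
#' mixture is always valid. Deterministic given `seed`.
#'
#' @param ranges a [variation_ranges()].
#' @param params the fitted [mixture_params()] being perturbed (needed for
#'   the variance-floor policy).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param var_floor minimum allowed perturbed variance.
#' @return An object of class `perturbation_sample`: list with `q_mu`,
#'   `q_var` and the `seed` used.
#' @export
sample_perturbation <- function(ranges, params, seed = NULL, var_floor = 1e-6) {
  stopifnot(inherits(ranges, "variation_ranges"), inherits(params, "mixture_params"))
  K <- params$K
  if (length(ranges$s_mu) != K) stop_gmmaug("ranges and params disagree on K")
  with_preserved_seed(seed, {
    q_mu <- stats::runif(K, -ranges$s_mu, ranges$s_mu)
    q_var <- numeric(K)
    for (k in seq_len(K)) {
      q <- stats::runif(1, -ranges$s_var[k], ranges$s_var[k])
      tries <- 1L
      while (params$var[k] + q < var_floor && tries < 100L) {
        q <- stats::runif(1, -ranges$s_var[k], ranges$s_var[k])
        tries <- tries + 1L
      }
      if (params$var[k] + q < var_floor) q <- var_floor - params$var[k]
      q_var[k] <- q
    }
    structure(list(q_mu = q_mu, q_var = q_var, seed = seed),
              class = "perturbation_sample")
  })
}

#' Apply a perturbation to mixture parameters
#'
#' Componentwise update `mu' = mu + q_mu`, `var' = var + q_var` with the
#' variance floor enforced; mixing coefficients are unchanged. Component
#' identity (index) is preserved even if the perturbed means change order:
#' extreme augmentations that reorder or overlap components are
#' intentional.
#'
#' @param params a [mixture_params()].
#' @param q a [sample_perturbation()] result.
#' @param var_floor minimum allowed perturbed variance.
#' @return A [mixture_params()] in the original component order.
#' @export
perturb_params <- function(params, q, var_floor = 1e-6) {
  stopifnot(inherits(params, "mixture_params"), inherits(q, "perturbation_sample"))
  mixture_params(params$pi,
                 params$mu + q$q_mu,
                 pmax(params$var + q$q_var, var_floor),
                 labels = params$labels, sort = FALSE)
}

#' Reconstruct a contrast-altered volume
#'
#' The core intensity remapping. For every masked voxel with intensity v,
#' the signed Mahalanobis distance to each original component,
#' `d_vk = (v - mu_k) / sigma_k`, is preserved under the new parameters,
#' giving a per-component candidate `v_k' = mu_k' + d_vk * sigma_k'`; the
#' new intensity is the blend of the candidates weighted by the ORIGINAL
#' class posteriors, `v' = sum_k p(C = k | v) v_k'`. Using the original
#' posteriors is what makes zero perturbation an exact no-op and keeps
#' voxels that clearly belong to one tissue representing that tissue.
#' Background voxels are untouched. Output is not clipped by default,
#' since the blend can legitimately leave `[0, 1]`.
#'
#' @param vol the preprocessed [intensity_volume()] the posteriors were
#'   computed from.
#' @param params the original fitted [mixture_params()] (all variances must
#'   be > 0, otherwise the distance is undefined).
#' @param new_params the perturbed [mixture_params()].
#' @param post the [posteriors()] of `vol` under `params`.
#' @param clip clamp masked output to `[0, 1]`? Default `FALSE`.
#' @return An [intensity_volume()] with the same mask.
#' @export
reconstruct <- function(vol, params, new_params, post, clip = FALSE) {
  stopifnot(inherits(vol, "intensity_volume"), inherits(params, "mixture_params"),
            inherits(new_params, "mixture_params"), inherits(post, "posterior_field"))
  if (params$K != new_params$K) stop_gmmaug("params and new_params disagree on K")
  if (any(params$var <= 0)) stop_gmmaug("zero variance in original params: Mahalanobis distance undefined")
  if (!identical(dim(vol$data), post$dim)) stop_gmmaug("volume and posterior shapes differ")
  v <- vol$data[vol$mask]
  if (nrow(post$probs) != length(v)) stop_gmmaug("posterior field does not match the volume mask")
  sig <- sqrt(params$var)
  sig_new <- sqrt(new_params$var)
  out_v <- numeric(length(v))
  for (k in seq_len(params$K)) {
    d <- (v - params$mu[k]) / sig[k]
    out_v <- out_v + post$probs[, k] * (new_params$mu[k] + d * sig_new[k])
  }
  if (clip) out_v <- pmin(pmax(out_v, 0), 1)
  data <- array(0, dim(vol$data))
  data[vol$mask] <- out_v
  intensity_volume(data, vol$mask)
}

#' Generate contrast-augmented variants of a volume
#'
#' Full pipeline: normalize with [prepare_for_gmm()], fit the mixture once,
#' compute posteriors once, then for each variant sample a perturbation,
#' update the parameters and [reconstruct()]. Each variant uses a sub-seed
#' derived from `seed` and the variant counter, so variant i is the same
#' regardless of how many variants are requested.
#'
#' @param vol an [intensity_volume()], assumed skull-stripped and
#'   bias-field corrected (the mixture misreads tissue intensities
#'   otherwise).
#' @param ranges a [variation_ranges()]; defaults to the published
#'   calibration [default_ranges()].
#' @param K number of mixture components.
#' @param seed master integer seed.
#' @param n_variants number of augmented variants to generate.
#' @param clip clamp outputs to `[0, 1]`?
#' @param preprocessed set `TRUE` if `vol` has already been through
#'   [prepare_for_gmm()].
#' @return An object of class `gmm_augmentation`: list with `variants`
#'   (list of [intensity_volume()]s), `perturbations`, `new_params`
#'   (per-variant), plus the shared `params`, `report`, `input`
#'   (preprocessed volume), `ranges` and `seed`.
#' @export
augment <- function(vol, ranges = default_ranges(), K = 3L, seed = 1L,
                    n_variants = 1L, clip = FALSE, preprocessed = FALSE) {
  stopifnot(inherits(vol, "intensity_volume"), inherits(ranges, "variation_ranges"))
  pvol <- if (preprocessed) vol else prepare_for_gmm(vol)
  fit <- fit_gmm(pvol, K = K)
  post <- posteriors(pvol, fit$params)
  variants <- vector("list", n_variants)
  perts <- vector("list", n_variants)
  new_params <- vector("list", n_variants)
  for (i in seq_len(n_variants)) {
    q <- sample_perturbation(ranges, fit$params, seed = derive_seed(seed, i))
    np <- perturb_params(fit$params, q)
    variants[[i]] <- reconstruct(pvol, fit$params, np, post, clip = clip)
    perts[[i]] <- q
    new_params[[i]] <- np
  }
  structure(list(variants = variants, perturbations = perts,
                 new_params = new_params, params = fit$params,
                 report = fit$report, input = pvol, ranges = ranges,
                 seed = as.integer(seed)),
            class = "gmm_augmentation")
}

#' @export
print.gmm_augmentation <- function(x, ...) {
  cat(sprintf("<gmm_augmentation> %d variant(s), seed %d, ranges: %s\n",
              length(x$variants), x$seed, x$ranges$provenance))
  print(x$params)
  invisible(x)
}

#' On-the-fly augmentation stream
#'
#' Builds a lazy iterator over augmented variants for a training pipeline:
#' each call to `$nxt()` yields one fresh variant, cycling through the
#' input volumes. Each volume's preprocessing, mixture fit and posteriors
#' are computed once and cached; restarting the iterator with the same seed
#' reproduces the stream element-for-element because element i's
#' perturbation seed depends only on `(seed, i)`.
#'
#' @param volumes list of [intensity_volume()]s (may be empty, giving an
#'   exhausted stream).
#' @param ranges a [variation_ranges()].
#' @param seed master integer seed.
#' @param K number of mixture components.
#' @param clip clamp outputs to `[0, 1]`?
#' @return An object of class `augment_iterator`: list with `nxt()`
#'   (returns `list(volume, source, index, perturbation)` or `NULL` when
#'   the stream is empty) and `fit_count()` (number of mixture fits
#'   performed so far, for verifying the caching contract).
#' @export
augmenting_iterator <- function(volumes, ranges = default_ranges(), seed = 1L,
                                K = 3L, clip = FALSE) {
  stopifnot(is.list(volumes), inherits(ranges, "variation_ranges"))
  env <- new.env(parent = emptyenv())
  env$i <- 0L
  env$cache <- vector("list", length(volumes))
  env$fits <- 0L
  get_fit <- function(j) {
    if (is.null(env$cache[[j]])) {
      pvol <- prepare_for_gmm(volumes[[j]])
      fit <- fit_gmm(pvol, K = K)
      env$cache[[j]] <- list(pvol = pvol, params = fit$params,
                             post = posteriors(pvol, fit$params))
      env$fits <- env$fits + 1L
    }
    env$cache[[j]]
  }
  nxt <- function() {
    if (length(volumes) == 0L) return(NULL)
    env$i <- env$i + 1L
    j <- ((env$i - 1L) %% length(volumes)) + 1L
    cc <- get_fit(j)
    q <- sample_perturbation(ranges, cc$params, seed = derive_seed(seed, env$i, 2L))
    np <- perturb_params(cc$params, q)
    list(volume = reconstruct(cc$pvol, cc$params, np, cc$post, clip = clip),
         source = j, index = env$i, perturbation = q)
  }
  structure(list(nxt = nxt, fit_count = function() env$fits),
            class = "augment_iterator")
}
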