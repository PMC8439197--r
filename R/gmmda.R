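#' Fit the tissue-intensity mixture model of a brain volume
#'
#' The front door of the package. `gmmda()` normalizes a skull-stripped
#' volume, fits the K-component Gaussian mixture over its masked
#' intensities by EM, computes the per-voxel class posteriors, and returns
#' a fitted-model object from which contrast-augmented variants can be
#' drawn with [simulate()]. The object behaves like other fitted models in
#' R: `coef()`, `logLik()`, `fitted()`, `residuals()`, `predict()`,
#' `summary()` and `plot()` all work.
#'
#' `fitted()` returns the posterior-weighted mean intensity per voxel (the
#' mixture's reconstruction of the image); `residuals()` the difference
#' between observed and fitted masked intensities. `predict()` evaluates
#' posteriors (or hard class labels) for new intensities or a new volume
#' under the fitted parameters. `simulate()` draws augmented variants, the
#' model's generative use.
#'
#' @param vol an [intensity_volume()], or a path to a NIfTI file.
#' @param K number of mixture components (default 3: CSF, GM, WM).
#' @param ranges [variation_ranges()] used by `simulate()`; defaults to the
#'   published calibration.
#' @param preprocess run [prepare_for_gmm()] first (default `TRUE`).
#' @param ... passed to [fit_gmm()] (`init`, `tol`, `max_iter`, ...).
#' @return An object of class `gmmda`: list with `volume` (preprocessed),
#'   `params`, `posterior`, `report`, `ranges`, `call`.
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(32, 32, 32), seed = 1))
#' fit <- gmmda(ph$volume)
#' coef(fit)
#' variants <- simulate(fit, nsim = 2, seed = 42)
#' @export
gmmda <- function(vol, K = 3L, ranges = default_ranges(), preprocess = TRUE, ...) {
  if (is.character(vol)) vol <- read_volume(vol)
  stopifnot(inherits(vol, "intensity_volume"))
  pvol <- if (preprocess) prepare_for_gmm(vol) else vol
  fit <- fit_gmm(pvol, K = K, ...)
  structure(list(volume = pvol, params = fit$params,
                 posterior = posteriors(pvol, fit$params),
                 report = fit$report, ranges = ranges,
                 call = match.call()),
            class = "gmmda")
}

#' @export
print.gmmda <- function(x, digits = 4, ...) {
  cat("Gaussian-mixture intensity model\n")
  cat("Call: ", deparse(x$call), "\n\n", sep = "")
  m <- rbind(pi = x$params$pi, mu = x$params$mu, sigma = sqrt(x$params$var))
  colnames(m) <- x$params$labels
  print(round(m, digits))
  cat(sprintf("\nMean log-likelihood %.5f after %d EM iteration(s)%s\n",
              x$report$log_likelihood, x$report$n_iterations,
              if (x$report$converged) " (converged)" else " (max iterations)"))
  invisible(x)
}

#' @export
summary.gmmda <- function(object, ...) {
  cmap <- class_map(object$posterior)
  counts <- tabulate(cmap$labels[object$posterior$mask], nbins = object$params$K)
  structure(list(params = object$params, report = object$report,
                 n_voxels = sum(object$posterior$mask),
                 class_fractions = counts / sum(counts),
                 ranges = object$ranges, call = object$call),
            class = "summary.gmmda")
}

#' @export
print.summary.gmmda <- function(x, digits = 4, ...) {
  cat("Gaussian-mixture intensity model\n")
  cat("Call: ", deparse(x$call), "\n\n", sep = "")
  m <- rbind(pi = x$params$pi, mu = x$params$mu, var = x$params$var,
             sigma = sqrt(x$params$var), `hard fraction` = x$class_fractions)
  colnames(m) <- x$params$labels
  print(round(m, digits))
  cat(sprintf("\n%d masked voxels; mean log-likelihood %.5f; %d EM iteration(s); converged: %s\n",
              x$n_voxels, x$report$log_likelihood, x$report$n_iterations,
              x$report$converged))
  cat(sprintf("Perturbation ranges (%s): s_mu = (%s), s_var = (%s)\n",
              x$ranges$provenance,
              paste(signif(x$ranges$s_mu, 3), collapse = ", "),
              paste(signif(x$ranges$s_var, 3), collapse = ", ")))
  invisible(x)
}

#' @export
coef.gmmda <- function(object, ...) {
  m <- cbind(pi = object$params$pi, mu = object$params$mu, var = object$params$var)
  rownames(m) <- object$params$labels
  m
}

#' @export
logLik.gmmda <- function(object, ...) {
  n <- nrow(object$posterior$probs)
  structure(object$report$log_likelihood * n,
            df = 3 * object$params$K - 1, nobs = n, class = "logLik")
}

#' @export
fitted.gmmda <- function(object, ...) {
  fv <- as.numeric(object$posterior$probs %*% object$params$mu)
  data <- array(0, object$posterior$dim)
  data[object$posterior$mask] <- fv
  intensity_volume(data, object$posterior$mask)
}

#' @export
residuals.gmmda <- function(object, ...) {
  r <- object$volume$data - fitted(object)$data
  r[!object$volume$mask] <- 0
  intensity_volume(r, object$volume$mask)
}

#' @param object a fitted `gmmda` model.
#' @param newdata an [intensity_volume()], a numeric vector of intensities,
#'   or `NULL` for the training volume.
#' @param type `"posterior"` for the probability matrix, `"class"` for hard
#'   labels.
#' @rdname gmmda
#' @export
predict.gmmda <- function(object, newdata = NULL,
                          type = c("posterior", "class"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    post <- object$posterior
  } else if (inherits(newdata, "intensity_volume")) {
    post <- posteriors(newdata, object$params)
  } else {
    v <- as.numeric(newdata)
    ld <- log_weighted_dens(v, object$params)
    probs <- exp(ld - row_logsumexp(ld))
    colnames(probs) <- object$params$labels
    if (type == "posterior") return(probs)
    return(max.col(probs, ties.method = "first"))
  }
  if (type == "posterior") post else class_map(post)
}

#' @param nsim number of augmented variants.
#' @param seed integer seed for the perturbation draws.
#' @param clip clamp simulated intensities to `[0, 1]`?
#' @rdname gmmda
#' @export
simulate.gmmda <- function(object, nsim = 1, seed = 1L, clip = FALSE, ...) {
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    q <- sample_perturbation(object$ranges, object$params,
                             seed = derive_seed(seed, i))
    np <- perturb_params(object$params, q)
    v <- reconstruct(object$volume, object$params, np, object$posterior,
                     clip = clip)
    attr(v, "perturbation") <- q
    attr(v, "new_params") <- np
    out[[i]] <- v
  }
  out
}

#' @param x a fitted `gmmda` model.
#' @param breaks histogram breaks for the intensity histogram.
#' @rdname gmmda
#' @export
plot.gmmda <- function(x, breaks = 80, ...) {
  v <- x$volume$data[x$volume$mask]
  graphics::hist(v, breaks = breaks, freq = FALSE,
                 main = "Masked intensity histogram with fitted mixture",
                 xlab = "normalized intensity", border = "grey70", ...)
  xs <- seq(min(v), max(v), length.out = 512)
  dens <- 0
  for (k in seq_len(x$params$K)) {
    dk <- x$params$pi[k] * stats::dnorm(xs, x$params$mu[k], sqrt(x$params$var[k]))
    graphics::lines(xs, dk, col = k + 1, lty = 2)
    dens <- dens + dk
  }
  graphics::lines(xs, dens, lwd = 2)
  graphics::legend("topright", bty = "n", lwd = c(2, rep(1, x$params$K)),
                   lty = c(1, rep(2, x$params$K)),
                   col = c(1, seq_len(x$params$K) + 1),
                   legend = c("mixture", x$params$labels))
  invisible(x)
}
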