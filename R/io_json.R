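#' Serialize mixture parameters and ranges
#'
#' JSON round-trips for [mixture_params()] and [variation_ranges()], and a
#' YAML round-trip for [phantom_spec()]. Numbers are written at full
#' precision so a write/read cycle is lossless.
#'
#' @param params a [mixture_params()].
#' @param path output/input file path.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "mixture_params"))
  jsonlite::write_json(list(K = params$K, pi = params$pi, mu = params$mu,
                            var = params$var, labels = params$labels),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("pi", "mu", "var")) {
    if (is.null(x[[f]])) stop_gmmaug("parameter file %s lacks field '%s'", path, f)
  }
  mixture_params(x$pi, x$mu, x$var, labels = x$labels, sort = FALSE)
}

#' @param ranges a [variation_ranges()].
#' @rdname write_params
#' @export
write_ranges <- function(ranges, path) {
  stopifnot(inherits(ranges, "variation_ranges"))
  jsonlite::write_json(list(s_mu = ranges$s_mu, s_var = ranges$s_var,
                            provenance = ranges$provenance),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_ranges <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$s_mu) || is.null(x$s_var)) {
    stop_gmmaug("ranges file %s lacks 's_mu'/'s_var'", path)
  }
  variation_ranges(x$s_mu, x$s_var, provenance = x$provenance %||% "file")
}

#' @param spec a [phantom_spec()].
#' @rdname write_params
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_phantom_spec <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(phantom_spec, x[intersect(names(x), names(formals(phantom_spec)))])
}

# Provenance sidecar written next to each augmented variant: everything
# needed to regenerate it exactly.
write_provenance <- function(path, aug, i) {
  jsonlite::write_json(
    list(variant = i, seed = aug$seed,
         variant_seed = aug$perturbations[[i]]$seed,
         q_mu = aug$perturbations[[i]]$q_mu,
         q_var = aug$perturbations[[i]]$q_var,
         fitted = list(pi = aug$params$pi, mu = aug$params$mu, var = aug$params$var),
         perturbed = list(pi = aug$new_params[[i]]$pi, mu = aug$new_params[[i]]$mu,
                          var = aug$new_params[[i]]$var),
         ranges = list(s_mu = aug$ranges$s_mu, s_var = aug$ranges$s_var,
                       provenance = aug$ranges$provenance)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
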