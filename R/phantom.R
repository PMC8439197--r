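#' Specify a synthetic brain phantom
#'
#' Builds the specification for a seeded synthetic 3-D "brain" used to
#' exercise every stage of the augmentation pipeline with known ground
#' truth. The geometry is a set of nested ellipsoids emulating the T1w
#' tissue layout: a white-matter core (label 3), a gray-matter shell
#' (label 2), an outer CSF shell (label 1) and an interior ventricle
#' ellipsoid also labeled CSF. Each tissue class k draws its voxel
#' intensities from Normal(class_means[k], class_stds[k]^2); an optional
#' smooth multiplicative bias field and optional Rician noise can then be
#' applied, in that order. Intensities are deliberately not clipped to
#' [0, 1] at generation time: clipping belongs to [prepare_for_gmm()].
#'
#' @param grid_shape integer triple, voxel grid dimensions.
#' @param class_means per-class true mean intensities, strictly increasing
#'   with class index (CSF < GM < WM convention), nominally in `[0, 1]`.
#' @param class_stds per-class intensity standard deviations (>= 0; 0 gives
#'   a degenerate noiseless class, useful in tests).
#' @param radii increasing fractional ellipsoid boundaries (of the brain
#'   ellipsoid) separating, from the centre outwards, WM / GM / CSF. The
#'   defaults `(0.693, 0.874, 1)` give roughly equal volume fractions for
#'   the three shells.
#' @param ventricle fractional radius of the central ventricle ellipsoid
#'   (labeled CSF); `0` disables it.
#' @param bias_field `NULL` for none, or `list(order =, amplitude =)` for a
#'   smooth low-order polynomial multiplicative field; see
#'   [generate_bias_field()].
#' @param noise `NULL` for none, or `list(model = "rician", sigma =)` for
#'   magnitude-MRI Rician noise with per-channel standard deviation `sigma`
#'   (intensity units), applied after the bias field.
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         class_means = c(0.2, 0.5, 0.8),
                         class_stds = c(0.02, 0.02, 0.02),
                         radii = c(0.693, 0.874, 1),
                         ventricle = 0.18,
                         bias_field = NULL,
                         noise = NULL,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L)) {
    stop_gmmaug("'grid_shape' must be a positive integer triple")
  }
  K <- length(class_means)
  if (length(class_stds) != K) stop_gmmaug("class_means and class_stds lengths differ")
  if (K < 1L || any(diff(class_means) <= 0)) {
    stop_gmmaug("'class_means' must be strictly increasing (CSF < GM < WM)")
  }
  if (K != 3L) stop_gmmaug("the nested-ellipsoid layout models exactly 3 tissue classes")
  if (any(class_stds < 0)) stop_gmmaug("'class_stds' must be >= 0")
  if (length(radii) != 3L || any(diff(radii) <= 0) || radii[1] <= 0 || radii[3] > 1) {
    stop_gmmaug("'radii' must be increasing in (0, 1]")
  }
  if (ventricle < 0 || ventricle >= radii[1]) {
    stop_gmmaug("'ventricle' must lie in [0, radii[1]) so it stays inside the WM core")
  }
  if (!is.null(bias_field)) {
    if (!is.list(bias_field) || is.null(bias_field$order) || is.null(bias_field$amplitude)) {
      stop_gmmaug("'bias_field' must be NULL or list(order =, amplitude =)")
    }
    if (bias_field$amplitude < 0) stop_gmmaug("bias-field amplitude must be >= 0")
  }
  if (!is.null(noise)) {
    if (!is.list(noise) || !identical(noise$model %||% "rician", "rician") ||
        is.null(noise$sigma) || noise$sigma < 0) {
      stop_gmmaug("'noise' must be NULL or list(model = \"rician\", sigma >= 0)")
    }
  }
  structure(list(grid_shape = grid_shape, class_means = as.numeric(class_means),
                 class_stds = as.numeric(class_stds), radii = as.numeric(radii),
                 ventricle = ventricle, bias_field = bias_field, noise = noise,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s grid, means (%s), stds (%s), seed %d\n",
              paste(x$grid_shape, collapse = "x"),
              paste(x$class_means, collapse = ", "),
              paste(x$class_stds, collapse = ", "), x$seed))
  if (!is.null(x$bias_field)) {
    cat(sprintf("  bias field: order %d, amplitude %.3g\n",
                x$bias_field$order, x$bias_field$amplitude))
  }
  if (!is.null(x$noise)) cat(sprintf("  Rician noise: sigma %.3g\n", x$noise$sigma))
  invisible(x)
}

# Normalized ellipsoidal radius of every voxel: rho <= 1 on the brain
# ellipsoid. Mildly anisotropic semi-axes so the phantom is not a sphere.
phantom_rho <- function(grid_shape, semi_axes = c(0.90, 0.95, 0.85)) {
  ax <- lapply(seq_len(3L), function(i) {
    n <- grid_shape[i]
    x <- if (n == 1L) 0 else (seq_len(n) - (n + 1) / 2) / ((n - 1) / 2)
    (x / semi_axes[i])^2
  })
  r2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  sqrt(r2)
}

#' Generate a synthetic phantom volume
#'
#' Realizes a [phantom_spec()]: returns the intensity volume and the
#' ground-truth tissue labels. Generation is fully deterministic given the
#' spec (which includes its seed).
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` (an [intensity_volume()]) and
#'   `labels` (a [labeled_volume()]).
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(24, 24, 24), seed = 7))
#' table(ph$labels$labels)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  rho <- phantom_rho(spec$grid_shape)
  labels <- array(0L, spec$grid_shape)
  labels[rho <= spec$radii[3]] <- 1L              # CSF outer shell
  labels[rho <= spec$radii[2]] <- 2L              # GM shell
  labels[rho <= spec$radii[1]] <- 3L              # WM core
  if (spec$ventricle > 0) labels[rho <= spec$ventricle] <- 1L  # ventricle = CSF
  counts <- tabulate(labels, nbins = 3L)
  if (any(counts == 0L)) {
    stop_gmmaug("invalid geometry: grid %s too small to host all tissue compartments",
                paste(spec$grid_shape, collapse = "x"))
  }
  mask <- labels > 0L
  data <- array(0, spec$grid_shape)
  with_preserved_seed(spec$seed, {
    for (k in 1:3) {
      idx <- labels == k
      data[idx] <- stats::rnorm(counts[k], spec$class_means[k], spec$class_stds[k])
    }
    if (!is.null(spec$bias_field) && spec$bias_field$amplitude > 0) {
      field <- generate_bias_field(spec$grid_shape,
                                   order = spec$bias_field$order,
                                   amplitude = spec$bias_field$amplitude,
                                   seed = derive_seed(spec$seed, 1L, 1L),
                                   mask = mask)
      data <- data * field
    }
    if (!is.null(spec$noise) && spec$noise$sigma > 0) {
      n <- sum(mask)
      re <- stats::rnorm(n, 0, spec$noise$sigma)
      im <- stats::rnorm(n, 0, spec$noise$sigma)
      data[mask] <- sqrt((data[mask] + re)^2 + im^2)
    }
  })
  data[!mask] <- 0
  list(volume = intensity_volume(data, mask), labels = labeled_volume(labels))
}

#' Generate a smooth multiplicative bias field
#'
#' Produces the smooth, low-frequency multiplicative intensity
#' inhomogeneity that corrupts real MRI acquisitions, as a random low-order
#' 3-D polynomial. The field is normalized to mean 1 (over `mask` if given,
#' otherwise the whole grid) and rescaled so its values span
#' `[1 - amplitude, 1 + amplitude]`.
#'
#' @param grid_shape integer triple.
#' @param order maximum total polynomial degree (>= 1); 2 gives the classic
#'   slowly-varying quadratic shading.
#' @param amplitude fractional field strength in `[0, 1)`; values >= 1 are
#'   rejected because the field could then zero or negate intensities.
#' @param seed integer seed for the random polynomial coefficients.
#' @param mask optional logical array; when supplied the field has mean
#'   exactly 1 over the masked voxels.
#' @return A 3-D numeric array of positive multipliers.
#' @export
generate_bias_field <- function(grid_shape, order = 2L, amplitude = 0.3,
                                seed = 1L, mask = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L) stop_gmmaug("'grid_shape' must be an integer triple")
  if (order < 1L) stop_gmmaug("'order' must be >= 1")
  if (amplitude < 0 || amplitude >= 1) {
    stop_gmmaug("'amplitude' must be in [0, 1): larger fields would produce non-positive intensities")
  }
  if (amplitude == 0) return(array(1, grid_shape))
  ax <- lapply(grid_shape, function(n) {
    if (n == 1L) 0 else (seq_len(n) - (n + 1) / 2) / ((n - 1) / 2)
  })
  f0 <- array(0, grid_shape)
  with_preserved_seed(seed, {
    for (i in 0:order) for (j in 0:(order - i)) for (k in 0:(order - i - j)) {
      if (i + j + k == 0L) next
      cf <- stats::rnorm(1)
      f0 <- f0 + cf * outer(outer(ax[[1]]^i, ax[[2]]^j), ax[[3]]^k)
    }
  })
  msk <- if (is.null(mask)) array(TRUE, grid_shape) else mask
  g <- f0 - mean(f0[msk])
  # scale so the stated amplitude is attained within the mask (a random
  # polynomial peaks at the grid corners, which lie outside any brain);
  # the clamp only ever acts on voxels outside the mask
  s <- max(abs(g[msk]))
  if (s == 0) return(array(1, grid_shape))
  f <- 1 + amplitude * g / s
  pmin(pmax(f, 1 - amplitude), 1 + amplitude)
}
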