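#' Intensity volumes and label volumes
#'
#' `intensity_volume()` wraps a 3-D scalar array of voxel intensities
#' together with a logical brain mask. Voxels outside the mask are forced to
#' zero, matching the skull-stripped convention where background is exactly
#' 0. If no mask is supplied, the mask defaults to `data > 0`.
#'
#' `labeled_volume()` wraps a 3-D array of integer tissue labels, with 0 for
#' background and 1..K for tissue classes.
#'
#' @param data 3-D numeric array of voxel intensities.
#' @param mask optional 3-D logical array of the same shape; `TRUE` marks
#'   brain voxels. Defaults to `data > 0`.
#' @return An object of class `intensity_volume`: a list with elements
#'   `data` (numeric 3-D array) and `mask` (logical 3-D array).
#' @examples
#' v <- intensity_volume(array(runif(27), c(3, 3, 3)))
#' dim(v)
#' @export
intensity_volume <- function(data, mask = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_gmmaug("'data' must be a 3-D array (got %s dimensions)",
                if (is.array(data)) length(dim(data)) else "no")
  }
  storage.mode(data) <- "double"
  if (is.null(mask)) {
    mask <- data > 0
  }
  if (!identical(dim(mask), dim(data))) {
    stop_gmmaug("'mask' and 'data' shapes differ")
  }
  mask <- array(as.logical(mask), dim(data))
  if (anyNA(mask)) stop_gmmaug("'mask' contains NA")
  data[!mask] <- 0
  structure(list(data = data, mask = mask), class = "intensity_volume")
}

#' @param labels 3-D array of non-negative integer labels (0 = background).
#' @rdname intensity_volume
#' @export
labeled_volume <- function(labels) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stop_gmmaug("'labels' must be a 3-D array")
  }
  lv <- as.vector(labels)
  if (anyNA(lv) || any(lv != round(lv)) || any(lv < 0)) {
    stop_gmmaug("labels must be non-negative integers (0 = background)")
  }
  labels <- array(as.integer(round(lv)), dim(labels))
  structure(list(labels = labels), class = "labeled_volume")
}

#' @export
dim.intensity_volume <- function(x) dim(x$data)

#' @export
dim.labeled_volume <- function(x) dim(x$labels)

#' @export
print.intensity_volume <- function(x, ...) {
  d <- dim(x)
  v <- x$data[x$mask]
  cat(sprintf("<intensity_volume> %d x %d x %d, %d masked voxels\n",
              d[1], d[2], d[3], sum(x$mask)))
  if (length(v)) {
    cat(sprintf("  masked intensity range [%.4g, %.4g], mean %.4g\n",
                min(v), max(v), mean(v)))
  }
  invisible(x)
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<labeled_volume> %d x %d x %d\n", d[1], d[2], d[3]))
  print(table(label = x$labels))
  invisible(x)
}

#' Read and write NIfTI-1 volumes
#'
#' Thin wrappers around \pkg{RNifti} that move between `.nii`/`.nii.gz`
#' files and [intensity_volume()] / [labeled_volume()] objects. The NIfTI
#' header of a read volume is carried along as an attribute and re-used on
#' write so that affine and geometry fields survive a round trip. Volumes
#' are stored as float32 (the usual MRI convention); all internal
#' computation is double precision.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return `read_volume()` returns an [intensity_volume()];
#'   `read_labels()` a [labeled_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop_gmmaug("input file not found: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop_gmmaug("only 3-D scalar volumes are supported (got %d-D input)", length(d))
  }
  vol <- intensity_volume(array(as.numeric(img), dim = d))
  attr(vol, "nifti_header") <- RNifti::niftiHeader(img)
  vol
}

#' @rdname read_volume
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop_gmmaug("input file not found: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop_gmmaug("only 3-D label volumes are supported (got %d-D input)", length(d))
  }
  v <- as.numeric(img)
  if (any(v != round(v)) || any(v < 0)) {
    stop_gmmaug("label volume contains non-integer or negative values; not a valid label map")
  }
  lab <- labeled_volume(array(v, dim = d))
  attr(lab, "nifti_header") <- RNifti::niftiHeader(img)
  lab
}

#' @param vol an [intensity_volume()] or [labeled_volume()].
#' @param template optional NIfTI header (or image) whose geometry is copied
#'   onto the output; defaults to the header the volume was read with, if any.
#' @param datatype on-disk NIfTI datatype; `"float"` for intensities,
#'   `"int16"` is sensible for labels.
#' @rdname read_volume
#' @export
write_volume <- function(vol, path, template = NULL, datatype = "float") {
  arr <- if (inherits(vol, "labeled_volume")) vol$labels else vol$data
  ref <- template %||% attr(vol, "nifti_header")
  img <- RNifti::asNifti(arr, reference = ref)
  invisible(RNifti::writeNifti(img, path, datatype = datatype))
}
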