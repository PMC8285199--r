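#' Image grid container
#'
#' A lightweight carrier for 2-D or 3-D grayscale intensity data together
#' with per-axis voxel spacing (millimetres) and a free-text modality tag
#' (e.g. `"T1WI"`, `"T2WI"`, `"synthetic"`).  Intensities must be finite and
#' non-negative; arbitrary real-valued arrays (log-domain data, gradients,
#' residuals) are handled as plain arrays, not as `image_grid` objects.
#'
#' @param values numeric matrix (2-D) or 3-D array of non-negative, finite
#'   intensities.  Every axis must have length at least 1.
#' @param spacing numeric vector of per-axis physical sizes in mm, one entry
#'   per array dimension, all strictly positive.  Defaults to 1 mm per axis.
#' @param modality free-text modality tag.  Defaults to `"synthetic"`.
#'
#' @return An object of class `image_grid`: a list with elements `values`,
#'   `spacing` and `modality`.
#' @examples
#' img <- image_grid(matrix(runif(64), 8, 8), spacing = c(0.5, 0.5))
#' dim(img)
#' @export
image_grid <- function(values, spacing = NULL, modality = "synthetic") {
  if (is.null(dim(values))) {
    stop("`values` must be a matrix or a 3-D array", call. = FALSE)
  }
  nd <- length(dim(values))
  if (nd < 2L || nd > 3L) {
    stop("`values` must be 2-D or 3-D, got ", nd, " dimensions", call. = FALSE)
  }
  if (any(dim(values) < 1L)) stop("all image dimensions must be >= 1", call. = FALSE)
  if (!is.numeric(values)) stop("`values` must be numeric", call. = FALSE)
  if (any(!is.finite(values))) stop("intensities must be finite", call. = FALSE)
  if (any(values < 0)) stop("intensity images cannot contain negative values", call. = FALSE)
  if (is.null(spacing)) spacing <- rep(1, nd)
  if (length(spacing) != nd || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must give one positive value per axis", call. = FALSE)
  }
  structure(
    list(values = values, spacing = as.numeric(spacing),
         modality = as.character(modality)[1]),
    class = "image_grid"
  )
}

#' @export
dim.image_grid <- function(x) dim(x$values)

#' @export
as.array.image_grid <- function(x, ...) x$values

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %s  [%s]  spacing %s mm  range [%.4g, %.4g]\n",
              paste(dim(x$values), collapse = " x "), x$modality,
              paste(format(x$spacing), collapse = " x "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Test for image_grid objects
#' @param x object to test.
#' @return `TRUE` if `x` is an `image_grid`.
#' @export
is_image_grid <- function(x) inherits(x, "image_grid")

## Accept either an image_grid or a bare numeric array; return the array.
grid_values <- function(x, arg = "image") {
  if (is_image_grid(x)) return(x$values)
  if (is.numeric(x) && !is.null(dim(x))) return(x)
  stop("`", arg, "` must be an image_grid or a numeric array", call. = FALSE)
}
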