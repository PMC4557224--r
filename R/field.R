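#' Scalar density fields
#'
#' A `scalar_field` wraps a numeric matrix of field values together with the
#' RBF parameters that produced it, the number of convolved sources, and a
#' flag recording whether the values have been rescaled to the canonical
#' 0--100 range. The matrix is stored in image orientation: rows are image
#' rows, columns image columns.
#'
#' @param values Numeric matrix of finite field values.
#' @param params [rbf_params()] used to build the field (or `NULL`).
#' @param normalized Has [normalize_field()] been applied?
#' @param n_sources Number of source objects summed into the field.
#' @name scalar_field
NULL

new_scalar_field <- function(values, params = NULL, normalized = FALSE,
                             n_sources = NA_integer_, role = "field",
                             center = NULL, image_shape = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (!all(is.finite(values))) abort("field values must be finite")
  structure(
    list(values = values, params = params, normalized = isTRUE(normalized),
         n_sources = as.integer(n_sources), role = role, center = center,
         image_shape = image_shape),
    class = "scalar_field"
  )
}

#' @rdname scalar_field
#' @param x A `scalar_field`.
#' @return `field_values()` returns the underlying numeric matrix;
#'   `is_normalized()` the normalization flag.
#' @export
field_values <- function(x) {
  stopifnot(inherits(x, "scalar_field"))
  x$values
}

#' @rdname scalar_field
#' @export
is_normalized <- function(x) {
  stopifnot(inherits(x, "scalar_field"))
  x$normalized
}

#' @export
print.scalar_field <- function(x, ...) {
  v <- x$values
  cat(sprintf("<scalar_field %dx%d> %s, %s, range [%.4g, %.4g], sources: %s\n",
              nrow(v), ncol(v),
              if (is.null(x$params)) "no params" else paste0("mode ", x$params$mode),
              if (x$normalized) "normalized" else "raw",
              min(v), max(v),
              ifelse(is.na(x$n_sources), "?", x$n_sources)))
  invisible(x)
}

#' @export
dim.scalar_field <- function(x) dim(x$values)

#' @export
as.matrix.scalar_field <- function(x, ...) x$values

#' Turn a field into a tidy pixel table
#'
#' @param x A [scalar_field].
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `value` in row-major pixel
#'   order.
#' @method tidy scalar_field
#' @export
tidy.scalar_field <- function(x, ...) {
  v <- x$values
  tibble(
    row = rep(seq_len(nrow(v)), times = ncol(v)),
    col = rep(seq_len(ncol(v)), each = nrow(v)),
    value = as.numeric(v)
  )
}

#' Convolve point sources or a mask with an RBF kernel
#'
#' Builds the summation field of a set of objects: the source indicator grid
#' (one at each centroid, or one at every mask-positive pixel) is convolved
#' with the kernel by zero-padded FFT multiplication and cropped back to the
#' image size. Fields are additive, so the result is exactly the sum of the
#' per-object fields.
#'
#' With an `extent = "image"` kernel the crop truncates the field of any
#' off-centre source at the opposite border (a strip of zeros of width equal
#' to the source's offset from the image centre). With an `extent = "full"`
#' kernel the result is the untruncated superposition and is strictly
#' positive everywhere.
#'
#' @param sources Either a binary matrix (same size as the target image) or
#'   a two-column matrix / data frame of (row, col) pixel coordinates.
#' @param kernel A kernel built by [build_kernel()].
#' @param shape Target image size `c(height, width)`; required when
#'   `sources` is a coordinate table, inferred from a matrix otherwise.
#' @return An un-normalized [scalar_field]; `n_sources` records the number
#'   of source pixels.
#' @examples
#' k <- build_kernel(rbf_direct(), 21, 21)
#' f <- convolve_sources(cbind(11, 11), k, shape = c(21, 21))
#' all.equal(field_values(f), field_values(k))  # delta identity
#' @export
convolve_sources <- function(sources, kernel, shape = NULL) {
  stopifnot(inherits(kernel, "scalar_field"), identical(kernel$role, "kernel"))
  ishape <- kernel$image_shape
  is_coords <- is.data.frame(sources) ||
    (is.matrix(sources) && ncol(sources) == 2L &&
       !identical(dim(sources), as.integer(ishape)))
  if (is_coords) {
    src <- make_point_image(ishape[1], ishape[2], sources)
  } else {
    src <- sources
    if (!identical(dim(src), as.integer(ishape)))
      stop_shape(sprintf("source grid is %dx%d but kernel was built for %dx%d",
                         nrow(src), ncol(src), ishape[1], ishape[2]))
  }
  n_src <- sum(src != 0)
  if (n_src == 0L)
    abort("no source objects: cannot build a field from an empty set",
          class = "histofield_empty_error")
  vals <- conv2d_same(src, kernel$values, kernel$center[1], kernel$center[2])
  vals[vals < 0] <- 0   # clip FFT round-off below zero
  new_scalar_field(vals, params = kernel$params, normalized = FALSE,
                   n_sources = n_src)
}

#' Rescale a field linearly onto the 0--100 range
#'
#' Affine min--max mapping: the field minimum goes to 0 and the maximum to
#' 100, preserving the order of all pixel values. Summation fields of many
#' objects easily exceed 10,000 raw units; all colocalization thresholds in
#' this package (pair threshold 25, Manders threshold 50) refer to this
#' normalized scale.
#'
#' @param field A [scalar_field] with `max > min`.
#' @return The normalized [scalar_field].
#' @export
normalize_field <- function(field) {
  stopifnot(inherits(field, "scalar_field"))
  v <- field$values
  lo <- min(v); hi <- max(v)
  if (hi <= lo)
    abort("cannot normalize a constant field (max == min)",
          class = "histofield_degenerate_error")
  field$values <- 100 * (v - lo) / (hi - lo)
  field$normalized <- TRUE
  field
}

#' Build a normalized field straight from points
#'
#' Convenience wrapper: indicator image, kernel, convolution, normalization
#' in one call. This is the field construction used throughout the package's
#' worked examples.
#'
#' @param points Two-column matrix or data frame of (row, col) coordinates,
#'   or a binary source matrix.
#' @param shape Image size `c(height, width)`.
#' @param params [rbf_params()]; default [rbf_direct()].
#' @param extent Kernel extent, see [build_kernel()].
#' @param normalize Normalize onto 0--100 (default `TRUE`).
#' @return A [scalar_field].
#' @examples
#' f <- point_field(cbind(251, 251), c(500, 500))
#' range(field_values(f))  # 0 100
#' @export
point_field <- function(points, shape, params = rbf_direct(),
                        extent = c("image", "full"), normalize = TRUE) {
  extent <- match.arg(extent)
  ker <- build_kernel(params, shape[1], shape[2], extent = extent)
  f <- convolve_sources(points, ker, shape = shape)
  if (normalize) normalize_field(f) else f
}
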