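#' Image series with a per-frame acquisition axis
#'
#' An `image_series` is a 2D multi-frame acquisition: a numeric array of
#' dimension `nx x ny x nframes` together with the physical meaning of the
#' frame axis. The axis is one of inversion time (`"ti_ms"`), dynamic time
#' (`"time_s"`) or flip angle (`"flip_deg"`). When the acquisition repeats
#' the whole axis (ASL measurements), `repeats > 1` and frames are ordered
#' axis-fastest: frame `(r - 1) * length(values) + i` holds axis value `i`
#' of repeat `r`.
#'
#' @param data numeric array `nx x ny x nframes` (a matrix is promoted to a
#'   single frame).
#' @param axis one of `"ti_ms"`, `"time_s"`, `"flip_deg"`.
#' @param values numeric vector of axis values, one per frame within a repeat.
#' @param repeats integer number of repeats of the whole axis.
#' @param pixel_size_mm in-plane pixel size, length-1 or length-2, mm.
#' @return an object of class `image_series`.
#' @export
image_series <- function(data, axis = c("ti_ms", "time_s", "flip_deg"),
                         values, repeats = 1L,
                         pixel_size_mm = c(0.44, 0.44)) {
  axis <- match.arg(axis)
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (length(dim(data)) != 3L)
    stop("`data` must be an nx x ny x nframes array", call. = FALSE)
  values <- as.numeric(values)
  repeats <- as.integer(repeats)
  if (repeats < 1L) stop("`repeats` must be >= 1", call. = FALSE)
  nframes <- dim(data)[3]
  if (length(values) * repeats != nframes)
    stop(sprintf(
      "frame count mismatch: axis length %d x repeats %d != %d frames",
      length(values), repeats, nframes), call. = FALSE)
  if (length(pixel_size_mm) == 1L) pixel_size_mm <- rep(pixel_size_mm, 2L)
  structure(
    list(data = data, axis = axis, values = values, repeats = repeats,
         pixel_size_mm = as.numeric(pixel_size_mm)),
    class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_series> %d x %d, %d frame(s)\n", d[1], d[2], d[3]))
  cat(sprintf("  axis: %s (%d values%s)\n", x$axis, length(x$values),
              if (x$repeats > 1L) sprintf(" x %d repeats", x$repeats) else ""))
  cat(sprintf("  pixel size: %.3g x %.3g mm\n",
              x$pixel_size_mm[1], x$pixel_size_mm[2]))
  invisible(x)
}

#' @export
dim.image_series <- function(x) dim(x$data)

grid_shape <- function(series) dim(series$data)[1:2]

stopifnot_same_grid <- function(a, b, what = "inputs") {
  if (!identical(dim(a)[1:2], dim(b)[1:2]))
    stop(sprintf("%s have mismatched grid shapes: %s vs %s", what,
                 paste(dim(a)[1:2], collapse = "x"),
                 paste(dim(b)[1:2], collapse = "x")), call. = FALSE)
  invisible(TRUE)
}

#' Average repeats of an image series
#'
#' Collapses the repeat dimension by voxel-wise averaging, returning a series
#' with `repeats = 1` and one frame per axis value.
#'
#' @param series an [image_series()].
#' @return an `image_series` with one frame per axis value.
#' @export
average_repeats <- function(series) {
  if (!inherits(series, "image_series")) stop("not an image_series")
  if (series$repeats == 1L) return(series)
  d <- dim(series$data)
  nv <- length(series$values)
  x <- array(series$data, dim = c(d[1], d[2], nv, series$repeats))
  m <- apply(x, c(1, 2, 3), mean)
  image_series(m, series$axis, series$values, 1L, series$pixel_size_mm)
}
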