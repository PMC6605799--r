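#' Calibrated 2-D image
#'
#' Container for a single grayscale frame: a non-negative intensity matrix
#' plus the physical pixel size. All faprox functions take and return pixel
#' coordinates as 0-based `(row, col)` pairs with pixel centers at integer
#' coordinates; matrices themselves are ordinary R matrices.
#'
#' @param intensity numeric matrix of finite, non-negative intensities.
#' @param pixel_size pixel size in micrometers per pixel (> 0).
#' @param channel_name optional channel label.
#' @return An object of class `image2d`.
#' @export
image2d <- function(intensity, pixel_size, channel_name = "") {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop("intensity must be a numeric matrix")
  if (any(!is.finite(intensity)))
    stop("intensities must be finite")
  if (any(intensity < 0))
    stop("intensities must be non-negative")
  check_positive_scalar(pixel_size, "pixel_size")
  structure(
    list(intensity = intensity, pixel_size = pixel_size,
         channel_name = as.character(channel_name)),
    class = "image2d")
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d> %d x %d px, %.4g um/px%s\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_size,
              if (nzchar(x$channel_name)) paste0(", channel '", x$channel_name, "'") else ""))
  invisible(x)
}

#' Calibrated image stack (time lapse)
#'
#' @param frames list of intensity matrices (one per frame), all of the same
#'   shape, or a list of [image2d] objects sharing `pixel_size`.
#' @param pixel_size micrometers per pixel (> 0).
#' @param frame_interval seconds between consecutive frames (> 0).
#' @param channel_name optional channel label.
#' @return An object of class `image_stack` with elements `frames`
#'   (list of matrices), `pixel_size`, `frame_interval`, `channel_name`.
#' @export
image_stack <- function(frames, pixel_size, frame_interval, channel_name = "") {
  if (!is.list(frames) || length(frames) == 0)
    stop("frames must be a non-empty list")
  frames <- lapply(frames, function(f) {
    if (inherits(f, "image2d")) f$intensity else f
  })
  if (!all(vapply(frames, is.matrix, logical(1))))
    stop("every frame must be a matrix (or image2d)")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share the same shape")
  check_positive_scalar(pixel_size, "pixel_size")
  check_positive_scalar(frame_interval, "frame_interval")
  structure(
    list(frames = frames, pixel_size = pixel_size,
         frame_interval = frame_interval,
         channel_name = as.character(channel_name)),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %d frames of %d x %d px, %.4g um/px, dt = %.4g s\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Cell region of interest polygon
#'
#' A simple (non-self-intersecting) polygon outlining the analysed cell,
#' in 0-based `(row, col)` pixel coordinates. Vertices may be fractional:
#' pixel membership is decided by a center-in-polygon test (even-odd rule),
#' so a rectangle meant to contain pixel rows 2..5 should run from row 1.5
#' to row 5.5.
#'
#' @param polygon numeric matrix with >= 3 rows and 2 columns `(row, col)`.
#' @return An object of class `cell_roi`.
#' @export
cell_roi <- function(polygon) {
  polygon <- as.matrix(polygon)
  if (!is.numeric(polygon) || ncol(polygon) != 2)
    stop("polygon must be a numeric matrix with 2 columns (row, col)")
  if (nrow(polygon) < 3)
    stop("polygon needs at least 3 vertices")
  if (any(!is.finite(polygon)))
    stop("polygon vertices must be finite")
  if (abs(polygon_area(polygon)) <= .Machine$double.eps * 100)
    stop("degenerate polygon: zero area")
  if (polygon_self_intersects(polygon))
    stop("polygon must not self-intersect")
  structure(list(polygon = unname(polygon)), class = "cell_roi")
}

#' @export
print.cell_roi <- function(x, ...) {
  cat(sprintf("<cell_roi> %d vertices, area %.1f px^2\n",
              nrow(x$polygon), abs(polygon_area(x$polygon))))
  invisible(x)
}

# shoelace signed area; vertices (row, col)
polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(n, seq_len(n - 1))
  sum(p[j, 2] * p[, 1] - p[, 2] * p[j, 1]) / 2
}

# proper-intersection test between all pairs of non-adjacent edges
polygon_self_intersects <- function(p) {
  n <- nrow(p)
  nxt <- c(seq_len(n)[-1], 1)
  orient <- function(a, b, c) {
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i || j == nxt[i] || nxt[j] == i) next
      a <- p[i, ]; b <- p[nxt[i], ]; c <- p[j, ]; d <- p[nxt[j], ]
      o1 <- orient(a, b, c); o2 <- orient(a, b, d)
      o3 <- orient(c, d, a); o4 <- orient(c, d, b)
      if (o1 * o2 < 0 && o3 * o4 < 0) return(TRUE)
    }
  }
  FALSE
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
    stop(sprintf("%s must be a single positive finite number", name))
  invisible(TRUE)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 ||
      x != floor(x))
    stop(sprintf("%s must be a single non-negative integer", name))
  invisible(TRUE)
}

as_mask <- function(m, name = "mask") {
  if (is.matrix(m) && is.logical(m)) return(m)
  if (is.matrix(m) && is.numeric(m)) return(m != 0)
  stop(sprintf("%s must be a logical (or numeric) matrix", name))
}
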