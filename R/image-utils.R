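# Shared low-level raster helpers: separable Gaussian smoothing with
# replicate borders, Otsu threshold over an arbitrary pixel subset, and
# bilinear interpolation. Pure R; images in this domain are small enough.

gaussian_kernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# shift matrix by `o` along dimension `along` (1 = rows), replicating edges
shift_mat <- function(m, o, along) {
  n <- dim(m)[along]
  idx <- pmin(pmax(seq_len(n) + o, 1L), n)
  if (along == 1) m[idx, , drop = FALSE] else m[, idx, drop = FALSE]
}

#' Gaussian smoothing of an intensity matrix
#'
#' Separable Gaussian convolution with replicate (edge-clamp) boundary
#' handling, kernel truncated at 3 sigma. `sigma = 0` returns the input.
#'
#' @param m numeric matrix.
#' @param sigma Gaussian standard deviation in pixels (>= 0).
#' @return Smoothed matrix of the same shape.
#' @export
gaussian_smooth <- function(m, sigma) {
  if (!is.matrix(m)) stop("m must be a matrix")
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(m)
  k <- gaussian_kernel1d(sigma)
  r <- (length(k) - 1L) / 2L
  offs <- seq(-r, r)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(offs)) out <- out + k[i] * shift_mat(m, offs[i], 1L)
  m2 <- out
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(offs)) out <- out + k[i] * shift_mat(m2, offs[i], 2L)
  out
}

#' Otsu threshold of a set of intensities
#'
#' Classic between-class-variance maximization on a 256-bin histogram over
#' the value range. Returns a threshold value; foreground is `value >
#' threshold`.
#'
#' @param x numeric vector of intensities (e.g. the ROI pixels).
#' @param n_bins histogram resolution.
#' @return Scalar threshold.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("no finite values for Otsu threshold")
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(lo)
  h <- tabulate(pmin(pmax(floor((x - lo) / (hi - lo) * n_bins) + 1L, 1L),
                     n_bins), nbins = n_bins)
  p <- h / sum(h)
  centers <- lo + (seq_len(n_bins) - 0.5) * (hi - lo) / n_bins
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  ok <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins)
  bcv[ok] <- (mu_t * w0[ok] - mu[ok])^2 / (w0[ok] * w1[ok])
  k <- which.max(bcv)
  lo + k * (hi - lo) / n_bins
}

# bilinear interpolation at 0-based fractional (row, col); coordinates are
# clamped to the image domain (used for kymograph line-width offsets).
bilinear_at <- function(m, r, c) {
  H <- nrow(m); W <- ncol(m)
  r <- pmin(pmax(r, 0), H - 1)
  c <- pmin(pmax(c, 0), W - 1)
  r0 <- pmin(floor(r), H - 2); r0 <- pmax(r0, 0)
  c0 <- pmin(floor(c), W - 2); c0 <- pmax(c0, 0)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0 + 1, c0 + 1)
  i10 <- cbind(r0 + 2, c0 + 1)
  i01 <- cbind(r0 + 1, c0 + 2)
  i11 <- cbind(r0 + 2, c0 + 2)
  m[i00] * (1 - fr) * (1 - fc) + m[i10] * fr * (1 - fc) +
    m[i01] * (1 - fr) * fc + m[i11] * fr * fc
}

# render a sum of isotropic Gaussian spots onto an H x W canvas
# centers: n x 2 matrix of 0-based (row, col); truncated at 5 sigma
render_gaussian_spots <- function(shape, centers, amplitude, sigma) {
  img <- matrix(0, shape[1], shape[2])
  if (is.null(centers) || nrow(centers) == 0) return(img)
  r5 <- ceiling(5 * sigma)
  for (i in seq_len(nrow(centers))) {
    r0 <- centers[i, 1]; c0 <- centers[i, 2]
    rr <- max(0, floor(r0 - r5)):min(shape[1] - 1, ceiling(r0 + r5))
    cc <- max(0, floor(c0 - r5)):min(shape[2] - 1, ceiling(c0 + r5))
    if (length(rr) == 0 || length(cc) == 0) next
    g <- amplitude * exp(-outer((rr - r0)^2, (cc - c0)^2, "+") / (2 * sigma^2))
    img[rr + 1, cc + 1] <- img[rr + 1, cc + 1] + g
  }
  img
}
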