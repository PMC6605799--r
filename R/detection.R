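# Segmentation and spot-level quantification: threshold + Gaussian-filter
# segmentation of FA / cargo channels, Find-Maxima-style spot detection,
# object counting and the secreted-spot intensity normalization.

#' Rasterize a cell ROI polygon to a binary mask
#'
#' A pixel belongs to the mask when its center (integer 0-based
#' coordinates) lies inside the polygon under the even-odd rule.
#'
#' @param roi a [cell_roi] (or a vertex matrix accepted by [cell_roi()]).
#' @param shape integer `(H, W)` of the target frame.
#' @return Logical `H x W` matrix.
#' @export
make_roi_mask <- function(roi, shape) {
  if (!inherits(roi, "cell_roi")) roi <- cell_roi(roi)
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  if (H < 1 || W < 1) stop("invalid shape")
  p <- roi$polygon
  if (any(p[, 1] < -0.5 | p[, 1] > H - 0.5 | p[, 2] < -0.5 | p[, 2] > W - 0.5))
    stop("polygon does not fit inside the image shape")
  py <- matrix(rep(0:(H - 1), W), H)        # pixel-center rows
  px <- matrix(rep(0:(W - 1), each = H), H) # pixel-center cols
  inside <- matrix(FALSE, H, W)
  n <- nrow(p)
  j <- n
  for (i in seq_len(n)) {
    y1 <- p[j, 1]; x1 <- p[j, 2]
    y2 <- p[i, 1]; x2 <- p[i, 2]
    if (y1 != y2) {
      cross <- ((y1 > py) != (y2 > py)) &
        (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
      inside <- xor(inside, cross)
    }
    j <- i
  }
  inside
}

#' Segment objects by Gaussian filtering and thresholding
#'
#' Smooths the image with a Gaussian of width `sigma`, thresholds (either
#' at an explicit intensity or with Otsu's method computed over the ROI
#' pixels only), restricts to the ROI and labels 8-connected components.
#' The parameters actually used are recorded in the result for provenance,
#' as a reproducible stand-in for per-image manual threshold adjustment.
#'
#' @param image an [image2d] (or bare matrix).
#' @param roi_mask logical mask of the analysed cell.
#' @param sigma Gaussian width in pixels (default 1).
#' @param threshold numeric intensity, or `"otsu"` (default) for Otsu over
#'   ROI pixels. Foreground is `smoothed > threshold`.
#' @return A `label_mask`: list with `labels` (integer matrix, 0 =
#'   background, objects labeled 1..n), `n_objects`, `sigma_used`,
#'   `threshold_used`.
#' @export
segment_objects <- function(image, roi_mask, sigma = 1, threshold = "otsu") {
  m <- if (inherits(image, "image2d")) image$intensity else image
  roi_mask <- as_mask(roi_mask, "roi_mask")
  if (!all(dim(m) == dim(roi_mask)))
    stop("image and roi_mask must share the same shape")
  if (!any(roi_mask)) stop("empty ROI")
  if (sigma < 0) stop("sigma must be >= 0")
  sm <- gaussian_smooth(m, sigma)
  thr <- if (identical(threshold, "otsu")) otsu_threshold(sm[roi_mask])
         else as.numeric(threshold)
  fg <- (sm > thr) & roi_mask
  lab <- label_components_cpp(fg)
  structure(
    list(labels = lab, n_objects = attr(lab, "n_objects"),
         sigma_used = sigma, threshold_used = thr),
    class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d objects (sigma = %.3g px, threshold = %.6g)\n",
              x$n_objects, x$sigma_used, x$threshold_used))
  invisible(x)
}

#' Count labeled objects above a minimum area
#'
#' The explicit `min_area` filter replaces the interactive manual selection
#' step used when counting FAs or secreted spots.
#'
#' @param mask a `label_mask` from [segment_objects()].
#' @param min_area minimum object area in pixels (>= 0; 0 keeps all).
#' @return Integer count.
#' @export
count_objects <- function(mask, min_area = 0) {
  stopifnot(inherits(mask, "label_mask"))
  check_count(min_area, "min_area")
  if (mask$n_objects == 0) return(0L)
  areas <- tabulate(mask$labels[mask$labels > 0], nbins = mask$n_objects)
  sum(areas >= min_area)
}

#' Detect fluorescent spots as prominence-filtered local maxima
#'
#' Deterministic replacement for interactive Find-Maxima counting. The
#' image is lightly smoothed (Gaussian sigma 1 px); 8-neighborhood local
#' maxima inside the ROI are kept when their height above the local
#' background (the minimum smoothed intensity in a surrounding window)
#' exceeds `prominence`. Candidates closer than `min_distance` are pruned
#' brighter-first, ties broken by lower `(row, col)`. Centroids are refined
#' by background-subtracted intensity weighting in a small window.
#'
#' @param image an [image2d] or matrix.
#' @param roi_mask logical mask; `NULL` means the whole frame.
#' @param min_distance minimum separation between spots in pixels (>= 1).
#' @param prominence minimum height above local background (> 0).
#' @param frame_index frame number recorded in the output (0-based).
#' @return A `spot_set` data.frame: `frame`, `row`, `col` (0-based, may be
#'   fractional), `peak` (smoothed peak height), `mean` (mean raw intensity
#'   over the spot's half-max area), `area` (px of that area).
#' @export
detect_spots <- function(image, roi_mask = NULL, min_distance = 3,
                         prominence, frame_index = 0) {
  m <- if (inherits(image, "image2d")) image$intensity else image
  H <- nrow(m); W <- ncol(m)
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, H, W)
  roi_mask <- as_mask(roi_mask, "roi_mask")
  if (!all(dim(m) == dim(roi_mask)))
    stop("image and roi_mask must share the same shape")
  if (min_distance < 1) stop("min_distance must be >= 1")
  if (prominence <= 0) stop("prominence must be > 0")
  sm <- gaussian_smooth(m, 1)
  # local maxima: >= all 8 neighbors
  is_max <- matrix(TRUE, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (sm >= shift_mat(shift_mat(sm, dr, 1L), dc, 2L))
  }
  cand <- which(is_max & roi_mask, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty_spot_set())
  # prominence over local background (window minimum)
  wr <- max(2L * ceiling(min_distance), 5L)
  vals <- sm[cand]
  bg <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    rr <- max(1, cand[i, 1] - wr):min(H, cand[i, 1] + wr)
    cc <- max(1, cand[i, 2] - wr):min(W, cand[i, 2] + wr)
    bg[i] <- min(sm[rr, cc])
  }
  keep <- (vals - bg) > prominence
  cand <- cand[keep, , drop = FALSE]
  vals <- vals[keep]; bg <- bg[keep]
  if (nrow(cand) == 0) return(empty_spot_set())
  # brighter-first greedy min_distance suppression; ties by lower (row, col)
  ord <- order(-vals, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]; vals <- vals[ord]; bg <- bg[ord]
  acc <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(acc) == 0 ||
        all((cand[acc, 1] - cand[i, 1])^2 + (cand[acc, 2] - cand[i, 2])^2 >=
            min_distance^2))
      acc <- c(acc, i)
  }
  cand <- cand[acc, , drop = FALSE]; vals <- vals[acc]; bg <- bg[acc]
  # centroid refinement + half-max area / mean raw intensity; window capped
  # at 3 px so huge min_distance values cannot drag centroids toward
  # neighboring structures
  rw <- max(1L, min(floor(min_distance / 2), 3L))
  out <- data.frame(frame = integer(0), row = numeric(0), col = numeric(0),
                    peak = numeric(0), mean = numeric(0), area = integer(0))
  for (i in seq_len(nrow(cand))) {
    rr <- max(1, cand[i, 1] - rw):min(H, cand[i, 1] + rw)
    cc <- max(1, cand[i, 2] - rw):min(W, cand[i, 2] + rw)
    w <- pmax(sm[rr, cc, drop = FALSE] - bg[i], 0)
    tw <- sum(w)
    r_ref <- if (tw > 0) sum((rr - 1) * rowSums(w)) / tw else cand[i, 1] - 1
    c_ref <- if (tw > 0) sum((cc - 1) * colSums(w)) / tw else cand[i, 2] - 1
    half <- sm[rr, cc, drop = FALSE] > bg[i] + (vals[i] - bg[i]) / 2
    out[nrow(out) + 1, ] <- list(as.integer(frame_index), r_ref, c_ref,
                                 vals[i] - bg[i],
                                 mean(m[rr, cc, drop = FALSE][half]),
                                 as.integer(sum(half)))
  }
  # stable output order: by frame, then (row, col)
  out <- out[order(out$row, out$col), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("spot_set", "data.frame")
  out
}

empty_spot_set <- function() {
  out <- data.frame(frame = integer(0), row = numeric(0), col = numeric(0),
                    peak = numeric(0), mean = numeric(0), area = integer(0))
  class(out) <- c("spot_set", "data.frame")
  out
}

#' Spot counts per cell and per unit area
#'
#' @param spots a `spot_set` from [detect_spots()].
#' @param roi_mask logical cell mask (non-empty).
#' @param pixel_size micrometers per pixel.
#' @return List with `per_cell` (spots whose centers fall inside the ROI)
#'   and `per_area` (count / um^2 of ROI).
#' @export
spot_density <- function(spots, roi_mask, pixel_size) {
  roi_mask <- as_mask(roi_mask, "roi_mask")
  check_positive_scalar(pixel_size, "pixel_size")
  if (!any(roi_mask)) stop("empty ROI")
  n_in <- 0L
  if (nrow(spots) > 0) {
    ri <- pmin(pmax(round(spots$row) + 1, 1), nrow(roi_mask))
    ci <- pmin(pmax(round(spots$col) + 1, 1), ncol(roi_mask))
    n_in <- sum(roi_mask[cbind(ri, ci)])
  }
  area_um2 <- sum(roi_mask) * pixel_size^2
  list(per_cell = as.integer(n_in), per_area = n_in / area_um2)
}

#' Normalized mean intensity of secreted spots
#'
#' Mean intensity over the spot pixels divided by the mean intensity over
#' all ROI pixels of the same channel, i.e. the per-cell normalization used
#' for secreted-spot intensities.
#'
#' @param image an [image2d] or matrix.
#' @param spot_mask logical mask of secreted-spot pixels (subset of ROI).
#' @param roi_mask logical cell mask.
#' @return Scalar ratio.
#' @export
normalized_spot_intensity <- function(image, spot_mask, roi_mask) {
  m <- if (inherits(image, "image2d")) image$intensity else image
  spot_mask <- as_mask(spot_mask, "spot_mask")
  roi_mask <- as_mask(roi_mask, "roi_mask")
  if (!all(dim(m) == dim(roi_mask)) || !all(dim(spot_mask) == dim(roi_mask)))
    stop("image and masks must share the same shape")
  if (!any(roi_mask)) stop("empty ROI")
  if (!any(spot_mask)) stop("no secreted spots")
  if (any(spot_mask & !roi_mask)) stop("spot_mask must be a subset of roi_mask")
  mean(m[spot_mask]) / mean(m[roi_mask])
}
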