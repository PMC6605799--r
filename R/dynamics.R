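# Vesicle kinetics: greedy nearest-neighbor linking of per-frame
# detections into tracks, per-track velocity / covered-distance metrics,
# kymographs along polylines, and the temporal (time-of-peak) projection.

#' Link per-frame spot detections into tracks
#'
#' Deterministic greedy nearest-neighbor linking, the auditable stand-in
#' for frame-by-frame manual tracking: for each consecutive frame pair,
#' candidate links are taken in increasing centroid distance, each end
#' used at most once, and links longer than `max_disp` are discarded.
#' Unmatched detections start new tracks; there is no gap closing, so
#' frames within a track increase strictly by 1.
#'
#' @param spots a `spot_set` with a `frame` column (0-based frame indices).
#' @param max_disp maximum link length in pixels (> 0).
#' @return A `track_set` data.frame: `track_id`, `frame`, `row`, `col`.
#' @export
link_detections <- function(spots, max_disp) {
  check_positive_scalar(max_disp, "max_disp")
  if (nrow(spots) == 0) {
    out <- data.frame(track_id = integer(0), frame = integer(0),
                      row = numeric(0), col = numeric(0))
    class(out) <- c("track_set", "data.frame")
    return(out)
  }
  spots <- spots[order(spots$frame, spots$row, spots$col), , drop = FALSE]
  frames <- sort(unique(spots$frame))
  by_frame <- split(seq_len(nrow(spots)), spots$frame)
  track_of <- integer(nrow(spots))
  next_id <- 0L
  # open tracks active at the previous frame: spot index of their last point
  prev_idx <- integer(0); prev_frame <- -Inf
  for (f in frames) {
    idx <- by_frame[[as.character(f)]]
    assigned <- rep(FALSE, length(idx))
    if (length(prev_idx) > 0 && f == prev_frame + 1) {
      d2 <- outer(spots$row[prev_idx], spots$row[idx], "-")^2 +
            outer(spots$col[prev_idx], spots$col[idx], "-")^2
      cand <- which(d2 <= max_disp^2, arr.ind = TRUE)
      if (length(cand) > 0) {
        used_prev <- rep(FALSE, length(prev_idx))
        ord <- order(d2[cand])
        cand <- matrix(cand[ord, ], ncol = 2)
        for (k in seq_len(nrow(cand))) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (used_prev[i] || assigned[j]) next
          used_prev[i] <- TRUE; assigned[j] <- TRUE
          track_of[idx[j]] <- track_of[prev_idx[i]]
        }
      }
    }
    for (j in which(!assigned)) {
      next_id <- next_id + 1L
      track_of[idx[j]] <- next_id
    }
    prev_idx <- idx
    prev_frame <- f
  }
  out <- data.frame(track_id = track_of, frame = as.integer(spots$frame),
                    row = spots$row, col = spots$col)
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("track_set", "data.frame")
  out
}

#' Per-track velocity and covered distance
#'
#' Track length `L` is the covered distance (sum of step lengths, um);
#' velocity `v` is the mean path speed `L / ((n - 1) * frame_interval)`.
#' Single-point tracks get `v = 0`, `L = 0` and are flagged.
#'
#' @param tracks a `track_set` from [link_detections()].
#' @param pixel_size micrometers per pixel.
#' @param frame_interval seconds per frame.
#' @return data.frame: `track_id`, `n_points`, `length_um`, `v_um_s`,
#'   `single_point`.
#' @export
track_metrics <- function(tracks, pixel_size, frame_interval) {
  check_positive_scalar(pixel_size, "pixel_size")
  check_positive_scalar(frame_interval, "frame_interval")
  ids <- unique(tracks$track_id)
  out <- data.frame(track_id = ids, n_points = 0L, length_um = 0,
                    v_um_s = 0, single_point = FALSE)
  for (k in seq_along(ids)) {
    t <- tracks[tracks$track_id == ids[k], , drop = FALSE]
    t <- t[order(t$frame), , drop = FALSE]
    n <- nrow(t)
    out$n_points[k] <- n
    if (n < 2) {
      out$single_point[k] <- TRUE
      next
    }
    L <- sum(sqrt(diff(t$row)^2 + diff(t$col)^2)) * pixel_size
    out$length_um[k] <- L
    out$v_um_s[k] <- L / ((n - 1) * frame_interval)
  }
  out
}

# cumulative arc length of a polyline (rows = vertices, (row, col))
polyline_arclength <- function(path) {
  if (nrow(path) < 2) return(0)
  sum(sqrt(rowSums(diff(path)^2)))
}

# point and unit tangent at arc length s along a polyline; s clamped to
# [0, total length]
point_along_path <- function(path, s) {
  seg <- sqrt(rowSums(diff(path)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  s <- pmin(pmax(s, 0), total)
  out_p <- matrix(0, length(s), 2)
  out_t <- matrix(0, length(s), 2)
  for (i in seq_along(s)) {
    k <- findInterval(s[i], cum, rightmost.closed = TRUE)
    k <- min(max(k, 1L), length(seg))
    f <- if (seg[k] > 0) (s[i] - cum[k]) / seg[k] else 0
    out_p[i, ] <- path[k, ] + f * (path[k + 1, ] - path[k, ])
    tv <- path[k + 1, ] - path[k, ]
    nt <- sqrt(sum(tv^2))
    out_t[i, ] <- if (nt > 0) tv / nt else c(0, 0)
  }
  list(point = out_p, tangent = out_t)
}

#' Kymograph (space-time plot) along a polyline
#'
#' Samples each frame by bilinear interpolation at unit-arc-length steps
#' along the path (rows) for every frame (columns), averaging over
#' `line_width` perpendicular 1-px offsets, the reslice convention of the
#' usual time-lapse tools.
#'
#' @param stack an [image_stack].
#' @param path polyline vertex matrix, 0-based `(row, col)`, inside the
#'   image bounds.
#' @param line_width odd integer >= 1; perpendicular averaging width (px).
#' @return A `kymograph`: list with `values` (matrix, ceil(arc length) + 1
#'   rows x n_frames cols), `path`, `line_width`, `frame_interval`,
#'   `pixel_size`.
#' @export
make_kymograph <- function(stack, path, line_width = 3) {
  stopifnot(inherits(stack, "image_stack"))
  path <- as.matrix(path)
  if (ncol(path) != 2 || nrow(path) < 2) stop("path must be an n x 2 matrix")
  if (line_width < 1 || line_width %% 2 != 1)
    stop("line_width must be an odd integer >= 1")
  H <- nrow(stack$frames[[1]]); W <- ncol(stack$frames[[1]])
  if (any(path[, 1] < 0 | path[, 1] > H - 1 | path[, 2] < 0 | path[, 2] > W - 1))
    stop("path outside image bounds")
  total <- polyline_arclength(path)
  s <- 0:ceiling(total)
  pt <- point_along_path(path, pmin(s, total))
  normal <- cbind(-pt$tangent[, 2], pt$tangent[, 1])
  offs <- seq(-(line_width - 1) / 2, (line_width - 1) / 2)
  vals <- matrix(0, length(s), length(stack$frames))
  for (t in seq_along(stack$frames)) {
    m <- stack$frames[[t]]
    acc <- numeric(length(s))
    for (o in offs) {
      acc <- acc + bilinear_at(m, pt$point[, 1] + o * normal[, 1],
                               pt$point[, 2] + o * normal[, 2])
    }
    vals[, t] <- acc / length(offs)
  }
  structure(list(values = vals, path = path, line_width = line_width,
                 frame_interval = stack$frame_interval,
                 pixel_size = stack$pixel_size),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d arc samples x %d frames (line width %d px)\n",
              nrow(x$values), ncol(x$values), x$line_width))
  invisible(x)
}

#' Temporal (time-of-peak) projection of a stack
#'
#' Per-pixel maximum intensity over time plus the 0-based index of the
#' earliest frame achieving it — the information content of a
#' temporal-color-code rendering.
#'
#' @param stack an [image_stack] with >= 2 frames.
#' @return A `temporal_projection`: list with `max` (matrix) and `argmax`
#'   (integer matrix of 0-based frame indices; ties take the earliest
#'   frame).
#' @export
temporal_projection <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (length(stack$frames) < 2) stop("need at least 2 frames")
  mx <- stack$frames[[1]]
  am <- matrix(0L, nrow(mx), ncol(mx))
  for (t in seq_along(stack$frames)[-1]) {
    f <- stack$frames[[t]]
    upd <- f > mx
    mx[upd] <- f[upd]
    am[upd] <- t - 1L
  }
  structure(list(max = mx, argmax = am), class = "temporal_projection")
}
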