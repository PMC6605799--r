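# Colocalization (object-based and Pearson), the pulse-chase secreted
# fraction, and the two-sample comparison used for group statistics.

#' Object-based colocalization of two spot sets
#'
#' Deterministic surrogate for per-vesicle manual colocalization calls:
#' within each frame, spots of A and B are matched one-to-one greedily in
#' increasing centroid distance, cut at `radius`. The reported fraction is
#' matched A spots over all A spots; call with the arguments swapped for
#' the B-in-A fraction.
#'
#' @param spots_A,spots_B `spot_set` data.frames (columns `frame`, `row`,
#'   `col`). Spots are compared within the same frame only.
#' @param radius maximum match distance in pixels (> 0); default 3 px,
#'   about one vesicle radius.
#' @return A `coloc_result`: list with `fraction_A_in_B`, `n_A`, `n_B`,
#'   `matches` (data.frame `index_A`, `index_B`, `distance_px`, `frame`).
#' @export
object_colocalization <- function(spots_A, spots_B, radius = 3) {
  check_positive_scalar(radius, "radius")
  if (nrow(spots_A) == 0) stop("no reference objects")
  matches <- data.frame(index_A = integer(0), index_B = integer(0),
                        distance_px = numeric(0), frame = integer(0))
  if (nrow(spots_B) > 0) {
    for (f in intersect(unique(spots_A$frame), unique(spots_B$frame))) {
      ia <- which(spots_A$frame == f)
      ib <- which(spots_B$frame == f)
      d2 <- outer(spots_A$row[ia], spots_B$row[ib], "-")^2 +
            outer(spots_A$col[ia], spots_B$col[ib], "-")^2
      cand <- which(d2 <= radius^2, arr.ind = TRUE)
      if (length(cand) == 0) next
      cand <- matrix(cand[order(d2[cand]), ], ncol = 2)
      used_a <- rep(FALSE, length(ia)); used_b <- rep(FALSE, length(ib))
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (used_a[i] || used_b[j]) next
        used_a[i] <- TRUE; used_b[j] <- TRUE
        matches[nrow(matches) + 1, ] <- list(ia[i], ib[j],
                                             sqrt(d2[i, j]), as.integer(f))
      }
    }
  }
  structure(list(fraction_A_in_B = nrow(matches) / nrow(spots_A),
                 n_A = nrow(spots_A), n_B = nrow(spots_B),
                 matches = matches),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %.3f of %d A spots matched (%d B spots)\n",
              x$fraction_A_in_B, x$n_A, x$n_B))
  invisible(x)
}

#' Pearson correlation of two channels over a ROI
#'
#' @param img_A,img_B [image2d] objects or matrices of the same shape.
#' @param roi_mask logical mask with >= 2 pixels and nonzero variance in
#'   both channels.
#' @return Pearson's r in `[-1, 1]`.
#' @export
pearson_coefficient <- function(img_A, img_B, roi_mask) {
  a <- if (inherits(img_A, "image2d")) img_A$intensity else img_A
  b <- if (inherits(img_B, "image2d")) img_B$intensity else img_B
  roi_mask <- as_mask(roi_mask, "roi_mask")
  if (!all(dim(a) == dim(b)) || !all(dim(a) == dim(roi_mask)))
    stop("images and ROI must share the same shape")
  x <- a[roi_mask]; y <- b[roi_mask]
  if (length(x) < 2) stop("ROI must contain at least 2 pixels")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined correlation: zero variance in a channel")
  stats::cor(x, y)
}

#' Secreted fraction from supernatant and lysate band intensities
#'
#' `F = supernatant / (supernatant + lysate)` per chase time point — the
#' normalization used for puromycin pulse-chase (SUnSET-style) secretion
#' time courses. Vectorized over time points.
#'
#' @param supernatant,lysate non-negative band intensities (equal length).
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
secreted_fraction <- function(supernatant, lysate) {
  if (length(supernatant) != length(lysate))
    stop("supernatant and lysate must have equal length")
  if (any(supernatant < 0) || any(lysate < 0))
    stop("intensities must be non-negative")
  tot <- supernatant + lysate
  if (any(tot == 0)) stop("supernatant and lysate both zero: fraction undefined")
  supernatant / tot
}

#' Two-sample comparison with Student's t test
#'
#' Pooled-variance Student's t by default (`welch = TRUE` for unequal
#' variances), two-sided, with per-group mean +/- SEM summaries.
#'
#' @param values_A,values_B numeric vectors, each of length >= 2.
#' @param welch use Welch's unequal-variance t test.
#' @return List with `t`, `p`, `df` and `summary` (data.frame `group`,
#'   `n`, `mean`, `sem`).
#' @export
compare_groups <- function(values_A, values_B, welch = FALSE) {
  if (length(values_A) < 2 || length(values_B) < 2)
    stop("each group needs n >= 2")
  tt <- stats::t.test(values_A, values_B, var.equal = !welch)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter),
       summary = data.frame(
         group = c("A", "B"),
         n = c(length(values_A), length(values_B)),
         mean = c(mean(values_A), mean(values_B)),
         sem = c(sem(values_A), sem(values_B))))
}
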