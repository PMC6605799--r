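# Fixtures and independent oracles, built in code.

# exhaustive nearest-true-pixel Euclidean distance (px) — the brute-force
# oracle for the distance transform
brute_edt <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  H <- nrow(mask); W <- ncol(mask)
  rr <- matrix(rep(seq_len(H), W), H)
  cc <- matrix(rep(seq_len(W), each = H), H)
  d <- matrix(Inf, H, W)
  for (k in seq_len(nrow(idx)))
    d <- pmin(d, sqrt((rr - idx[k, 1])^2 + (cc - idx[k, 2])^2))
  d
}

# recursive flood-fill 8-connected component count — labeling oracle
brute_component_count <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  n <- 0L
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    n <- n + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- (p - 1) %% H + 1; c <- (p - 1) %/% H + 1
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- r + dr; c2 <- c + dc
        if (r2 < 1 || r2 > H || c2 < 1 || c2 > W) next
        q <- (c2 - 1) * H + r2
        if (mask[q] && !seen[q]) { seen[q] <- TRUE; queue <- c(queue, q) }
      }
    }
  }
  n
}

# disks of given radius rendered as hard-edged amplitude plateaus
disk_image <- function(shape, centers, radius, amplitude) {
  H <- shape[1]; W <- shape[2]
  rr <- matrix(rep(0:(H - 1), W), H)
  cc <- matrix(rep(0:(W - 1), each = H), H)
  img <- matrix(0, H, W)
  for (k in seq_len(nrow(centers)))
    img[(rr - centers[k, 1])^2 + (cc - centers[k, 2])^2 <= radius^2] <- amplitude
  img
}

# sum of isotropic Gaussian peaks, analytic (0-based centers)
gaussian_peaks_image <- function(shape, centers, amplitude, sigma) {
  H <- shape[1]; W <- shape[2]
  rr <- matrix(rep(0:(H - 1), W), H)
  cc <- matrix(rep(0:(W - 1), each = H), H)
  img <- matrix(0, H, W)
  for (k in seq_len(nrow(centers)))
    img <- img + amplitude *
      exp(-((rr - centers[k, 1])^2 + (cc - centers[k, 2])^2) / (2 * sigma^2))
  img
}

# rectangle ROI polygon enclosing pixel centers rows r0..r1, cols c0..c1
rect_roi <- function(r0, r1, c0, c1) {
  cell_roi(rbind(c(r0 - 0.5, c0 - 0.5), c(r0 - 0.5, c1 + 0.5),
                 c(r1 + 0.5, c1 + 0.5), c(r1 + 0.5, c0 - 0.5)))
}

# spot_set from bare (frame, row, col)
spots_df <- function(frame, row, col) {
  n <- length(frame)
  out <- data.frame(frame = frame, row = row, col = col,
                    peak = rep(1, n), mean = rep(1, n), area = rep(1L, n))
  class(out) <- c("spot_set", "data.frame")
  out
}

# random blob mask for property tests
random_mask <- function(H, W, p = 0.1) matrix(runif(H * W) < p, H, W)
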