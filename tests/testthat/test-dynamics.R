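test_that("link_detections handles static, parallel and jumping particles", {
  # one static spot over 10 frames -> one track, L = v = 0
  sp <- spots_df(0:9, rep(5, 10), rep(5, 10))
  tr <- link_detections(sp, max_disp = 3)
  expect_equal(length(unique(tr$track_id)), 1)
  m <- track_metrics(tr, 0.1, 0.5)
  expect_equal(m$length_um, 0)
  expect_equal(m$v_um_s, 0)
  expect_equal(m$n_points, 10L)
  # two parallel particles 20 px apart, 2 px/frame, max_disp 5: no swap
  # [oracle: on each frame pair the optimal assignment links same-row pairs]
  f <- rep(0:9, each = 2)
  rows <- rep(c(10, 30), 10)
  cols <- as.vector(vapply(0:9, function(t) rep(5 + 2 * t, 2), numeric(2)))
  tr2 <- link_detections(spots_df(f, rows, cols), max_disp = 5)
  expect_equal(length(unique(tr2$track_id)), 2)
  for (id in unique(tr2$track_id)) {
    t <- tr2[tr2$track_id == id, ]
    expect_equal(length(unique(t$row)), 1) # stayed on its own lane
    expect_equal(nrow(t), 10)
  }
  # jumps beyond max_disp break every link
  sp3 <- spots_df(0:9, rep(5, 10), 10 * (0:9))
  tr3 <- link_detections(sp3, max_disp = 5)
  expect_equal(length(unique(tr3$track_id)), 10)
})

test_that("linking never exceeds max_disp and never merges co-frame spots", {
  withr::local_seed(31)
  for (rep_i in 1:5) {
    n <- 40
    sp <- spots_df(sample(0:7, n, replace = TRUE),
                   runif(n, 0, 60), runif(n, 0, 60))
    sp <- sp[!duplicated(sp[c("frame", "row", "col")]), ]
    tr <- link_detections(sp, max_disp = 8)
    expect_equal(nrow(tr), nrow(sp)) # every detection appears exactly once
    for (id in unique(tr$track_id)) {
      t <- tr[tr$track_id == id, ]
      t <- t[order(t$frame), ]
      if (nrow(t) > 1) {
        expect_true(all(diff(t$frame) == 1)) # no gap closing
        expect_true(all(sqrt(diff(t$row)^2 + diff(t$col)^2) <= 8 + 1e-9))
      }
    }
    # one point per (track, frame)
    expect_false(any(duplicated(tr[c("track_id", "frame")])))
  }
})

test_that("track_metrics applies the closed-form calibration", {
  # steps of 3 px/frame at 0.2 um/px, 0.5 s -> v = 1.2 um/s
  sp <- spots_df(0:4, rep(0, 5), 3 * (0:4))
  tr <- link_detections(sp, max_disp = 4)
  m <- track_metrics(tr, 0.2, 0.5)
  expect_equal(m$v_um_s, 1.2)
  expect_equal(m$length_um, 4 * 3 * 0.2)
  expect_false(m$single_point)
  # single-point tracks are flagged with v = L = 0
  m1 <- track_metrics(link_detections(spots_df(0L, 1, 1), 2), 0.1, 0.1)
  expect_true(m1$single_point)
  expect_equal(m1$v_um_s, 0)
})

test_that("programmed vesicle speed is recovered from rendered movies", {
  cfg <- simulation_config(speed_um_s = 0.8, pixel_size = 0.1,
                           frame_interval_s = 0.2, n_vesicles = 20,
                           n_frames = 20, seed = 19, amplitude = 300,
                           background = 10, image_shape = c(256, 256))
  mv <- simulate_vesicle_movie(cfg)
  spots <- do.call(rbind, lapply(seq_along(mv$stack$frames), function(t)
    detect_spots(mv$stack$frames[[t]], NULL, min_distance = 3,
                 prominence = 60, frame_index = t - 1L)))
  tracks <- link_detections(spots, max_disp = 4)
  m <- track_metrics(tracks, 0.1, 0.2)
  m <- m[m$n_points >= 5, ]
  expect_gt(nrow(m), 10)
  expect_lt(abs(mean(m$v_um_s) - 0.8) / 0.8, 0.05)
})

test_that("kymographs respect geometry, time structure and contracts", {
  frames <- lapply(1:6, function(t) matrix(t, 32, 32))
  st <- image_stack(frames, 0.1, 0.5)
  path <- rbind(c(5, 2), c(5, 29))
  ky <- make_kymograph(st, path, 1)
  expect_equal(dim(ky$values), c(28, 6)) # ceil(27) + 1 rows
  # static movie modulo global scaling: columns proportional
  expect_true(all(apply(ky$values, 2, function(col) length(unique(col))) == 1))
  expect_error(make_kymograph(st, path, 2), "odd")
  expect_error(make_kymograph(st, rbind(c(5, 2), c(5, 40)), 1), "bounds")
  # time reversal flips columns
  withr::local_seed(23)
  frames2 <- lapply(1:6, function(t) matrix(runif(32 * 32), 32, 32))
  st2 <- image_stack(frames2, 0.1, 0.5)
  ky_f <- make_kymograph(st2, path, 3)
  ky_r <- make_kymograph(image_stack(rev(frames2), 0.1, 0.5), path, 3)
  expect_equal(ky_f$values, ky_r$values[, 6:1])
})

test_that("a constant-speed particle draws a streak of matching slope", {
  u <- 2.5 # px/frame along the path
  n_frames <- 10
  frames <- lapply(seq_len(n_frames), function(t)
    gaussian_peaks_image(c(24, 64), rbind(c(11, 5 + u * (t - 1))), 100, 1.5))
  st <- image_stack(frames, 0.1, 0.2)
  ky <- make_kymograph(st, rbind(c(11, 0), c(11, 63)), 3)
  peak_row <- apply(ky$values, 2, which.max) - 1
  fit <- stats::lm(peak_row ~ seq(0, n_frames - 1))
  expect_lt(abs(unname(stats::coef(fit)[2]) - u) / u, 0.10)
})

test_that("temporal projection takes per-pixel max with earliest-tie argmax", {
  frames <- lapply(1:9, function(t) matrix(1, 16, 16))
  frames[[8]][5, 5] <- 50 # bright only at frame index 7
  st <- image_stack(frames, 0.1, 0.5)
  tp <- temporal_projection(st)
  expect_equal(tp$argmax[5, 5], 7L)
  expect_equal(tp$max[5, 5], 50)
  expect_true(all(tp$argmax[-(5 + 16 * 4)] == 0L)) # constant pixels: frame 0
  # moving-particle argmax advances monotonically along the path
  u <- 3
  frames2 <- lapply(1:10, function(t)
    gaussian_peaks_image(c(24, 64), rbind(c(12, 4 + u * (t - 1))), 100, 1.5))
  tp2 <- temporal_projection(image_stack(frames2, 0.1, 0.2))
  am <- tp2$argmax[13, 5 + u * (0:9)] # pixels under the trajectory
  expect_true(all(diff(am) >= 0))
  expect_error(temporal_projection(image_stack(frames2[1], 0.1, 0.2)),
               "2 frames")
})
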