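test_that("config validation enforces the stated invariants", {
  expect_error(simulation_config(pixel_size = 0), "pixel_size")
  expect_error(simulation_config(n_fas = -1), "n_fas")
  expect_error(simulation_config(frame_interval_s = 0), "frame_interval_s")
  expect_error(simulation_config(speed_um_s = -1), "speed_um_s")
  cfg <- simulation_config(roi = list(type = "ellipse",
                                      center = c(128, 128), axes = c(200, 90)))
  expect_error(simulate_cell_scene(cfg), "ROI outside image")
  expect_error(
    simulate_cell_scene(simulation_config(n_fas = 0,
                                          cargo_mode = "fa_proximal")),
    "no FAs to anchor cargo")
})

test_that("scenes are deterministic and honor configured counts", {
  cfg <- simulation_config(n_fas = 5, n_spots = 12, seed = 7,
                           image_shape = c(128, 128))
  a <- simulate_cell_scene(cfg)
  b <- simulate_cell_scene(cfg)
  expect_identical(a$fa_image$intensity, b$fa_image$intensity)
  expect_identical(a$cargo_image$intensity, b$cargo_image$intensity)
  expect_identical(a$truth$spot_centers, b$truth$spot_centers)
  expect_equal(nrow(a$truth$fa_centroids), 5)
  expect_equal(nrow(a$truth$spot_centers), 12)
  # n_spots = 0 -> pure background cargo channel, empty truth
  c0 <- simulate_cell_scene(simulation_config(n_fas = 5, n_spots = 0,
                                              seed = 7, shot_noise = FALSE,
                                              gaussian_read_noise_sd = 0,
                                              image_shape = c(96, 96)))
  expect_equal(nrow(c0$truth$spot_centers), 0)
  expect_true(all(c0$cargo_image$intensity == c0$truth$config$background))
})

test_that("noiseless FA channel thresholds into exactly n_fas components", {
  cfg <- simulation_config(n_fas = 5, n_spots = 0, seed = 7,
                           background = 0, gaussian_read_noise_sd = 0,
                           shot_noise = FALSE, amplitude = 1000,
                           image_shape = c(160, 160))
  s <- simulate_cell_scene(cfg)
  fg <- s$fa_image$intensity > 500 # half maximum
  expect_equal(brute_component_count(fg), 5) # [oracle: flood-fill labeling]
  # ground-truth mask itself has 5 components and matches the render
  expect_equal(brute_component_count(s$truth$fa_mask), 5)
})

test_that("truth distances equal brute-force recomputation from the mask", {
  cfg <- simulation_config(n_fas = 8, n_spots = 40, seed = 21,
                           image_shape = c(128, 128))
  s <- simulate_cell_scene(cfg)
  pts <- as.matrix(s$truth$spot_centers[, c("row", "col")])
  fa <- which(s$truth$fa_mask, arr.ind = TRUE) - 1
  for (i in seq_len(nrow(pts))) {
    d <- sqrt(min((fa[, 1] - pts[i, 1])^2 + (fa[, 2] - pts[i, 2])^2)) * 0.1
    expect_equal(s$truth$spot_centers$dist_um[i], d)
  }
})

test_that("fa_proximal offsets follow the half-normal scale", {
  cfg <- simulation_config(n_fas = 12, n_spots = 600, seed = 13,
                           offset_scale_um = 0.5, image_shape = c(256, 256))
  s <- simulate_cell_scene(cfg)
  m <- mean(s$truth$spot_centers$dist_um)
  expect_lt(abs(m - 0.5 * sqrt(2 / pi)) / (0.5 * sqrt(2 / pi)), 0.10)
})

test_that("uniform cargo spreads evenly over the ROI", {
  cfg <- simulation_config(cargo_mode = "uniform", n_fas = 0, n_spots = 1200,
                           seed = 17, image_shape = c(200, 200))
  s <- simulate_cell_scene(cfg)
  roi <- s$truth$roi_mask
  pts <- s$truth$spot_centers
  # split the ROI into left/right halves of equal pixel area by column
  csum <- cumsum(colSums(roi))
  split_col <- which(csum >= csum[length(csum)] / 2)[1]
  n_left_px <- csum[split_col]
  p <- n_left_px / sum(roi)
  n_left <- sum(round(pts$col) + 1 <= split_col)
  # 3-sigma binomial bound around the area fraction
  sigma <- sqrt(nrow(pts) * p * (1 - p))
  expect_lt(abs(n_left - nrow(pts) * p), 3 * sigma)
})

test_that("hard-core spot placement enforces the minimum separation", {
  cfg <- simulation_config(cargo_mode = "uniform", n_fas = 0, n_spots = 60,
                           min_spot_separation_px = 8, seed = 29,
                           image_shape = c(200, 200))
  s <- simulate_cell_scene(cfg)
  p <- s$truth$spot_centers
  d <- as.matrix(stats::dist(cbind(p$row, p$col)))
  diag(d) <- Inf
  expect_gte(min(d), 8)
  expect_error(simulation_config(min_spot_separation_px = -1),
               "min_spot_separation_px")
})

test_that("movies honor speed closed forms and determinism", {
  # static case
  st0 <- simulate_vesicle_movie(simulation_config(speed_um_s = 0,
                                                  n_vesicles = 3,
                                                  n_frames = 5, seed = 2,
                                                  image_shape = c(64, 64)))
  for (id in unique(st0$truth$tracks$track_id)) {
    t <- st0$truth$tracks[st0$truth$tracks$track_id == id, ]
    expect_equal(diff(t$row), rep(0, 4))
    expect_equal(diff(t$col), rep(0, 4))
  }
  # v * dt / s = 1.0 * 0.2 / 0.1 = 2 px between consecutive frames
  cfg <- simulation_config(speed_um_s = 1, pixel_size = 0.1,
                           frame_interval_s = 0.2, n_vesicles = 4,
                           n_frames = 10, seed = 3, image_shape = c(128, 128))
  st <- simulate_vesicle_movie(cfg)
  tr <- st$truth$tracks
  # project each truth point back onto its polyline to get its arc length:
  # spacing along the path must be exactly 2 px (chords may be shorter at
  # polyline corners)
  arc_of <- function(path, p) {
    cum <- 0
    for (k in seq_len(nrow(path) - 1)) {
      a <- path[k, ]; b <- path[k + 1, ]
      ab <- b - a
      L2 <- sum(ab^2)
      t <- if (L2 > 0) sum((p - a) * ab) / L2 else 0
      if (t >= -1e-9 && t <= 1 + 1e-9 &&
          sqrt(sum((a + pmin(pmax(t, 0), 1) * ab - p)^2)) < 1e-6)
        return(cum + pmin(pmax(t, 0), 1) * sqrt(L2))
      cum <- cum + sqrt(L2)
    }
    NA_real_
  }
  n_paths <- length(st$truth$paths)
  for (id in unique(tr$track_id)) {
    t <- tr[tr$track_id == id, ]
    path <- st$truth$paths[[(id - 1) %% n_paths + 1]]
    s <- vapply(seq_len(nrow(t)),
                function(i) arc_of(path, c(t$row[i], t$col[i])), numeric(1))
    expect_false(any(is.na(s)))
    expect_equal(diff(s), rep(2, length(s) - 1), tolerance = 1e-6)
  }
  # determinism
  st2 <- simulate_vesicle_movie(cfg)
  expect_identical(st$stack$frames, st2$stack$frames)
  expect_identical(st$truth$tracks, st2$truth$tracks)
  expect_error(simulate_vesicle_movie(simulation_config(n_frames = 1)),
               "n_frames")
})

test_that("a vesicle outrunning its polyline stops at the endpoint", {
  cfg <- simulation_config(speed_um_s = 20, pixel_size = 0.1,
                           frame_interval_s = 0.5, n_vesicles = 1,
                           n_frames = 12, seed = 5, image_shape = c(96, 96))
  # 100 px per frame across a 96-px field: must clamp at the path end
  st <- simulate_vesicle_movie(cfg)
  t <- st$truth$tracks
  last <- t[t$frame >= 6, ]
  expect_true(all(abs(diff(last$row)) < 1e-9))
  expect_true(all(abs(diff(last$col)) < 1e-9))
})

test_that("write_simulation produces the TIFF + CSV + JSON sidecar set", {
  dir <- withr::local_tempdir()
  s <- simulate_cell_scene(simulation_config(n_fas = 4, n_spots = 6,
                                             seed = 1,
                                             image_shape = c(64, 64)))
  write_simulation(s, dir)
  expect_true(all(file.exists(file.path(dir,
    c("scene.tif", "fa_mask.tif", "spots_truth.csv",
      "simulation_config.json")))))
  pages <- read_tiff(file.path(dir, "scene.tif"), simplify = FALSE)
  expect_length(pages, 2)
  expect_equal(pages[[1]], s$fa_image$intensity, tolerance = 1e-4,
               ignore_attr = TRUE)
  mask <- read_tiff(file.path(dir, "fa_mask.tif"))
  expect_equal(mask > 0, unname(s$truth$fa_mask), ignore_attr = TRUE)
})
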