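test_that("make_roi_mask follows the pixel-center even-odd rule", {
  # full-frame rectangle
  full <- make_roi_mask(rect_roi(0, 9, 0, 9), c(10, 10))
  expect_true(all(full))
  # rows 2..5, cols 3..7 inclusive -> 4 * 5 = 20 pixels [oracle: enumerate]
  m <- make_roi_mask(rect_roi(2, 5, 3, 7), c(10, 10))
  expect_equal(sum(m), 20)
  expect_true(all(m[3:6, 4:8]))
  # polygon must fit the frame
  expect_error(make_roi_mask(rect_roi(2, 12, 0, 5), c(10, 10)), "fit")
})

test_that("segment_objects counts components and records provenance", {
  # all-zero image -> 0 objects (explicit threshold; Otsu needs contrast)
  roi <- matrix(TRUE, 32, 32)
  z <- segment_objects(matrix(0, 32, 32), roi, sigma = 1, threshold = 0.5)
  expect_equal(z$n_objects, 0)
  # two disjoint noiseless disks -> 2 objects [oracle: flood-fill count]
  img <- disk_image(c(40, 40), rbind(c(10, 10), c(28, 28)), 4, 100)
  roi <- matrix(TRUE, 40, 40)
  seg <- segment_objects(img, roi, sigma = 1, threshold = 50)
  expect_equal(seg$n_objects, 2)
  expect_equal(seg$n_objects, brute_component_count(seg$labels > 0))
  expect_equal(seg$sigma_used, 1)
  expect_equal(seg$threshold_used, 50)
  # threshold above max -> valid empty mask
  expect_equal(segment_objects(img, roi, 1, 101)$n_objects, 0)
  expect_error(segment_objects(img, matrix(FALSE, 40, 40), 1, 50),
               "empty ROI")
})

test_that("segmentation is monotone in threshold and labels stay in ROI", {
  withr::local_seed(42)
  img <- gaussian_peaks_image(c(48, 48),
                              cbind(runif(6, 8, 40), runif(6, 8, 40)),
                              100, 2) + matrix(runif(48 * 48), 48, 48)
  roi <- make_roi_mask(rect_roi(4, 43, 4, 43), c(48, 48))
  prev <- Inf
  for (thr in c(5, 20, 40, 60, 80)) {
    seg <- segment_objects(img, roi, 1, thr)
    px <- sum(seg$labels > 0)
    expect_lte(px, prev)
    prev <- px
    expect_true(all(roi[seg$labels > 0]))
    # contiguous labels 1..n
    if (seg$n_objects > 0)
      expect_setequal(unique(as.vector(seg$labels[seg$labels > 0])),
                      seq_len(seg$n_objects))
  }
})

test_that("label oracle agrees with C labeling on random masks", {
  withr::local_seed(7)
  for (i in 1:20) {
    m <- random_mask(24, 24, p = runif(1, 0.05, 0.5))
    lab <- faprox:::label_components_cpp(m)
    expect_equal(attr(lab, "n_objects"), brute_component_count(m))
  }
})

test_that("detect_spots finds analytic peaks with subpixel accuracy", {
  # constant image: no maxima with positive prominence
  expect_equal(nrow(detect_spots(matrix(5, 32, 32), NULL, 3, 1)), 0)
  # two noiseless Gaussian peaks [oracle: peak positions known]
  img <- gaussian_peaks_image(c(40, 40), rbind(c(10, 10), c(30, 30)), 100, 2)
  sp <- detect_spots(img, NULL, min_distance = 5, prominence = 20)
  expect_equal(nrow(sp), 2)
  err <- pmin(sqrt((sp$row - 10)^2 + (sp$col - 10)^2),
              sqrt((sp$row - 30)^2 + (sp$col - 30)^2))
  expect_true(all(err < 0.5))
  # min_distance larger than separation -> brighter / tie-broken single spot
  sp1 <- detect_spots(img, NULL, min_distance = 40, prominence = 20)
  expect_equal(nrow(sp1), 1)
  expect_lt(sqrt((sp1$row - 10)^2 + (sp1$col - 10)^2), 0.5) # (10,10) by tie
  expect_error(detect_spots(img, NULL, 0.5, 20), "min_distance")
  expect_error(detect_spots(img, NULL, 3, 0), "prominence")
})

test_that("detect_spots recovers every peak of well-separated grids", {
  centers <- as.matrix(expand.grid(row = c(8, 24, 40), col = c(8, 24, 40)))
  img <- gaussian_peaks_image(c(48, 48), centers, 80, 1.5)
  sp <- detect_spots(img, NULL, min_distance = 4, prominence = 10)
  expect_equal(nrow(sp), nrow(centers))
  for (k in seq_len(nrow(centers))) {
    d <- sqrt((sp$row - centers[k, 1])^2 + (sp$col - centers[k, 2])^2)
    expect_lt(min(d), 0.5)
  }
})

test_that("count_objects filters by area and matches a pixel-histogram recount", {
  img <- disk_image(c(40, 40), rbind(c(8, 8), c(30, 30)), 4, 100) +
    disk_image(c(40, 40), rbind(c(8, 30)), 1, 100)
  seg <- segment_objects(img, matrix(TRUE, 40, 40), 0, 50)
  expect_equal(count_objects(seg, 0), seg$n_objects)
  areas <- tabulate(seg$labels[seg$labels > 0], seg$n_objects)
  expect_equal(count_objects(seg, 10), sum(areas >= 10)) # big disks only
  expect_equal(count_objects(seg, 10), 2)
  expect_error(count_objects(seg, -1), "non-negative")
})

test_that("spot_density normalizes per cell and per area", {
  roi <- make_roi_mask(rect_roi(0, 99, 0, 99), c(100, 100))
  # ROI is 100 x 100 px at 0.1 um/px -> 100 um^2
  sp <- spots_df(rep(0L, 10), seq(5, 95, 10), seq(5, 95, 10))
  d <- spot_density(sp, roi, 0.1)
  expect_equal(d$per_cell, 10L)
  expect_equal(d$per_area, 0.1)
  d0 <- spot_density(spots_df(integer(0), numeric(0), numeric(0)), roi, 0.1)
  expect_equal(d0$per_cell, 0L)
  expect_equal(d0$per_area, 0)
  expect_error(spot_density(sp, matrix(FALSE, 100, 100), 0.1), "empty ROI")
})

test_that("normalized_spot_intensity is a mean ratio, scale invariant", {
  withr::local_seed(3)
  img <- matrix(runif(400, 1, 10), 20, 20)
  roi <- matrix(TRUE, 20, 20)
  spot <- matrix(FALSE, 20, 20); spot[5:8, 5:8] <- TRUE
  # uniform image -> 1 for any spot mask
  expect_equal(normalized_spot_intensity(matrix(7, 20, 20), spot, roi), 1)
  # constructed ratio: ROI mean 10, spot mean 50
  img2 <- matrix(0, 20, 20)
  img2[spot] <- 50
  img2[!spot] <- (10 * 400 - 50 * 16) / (400 - 16)
  expect_equal(normalized_spot_intensity(img2, spot, roi), 5)
  # identity mask and positive scaling
  expect_equal(normalized_spot_intensity(img, roi, roi), 1)
  r <- normalized_spot_intensity(img, spot, roi)
  expect_equal(normalized_spot_intensity(img * 17.3, spot, roi), r)
  expect_error(normalized_spot_intensity(img, matrix(FALSE, 20, 20), roi),
               "no secreted spots")
  spot_out <- spot; spot_out[1, 1] <- TRUE
  roi2 <- roi; roi2[1, 1] <- FALSE
  expect_error(normalized_spot_intensity(img, spot_out, roi2), "subset")
})
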