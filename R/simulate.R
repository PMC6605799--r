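# Seeded synthetic-microscopy generator with ground truth. Emulates the
# imaging geometry of the analysed experiments: an elliptical (or polygon)
# cell ROI, elongated focal-adhesion blobs near the cell edge oriented
# radially (paxillin-like), a cargo channel whose spots are placed either
# at controlled half-normal offsets from FA boundaries, uniformly over the
# cell (the homogeneous-membrane-marker control) or on FAs, and vesicle
# movies with particles moving along polyline tracks at programmed speeds.
# Rendering: Gaussian PSF, Poisson shot noise on signal + background, and
# Gaussian read noise (the standard camera model).

#' Simulation configuration
#'
#' Defaults describe a realistic TIRF-like field of a single adherent
#' cell: 256 x 256 px at 0.1 um/px (25.6 um field), ~20 FAs of about
#' 1.2 x 0.4 um at the cell margin, diffraction-limited spots
#' (sigma 1.5 px), peak signal 200 photons over a 10-photon background
#' with 2-photon read noise (peak SNR well above 5).
#'
#' @param image_shape integer `(H, W)` in pixels.
#' @param pixel_size micrometers per pixel (> 0).
#' @param seed integer seed; the same seed and config give bit-identical
#'   output.
#' @param roi `NULL` for the default centered ellipse (semi-axes 0.42 of
#'   the image), or `list(type = "ellipse", center = c(r, c), axes =
#'   c(ar, ac))`, or `list(type = "polygon", vertices = <n x 2 matrix>)`
#'   (0-based pixel coordinates).
#' @param n_fas number of focal-adhesion blobs.
#' @param fa_length_px,fa_width_px FA blob axes (full width at half
#'   maximum, px).
#' @param cargo_mode `"fa_proximal"`, `"uniform"` or `"on_fa"`.
#' @param offset_scale_um scale `d0` of the half-normal FA-boundary offset
#'   used in `fa_proximal` mode (um).
#' @param n_spots number of cargo spots.
#' @param min_spot_separation_px hard-core distance between cargo spot
#'   centers (0 disables; placement retries up to 100 times per spot).
#'   Emulates the physical size of vesicles when resolvable spots are
#'   required.
#' @param spot_sigma_px PSF width of rendered spots (px).
#' @param amplitude peak signal photons per spot / FA blob.
#' @param background background photons per pixel.
#' @param gaussian_read_noise_sd read noise sd (photons).
#' @param shot_noise apply Poisson shot noise (disable together with
#'   `background = 0`, `gaussian_read_noise_sd = 0` for a noiseless
#'   render).
#' @param n_vesicles,n_frames,frame_interval_s,speed_um_s,tracks_share_paths
#'   movie parameters: number of moving vesicles, frames, seconds per
#'   frame, programmed speed, and whether several vesicles reuse the same
#'   polyline at staggered start times.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(image_shape = c(256L, 256L),
                              pixel_size = 0.1,
                              seed = 1L,
                              roi = NULL,
                              n_fas = 20L,
                              fa_length_px = 12,
                              fa_width_px = 4,
                              cargo_mode = c("fa_proximal", "uniform", "on_fa"),
                              offset_scale_um = 0.5,
                              n_spots = 50L,
                              min_spot_separation_px = 0,
                              spot_sigma_px = 1.5,
                              amplitude = 200,
                              background = 10,
                              gaussian_read_noise_sd = 2,
                              shot_noise = TRUE,
                              n_vesicles = 10L,
                              n_frames = 30L,
                              frame_interval_s = 0.2,
                              speed_um_s = 0.8,
                              tracks_share_paths = FALSE) {
  cargo_mode <- match.arg(cargo_mode)
  check_positive_scalar(pixel_size, "pixel_size")
  check_positive_scalar(frame_interval_s, "frame_interval_s")
  check_count(n_fas, "n_fas"); check_count(n_spots, "n_spots")
  check_count(n_vesicles, "n_vesicles")
  if (length(image_shape) != 2 || any(image_shape < 8))
    stop("image_shape must be (H, W), each >= 8")
  if (speed_um_s < 0) stop("speed_um_s must be >= 0")
  if (background < 0 || gaussian_read_noise_sd < 0)
    stop("noise parameters must be >= 0")
  if (min_spot_separation_px < 0)
    stop("min_spot_separation_px must be >= 0")
  if (is.null(roi)) {
    H <- image_shape[1]; W <- image_shape[2]
    roi <- list(type = "ellipse", center = c((H - 1) / 2, (W - 1) / 2),
                axes = c(0.42 * H, 0.42 * W))
  }
  cfg <- list(image_shape = as.integer(image_shape), pixel_size = pixel_size,
              seed = as.integer(seed), roi = roi, n_fas = as.integer(n_fas),
              fa_length_px = fa_length_px, fa_width_px = fa_width_px,
              cargo_mode = cargo_mode, offset_scale_um = offset_scale_um,
              n_spots = as.integer(n_spots),
              min_spot_separation_px = min_spot_separation_px,
              spot_sigma_px = spot_sigma_px,
              amplitude = amplitude, background = background,
              gaussian_read_noise_sd = gaussian_read_noise_sd,
              shot_noise = isTRUE(shot_noise),
              n_vesicles = as.integer(n_vesicles),
              n_frames = as.integer(n_frames),
              frame_interval_s = frame_interval_s,
              speed_um_s = speed_um_s,
              tracks_share_paths = isTRUE(tracks_share_paths))
  class(cfg) <- "simulation_config"
  cfg
}

# binary ROI mask from a config's roi spec; errors when the ROI does not
# fit inside the image
config_roi_mask <- function(cfg) {
  H <- cfg$image_shape[1]; W <- cfg$image_shape[2]
  roi <- cfg$roi
  if (identical(roi$type, "ellipse")) {
    ctr <- roi$center; ax <- roi$axes
    if (ctr[1] - ax[1] < -0.5 || ctr[1] + ax[1] > H - 0.5 ||
        ctr[2] - ax[2] < -0.5 || ctr[2] + ax[2] > W - 0.5)
      stop("ROI outside image")
    rr <- matrix(rep(0:(H - 1), W), H)
    cc <- matrix(rep(0:(W - 1), each = H), H)
    ((rr - ctr[1]) / ax[1])^2 + ((cc - ctr[2]) / ax[2])^2 <= 1
  } else if (identical(roi$type, "polygon")) {
    make_roi_mask(cell_roi(roi$vertices), c(H, W))
  } else stop("roi$type must be 'ellipse' or 'polygon'")
}

# rotated-ellipse FA footprint (half-maximum contour of an anisotropic
# Gaussian): center (r0, c0), FWHM axes, orientation theta (radians,
# long axis); returns 0-based (row, col) pixel coordinates
fa_footprint_pixels <- function(center, length_px, width_px, theta, shape) {
  a <- length_px / 2; b <- width_px / 2
  r5 <- ceiling(max(a, b)) + 1
  rr <- max(0, floor(center[1] - r5)):min(shape[1] - 1, ceiling(center[1] + r5))
  cc <- max(0, floor(center[2] - r5)):min(shape[2] - 1, ceiling(center[2] + r5))
  g <- expand.grid(row = rr, col = cc)
  dr <- g$row - center[1]; dc <- g$col - center[2]
  u <- dr * cos(theta) + dc * sin(theta)   # along long axis
  v <- -dr * sin(theta) + dc * cos(theta)  # across
  inside <- (u / a)^2 + (v / b)^2 <= 1
  as.matrix(g[inside, , drop = FALSE])
}

# render anisotropic Gaussian FA blobs (sigma = FWHM / 2.355)
render_fa_blobs <- function(shape, centers, thetas, length_px, width_px,
                            amplitude) {
  img <- matrix(0, shape[1], shape[2])
  if (is.null(centers) || nrow(centers) == 0) return(img)
  sl <- length_px / 2.3548; sw <- width_px / 2.3548
  r5 <- ceiling(3 * max(sl, sw)) + 1
  for (i in seq_len(nrow(centers))) {
    r0 <- centers[i, 1]; c0 <- centers[i, 2]; th <- thetas[i]
    rr <- max(0, floor(r0 - r5)):min(shape[1] - 1, ceiling(r0 + r5))
    cc <- max(0, floor(c0 - r5)):min(shape[2] - 1, ceiling(c0 + r5))
    dr <- outer(rr - r0, rep(1, length(cc)))
    dc <- outer(rep(1, length(rr)), cc - c0)
    u <- dr * cos(th) + dc * sin(th)
    v <- -dr * sin(th) + dc * cos(th)
    img[rr + 1, cc + 1] <- img[rr + 1, cc + 1] +
      amplitude * exp(-(u^2 / (2 * sl^2) + v^2 / (2 * sw^2)))
  }
  img
}

# camera model: Poisson(signal + background) + Gaussian read noise,
# clamped at 0 (photon counts cannot be negative)
apply_camera_noise <- function(signal, cfg) {
  lam <- signal + cfg$background
  out <- if (cfg$shot_noise) {
    matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam))
  } else lam
  if (cfg$gaussian_read_noise_sd > 0)
    out <- out + matrix(stats::rnorm(length(out), 0, cfg$gaussian_read_noise_sd),
                        nrow(out), ncol(out))
  pmax(out, 0)
}

# run fn under the config's seed without disturbing the caller's RNG
with_sim_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# brute-force distance (um) from continuous 0-based points to the nearest
# true pixel center of mask — also the oracle the ground truth promises
nearest_mask_distance <- function(points, mask, pixel_size) {
  fa <- which(mask, arr.ind = TRUE) - 1 # 0-based
  vapply(seq_len(nrow(points)), function(i) {
    sqrt(min((fa[, 1] - points[i, 1])^2 + (fa[, 2] - points[i, 2])^2)) *
      pixel_size
  }, numeric(1))
}

#' Simulate a two-channel cell scene with ground truth
#'
#' FA channel: `n_fas` non-overlapping elongated blobs near the ROI
#' boundary, oriented radially. Cargo channel: `n_spots` PSF-sized spots
#' placed according to `cargo_mode`:
#' \describe{
#'   \item{fa_proximal}{offset outward from a random FA boundary pixel by
#'     `|N(0, d0)|` um — secretion-hotspot geometry;}
#'   \item{uniform}{uniform over the ROI — the homogeneous-membrane-marker
#'     control;}
#'   \item{on_fa}{centers on FA pixels.}
#' }
#' The ground truth records the noiseless geometry: the true FA mask
#' (half-maximum footprints), FA centers, and spot centers with their
#' nearest-FA distances recomputed from the mask.
#'
#' @param config a [simulation_config()].
#' @return List: `fa_image`, `cargo_image` (both [image2d]) and `truth`
#'   (class `ground_truth`: `fa_mask`, `fa_centroids`, `spot_centers`
#'   data.frame `row`, `col`, `dist_um`, plus the config).
#' @export
simulate_cell_scene <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  if (cfg$n_fas == 0 && cfg$cargo_mode %in% c("fa_proximal", "on_fa"))
    stop("no FAs to anchor cargo")
  with_sim_seed(cfg$seed, function() {
    H <- cfg$image_shape[1]; W <- cfg$image_shape[2]
    roi_mask <- config_roi_mask(cfg)
    # candidate FA centers: band of ROI pixels at a suitable edge distance
    edge_d <- sqrt(edt_sq_cpp(!roi_mask)) # distance to outside, in px
    band <- which(roi_mask & edge_d >= 0.6 * cfg$fa_length_px &
                    edge_d <= 2.0 * cfg$fa_length_px, arr.ind = TRUE) - 1
    if (cfg$n_fas > 0 && nrow(band) == 0)
      stop("ROI too small for FA placement band")
    ctr <- c(mean(which(roi_mask, arr.ind = TRUE)[, 1]) - 1,
             mean(which(roi_mask, arr.ind = TRUE)[, 2]) - 1)
    fa_mask <- matrix(FALSE, H, W)
    fa_centers <- matrix(numeric(0), 0, 2)
    fa_thetas <- numeric(0)
    attempts <- 0
    while (nrow(fa_centers) < cfg$n_fas) {
      attempts <- attempts + 1
      if (attempts > 1000) stop("could not place non-overlapping FAs in 1000 attempts")
      p <- band[sample.int(nrow(band), 1), ] + stats::runif(2, -0.5, 0.5)
      theta <- atan2(p[2] - ctr[2], p[1] - ctr[1]) # radial orientation
      fp <- fa_footprint_pixels(p, cfg$fa_length_px, cfg$fa_width_px, theta,
                                c(H, W))
      if (nrow(fp) == 0) next
      # require a 1-px gap so 8-connected components stay distinct
      idx <- cbind(fp[, 1] + 1, fp[, 2] + 1)
      clash <- FALSE
      for (dr in -1:1) for (dc in -1:1) {
        rr <- pmin(pmax(fp[, 1] + dr, 0), H - 1)
        cc <- pmin(pmax(fp[, 2] + dc, 0), W - 1)
        if (any(fa_mask[cbind(rr + 1, cc + 1)])) { clash <- TRUE; break }
      }
      if (clash) next
      fa_mask[idx] <- TRUE
      fa_centers <- rbind(fa_centers, p)
      fa_thetas <- c(fa_thetas, theta)
    }
    # cargo centers
    roi_px <- which(roi_mask, arr.ind = TRUE) - 1
    spot_centers <- matrix(numeric(0), 0, 2)
    if (cfg$n_spots > 0) {
      if (cfg$cargo_mode == "uniform" && cfg$min_spot_separation_px == 0) {
        k <- sample.int(nrow(roi_px), cfg$n_spots, replace = TRUE)
        spot_centers <- roi_px[k, , drop = FALSE] +
          matrix(stats::runif(2 * cfg$n_spots, -0.5, 0.5), ncol = 2)
      } else if (cfg$cargo_mode == "uniform") {
        # hard-core placement: reject candidates closer than the
        # separation to an accepted center (up to 100 tries per spot)
        sep2 <- cfg$min_spot_separation_px^2
        for (i in seq_len(cfg$n_spots)) {
          for (try in 1:100) {
            p <- roi_px[sample.int(nrow(roi_px), 1), ] +
              stats::runif(2, -0.5, 0.5)
            if (nrow(spot_centers) == 0 ||
                min((spot_centers[, 1] - p[1])^2 +
                      (spot_centers[, 2] - p[2])^2) >= sep2) break
          }
          spot_centers <- rbind(spot_centers, p)
        }
      } else if (cfg$cargo_mode == "on_fa") {
        fa_px <- which(fa_mask, arr.ind = TRUE) - 1
        k <- sample.int(nrow(fa_px), cfg$n_spots, replace = TRUE)
        spot_centers <- fa_px[k, , drop = FALSE] +
          matrix(stats::runif(2 * cfg$n_spots, -0.45, 0.45), ncol = 2)
      } else { # fa_proximal
        d0_px <- cfg$offset_scale_um / cfg$pixel_size
        boundary <- fa_boundary_pixels(fa_mask)
        a_ax <- cfg$fa_length_px / 2; b_ax <- cfg$fa_width_px / 2
        fa_px <- which(fa_mask, arr.ind = TRUE) - 1
        mask_dist <- function(p)
          sqrt(min((fa_px[, 1] - p[1])^2 + (fa_px[, 2] - p[2])^2))
        for (i in seq_len(cfg$n_spots)) {
          for (try in 1:100) {
            b <- boundary[sample.int(nrow(boundary), 1), ]
            # analytic outward normal of the anchoring blob's half-max
            # ellipse at this boundary pixel (a center-to-pixel direction
            # would be tangentially biased on elongated blobs)
            k_fa <- which.min((fa_centers[, 1] - b[1])^2 +
                                (fa_centers[, 2] - b[2])^2)
            th <- fa_thetas[k_fa]
            d <- b - fa_centers[k_fa, ]
            u <- d[1] * cos(th) + d[2] * sin(th)
            v <- -d[1] * sin(th) + d[2] * cos(th)
            nr <- c(u / a_ax^2, v / b_ax^2)
            nn <- sqrt(sum(nr^2))
            nr <- if (nn > 0) nr / nn else c(1, 0)
            dir <- c(nr[1] * cos(th) - nr[2] * sin(th),
                     nr[1] * sin(th) + nr[2] * cos(th))
            off <- abs(stats::rnorm(1, 0, d0_px))
            p <- b + dir * off
            # one corrective step so the realized mask distance equals the
            # drawn offset (the sampled boundary pixel center need not be
            # the outermost mask pixel along the normal)
            if (off > 0) p <- p + dir * (off - mask_dist(p))
            if (p[1] >= 0 && p[1] <= H - 1 && p[2] >= 0 && p[2] <= W - 1)
              break
          }
          p <- pmin(pmax(p, 0), c(H - 1, W - 1))
          spot_centers <- rbind(spot_centers, p)
        }
      }
    }
    # render
    fa_signal <- render_fa_blobs(c(H, W), fa_centers, fa_thetas,
                                 cfg$fa_length_px, cfg$fa_width_px,
                                 cfg$amplitude)
    cargo_signal <- render_gaussian_spots(c(H, W), spot_centers,
                                          cfg$amplitude, cfg$spot_sigma_px)
    fa_img <- apply_camera_noise(fa_signal, cfg)
    cargo_img <- apply_camera_noise(cargo_signal, cfg)
    dist_um <- if (nrow(spot_centers) > 0 && any(fa_mask))
      nearest_mask_distance(spot_centers, fa_mask, cfg$pixel_size)
    else rep(NA_real_, nrow(spot_centers))
    truth <- structure(
      list(fa_mask = fa_mask,
           fa_centroids = unname(fa_centers),
           spot_centers = data.frame(
             row = as.numeric(spot_centers[, 1]),
             col = as.numeric(spot_centers[, 2]),
             dist_um = as.numeric(dist_um)),
           roi_mask = roi_mask,
           config = cfg),
      class = "ground_truth")
    list(fa_image = image2d(fa_img, cfg$pixel_size, "fa"),
         cargo_image = image2d(cargo_img, cfg$pixel_size, "cargo"),
         truth = truth)
  })
}

# boundary pixels of a mask (true pixels with at least one 4-neighbor
# outside the mask), as 0-based coordinates
fa_boundary_pixels <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  er <- mask
  er <- er & rbind(mask[-1, , drop = FALSE], rep(FALSE, W))
  er <- er & rbind(rep(FALSE, W), mask[-H, , drop = FALSE])
  er <- er & cbind(mask[, -1, drop = FALSE], rep(FALSE, H))
  er <- er & cbind(rep(FALSE, H), mask[, -W, drop = FALSE])
  which(mask & !er, arr.ind = TRUE) - 1
}

#' Simulate a vesicle movie with ground-truth tracks
#'
#' Each vesicle moves at the programmed speed along a polyline; when
#' `tracks_share_paths` is set, several vesicles reuse the same polyline
#' at staggered start times (a vesicle waits at the path start until its
#' start frame). A vesicle reaching the end of its polyline stops there.
#' Frames are rendered with the PSF and the camera noise model.
#'
#' @param config a [simulation_config()] with `n_frames >= 2`.
#' @return List: `stack` (an [image_stack]) and `truth` (class
#'   `ground_truth`: `tracks` data.frame `track_id`, `frame`, `row`,
#'   `col`, plus `paths`, `speed_um_s` and the config).
#' @export
simulate_vesicle_movie <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  if (cfg$n_frames < 2) stop("n_frames must be >= 2")
  with_sim_seed(cfg$seed, function() {
    H <- cfg$image_shape[1]; W <- cfg$image_shape[2]
    step_px <- cfg$speed_um_s * cfg$frame_interval_s / cfg$pixel_size
    need_len <- step_px * (cfg$n_frames - 1) + 2
    n_paths <- if (cfg$tracks_share_paths)
      max(1L, ceiling(cfg$n_vesicles / 3)) else max(cfg$n_vesicles, 1L)
    margin <- 6
    paths <- lapply(seq_len(n_paths), function(i) {
      p <- c(stats::runif(1, margin, H - 1 - margin),
             stats::runif(1, margin, W - 1 - margin))
      th <- stats::runif(1, 0, 2 * pi)
      verts <- matrix(p, 1, 2)
      remaining <- max(need_len, 10)
      n_seg <- 3
      for (s in seq_len(n_seg)) {
        L <- remaining / (n_seg - s + 1) * stats::runif(1, 0.9, 1.1)
        if (s == n_seg) L <- remaining
        for (try in 1:50) {
          q <- p + L * c(cos(th), sin(th))
          if (q[1] >= margin && q[1] <= H - 1 - margin &&
              q[2] >= margin && q[2] <= W - 1 - margin) break
          th <- stats::runif(1, 0, 2 * pi)
        }
        q <- pmin(pmax(q, margin), c(H - 1 - margin, W - 1 - margin))
        verts <- rbind(verts, q)
        remaining <- remaining - sqrt(sum((q - p)^2))
        remaining <- max(remaining, 0)
        p <- q
        th <- th + stats::runif(1, -pi / 4, pi / 4)
        if (remaining <= 0) break
      }
      verts
    })
    stagger <- 3L # frames between successive vesicles on a shared path
    track_rows <- list()
    positions <- vector("list", cfg$n_vesicles)
    for (i in seq_len(cfg$n_vesicles)) {
      path <- paths[[(i - 1) %% n_paths + 1]]
      t0 <- if (cfg$tracks_share_paths) ((i - 1) %/% n_paths) * stagger else 0L
      s <- pmax(0, (0:(cfg$n_frames - 1)) - t0) * step_px
      pos <- point_along_path(path, s)$point
      positions[[i]] <- pos
      track_rows[[i]] <- data.frame(track_id = i,
                                    frame = 0:(cfg$n_frames - 1),
                                    row = pos[, 1], col = pos[, 2])
    }
    frames <- vector("list", cfg$n_frames)
    for (t in seq_len(cfg$n_frames)) {
      centers <- if (cfg$n_vesicles > 0)
        do.call(rbind, lapply(positions, function(p) p[t, , drop = FALSE]))
      else matrix(numeric(0), 0, 2)
      sig <- render_gaussian_spots(c(H, W), centers, cfg$amplitude,
                                   cfg$spot_sigma_px)
      frames[[t]] <- apply_camera_noise(sig, cfg)
    }
    truth <- structure(
      list(tracks = if (cfg$n_vesicles > 0) do.call(rbind, track_rows)
           else data.frame(track_id = integer(0), frame = integer(0),
                           row = numeric(0), col = numeric(0)),
           paths = paths, speed_um_s = cfg$speed_um_s, config = cfg),
      class = "ground_truth")
    list(stack = image_stack(frames, cfg$pixel_size, cfg$frame_interval_s,
                             "vesicles"),
         truth = truth)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  if (!is.null(x$fa_mask))
    cat(sprintf("<ground_truth> %d FAs, %d spots\n",
                nrow(x$fa_centroids), nrow(x$spot_centers)))
  else
    cat(sprintf("<ground_truth> %d tracks x %d frames at %.3g um/s\n",
                length(unique(x$tracks$track_id)),
                x$config$n_frames, x$speed_um_s))
  invisible(x)
}

#' Write a simulated scene or movie with its ground-truth sidecars
#'
#' Images go to multi-page TIFF; spot centers / tracks to CSV; the FA mask
#' to a second TIFF (0/1 uint8) and the configuration to a JSON manifest.
#'
#' @param sim result of [simulate_cell_scene()] or
#'   [simulate_vesicle_movie()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim$truth$config
  if (!is.null(sim$fa_image)) {
    write_tiff(list(sim$fa_image$intensity, sim$cargo_image$intensity),
               file.path(dir, "scene.tif"), dtype = "float32")
    write_tiff(sim$truth$fa_mask + 0, file.path(dir, "fa_mask.tif"),
               dtype = "uint8")
    write_csv_strict(cbind(spot_id = seq_len(nrow(sim$truth$spot_centers)),
                           sim$truth$spot_centers),
                     file.path(dir, "spots_truth.csv"))
  } else {
    write_tiff(sim$stack$frames, file.path(dir, "movie.tif"),
               dtype = "float32")
    write_csv_strict(sim$truth$tracks, file.path(dir, "tracks_truth.csv"))
  }
  cfg_out <- cfg
  class(cfg_out) <- NULL
  jsonlite::write_json(cfg_out, file.path(dir, "simulation_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
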