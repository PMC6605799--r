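# End-to-end orchestration: simulate or load a two-channel scene (and
# optionally a vesicle movie), segment both channels, compute the
# distance-to-FA enrichment, detect and count spots, track vesicles, and
# write a stable set of CSV/TIFF/JSON artifacts.

#' Analysis configuration for the pipeline
#'
#' Either `simulate` is a [simulation_config()] (the scene — and, when
#' `with_movie`, a movie with the same seed — is generated), or
#' `fa_path` / `cargo_path` / `roi_path` point to input TIFFs and a ROI
#' JSON.
#'
#' @param simulate optional [simulation_config()].
#' @param with_movie also simulate and track a vesicle movie.
#' @param fa_path,cargo_path,roi_path input files (ignored when
#'   simulating).
#' @param pixel_size,frame_interval calibrations for file inputs.
#' @param sigma_fa,threshold_fa,sigma_cargo,threshold_cargo segmentation
#'   parameters per channel (see [segment_objects()]).
#' @param bin_width,d_cut enrichment binning and cutoff (um).
#' @param min_distance,prominence spot-detection parameters.
#' @param min_area minimum object area (px) for FA counting.
#' @param max_disp tracking link cutoff (px).
#' @param coloc_radius object-colocalization radius (px).
#' @param out_dir output directory.
#' @param seed integer seed for any randomness.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(simulate = NULL, with_movie = FALSE,
                            fa_path = NULL, cargo_path = NULL,
                            roi_path = NULL,
                            pixel_size = 0.1, frame_interval = 0.2,
                            sigma_fa = 1, threshold_fa = "otsu",
                            sigma_cargo = 1, threshold_cargo = "otsu",
                            bin_width = 0.5, d_cut = 1,
                            min_distance = 3, prominence = 50,
                            min_area = 4, max_disp = 5,
                            coloc_radius = 3,
                            out_dir = tempfile("faprox_run_"), seed = 1L) {
  if (is.null(simulate)) {
    for (p in c(fa_path, cargo_path, roi_path))
      if (!file.exists(p)) stop("input file not found: ", p)
    check_positive_scalar(pixel_size, "pixel_size")
  } else stopifnot(inherits(simulate, "simulation_config"))
  check_positive_scalar(bin_width, "bin_width")
  check_positive_scalar(d_cut, "d_cut")
  cfg <- list(simulate = simulate, with_movie = isTRUE(with_movie),
              fa_path = fa_path, cargo_path = cargo_path,
              roi_path = roi_path, pixel_size = pixel_size,
              frame_interval = frame_interval,
              sigma_fa = sigma_fa, threshold_fa = threshold_fa,
              sigma_cargo = sigma_cargo, threshold_cargo = threshold_cargo,
              bin_width = bin_width, d_cut = d_cut,
              min_distance = min_distance, prominence = prominence,
              min_area = min_area, max_disp = max_disp,
              coloc_radius = coloc_radius,
              out_dir = out_dir, seed = as.integer(seed))
  class(cfg) <- "analysis_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Stages: acquire (simulate or load) -> segment FA and cargo channels ->
#' distance-to-FA enrichment -> spot detection, density and normalized
#' intensity -> (optional) movie tracking -> report. All intermediate
#' artifacts (masks, distance map, profile CSV, spots CSV, tracks CSV) and
#' a JSON MANIFEST with the full parameter set are written to
#' `config$out_dir`. Identical config + seed gives byte-identical CSVs.
#' A failing stage aborts with the stage name; the MANIFEST then records
#' the incomplete state.
#'
#' @param config an [analysis_config()].
#' @return A `report_bundle`: list with `report` (one-row per-cell
#'   data.frame), `profile`, `spots`, `tracks` (or `NULL`), `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "faprox",
                   version = as.character(utils::packageVersion("faprox")),
                   seed = cfg$seed, complete = FALSE,
                   parameters = manifest_params(cfg))
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "MANIFEST.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  write_manifest()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$failed_stage <<- name
      manifest$error <<- conditionMessage(e)
      write_manifest()
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  acq <- stage("acquire", {
    if (!is.null(cfg$simulate)) {
      sim <- simulate_cell_scene(cfg$simulate)
      movie <- if (cfg$with_movie) simulate_vesicle_movie(cfg$simulate)
      write_simulation(sim, file.path(cfg$out_dir, "simulated"))
      list(fa = sim$fa_image, cargo = sim$cargo_image,
           roi_mask = sim$truth$roi_mask, truth = sim$truth, movie = movie,
           pixel_size = cfg$simulate$pixel_size,
           frame_interval = cfg$simulate$frame_interval_s)
    } else {
      fa <- image2d(read_tiff(cfg$fa_path), cfg$pixel_size, "fa")
      cargo <- image2d(read_tiff(cfg$cargo_path), cfg$pixel_size, "cargo")
      roi <- read_roi_json(cfg$roi_path)
      list(fa = fa, cargo = cargo,
           roi_mask = make_roi_mask(roi, dim(fa$intensity)),
           truth = NULL, movie = NULL,
           pixel_size = cfg$pixel_size, frame_interval = cfg$frame_interval)
    }
  })

  seg <- stage("segment", {
    fa_seg <- segment_objects(acq$fa, acq$roi_mask, cfg$sigma_fa,
                              cfg$threshold_fa)
    cargo_seg <- segment_objects(acq$cargo, acq$roi_mask, cfg$sigma_cargo,
                                 cfg$threshold_cargo)
    write_tiff(fa_seg$labels + 0, file.path(cfg$out_dir, "fa_labels.tif"),
               dtype = "uint16")
    write_tiff(cargo_seg$labels + 0,
               file.path(cfg$out_dir, "cargo_labels.tif"), dtype = "uint16")
    list(fa = fa_seg, cargo = cargo_seg)
  })

  enr <- stage("enrich", {
    fa_mask <- seg$fa$labels > 0
    cargo_mask <- seg$cargo$labels > 0
    dm <- distance_to_fa(fa_mask, acq$pixel_size)
    write_tiff(dm$dist, file.path(cfg$out_dir, "distance_um.tif"),
               dtype = "float32")
    prof <- enrichment_profile(cargo_mask, fa_mask, acq$roi_mask,
                               acq$pixel_size, cfg$bin_width)
    write_csv_strict(as.data.frame(prof),
                     file.path(cfg$out_dir, "enrichment_profile.csv"))
    list(profile = prof,
         near = enrichment_near(prof, cfg$d_cut),
         mean_dist = mean_cargo_distance(cargo_mask, fa_mask,
                                         acq$pixel_size))
  })

  det <- stage("detect", {
    spots <- detect_spots(acq$cargo, acq$roi_mask, cfg$min_distance,
                          cfg$prominence)
    dens <- spot_density(spots, acq$roi_mask, acq$pixel_size)
    nsi <- tryCatch(
      normalized_spot_intensity(acq$cargo, seg$cargo$labels > 0,
                                acq$roi_mask),
      error = function(e) NA_real_)
    write_csv_strict(as.data.frame(spots),
                     file.path(cfg$out_dir, "spots.csv"))
    list(spots = spots, dens = dens, nsi = nsi)
  })

  trk <- NULL
  if (!is.null(acq$movie)) {
    trk <- stage("track", {
      st <- acq$movie$stack
      per_frame <- do.call(rbind, lapply(seq_along(st$frames), function(t) {
        detect_spots(st$frames[[t]], NULL, cfg$min_distance,
                     cfg$prominence, frame_index = t - 1L)
      }))
      class(per_frame) <- c("spot_set", "data.frame")
      tracks <- link_detections(per_frame, cfg$max_disp)
      metrics <- track_metrics(tracks, st$pixel_size, st$frame_interval)
      tracks_out <- merge(tracks, metrics[, c("track_id", "length_um",
                                              "v_um_s")], by = "track_id")
      tracks_out <- tracks_out[order(tracks_out$track_id, tracks_out$frame), ]
      rownames(tracks_out) <- NULL
      write_csv_strict(tracks_out, file.path(cfg$out_dir, "tracks.csv"))
      list(tracks = tracks, metrics = metrics)
    })
  }

  report <- stage("report", {
    rep <- data.frame(
      cell_id = 1L,
      n_fas = count_objects(seg$fa, cfg$min_area),
      n_spots_detected = det$dens$per_cell,
      spots_per_um2 = det$dens$per_area,
      normalized_spot_intensity = det$nsi,
      enrichment_near_um = enr$near,
      d_cut_um = cfg$d_cut,
      mean_cargo_distance_um = enr$mean_dist,
      mean_track_v_um_s = if (!is.null(trk)) {
        m <- trk$metrics[!trk$metrics$single_point, ]
        if (nrow(m) > 0) mean(m$v_um_s) else NA_real_
      } else NA_real_,
      n_tracks = if (!is.null(trk)) nrow(trk$metrics) else NA_integer_,
      track_stage = if (is.null(trk)) "disabled: no movie input" else "ok")
    write_csv_strict(rep, file.path(cfg$out_dir, "report.csv"))
    rep
  })

  manifest$complete <- TRUE
  write_manifest()
  structure(list(report = report, profile = enr$profile,
                 spots = det$spots,
                 tracks = if (!is.null(trk)) trk else NULL,
                 out_dir = cfg$out_dir),
            class = "report_bundle")
}

manifest_params <- function(cfg) {
  p <- cfg
  class(p) <- NULL
  if (!is.null(p$simulate)) {
    sc <- p$simulate
    class(sc) <- NULL
    p$simulate <- sc
  }
  p
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  print(x$report)
  invisible(x)
}
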