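# End-to-end pipelines tying the stages together in their fixed order
# (slice: drift -> regions -> preprocess -> detect -> collapse -> link ->
# merge -> filter -> metrics -> summary; Matrigel: segment -> distances ->
# fractions), with provenance of every effective parameter.

#' Parameters of the slice-migration pipeline
#'
#' Every unset (`NULL`) derived parameter is filled in from the nominal
#' cell geometry and expected speed: size bounds default to
#' `[0.25, 2.5] x` the nominal cell area `pi * cell_radius^2`, the
#' Z-collapse match radius to one cell radius, and the linking gate
#' `max_disp` to three times the expected step length
#' `expected_speed * frame_interval`.
#'
#' @param cell_radius Nominal cell radius, um.
#' @param expected_speed Expected mean speed, um/min (for the linking
#'   gate).
#' @param max_disp Linking gate, um (`NULL` = derived).
#' @param memory Linking gap memory, frames.
#' @param min_area,max_area Size-filter bounds, um^2 (`NULL` = derived).
#' @param match_radius Z-collapse grouping radius, um (`NULL` = one cell
#'   radius).
#' @param bleed_coeff Bleed-through coefficient (`NULL` = estimated).
#' @param median_radius Median-filter half-width, px.
#' @param merge_dist,merge_gap Track-merging gates (um, frames).
#' @param min_frames Minimum track length kept.
#' @param threshold Segmentation threshold method.
#' @param mask_min_area Region-mask speck size, um^2.
#' @param outlier_policy Passed to [summarize_acquisition()].
#' @return A named list of class `SliceParams`.
#' @export
slice_params <- function(cell_radius = 4, expected_speed = 4,
                         max_disp = NULL, memory = 1L, min_area = NULL,
                         max_area = NULL, match_radius = NULL,
                         bleed_coeff = NULL, median_radius = 1L,
                         merge_dist = 10, merge_gap = 2L, min_frames = 6L,
                         threshold = "otsu", mask_min_area = 25,
                         outlier_policy = "none") {
  structure(list(cell_radius = cell_radius, expected_speed = expected_speed,
                 max_disp = max_disp, memory = memory, min_area = min_area,
                 max_area = max_area, match_radius = match_radius,
                 bleed_coeff = bleed_coeff, median_radius = median_radius,
                 merge_dist = merge_dist, merge_gap = merge_gap,
                 min_frames = min_frames, threshold = threshold,
                 mask_min_area = mask_min_area,
                 outlier_policy = outlier_policy),
            class = "SliceParams")
}

resolve_slice_params <- function(p, frame_interval) {
  nominal_area <- pi * p$cell_radius^2
  if (is.null(p$min_area)) p$min_area <- 0.25 * nominal_area
  if (is.null(p$max_area)) p$max_area <- 2.5 * nominal_area
  if (is.null(p$match_radius)) p$match_radius <- p$cell_radius
  if (is.null(p$max_disp))
    p$max_disp <- 3 * p$expected_speed * frame_interval / 60
  p
}

#' Run the full slice-migration analysis
#'
#' @param stack An `ImageStack` (or a path to one written by
#'   [write_stack()]).
#' @param masks Optional manual `RegionMaskSet` (already in the
#'   drift-corrected frame); when absent, masks are derived from the ECM
#'   channel after drift correction.
#' @param params A [slice_params()] list.
#' @param output_dir Optional directory; when given, tracks, per-track
#'   metrics, the acquisition summary, the drift model and a provenance
#'   JSON are written as CSV/JSON files.
#' @return List with `tracks`, `metrics`, `summary`, `drift`, `masks`,
#'   `detections_per_frame`, and the resolved `params`.
#' @export
run_slice_pipeline <- function(stack, masks = NULL, params = slice_params(),
                               output_dir = NULL) {
  if (is.character(stack)) stack <- load_stack(stack)
  stopifnot(inherits(stack, "ImageStack"))
  p <- resolve_slice_params(params, stack$frame_interval)
  d <- dim(stack$data)
  # 1. drift
  drift <- estimate_drift(stack)
  corrected <- apply_drift(stack, drift)
  # 2. regions
  if (is.null(masks))
    masks <- derive_region_masks(corrected, min_area = p$mask_min_area)
  # 3. cell-channel preprocessing (one bleed coefficient per acquisition)
  cell_ch <- corrected$channel_roles[["cell"]]
  ecm_ch <- corrected$channel_roles[["ecm"]]
  bleed <- p$bleed_coeff
  if (is.null(bleed))
    bleed <- estimate_bleed(corrected$data[, , , , cell_ch],
                            corrected$data[, , , , ecm_ch])
  # 4.-5. detection, size filter, Z-collapse. The intensity threshold is
  # computed per frame across all planes: planes without any cell would
  # otherwise be thresholded at their noise floor and emit spurious
  # detections.
  per_frame <- vector("list", d[1L])
  for (t in seq_len(d[1L])) {
    imgs <- vector("list", d[2L])
    for (z in seq_len(d[2L]))
      imgs[[z]] <- correct_cell_channel(corrected$data[t, z, , , cell_ch],
                                        corrected$data[t, z, , , ecm_ch],
                                        bleed_coeff = bleed,
                                        median_radius = p$median_radius)
    thr_t <- if (identical(p$threshold, "otsu"))
      otsu_threshold(unlist(imgs)) else p$threshold
    dets_t <- list()
    for (z in seq_len(d[2L])) {
      # planes without any cell legitimately fall below the global
      # threshold; that is not worth a warning here
      dd <- withCallingHandlers(
        segment_frame(imgs[[z]], stack$pixel_size_xy, frame = t,
                      plane = z, threshold = "fixed",
                      fixed_threshold = thr_t),
        warning = function(w) {
          if (grepl("above image maximum", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      dd <- filter_by_size(dd, p$min_area, p$max_area)
      dets_t <- c(dets_t, dd)
    }
    per_frame[[t]] <- collapse_z(dets_t, p$match_radius)
  }
  # 6.-8. link, merge, length filter
  tracks <- link_tracks(do.call(c, per_frame), max_disp = p$max_disp,
                        memory = p$memory)
  tracks <- merge_tracks(tracks, dist_thresh = p$merge_dist,
                         frame_gap_thresh = p$merge_gap)
  tracks <- filter_min_length(tracks, min_frames = p$min_frames)
  # 9.-10. metrics and summary
  metrics <- track_metrics(tracks, masks, stack$frame_interval)
  summary <- if (length(metrics))
    summarize_acquisition(metrics, outlier_policy = p$outlier_policy)
    else NULL
  p$bleed_coeff <- bleed
  res <- list(tracks = tracks, metrics = metrics, summary = summary,
              drift = drift, masks = masks,
              detections_per_frame = per_frame, params = p)
  if (!is.null(output_dir)) write_slice_outputs(res, output_dir)
  res
}

write_slice_outputs <- function(res, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(output_dir, name), row.names = FALSE)
  wcsv(tracks_to_df(res$tracks), "tracks.csv")
  if (length(res$metrics)) {
    wcsv(metrics_to_df(res$metrics), "metrics.csv")
    wcsv(speeds_long(res$metrics), "speeds_long.csv")
  }
  if (!is.null(res$summary)) {
    s <- res$summary
    wcsv(data.frame(n_tracks = s$n_tracks,
                    pct_entered_tumor = s$pct_entered_tumor,
                    pct_high_dwell = s$pct_high_dwell,
                    mean_speed = s$mean_speed,
                    mean_speed_tumor = if (is.null(s$speed_tumor)) NA
                      else s$speed_tumor$mean_pooled,
                    mean_speed_ecm = if (is.null(s$speed_ecm)) NA
                      else s$speed_ecm$mean_pooled,
                    n_outliers_removed = length(s$outlier_removed_ids)),
         "summary.csv")
  }
  wcsv(as.data.frame(res$drift), "drift.csv")
  prov <- list(tool = "slicetracks",
               version = as.character(utils::packageVersion("slicetracks")),
               stage_order = c("drift", "regions", "preprocess", "detect",
                               "collapse_z", "link", "merge",
                               "filter_min_length", "metrics", "summary"),
               params = res$params[!vapply(res$params, is.null,
                                           logical(1))],
               mask_source = res$masks$source)
  jsonlite::write_json(prov, file.path(output_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(output_dir)
}

#' Run the Matrigel invasion analysis
#'
#' @param x A `MatrigelStack`, a `Z x Y x X` array (with `pixel_size_xy`
#'   and `z_step`), or a path to a single-channel TIFF Z-stack.
#' @param pixel_size_xy,z_step Calibration for arrays/files, um.
#' @param threshold,fixed_threshold,min_seed_separation Passed to
#'   [segment_nuclei_3d()].
#' @param thresholds Invasion thresholds for [fraction_beyond()], um.
#' @param output_dir Optional directory for per-cell and summary CSVs
#'   plus provenance JSON.
#' @return List with `labels`, `result` (`InvasionResult` or `NULL` when
#'   no cells), `fractions`, `n_cells`.
#' @export
run_matrigel_pipeline <- function(x, pixel_size_xy = NULL, z_step = NULL,
                                  threshold = "otsu", fixed_threshold = NULL,
                                  min_seed_separation = 4,
                                  thresholds = c(10, 100),
                                  output_dir = NULL) {
  if (is.character(x)) {
    pages <- read_tiff(x)
    vol <- array(0, c(length(pages), dim(pages[[1L]])))
    for (i in seq_along(pages)) vol[i, , ] <- pages[[i]]
    x <- vol
  }
  if (inherits(x, "MatrigelStack")) {
    pixel_size_xy <- x$pixel_size_xy
    z_step <- x$z_step
    x <- x$volume
  }
  if (is.null(pixel_size_xy) || is.null(z_step))
    stop("run_matrigel_pipeline: pixel_size_xy and z_step are required")
  labels <- segment_nuclei_3d(x, threshold = threshold,
                              fixed_threshold = fixed_threshold,
                              min_seed_separation = min_seed_separation,
                              pixel_size_xy = pixel_size_xy, z_step = z_step)
  n <- attr(labels, "n_labels")
  result <- NULL
  fractions <- stats::setNames(rep(NA_real_, length(thresholds)),
                               paste0(">", thresholds))
  if (n > 0L) {
    result <- invasion_distances(labels, pixel_size_xy, z_step)
    fractions <- fraction_beyond(result, thresholds)
  }
  out <- list(labels = labels, result = result, fractions = fractions,
              n_cells = n)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(result)) {
      per_cell <- result$centroids
      per_cell$distance_um <- result$distances
      utils::write.csv(per_cell, file.path(output_dir, "cells.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(
      data.frame(n_cells = n,
                 baseline_z = if (is.null(result)) NA
                   else result$baseline_z,
                 t(fractions), check.names = FALSE),
      file.path(output_dir, "summary.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(tool = "slicetracks",
           version = as.character(utils::packageVersion("slicetracks")),
           params = list(pixel_size_xy = pixel_size_xy, z_step = z_step,
                         threshold = threshold,
                         min_seed_separation = min_seed_separation,
                         thresholds = thresholds)),
      file.path(output_dir, "provenance.json"), auto_unbox = TRUE,
      digits = NA)
  }
  out
}
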