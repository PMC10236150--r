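# Momentary speeds, tumor/ECM localization, dwell fractions, and
# per-acquisition summaries.
#
# Localization follows the strict pixel-overlap rule: a cell localizes to
# a tumor region only when no pixel of its segmented footprint overlaps
# the fibronectin (ECM) mask of its own plane. Dwell >= 50% of observed
# frames counts as high tumor dwell (the inclusive reading of "at least
# 50%"; a 5-of-10 track is high-dwell, pinned by tests).

#' Momentary speeds of a track
#'
#' The distance travelled between two successive observations of the same
#' cell divided by the time between them. Gap pairs use the actual
#' elapsed time (`gap * frame_interval`).
#'
#' @param track A `Track`.
#' @param frame_interval Seconds between frames.
#' @return Numeric vector of um/min, one value per successive observation
#'   pair (length `n_obs - 1`; empty for single-observation tracks).
#' @export
momentary_speed <- function(track, frame_interval) {
  f <- track_frames(track)
  if (length(f) < 2L) return(numeric(0))
  xy <- track_xy(track)
  d <- sqrt(diff(xy[, 1L])^2 + diff(xy[, 2L])^2)
  dt_min <- diff(f) * frame_interval / 60
  d / dt_min
}

#' Per-frame tumor/ECM localization of a track
#'
#' A frame is labeled `"tumor"` iff no pixel of the detection's footprint
#' overlaps the ECM mask of the detection's plane; a single overlapping
#' pixel makes it `"ecm"`.
#'
#' @param track A `Track` whose observations carry pixel footprints.
#' @param masks A `RegionMaskSet` in the same (drift-corrected) frame and
#'   resolution as the detections.
#' @return Character vector of `"tumor"` / `"ecm"`, one per observation.
#' @export
classify_localization <- function(track, masks) {
  nZ <- dim(masks$ecm)[1L]
  vapply(track$obs, function(d) {
    if (is.na(d$plane) || d$plane < 1L || d$plane > nZ)
      stop("classify_localization: plane ", d$plane,
           " outside the mask set (", nZ, " planes)")
    hit <- any(masks$ecm[cbind(d$plane, d$pixels[, 1L], d$pixels[, 2L])])
    if (hit) "ecm" else "tumor"
  }, character(1))
}

#' Dwell fraction, tumor entry and high-dwell flags
#'
#' @param region_per_frame Character vector of `"tumor"` / `"ecm"` labels.
#' @return List with `dwell_fraction` (#tumor / #observed), `entered_tumor`
#'   (any tumor frame) and `high_dwell` (`dwell_fraction >= 0.5`).
#' @export
dwell_and_entry <- function(region_per_frame) {
  if (!length(region_per_frame))
    stop("dwell_and_entry: empty label vector")
  n_tum <- sum(region_per_frame == "tumor")
  dwell <- n_tum / length(region_per_frame)
  list(dwell_fraction = dwell, entered_tumor = n_tum >= 1L,
       high_dwell = dwell >= 0.5)
}

#' Per-track migration metrics
#'
#' Combines momentary speeds, localization and dwell statistics for every
#' track. Each speed step is attributed to the compartment of its first
#' observation.
#'
#' @param tracks List of `Track`s.
#' @param masks A `RegionMaskSet`.
#' @param frame_interval Seconds between frames.
#' @return A list of class `TrackMetricsSet`; each element has
#'   `track_id`, `momentary_speeds`, `region_per_frame`, `step_region`,
#'   `dwell_fraction`, `entered_tumor`, `high_dwell`, `mean_speed`,
#'   `mean_speed_tumor`, `mean_speed_ecm`.
#' @export
track_metrics <- function(tracks, masks, frame_interval) {
  out <- lapply(tracks, function(tr) {
    sp <- momentary_speed(tr, frame_interval)
    reg <- classify_localization(tr, masks)
    de <- dwell_and_entry(reg)
    step_reg <- if (length(reg) > 1L) reg[-length(reg)] else character(0)
    mean_or_na <- function(v) if (length(v)) mean(v) else NA_real_
    list(track_id = tr$track_id, momentary_speeds = sp,
         region_per_frame = reg, step_region = step_reg,
         dwell_fraction = de$dwell_fraction,
         entered_tumor = de$entered_tumor, high_dwell = de$high_dwell,
         mean_speed = mean_or_na(sp),
         mean_speed_tumor = mean_or_na(sp[step_reg == "tumor"]),
         mean_speed_ecm = mean_or_na(sp[step_reg == "ecm"]))
  })
  class(out) <- "TrackMetricsSet"
  out
}

#' Metrics as a per-track data frame
#'
#' @param metrics A `TrackMetricsSet`.
#' @return data.frame, one row per track.
#' @export
metrics_to_df <- function(metrics) {
  do.call(rbind, lapply(metrics, function(m)
    data.frame(track_id = m$track_id, n_obs = length(m$region_per_frame),
               dwell_fraction = m$dwell_fraction,
               entered_tumor = m$entered_tumor, high_dwell = m$high_dwell,
               mean_speed = m$mean_speed,
               mean_speed_tumor = m$mean_speed_tumor,
               mean_speed_ecm = m$mean_speed_ecm)))
}

#' Tidy long table of momentary speeds
#'
#' One row per track step with its compartment attribution, for external
#' statistics tools.
#'
#' @param metrics A `TrackMetricsSet`.
#' @return data.frame with `track_id, step, speed_um_min, region`.
#' @export
speeds_long <- function(metrics) {
  rows <- lapply(metrics, function(m) {
    if (!length(m$momentary_speeds)) return(NULL)
    data.frame(track_id = m$track_id,
               step = seq_along(m$momentary_speeds),
               speed_um_min = m$momentary_speeds,
               region = m$step_region)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(track_id = integer(0), step = integer(0),
                      speed_um_min = numeric(0), region = character(0))
  out
}

#' Summarize an acquisition
#'
#' Pools per-track metrics into the acquisition-level numbers reported
#' per time-lapse experiment: the percentage of tracks that entered tumor
#' tissue, the percentage with tumor dwell >= 50%, and speed summaries per
#' compartment (both pooled momentary speeds and per-track means are
#' emitted). Optional outlier removal uses a robust MAD z-score at a
#' nominal two-sided level Q on per-track mean speeds; this approximates,
#' but is not, the proprietary ROUT procedure, and is off by default.
#'
#' @param metrics A `TrackMetricsSet` (>= 1 track).
#' @param outlier_policy `"none"` (default) or `"mad"`.
#' @param Q Nominal outlier rate for `"mad"` (default 0.02).
#' @return An `AcquisitionSummary` list: `n_tracks`, `pct_entered_tumor`,
#'   `pct_high_dwell`, `mean_speed` (grand mean of per-track means),
#'   `speed_tumor` / `speed_ecm` (lists with pooled momentary speeds,
#'   their mean, and the mean of per-track means; `NULL` when a
#'   compartment has no data), `outlier_removed_ids`.
#' @export
summarize_acquisition <- function(metrics, outlier_policy = c("none", "mad"),
                                  Q = 0.02) {
  outlier_policy <- match.arg(outlier_policy)
  if (!length(metrics)) stop("summarize_acquisition: no tracks")
  removed <- integer(0)
  if (outlier_policy == "mad") {
    ms <- vapply(metrics, `[[`, numeric(1), "mean_speed")
    med <- stats::median(ms, na.rm = TRUE)
    s <- stats::mad(ms, na.rm = TRUE)
    if (is.finite(s) && s > 0) {
      z <- abs(ms - med) / s
      removed <- vapply(metrics, `[[`, numeric(1), "track_id")[
        !is.na(z) & z > stats::qnorm(1 - Q / 2)]
      metrics <- metrics[!(vapply(metrics, `[[`, numeric(1), "track_id")
                           %in% removed)]
    }
  }
  n <- length(metrics)
  entered <- vapply(metrics, `[[`, logical(1), "entered_tumor")
  high <- vapply(metrics, `[[`, logical(1), "high_dwell")
  comp <- function(region) {
    pooled <- unlist(lapply(metrics, function(m)
      m$momentary_speeds[m$step_region == region]))
    per_track <- vapply(metrics, `[[`, numeric(1),
                        paste0("mean_speed_", if (region == "tumor")
                          "tumor" else "ecm"))
    per_track <- per_track[!is.na(per_track)]
    if (!length(pooled)) return(NULL)  # compartment absent, not zero
    list(pooled = pooled, mean_pooled = mean(pooled),
         mean_of_track_means = if (length(per_track)) mean(per_track)
           else NA_real_)
  }
  all_speeds <- vapply(metrics, `[[`, numeric(1), "mean_speed")
  structure(list(n_tracks = n,
                 pct_entered_tumor = 100 * mean(entered),
                 pct_high_dwell = 100 * mean(high),
                 mean_speed = mean(all_speeds, na.rm = TRUE),
                 speed_tumor = comp("tumor"),
                 speed_ecm = comp("ecm"),
                 outlier_removed_ids = as.integer(removed)),
            class = "AcquisitionSummary")
}

#' @export
print.AcquisitionSummary <- function(x, ...) {
  cat(sprintf("AcquisitionSummary: %d tracks\n", x$n_tracks))
  cat(sprintf("  entered tumor: %.1f%%   high dwell (>=50%%): %.1f%%\n",
              x$pct_entered_tumor, x$pct_high_dwell))
  fmt <- function(cc, nm) {
    if (is.null(cc)) cat("  ", nm, ": absent\n", sep = "")
    else cat(sprintf("  %s: %.2f um/min (pooled, n=%d steps)\n", nm,
                     cc$mean_pooled, length(cc$pooled)))
  }
  fmt(x$speed_tumor, "speed in tumor")
  fmt(x$speed_ecm, "speed in ECM")
  if (length(x$outlier_removed_ids))
    cat("  outliers removed:", paste(x$outlier_removed_ids,
                                     collapse = ", "), "\n")
  invisible(x)
}
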