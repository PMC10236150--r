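# Shared fixtures. Everything is generated in code; heavier scenes are
# cached per test run so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

# A minimal detection for constructed tracking/metrics fixtures.
make_det <- function(frame, x, y = 0, plane = 1L, area = 30,
                     intensity = 100,
                     pixels = matrix(c(1L, 1L), 1L)) {
  list(frame = frame, plane = plane, label = 1L, centroid = c(x, y),
       area = area, intensity = intensity, pixels = pixels)
}

make_track <- function(id, dets) slicetracks:::new_track(id, dets)

noise_free <- list(gaussian_sd = 0, poisson_scale = 0)

# Small default-noise scene reused by io/preprocess/detection tests.
small_scene <- function() cached("small_scene", {
  generate_slice_scene(scene_config(n_frames = 12, n_planes = 2,
                                    n_cells = 12, min_separation = 15,
                                    rng_seed = 101))
})

# Noise-free, drift-free scene with well-separated single-plane cells.
clean_scene <- function() cached("clean_scene", {
  generate_slice_scene(scene_config(n_frames = 6, n_planes = 1,
                                    n_cells = 10, min_separation = 20,
                                    drift_per_frame = c(0, 0),
                                    bleed_coeff = 0,
                                    noise = noise_free, rng_seed = 55))
})

# Brute-force all-pairs merge oracle: same rule as merge_tracks but
# implemented independently (repeatedly scan all ordered pairs, merge the
# spatially nearest eligible one).
merge_oracle <- function(tracks, dist_thresh = 10, frame_gap_thresh = 2L) {
  repeat {
    n <- length(tracks)
    if (n < 2L) break
    best <- NULL
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a == b) next
      fa <- vapply(tracks[[a]]$obs, `[[`, numeric(1), "frame")
      fb <- vapply(tracks[[b]]$obs, `[[`, numeric(1), "frame")
      gap <- fb[1L] - fa[length(fa)]
      if (!(gap > 0 && gap < frame_gap_thresh)) next
      pa <- tracks[[a]]$obs[[length(fa)]]$centroid
      pb <- tracks[[b]]$obs[[1L]]$centroid
      d <- sqrt(sum((pa - pb)^2))
      if (d >= dist_thresh) next
      if (is.null(best) || d < best$d ||
          (d == best$d && (a < best$a || (a == best$a && b < best$b))))
        best <- list(a = a, b = b, d = d)
    }
    if (is.null(best)) break
    tracks[[best$a]]$obs <- c(tracks[[best$a]]$obs, tracks[[best$b]]$obs)
    tracks[[best$b]] <- NULL
  }
  tracks
}

# Sort-and-interpolate percentile oracle (independent of the package's
# implementation and of stats::quantile).
percentile_oracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  pos <- 1 + (n - 1) * p
  lo <- floor(pos)
  hi <- ceiling(pos)
  s[lo] + (pos - lo) * (s[hi] - s[lo])
}

# Greedy matching of recovered track observations to ground truth:
# fraction of recovered (frame, position) observations lying within
# `tol` um of a true cell position in the same frame, plus per-cell
# bookkeeping for track-count checks.
match_to_truth <- function(tracks_df, truth_df, tol = 3) {
  hit <- logical(nrow(tracks_df))
  for (i in seq_len(nrow(tracks_df))) {
    cand <- truth_df[truth_df$frame == tracks_df$frame[i], ]
    if (!nrow(cand)) next
    d <- sqrt((cand$x_um - tracks_df$x_um[i])^2 +
                (cand$y_um - tracks_df$y_um[i])^2)
    hit[i] <- min(d) <= tol
  }
  mean(hit)
}
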