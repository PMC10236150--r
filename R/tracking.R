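# Frame-to-frame track linking with gap memory, rule-based merging of
# broken tracks, and the minimum-length filter.
#
# Linking reimplements the contract of standard particle linking
# (frame-to-frame assignment minimizing total squared displacement,
# subject to a per-cell displacement bound, with gap memory), solved
# exactly per frame with the Hungarian algorithm. Merging follows the
# hard rule: an earlier track's final point and a later track's initial
# point closer than 10 um and fewer than 2 frames apart belong to one
# cell; "less than two frames apart" is read strictly, so a start at
# end-frame + 1 merges and end-frame + 2 does not.

new_track <- function(track_id, obs, merged_from = integer(0)) {
  list(track_id = track_id, obs = obs, merged_from = merged_from)
}

track_frames <- function(tr) vapply(tr$obs, `[[`, numeric(1), "frame")
track_xy <- function(tr)
  t(vapply(tr$obs, function(d) d$centroid, numeric(2)))

#' Link detections into tracks
#'
#' Detections of successive frames are assigned to tracks by minimizing
#' the total squared displacement, with links longer than `max_disp`
#' forbidden; unassignable detections start new tracks, and a track
#' missing from up to `memory` consecutive frames can still be continued
#' (gap closing). The per-frame assignment is solved exactly (Hungarian
#' algorithm), so ties are resolved deterministically.
#'
#' @param detections Flat list of detections (each carrying `frame`), or
#'   a list of per-frame detection lists.
#' @param max_disp Maximum displacement per frame step, um.
#' @param memory Number of frames a track may skip and still be linked.
#' @return List of `Track` objects (id, time-ordered observations,
#'   `merged_from` ancestry, empty at this stage).
#' @export
link_tracks <- function(detections, max_disp, memory = 1L) {
  if (max_disp <= 0) stop("link_tracks: max_disp must be > 0")
  if (length(detections) && is.list(detections[[1L]]) &&
      !is.null(detections[[1L]]$frame)) {
    flat <- detections
  } else {
    flat <- do.call(c, detections)
  }
  if (!length(flat)) return(list())
  frames <- vapply(flat, `[[`, numeric(1), "frame")
  tracks <- list()
  open_last <- numeric(0)   # last observed frame per open track
  U <- max_disp^2
  for (t in sort(unique(frames))) {
    dets <- flat[frames == t]
    nD <- length(dets)
    active <- which(open_last >= t - 1L - memory)
    nT <- length(active)
    if (nT == 0L) {
      for (d in dets) {
        tracks[[length(tracks) + 1L]] <- new_track(length(tracks) + 1L,
                                                   list(d))
        open_last[length(tracks)] <- t
      }
      next
    }
    ends <- t(vapply(tracks[active],
                     function(tr) tr$obs[[length(tr$obs)]]$centroid,
                     numeric(2)))
    pts <- t(vapply(dets, function(d) d$centroid, numeric(2)))
    C <- outer(ends[, 1L], pts[, 1L], "-")^2 +
      outer(ends[, 2L], pts[, 2L], "-")^2
    BIG <- 4 * U * (nT + nD) + 1
    C[C > U] <- BIG
    n <- nT + nD
    M <- matrix(BIG, n, n)
    M[seq_len(nT), seq_len(nD)] <- C
    for (i in seq_len(nT)) M[i, nD + i] <- U
    for (j in seq_len(nD)) M[nT + j, j] <- U
    if (nT > 0L && nD > 0L)
      M[(nT + 1L):n, (nD + 1L):n] <- 0
    assign <- cpp_hungarian(M)
    claimed <- logical(nD)
    for (i in seq_len(nT)) {
      j <- assign[i]
      if (j >= 1L && j <= nD && C[i, j] <= U) {
        tr_id <- active[i]
        tracks[[tr_id]]$obs[[length(tracks[[tr_id]]$obs) + 1L]] <- dets[[j]]
        open_last[tr_id] <- t
        claimed[j] <- TRUE
      }
    }
    for (j in which(!claimed)) {
      tracks[[length(tracks) + 1L]] <- new_track(length(tracks) + 1L,
                                                 list(dets[[j]]))
      open_last[length(tracks)] <- t
    }
  }
  tracks
}

#' Merge broken track fragments
#'
#' Two tracks A (ending at frame `t_A`) and B (starting at `t_B > t_A`)
#' are merged when `t_B - t_A < frame_gap_thresh` and the distance from
#' A's final to B's initial point is `< dist_thresh`. When several
#' candidates compete, the nearest pair in space wins; merging repeats to
#' the fixpoint. Tracks overlapping in time are never merged. Ancestry is
#' recorded in `merged_from`; the total observation count is conserved.
#'
#' @param tracks List of `Track`s.
#' @param dist_thresh Spatial gate, um (default 10).
#' @param frame_gap_thresh Temporal gate, frames (default 2, strict).
#' @return Merged track list (ids renumbered consecutively).
#' @export
merge_tracks <- function(tracks, dist_thresh = 10, frame_gap_thresh = 2L) {
  if (length(tracks) < 2L) return(tracks)
  repeat {
    n <- length(tracks)
    starts <- t(vapply(tracks, function(tr)
      c(track_frames(tr)[1L], tr$obs[[1L]]$centroid), numeric(3)))
    ends <- t(vapply(tracks, function(tr) {
      f <- track_frames(tr)
      c(f[length(f)], tr$obs[[length(tr$obs)]]$centroid)
    }, numeric(3)))
    best <- NULL
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a == b) next
      gap <- starts[b, 1L] - ends[a, 1L]
      if (gap <= 0 || gap >= frame_gap_thresh) next
      d <- sqrt((ends[a, 2L] - starts[b, 2L])^2 +
                  (ends[a, 3L] - starts[b, 3L])^2)
      if (d >= dist_thresh) next
      if (is.null(best) || d < best$d ||
          (d == best$d && (a < best$a || (a == best$a && b < best$b))))
        best <- list(a = a, b = b, d = d)
    }
    if (is.null(best)) break
    A <- tracks[[best$a]]
    B <- tracks[[best$b]]
    anc <- function(tr) if (length(tr$merged_from)) tr$merged_from
      else tr$track_id
    merged <- new_track(A$track_id, c(A$obs, B$obs),
                        merged_from = c(anc(A), anc(B)))
    tracks[[best$a]] <- merged
    tracks[[best$b]] <- NULL
  }
  for (i in seq_along(tracks)) tracks[[i]]$track_id <- i
  tracks
}

#' Drop short tracks
#'
#' Only tracks observed in at least `min_frames` frames are kept for
#' analysis (counted after merging: merge first, filter second, so that
#' mergeable fragments are not discarded prematurely).
#'
#' @param tracks List of `Track`s.
#' @param min_frames Minimum number of observations (default 6).
#' @return Filtered track list.
#' @export
filter_min_length <- function(tracks, min_frames = 6L) {
  keep <- vapply(tracks, function(tr) length(tr$obs) >= min_frames,
                 logical(1))
  tracks[keep]
}

#' Tracks as a tidy data frame
#'
#' @param tracks List of `Track`s.
#' @return data.frame with `track_id, frame, plane, x_um, y_um, area_um2`.
#' @export
tracks_to_df <- function(tracks) {
  if (!length(tracks))
    return(data.frame(track_id = integer(0), frame = integer(0),
                      plane = integer(0), x_um = numeric(0),
                      y_um = numeric(0), area_um2 = numeric(0)))
  do.call(rbind, lapply(tracks, function(tr) {
    df <- detections_to_df(tr$obs)
    data.frame(track_id = tr$track_id, frame = df$frame, plane = df$plane,
               x_um = df$x_um, y_um = df$y_um, area_um2 = df$area_um2)
  }))
}
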