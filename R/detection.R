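# Per-frame, per-plane cell segmentation by intensity, size filtering,
# and Z-collapse of cells apparent in more than one optical plane.

# A Detection is a plain list: frame, plane, label (per frame/plane id),
# centroid = c(x, y) in um, area in um^2, intensity (summed), and
# pixels (n x 2 integer matrix of row, col subscripts).
new_detection <- function(frame, plane, label, centroid, area, intensity,
                          pixels) {
  list(frame = frame, plane = plane, label = label, centroid = centroid,
       area = area, intensity = intensity, pixels = pixels)
}

#' Segment cells in one preprocessed frame
#'
#' Thresholds the corrected cell-channel image (Otsu by default) and
#' returns one detection per connected component, with binary
#' (unweighted) centroids by default for exact testability.
#'
#' @param img `Y x X` corrected cell image (NA allowed for out-of-field).
#' @param pixel_size_xy um/px.
#' @param frame,plane Indices stored on each detection.
#' @param threshold `"otsu"` or `"fixed"`.
#' @param fixed_threshold Intensity cutoff when `threshold = "fixed"`.
#' @param weighted_centroid If `TRUE`, centroids are intensity-weighted.
#' @return List of detections (possibly empty).
#' @export
segment_frame <- function(img, pixel_size_xy, frame = NA_integer_,
                          plane = NA_integer_,
                          threshold = c("otsu", "fixed"),
                          fixed_threshold = NULL,
                          weighted_centroid = FALSE) {
  threshold <- match.arg(threshold)
  thr <- if (threshold == "otsu") otsu_threshold(img) else fixed_threshold
  mx <- suppressWarnings(max(img, na.rm = TRUE))
  if (!is.finite(mx) || thr >= mx) {
    if (threshold == "fixed" && is.finite(mx) && thr > mx)
      warning("segment_frame: threshold ", thr, " above image maximum ",
              signif(mx, 4), "; no detections")
    return(list())
  }
  binary <- !is.na(img) & img > thr
  lab_v <- cpp_label(as.vector(binary), dim(img), 2L)
  n_lab <- attr(lab_v, "max_label")
  lab <- matrix(lab_v, nrow(img))
  if (n_lab == 0L) return(list())
  out <- vector("list", n_lab)
  px2 <- pixel_size_xy^2
  idx <- which(lab > 0L, arr.ind = TRUE)
  labs <- lab[idx]
  ord <- order(labs)
  idx <- idx[ord, , drop = FALSE]
  labs <- labs[ord]
  starts <- c(1L, which(diff(labs) > 0L) + 1L, length(labs) + 1L)
  for (k in seq_len(n_lab)) {
    rows <- idx[starts[k]:(starts[k + 1L] - 1L), , drop = FALSE]
    vals <- img[rows]
    if (weighted_centroid) {
      w <- vals / sum(vals)
      cx <- sum((rows[, 2L] - 0.5) * w) * pixel_size_xy
      cy <- sum((rows[, 1L] - 0.5) * w) * pixel_size_xy
    } else {
      cx <- mean(rows[, 2L] - 0.5) * pixel_size_xy
      cy <- mean(rows[, 1L] - 0.5) * pixel_size_xy
    }
    out[[k]] <- new_detection(frame, plane, k, c(cx, cy),
                              nrow(rows) * px2, sum(vals), rows)
  }
  out
}

#' Filter detections by area
#'
#' Removes noise specks (below `min_area`) and cell clumps (above
#' `max_area`); removing clumps by size stands in for splitting fused
#' cells, which is out of scope.
#'
#' @param detections List of detections.
#' @param min_area,max_area Area bounds, um^2 (inclusive).
#' @return Filtered list with attributes `removed_small` and
#'   `removed_large` (counts).
#' @export
filter_by_size <- function(detections, min_area, max_area) {
  if (min_area >= max_area)
    stop("filter_by_size: min_area must be < max_area")
  areas <- vapply(detections, `[[`, numeric(1), "area")
  keep <- areas >= min_area & areas <= max_area
  out <- detections[keep]
  attr(out, "removed_small") <- sum(areas < min_area)
  attr(out, "removed_large") <- sum(areas > max_area)
  out
}

#' Collapse multi-plane appearances to the maximal-area plane
#'
#' Cells apparent in more than one Z plane are only considered in the
#' plane in which their size is maximal. Detections of one frame whose
#' centroids lie within `match_radius` in adjacent planes are grouped
#' (transitively); each group keeps the member with the largest area,
#' ties broken by lower plane index, then higher summed intensity.
#'
#' @param detections List of detections from one frame (any set of
#'   planes).
#' @param match_radius Grouping radius in um (default: one cell radius is
#'   a sensible choice; there is no canonical value).
#' @return The collapsed detection list. Never larger than the input;
#'   idempotent.
#' @export
collapse_z <- function(detections, match_radius) {
  n <- length(detections)
  if (n <= 1L) return(detections)
  planes <- vapply(detections, `[[`, numeric(1), "plane")
  cx <- vapply(detections, function(d) d$centroid[1L], numeric(1))
  cy <- vapply(detections, function(d) d$centroid[2L], numeric(1))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (abs(planes[i] - planes[j]) != 1L) next
    if ((cx[i] - cx[j])^2 + (cy[i] - cy[j])^2 > match_radius^2) next
    ri <- find(i)
    rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  keep <- logical(n)
  for (g in unique(roots)) {
    members <- which(roots == g)
    areas <- vapply(detections[members], `[[`, numeric(1), "area")
    best <- members[areas == max(areas)]
    if (length(best) > 1L) {
      pl <- planes[best]
      best <- best[pl == min(pl)]
      if (length(best) > 1L) {
        ints <- vapply(detections[best], `[[`, numeric(1), "intensity")
        best <- best[which.max(ints)]
      }
    }
    keep[best[1L]] <- TRUE
  }
  detections[keep]
}

#' Detections as a data frame
#'
#' @param detections List of detections.
#' @return data.frame with `frame, plane, label, x_um, y_um, area_um2`.
#' @export
detections_to_df <- function(detections) {
  if (!length(detections))
    return(data.frame(frame = integer(0), plane = integer(0),
                      label = integer(0), x_um = numeric(0),
                      y_um = numeric(0), area_um2 = numeric(0)))
  data.frame(
    frame = vapply(detections, `[[`, numeric(1), "frame"),
    plane = vapply(detections, `[[`, numeric(1), "plane"),
    label = vapply(detections, `[[`, numeric(1), "label"),
    x_um = vapply(detections, function(d) d$centroid[1L], numeric(1)),
    y_um = vapply(detections, function(d) d$centroid[2L], numeric(1)),
    area_um2 = vapply(detections, `[[`, numeric(1), "area"))
}
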