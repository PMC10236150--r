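# 3D invasion-distance quantification in Matrigel Z-stacks: intensity
# thresholding, distance-transform-seeded 3D watershed to separate
# touching nuclei, centroids, 10th-percentile baseline normalization and
# threshold fractions.

# Linear-interpolation percentile between order statistics (the common
# "type 7" convention): for sorted x and p in [0,1], the value at rank
# 1 + (n-1)p, linearly interpolated. The workflow's baseline is the 10th
# percentile of all cells' z coordinates per image.
percentile_linear <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  if (n == 1L) return(x)
  h <- (n - 1) * p
  lo <- floor(h)
  x[lo + 1L] + (h - lo) * (x[min(lo + 2L, n)] - x[lo + 1L])
}

#' Segment nuclei in a 3D stack
#'
#' Global intensity threshold (Otsu by default) to a binary volume, then
#' a 3D watershed seeded from local maxima of the Euclidean distance
#' transform separates touching nuclei. Seeds closer than
#' `min_seed_separation` are pruned (strongest first), so one nucleus
#' yields one label.
#'
#' @param x A `MatrigelStack` from [generate_matrigel_stack()], or a
#'   `Z x Y x X` numeric array (then `pixel_size_xy` and `z_step` are
#'   required).
#' @param threshold `"otsu"` or `"fixed"`.
#' @param fixed_threshold Cutoff for `threshold = "fixed"`.
#' @param min_seed_separation Minimum distance between watershed seeds,
#'   um (default: one nucleus radius is sensible; there is no canonical
#'   rule).
#' @param pixel_size_xy,z_step Calibration for plain arrays.
#' @return Integer label array of the input shape with attribute
#'   `n_labels`; 0 labels (with a warning) when the foreground is empty.
#' @export
segment_nuclei_3d <- function(x, threshold = c("otsu", "fixed"),
                              fixed_threshold = NULL,
                              min_seed_separation = 4,
                              pixel_size_xy = NULL, z_step = NULL) {
  threshold <- match.arg(threshold)
  if (inherits(x, "MatrigelStack")) {
    vol <- x$volume
    pixel_size_xy <- x$pixel_size_xy
    z_step <- x$z_step
  } else {
    vol <- x
    if (is.null(pixel_size_xy) || is.null(z_step))
      stop("segment_nuclei_3d: pixel_size_xy and z_step are required ",
           "for plain arrays")
  }
  stopifnot(length(dim(vol)) == 3L)
  thr <- if (threshold == "otsu") otsu_threshold(vol) else fixed_threshold
  binary <- !is.na(vol) & vol > thr
  if (!any(binary)) {
    warning("segment_nuclei_3d: empty foreground; no nuclei found")
    out <- array(0L, dim(vol))
    attr(out, "n_labels") <- 0L
    return(out)
  }
  d <- dim(vol)
  spacing <- c(z_step, pixel_size_xy, pixel_size_xy)  # dim order Z, Y, X
  edt <- array(cpp_edt(as.vector(binary), d, spacing), d)
  edt[!is.finite(edt)] <- max(edt[is.finite(edt)], 1) + 1
  # seed candidates: local maxima of the distance transform
  r_vox <- max(1L, as.integer(round(min_seed_separation /
                                      min(spacing))))
  mx <- cpp_max_filter(edt, d, r_vox)
  cand <- which(binary & array(edt == mx, d), arr.ind = TRUE)
  if (nrow(cand) == 0L) cand <- which(binary, arr.ind = TRUE)[1, , drop = FALSE]
  # physical coordinates and greedy pruning, strongest seed first
  pos <- cbind((cand[, 1L] - 1) * z_step,
               (cand[, 2L] - 0.5) * pixel_size_xy,
               (cand[, 3L] - 0.5) * pixel_size_xy)
  strength <- edt[cand]
  o <- order(strength, pos[, 1L], pos[, 2L], pos[, 3L], decreasing = TRUE)
  kept <- integer(0)
  for (i in o) {
    if (!length(kept) ||
        min(sqrt(colSums((t(pos[kept, , drop = FALSE]) - pos[i, ])^2))) >=
          min_seed_separation)
      kept <- c(kept, i)
  }
  seeds <- array(0L, d)
  seeds[cand[kept, , drop = FALSE]] <- seq_along(kept)
  lab <- cpp_watershed(-edt, as.vector(binary), as.vector(seeds), d)
  out <- array(lab, d)
  attr(out, "n_labels") <- length(kept)
  out
}

#' Invasion distances from a labeled volume
#'
#' Each nucleus position is its label centroid in micrometres, with z
#' measured from the bottom plane (`z = plane_index * z_step`, 0-based).
#' The per-image baseline is the 10th percentile (linear interpolation
#' between order statistics) of all centroid z values; the invasion
#' distance is `max(z - baseline, 0)`.
#'
#' @param labels Integer label array (`Z x Y x X`) from
#'   [segment_nuclei_3d()].
#' @param pixel_size_xy,z_step Calibration, um.
#' @param baseline_percentile Baseline quantile (default 0.10).
#' @return An `InvasionResult`: `centroids` data.frame
#'   (`label, x_um, y_um, z_um`), `baseline_z`, `distances` (>= 0, one
#'   per label).
#' @export
invasion_distances <- function(labels, pixel_size_xy, z_step,
                               baseline_percentile = 0.1) {
  n <- max(labels)
  if (n < 1L) stop("invasion_distances: no labels")
  idx <- which(labels > 0L, arr.ind = TRUE)
  lb <- labels[idx]
  zc <- tapply((idx[, 1L] - 1) * z_step, lb, mean)
  yc <- tapply((idx[, 2L] - 0.5) * pixel_size_xy, lb, mean)
  xc <- tapply((idx[, 3L] - 0.5) * pixel_size_xy, lb, mean)
  labs_present <- as.integer(names(zc))
  z <- as.numeric(zc)
  baseline <- percentile_linear(z, baseline_percentile)
  structure(list(centroids = data.frame(label = labs_present,
                                        x_um = as.numeric(xc),
                                        y_um = as.numeric(yc),
                                        z_um = z),
                 baseline_z = baseline,
                 distances = pmax(z - baseline, 0)),
            class = "InvasionResult")
}

#' Fractions of cells invading beyond thresholds
#'
#' The fraction of cells whose baseline-corrected invasion distance is
#' strictly greater than each threshold ("migrating further than 10 and
#' 100 um").
#'
#' @param result An `InvasionResult`.
#' @param thresholds Positive distances, um (default `c(10, 100)`).
#' @return Named numeric vector of fractions in `[0, 1]`, non-increasing
#'   in the threshold.
#' @export
fraction_beyond <- function(result, thresholds = c(10, 100)) {
  stopifnot(inherits(result, "InvasionResult"), all(thresholds > 0))
  out <- vapply(thresholds, function(th) mean(result$distances > th),
                numeric(1))
  names(out) <- paste0(">", thresholds)
  out
}

#' @export
print.InvasionResult <- function(x, ...) {
  cat(sprintf("InvasionResult: %d cells, baseline z = %.2f um\n",
              nrow(x$centroids), x$baseline_z))
  fb <- fraction_beyond(x)
  cat(sprintf("  beyond 10 um: %.1f%%   beyond 100 um: %.1f%%\n",
              100 * fb[1L], 100 * fb[2L]))
  invisible(x)
}
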