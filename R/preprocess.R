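# Sample-drift correction from the ECM channel, bleed-through and
# background correction, and smoothing of the cell channel. Drift is
# estimated by detecting matching features in subsequent frames of the
# ECM channel (intensity maxima with subpixel centroid refinement,
# matched by nearest neighbour, robust median displacement), with a
# phase-correlation fallback when too few features match. The transform
# family is pure translation: the slice rests on a static insert, so
# bulk motion is translational.

# --- feature detection -----------------------------------------------------

# Local intensity maxima of a lightly smoothed image (integer pixel
# positions). Returns a matrix with columns (x, y) in 0-based pixel
# coordinates, strongest first.
detect_features <- function(img, min_distance = 5L, max_features = 100L) {
  img[is.na(img)] <- stats::median(img, na.rm = TRUE)
  sm <- smooth2d(img, radius = 1L, passes = 2L)
  ny <- nrow(sm)
  nx <- ncol(sm)
  mx <- matrix(cpp_max_filter(as.numeric(sm), c(ny, nx), min_distance),
               ny, nx)
  thr <- stats::quantile(sm, 0.6, names = FALSE)
  cand <- which(sm == mx & sm > thr, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(matrix(numeric(0), 0, 2))
  o <- order(sm[cand], decreasing = TRUE)
  cand <- cand[utils::head(o, max_features), , drop = FALSE]
  cbind(cand[, 2L] - 1, cand[, 1L] - 1)
}

# Joint subpixel refinement of the frame-to-frame translation: the sum of
# squared differences between patches around the matched features in `a`
# and the bilinearly shifted frame `b` is minimized on a coarse-to-fine
# offset grid around the integer displacement d0. Evaluating one global
# offset for all patches at once avoids the per-feature "pixel locking"
# bias that plagues independent parabola fits at fractional shifts.
# Returns c(dx, dy) or NULL if no feature patch is usable.
refine_shift_global <- function(a, b, feats, d0, patch = 6L) {
  ny <- nrow(a)
  nx <- ncol(a)
  guard <- patch + ceiling(max(abs(d0))) + 3L
  ok <- feats[, 1L] >= guard & feats[, 1L] < nx - guard &
    feats[, 2L] >= guard & feats[, 2L] < ny - guard
  feats <- feats[ok, , drop = FALSE]
  if (nrow(feats) == 0L) return(NULL)
  off <- -patch:patch
  rows <- as.vector(outer(rep(off, each = length(off)), feats[, 2L] + 1L,
                          "+"))
  cols <- as.vector(outer(rep(off, times = length(off)), feats[, 1L] + 1L,
                          "+"))
  A <- a[cbind(rows, cols)]
  ssd_at <- function(dx, dy) {
    # sample b at (col - 1 + dx, row - 1 + dy), bilinear
    xs <- cols - 1 + dx
    ys <- rows - 1 + dy
    x0 <- floor(xs)
    y0 <- floor(ys)
    fx <- xs - x0
    fy <- ys - y0
    i0 <- y0 + 1L
    j0 <- x0 + 1L
    v <- (1 - fy) * (1 - fx) * b[cbind(i0, j0)] +
      (1 - fy) * fx * b[cbind(i0, j0 + 1L)] +
      fy * (1 - fx) * b[cbind(i0 + 1L, j0)] +
      fy * fx * b[cbind(i0 + 1L, j0 + 1L)]
    sum((v - A)^2)
  }
  best <- d0
  for (step_px in c(0.5, 0.125)) {
    grid <- seq(-2 * step_px, 2 * step_px, by = step_px)
    ssd <- matrix(NA_real_, length(grid), length(grid))
    for (iu in seq_along(grid)) for (iv in seq_along(grid))
      ssd[iv, iu] <- ssd_at(best[1L] + grid[iu], best[2L] + grid[iv])
    k <- which(ssd == min(ssd), arr.ind = TRUE)[1L, ]
    du <- dv <- 0
    if (ssd[k[1L], k[2L]] > 0) {
      para <- function(cm, c0, cp) {
        den <- cm - 2 * c0 + cp
        if (!is.finite(den) || den <= 0) 0
        else max(-1, min(1, 0.5 * (cm - cp) / den))
      }
      if (k[2L] > 1L && k[2L] < length(grid))
        du <- para(ssd[k[1L], k[2L] - 1L], ssd[k[1L], k[2L]],
                   ssd[k[1L], k[2L] + 1L]) * step_px
      if (k[1L] > 1L && k[1L] < length(grid))
        dv <- para(ssd[k[1L] - 1L, k[2L]], ssd[k[1L], k[2L]],
                   ssd[k[1L] + 1L, k[2L]]) * step_px
    }
    best <- c(best[1L] + grid[k[2L]] + du, best[2L] + grid[k[1L]] + dv)
  }
  best
}

# Translation between two frames by phase correlation with parabolic
# subpixel peak refinement. Returns c(dx, dy) such that `b` looks like
# `a` translated by +(dx, dy).
phase_correlation <- function(a, b) {
  a[is.na(a)] <- stats::median(a, na.rm = TRUE)
  b[is.na(b)] <- stats::median(b, na.rm = TRUE)
  a <- a - mean(a)
  b <- b - mean(b)
  Fa <- stats::fft(a)
  Fb <- stats::fft(b)
  R <- Fb * Conj(Fa)
  mag <- Mod(R)
  if (all(mag < 1e-12)) stop("phase_correlation: featureless frames")
  R <- R / pmax(mag, 1e-12)
  cc <- Re(stats::fft(R, inverse = TRUE)) / length(R)
  ny <- nrow(cc)
  nx <- ncol(cc)
  pk <- which.max(cc)
  pi0 <- (pk - 1L) %% ny          # 0-based row of peak
  pj0 <- (pk - 1L) %/% ny         # 0-based col of peak
  sub <- function(i, j) cc[(i %% ny) + 1L, (j %% nx) + 1L]
  para <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (abs(den) < 1e-12) 0 else 0.5 * (cm - cp) / den
  }
  dj <- para(sub(pi0, pj0 - 1L), sub(pi0, pj0), sub(pi0, pj0 + 1L))
  di <- para(sub(pi0 - 1L, pj0), sub(pi0, pj0), sub(pi0 + 1L, pj0))
  sx <- pj0 + dj
  sy <- pi0 + di
  if (sx > nx / 2) sx <- sx - nx
  if (sy > ny / 2) sy <- sy - ny
  c(sx, sy)
}

drift_model <- function(df) {
  stopifnot(all(c("frame", "dx", "dy", "theta", "residual") %in% names(df)))
  if (df$dx[1L] != 0 || df$dy[1L] != 0)
    stop("drift_model: frame 1 must be the identity transform")
  structure(df, class = c("DriftModel", "data.frame"))
}

#' Estimate sample drift from the ECM channel
#'
#' Detects features (local intensity maxima, subpixel-refined) in
#' subsequent frames of the ECM channel, matches them by nearest
#' neighbour, and takes the per-frame translation as the componentwise
#' median of matched displacements; pairwise transforms are composed into
#' frame-1-referenced cumulative transforms. Frames with fewer than
#' `n_min` matches fall back to phase correlation.
#'
#' @param x An `ImageStack` with an `"ecm"` channel (maximum-projected
#'   over Z for estimation) or a `T x Y x X` numeric array of ECM frames.
#' @param max_drift Guard on the per-frame displacement, px: candidate
#'   matches farther apart are ignored, and a larger estimate triggers a
#'   warning.
#' @param n_min Minimum matched features before falling back to phase
#'   correlation.
#' @return A `DriftModel`: data.frame with `frame`, cumulative `dx`,
#'   `dy` (px, relative to frame 1), `theta` (always 0; the transform
#'   family is pure translation) and `residual` (median absolute
#'   deviation of matched displacements, px).
#' @export
estimate_drift <- function(x, max_drift = 10, n_min = 5L) {
  frames <- if (inherits(x, "ImageStack")) {
    if (!"ecm" %in% names(x$channel_roles))
      stop("estimate_drift: stack has no 'ecm' channel role")
    d <- dim(x$data)
    ecm_ch <- x$channel_roles[["ecm"]]
    arr <- array(NA_real_, d[c(1L, 3L, 4L)])
    for (t in seq_len(d[1L]))
      arr[t, , ] <- apply(array(x$data[t, , , , ecm_ch], d[c(2L, 3L, 4L)]),
                          c(2L, 3L), max)
    arr
  } else x
  nT <- dim(frames)[1L]
  if (nT < 2L) stop("estimate_drift: need at least 2 frames")
  step <- matrix(0, nT, 2)
  resid <- numeric(nT)
  prev_feat <- detect_features(frames[1L, , ])
  for (t in 2L:nT) {
    cur <- frames[t, , ]
    cur_feat <- detect_features(cur)
    est <- NULL
    if (nrow(prev_feat) >= n_min && nrow(cur_feat) >= n_min) {
      # nearest neighbour in the next frame for every feature, then
      # patch-based subpixel refinement of each matched displacement
      d2 <- outer(prev_feat[, 1L], cur_feat[, 1L], "-")^2 +
        outer(prev_feat[, 2L], cur_feat[, 2L], "-")^2
      j <- max.col(-d2, ties.method = "first")
      disp_int <- cur_feat[j, , drop = FALSE] - prev_feat
      keep <- which(sqrt(rowSums(disp_int^2)) <= max_drift)
      if (length(keep) >= n_min) {
        d0 <- c(stats::median(disp_int[keep, 1L]),
                stats::median(disp_int[keep, 2L]))
        resid[t] <- stats::median(sqrt((disp_int[keep, 1L] - d0[1L])^2 +
                                         (disp_int[keep, 2L] - d0[2L])^2))
        prev_f <- frames[t - 1L, , ]
        prev_f[is.na(prev_f)] <- stats::median(prev_f, na.rm = TRUE)
        cur_f <- cur
        cur_f[is.na(cur_f)] <- stats::median(cur_f, na.rm = TRUE)
        est <- refine_shift_global(prev_f, cur_f,
                                   prev_feat[keep, , drop = FALSE],
                                   round(d0))
      }
    }
    if (is.null(est)) {
      est <- tryCatch(phase_correlation(frames[t - 1L, , ], cur),
                      error = function(e)
                        stop("estimate_drift: too few features in frame ",
                             t, " and phase-correlation fallback failed: ",
                             conditionMessage(e)))
      resid[t] <- NA_real_
    }
    if (sqrt(sum(est^2)) > max_drift)
      warning("estimate_drift: frame ", t, " drift estimate ",
              sprintf("%.1f", sqrt(sum(est^2))), " px exceeds max_drift")
    step[t, ] <- est
    prev_feat <- cur_feat
  }
  cum <- apply(step, 2L, cumsum)
  drift_model(data.frame(frame = seq_len(nT), dx = cum[, 1L],
                         dy = cum[, 2L], theta = 0, residual = resid))
}

#' Resample a stack into the frame-1 reference
#'
#' Undoes the estimated drift by translating every channel and plane of
#' frame t by minus the cumulative drift. Pixels that fall outside the
#' acquired field become `NA` (invalid), never zero.
#'
#' @param stack An `ImageStack`.
#' @param model A `DriftModel` with one row per frame.
#' @return The corrected `ImageStack`.
#' @export
apply_drift <- function(stack, model) {
  d <- dim(stack$data)
  if (nrow(model) != d[1L])
    stop("apply_drift: model has ", nrow(model), " rows but the stack has ",
         d[1L], " frames")
  out <- stack
  for (t in seq_len(d[1L])) {
    sh <- c(-model$dx[t], -model$dy[t])
    if (all(sh == 0)) next
    for (z in seq_len(d[2L])) for (ch in seq_len(d[5L]))
      out$data[t, z, , , ch] <-
        translate_bilinear(stack$data[t, z, , , ch], sh, pad = "na")
  }
  out
}

#' Estimate the ECM-to-cell bleed-through coefficient
#'
#' Robust regression of cell-channel on ECM-channel intensities restricted
#' to ECM-bright pixels: after subtracting each channel's robust floor,
#' the coefficient is the median pixelwise ratio. The median makes the
#' estimate insensitive to the minority of pixels actually containing
#' cells.
#'
#' @param cell,ecm Co-registered images (matrices or equal-shaped arrays).
#' @return Estimated non-negative bleed coefficient.
#' @export
estimate_bleed <- function(cell, ecm) {
  v_c <- as.numeric(cell)
  v_e <- as.numeric(ecm)
  ok <- !is.na(v_c) & !is.na(v_e)
  v_c <- v_c[ok]
  v_e <- v_e[ok]
  floor_of <- function(v) stats::median(v[v <= stats::quantile(v, 0.25)])
  bg_c <- floor_of(v_c)
  bg_e <- floor_of(v_e)
  sel <- v_e > otsu_threshold(v_e)
  if (!any(sel)) return(0)
  ratio <- (v_c[sel] - bg_c) / (v_e[sel] - bg_e)
  max(stats::median(ratio, na.rm = TRUE), 0)
}

#' Background, bleed-through and median-filter correction of the cell channel
#'
#' Computes `median_filter(max(cell - bleed_coeff * ecm - background, 0))`
#' per frame, where the background is a robust per-frame floor (median of
#' the lowest-intensity quartile). This is the preprocessing applied to
#' the cell-tracker channel before segmentation.
#'
#' @param cell,ecm Co-registered cell and ECM images: `Y x X` matrices or
#'   `T x Y x X` arrays.
#' @param bleed_coeff Bleed-through coefficient; `NULL` estimates it from
#'   the data with [estimate_bleed()] (one coefficient per acquisition).
#' @param median_radius Half-width of the median filter window (1 = 3x3).
#' @return Corrected image(s), same shape as `cell`, everywhere >= 0
#'   (NA out-of-field pixels preserved), with the effective coefficient in
#'   attribute `bleed_coeff`.
#' @export
correct_cell_channel <- function(cell, ecm, bleed_coeff = NULL,
                                 median_radius = 1L) {
  one_frame <- is.matrix(cell)
  if (one_frame) {
    cell <- array(cell, c(1L, dim(cell)))
    ecm <- array(ecm, c(1L, dim(ecm)))
  }
  stopifnot(identical(dim(cell), dim(ecm)))
  if (is.null(bleed_coeff)) bleed_coeff <- estimate_bleed(cell, ecm)
  if (bleed_coeff < 0)
    stop("correct_cell_channel: bleed_coeff must be >= 0")
  out <- cell
  for (t in seq_len(dim(cell)[1L])) {
    fr <- cell[t, , ] - bleed_coeff * ecm[t, , ]
    v <- fr[!is.na(fr)]
    # robust floor of the residual signal; a background is an intensity,
    # so it is never taken negative
    bg <- if (length(v))
      max(stats::median(v[v <= stats::quantile(v, 0.25)]), 0) else 0
    fr <- pmax(fr - bg, 0)
    out[t, , ] <- cpp_median_filter(fr, as.integer(median_radius))
  }
  if (all(out == 0, na.rm = TRUE))
    warning("correct_cell_channel: corrected image is all zero; ",
            "bleed_coeff may be too large")
  res <- if (one_frame) out[1L, , ] else out
  attr(res, "bleed_coeff") <- bleed_coeff
  res
}
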