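# Internal numerical helpers shared across modules.

#' Otsu threshold of an image
#'
#' Histogram-based threshold maximizing between-class variance, the default
#' intensity threshold for cell and nucleus segmentation. `NA` pixels
#' (out-of-field after drift correction) are ignored.
#'
#' @param x Numeric vector, matrix or array of intensities.
#' @param n_bins Number of histogram bins.
#' @return Scalar threshold; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("otsu_threshold: no finite pixels")
  lo <- min(v)
  hi <- max(v)
  if (hi <= lo) return(lo)
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  h <- as.numeric(tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                                        all.inside = TRUE), nbins = n_bins))
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  n <- w[n_bins]
  mu <- m[n_bins]
  w0 <- w[-n_bins]
  m0 <- m[-n_bins]
  valid <- w0 > 0 & w0 < n
  between <- rep(-Inf, n_bins - 1L)
  between[valid] <- (mu * w0[valid] - n * m0[valid])^2 /
    (w0[valid] * (n - w0[valid]))
  k <- which.max(between)
  breaks[k + 1L]
}

# Box blur by running means along rows then columns (edge-replicated);
# `passes` repetitions approximate a Gaussian.
smooth2d <- function(img, radius = 1L, passes = 3L) {
  box1 <- function(m, r) {
    n <- nrow(m)
    pad <- rbind(m[rep(1L, r), , drop = FALSE], m,
                 m[rep(n, r), , drop = FALSE])
    cs <- apply(pad, 2L, cumsum)
    cs <- rbind(0, cs)
    (cs[(2L * r + 2L):(n + 2L * r + 1L), , drop = FALSE] -
       cs[1L:n, , drop = FALSE]) / (2L * r + 1L)
  }
  for (i in seq_len(passes)) {
    img <- box1(img, radius)
    img <- t(box1(t(img), radius))
  }
  img
}

# Translate a 2D image by a (possibly subpixel) offset using bilinear
# interpolation. `shift` is c(dx, dy) in pixels: the content moves +dx along
# x (columns) and +dy along y (rows). Out-of-field samples are reflected
# (`pad = "reflect"`) or marked invalid (`pad = "na"`).
translate_bilinear <- function(img, shift, pad = c("reflect", "na")) {
  pad <- match.arg(pad)
  ny <- nrow(img)
  nx <- ncol(img)
  dx <- shift[1L]
  dy <- shift[2L]
  # sample source coordinates (0-based)
  xs <- (seq_len(nx) - 1) - dx
  ys <- (seq_len(ny) - 1) - dy
  oob_x <- xs < 0 | xs > nx - 1
  oob_y <- ys < 0 | ys > ny - 1
  reflect <- function(p, n) {
    # reflect about the borders until inside [0, n-1]
    period <- 2 * (n - 1)
    p <- abs(p) %% period
    ifelse(p > n - 1, period - p, p)
  }
  xs <- reflect(xs, nx)
  ys <- reflect(ys, ny)
  x0 <- pmin(floor(xs), nx - 2)
  y0 <- pmin(floor(ys), ny - 2)
  fx <- xs - x0
  fy <- ys - y0
  i0 <- y0 + 1L
  j0 <- x0 + 1L
  # outer-product weights via recycling: rows vary with fy, cols with fx
  wy <- matrix(fy, ny, nx)
  wx <- matrix(fx, ny, nx, byrow = TRUE)
  ii <- matrix(i0, ny, nx)
  jj <- matrix(j0, ny, nx, byrow = TRUE)
  idx <- function(di, dj) cbind(as.vector(ii + di), as.vector(jj + dj))
  out <- (1 - wy) * (1 - wx) * matrix(img[idx(0L, 0L)], ny, nx) +
    (1 - wy) * wx * matrix(img[idx(0L, 1L)], ny, nx) +
    wy * (1 - wx) * matrix(img[idx(1L, 0L)], ny, nx) +
    wy * wx * matrix(img[idx(1L, 1L)], ny, nx)
  if (pad == "na") {
    out[oob_y, ] <- NA_real_
    out[, oob_x] <- NA_real_
  }
  out
}

# Binary morphology on a logical matrix/array via box min/max filters.
dilate <- function(mask, radius = 1L) {
  d <- dim(mask)
  out <- cpp_max_filter(as.numeric(mask), as.integer(d), as.integer(radius))
  array(out > 0.5, d)
}

erode <- function(mask, radius = 1L) {
  d <- dim(mask)
  out <- -cpp_max_filter(-as.numeric(mask), as.integer(d), as.integer(radius))
  array(out > 0.5, d)
}

closing <- function(mask, radius = 1L) erode(dilate(mask, radius), radius)

# Remove connected components smaller than min_px pixels.
remove_small_objects <- function(mask, min_px) {
  d <- dim(mask)
  lab <- cpp_label(as.vector(mask), as.integer(d), 2L)
  if (attr(lab, "max_label") == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_px)
  array(lab %in% keep, d)
}

# Preserve the caller's RNG state while running deterministic simulations.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
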