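# Calibrated image containers and region-mask handling.
#
# Coordinate convention (used everywhere in the package): pixel indices are
# 0-based in formulas, 1-based in R subscripts; the physical position of a
# pixel center is (index + 0.5) * pixel_size, so the pixel at R subscript
# [row = 1, col = 1] sits at (x, y) = (0.5, 0.5) * pixel_size_xy. x runs
# along columns, y along rows, z along planes (bottom plane first).

#' Construct a calibrated multichannel time-lapse stack
#'
#' @param data 5-D numeric array with dimensions `T x Z x Y x X x C`
#'   (frames, optical planes, rows, columns, channels).
#' @param pixel_size_xy Lateral calibration, micrometres per pixel.
#' @param z_spacing Distance between optical planes, micrometres.
#' @param frame_interval Time between frames, seconds.
#' @param channel_roles Named integer vector mapping roles (any of
#'   `"cell"`, `"ecm"`, `"tumor"`) to channel indices; must be injective.
#' @return An `ImageStack` object.
#' @export
image_stack <- function(data, pixel_size_xy, z_spacing, frame_interval,
                        channel_roles) {
  stopifnot(is.array(data), length(dim(data)) == 5L)
  if (pixel_size_xy <= 0 || z_spacing <= 0 || frame_interval <= 0)
    stop("image_stack: all calibration values must be > 0")
  nC <- dim(data)[5L]
  channel_roles <- vapply(channel_roles, as.integer, integer(1))
  if (anyDuplicated(channel_roles))
    stop("image_stack: channel_roles must be injective")
  if (any(channel_roles < 1L | channel_roles > nC))
    stop("image_stack: channel_roles reference ", length(channel_roles),
         " roles but the stack has only ", nC, " channels")
  bad <- setdiff(names(channel_roles), c("cell", "ecm", "tumor"))
  if (length(bad)) stop("image_stack: unknown channel role(s): ",
                        paste(bad, collapse = ", "))
  structure(list(data = data, pixel_size_xy = pixel_size_xy,
                 z_spacing = z_spacing, frame_interval = frame_interval,
                 channel_roles = channel_roles),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(paste0("ImageStack: %d frame(s) x %d plane(s) x %d x %d px x",
                     " %d channel(s)\n"), d[1], d[2], d[3], d[4], d[5]))
  cat(sprintf("  pixel %.4g um, z-spacing %.4g um, frame interval %.4g s\n",
              x$pixel_size_xy, x$z_spacing, x$frame_interval))
  cat("  roles:", paste(names(x$channel_roles), x$channel_roles,
                        sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Pull one 2D frame (Y x X matrix) out of a stack.
stack_frame <- function(stack, t, z, channel) {
  if (is.character(channel)) channel <- stack$channel_roles[[channel]]
  stack$data[t, z, , , channel]
}

#' Write an `ImageStack` as a multi-page TIFF
#'
#' Pages are ordered T (slowest), then Z, then C (fastest); the axis order
#' and full calibration are stored as JSON in the first page's
#' ImageDescription tag, so [load_stack()] can restore the stack without
#' side information.
#'
#' @param stack An `ImageStack`.
#' @param path Output TIFF path.
#' @param dtype Pixel storage type (see [write_tiff()]); `"float64"` is
#'   lossless for synthetic data.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, dtype = "float32") {
  d <- dim(stack$data)
  meta <- list(axes = "TZYXC", shape = d,
               pixel_size_xy = stack$pixel_size_xy,
               z_spacing = stack$z_spacing,
               frame_interval = stack$frame_interval,
               channel_roles = as.list(stack$channel_roles))
  pages <- vector("list", d[1] * d[2] * d[5])
  k <- 0L
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (ch in seq_len(d[5])) {
    k <- k + 1L
    pages[[k]] <- stack$data[t, z, , , ch]
  }
  write_tiff(pages, path, dtype = dtype,
             description = jsonlite::toJSON(meta, auto_unbox = TRUE))
  invisible(path)
}

#' Load a calibrated stack from a multi-page TIFF
#'
#' Reads stacks written by [write_stack()] (self-describing via embedded
#' JSON) or plain multi-page TIFFs, in which case the page layout and the
#' calibration must be supplied explicitly -- they are never silently
#' defaulted.
#'
#' @param path TIFF file.
#' @param calibration Optional list with `pixel_size_xy`, `z_spacing`,
#'   `frame_interval`; overrides (or supplies, for plain TIFFs) embedded
#'   metadata.
#' @param channel_roles Optional named integer vector (see
#'   [image_stack()]).
#' @param shape Optional integer vector `c(T, Z, C)` describing how the
#'   pages are laid out (T slowest, C fastest) when the file carries no
#'   metadata.
#' @return An `ImageStack`.
#' @export
load_stack <- function(path, calibration = NULL, channel_roles = NULL,
                       shape = NULL) {
  if (!file.exists(path)) stop("load_stack: no such file: ", path)
  pages <- read_tiff(path)
  meta <- NULL
  desc <- attr(pages, "description")
  if (!is.null(desc))
    meta <- tryCatch(jsonlite::fromJSON(desc), error = function(e) NULL)
  n_pages <- length(pages)
  if (!is.null(meta) && identical(meta$axes, "TZYXC")) {
    d <- as.integer(meta$shape)
    tzc <- d[c(1L, 2L, 5L)]
  } else if (!is.null(shape)) {
    tzc <- as.integer(shape)
  } else {
    # no metadata, no explicit layout: refuse, listing interpretations
    cands <- list()
    for (tt in seq_len(n_pages)) for (zz in seq_len(n_pages / tt))
      if (n_pages %% (tt * zz) == 0L)
        cands[[length(cands) + 1L]] <- c(tt, zz, n_pages / (tt * zz))
    ex <- vapply(utils::head(cands, 6L),
                 function(v) sprintf("T=%d,Z=%d,C=%d", v[1], v[2], v[3]), "")
    stop("load_stack: axis order of ", n_pages, " pages is ambiguous; pass ",
         "shape = c(T, Z, C). Candidates include: ",
         paste(ex, collapse = "; "))
  }
  if (prod(tzc) != n_pages)
    stop("load_stack: shape c(T,Z,C) = ", paste(tzc, collapse = "x"),
         " does not match ", n_pages, " pages")
  cal <- list(pixel_size_xy = NULL, z_spacing = NULL, frame_interval = NULL)
  if (!is.null(meta))
    for (f in names(cal)) cal[[f]] <- meta[[f]]
  if (!is.null(calibration))
    for (f in names(calibration)) cal[[f]] <- calibration[[f]]
  missing <- names(cal)[vapply(cal, is.null, TRUE)]
  if (length(missing))
    stop("load_stack: calibration not in file metadata and not supplied: ",
         paste(missing, collapse = ", "))
  cal <- lapply(cal, as.numeric)   # JSON round trips may yield integers
  if (is.null(channel_roles)) {
    if (!is.null(meta) && !is.null(meta$channel_roles))
      channel_roles <- unlist(meta$channel_roles)
    else stop("load_stack: channel_roles not in metadata and not supplied")
  }
  ny <- nrow(pages[[1L]])
  nx <- ncol(pages[[1L]])
  data <- array(NA_real_, c(tzc[1L], tzc[2L], ny, nx, tzc[3L]))
  k <- 0L
  for (t in seq_len(tzc[1L])) for (z in seq_len(tzc[2L]))
    for (ch in seq_len(tzc[3L])) {
      k <- k + 1L
      data[t, z, , , ch] <- pages[[k]]
    }
  image_stack(data, cal$pixel_size_xy, cal$z_spacing, cal$frame_interval,
              channel_roles)
}

#' Construct a tumor/ECM region mask set
#'
#' The two compartments partition the field: the tumor mask is always the
#' logical complement of the ECM (fibronectin-positive) mask, per plane.
#'
#' @param ecm Logical array `Z x Y x X` (or a `Y x X` matrix for a single
#'   plane), `TRUE` on the ECM/stromal compartment.
#' @param source `"manual"` or `"derived"`.
#' @param provenance Optional list describing how a derived mask was made.
#' @return A `RegionMaskSet`.
#' @export
region_mask_set <- function(ecm, source = c("manual", "derived"),
                            provenance = NULL) {
  source <- match.arg(source)
  if (is.matrix(ecm)) ecm <- array(ecm, c(1L, dim(ecm)))
  stopifnot(is.array(ecm), length(dim(ecm)) == 3L)
  ecm <- array(as.logical(ecm), dim(ecm))
  if (anyNA(ecm)) stop("region_mask_set: masks must be binary, no NA")
  structure(list(ecm = ecm, tumor = !ecm, source = source,
                 provenance = provenance),
            class = "RegionMaskSet")
}

#' @export
print.RegionMaskSet <- function(x, ...) {
  d <- dim(x$ecm)
  cat(sprintf("RegionMaskSet (%s): %d plane(s) of %d x %d px, %.1f%% ECM\n",
              x$source, d[1], d[2], d[3], 100 * mean(x$ecm)))
  invisible(x)
}

#' Derive tumor/ECM masks from the fibronectin channel
#'
#' The reference workflow for slice assays draws ECM regions by hand
#' from the fibronectin staining; this operation automates that step for
#' data without manual ROIs. Each plane's ECM channel is median-projected over time,
#' thresholded (Otsu by default), morphologically closed and cleaned of
#' small specks; fibronectin-negative area is the tumor compartment.
#'
#' @param stack An `ImageStack` with an `"ecm"` channel, already
#'   drift-corrected (masks are defined once per acquisition and live in
#'   the corrected frame).
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_threshold Threshold intensity when `method = "fixed"`.
#' @param min_area Smallest ECM or tumor fragment kept, in square
#'   micrometres.
#' @param closing_radius Radius (px) of the morphological closing.
#' @return A `RegionMaskSet` with `source = "derived"`.
#' @export
derive_region_masks <- function(stack, method = c("otsu", "fixed"),
                                fixed_threshold = NULL, min_area = 25,
                                closing_radius = 1L) {
  method <- match.arg(method)
  if (!"ecm" %in% names(stack$channel_roles))
    stop("derive_region_masks: stack has no 'ecm' channel role")
  d <- dim(stack$data)
  nZ <- d[2L]
  min_px <- max(1L, round(min_area / stack$pixel_size_xy^2))
  ecm <- array(FALSE, c(nZ, d[3L], d[4L]))
  ecm_ch <- stack$channel_roles[["ecm"]]
  for (z in seq_len(nZ)) {
    frames <- stack$data[, z, , , ecm_ch, drop = FALSE]
    proj <- apply(array(frames, d[c(1L, 3L, 4L)]), c(2L, 3L),
                  stats::median, na.rm = TRUE)
    proj[is.nan(proj)] <- NA_real_   # pixels never inside the field
    if (all(proj == 0, na.rm = TRUE))
      stop("derive_region_masks: ECM channel is all zero in plane ", z,
           "; no region structure")
    thr <- if (method == "otsu") otsu_threshold(proj) else fixed_threshold
    m <- !is.na(proj) & proj > thr
    if (closing_radius > 0L) m <- closing(m, closing_radius)
    m <- remove_small_objects(m, min_px)
    # also fill small fibronectin-negative specks inside ECM so tiny holes
    # do not masquerade as tumor islets
    ecm[z, , ] <- !remove_small_objects(!m, min_px)
  }
  region_mask_set(ecm, source = "derived",
                  provenance = list(method = method,
                                    fixed_threshold = fixed_threshold,
                                    min_area = min_area,
                                    closing_radius = closing_radius))
}

#' Load manually drawn region masks
#'
#' One binary mask image per optical plane, ECM-positive pixels non-zero
#' (0/1 or 0/255 encodings accepted).
#'
#' @param paths Character vector of mask TIFF paths, bottom plane first.
#' @param expected_shape Optional `c(Y, X)` to validate against a stack.
#' @return A `RegionMaskSet` with `source = "manual"`.
#' @export
load_region_masks <- function(paths, expected_shape = NULL) {
  planes <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    pg <- read_tiff(paths[[i]])
    if (length(pg) != 1L)
      stop("load_region_masks: '", paths[[i]], "' must hold a single plane")
    m <- pg[[1L]]
    vals <- sort(unique(as.vector(m)))
    if (!all(vals %in% c(0, 1)) && !all(vals %in% c(0, 255)))
      stop("load_region_masks: non-binary values in plane ", i,
           " ('", paths[[i]], "')")
    if (!is.null(expected_shape) && !identical(dim(m),
                                               as.integer(expected_shape)))
      stop("load_region_masks: plane ", i, " is ", nrow(m), "x", ncol(m),
           " but expected ", expected_shape[1L], "x", expected_shape[2L])
    planes[[i]] <- m > 0
  }
  ecm <- array(FALSE, c(length(planes), dim(planes[[1L]])))
  for (i in seq_along(planes)) ecm[i, , ] <- planes[[i]]
  region_mask_set(ecm, source = "manual")
}

#' Write region masks as one 8-bit TIFF per plane
#'
#' @param masks A `RegionMaskSet`.
#' @param paths Output paths, one per plane (ECM mask, 0/255).
#' @return `paths`, invisibly.
#' @export
write_region_masks <- function(masks, paths) {
  nZ <- dim(masks$ecm)[1L]
  stopifnot(length(paths) == nZ)
  for (z in seq_len(nZ))
    write_tiff(masks$ecm[z, , ] * 255, paths[[z]], dtype = "uint8")
  invisible(paths)
}

# Region label ("tumor"/"ecm") at a physical position, by pixel lookup in
# the plane's ECM mask. Positions outside the field clamp to the border.
mask_lookup <- function(masks, x_um, y_um, plane, pixel_size_xy) {
  d <- dim(masks$ecm)
  col <- pmin(pmax(floor(x_um / pixel_size_xy) + 1, 1), d[3L])
  row <- pmin(pmax(floor(y_um / pixel_size_xy) + 1, 1), d[2L])
  ifelse(masks$ecm[cbind(plane, row, col)], "ecm", "tumor")
}
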