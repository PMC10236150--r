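# Synthetic slice-migration movies and Matrigel Z-stacks with exported
# ground truth. The generator emulates the acquisition geometry of the
# slice assay (nine optical planes over 63 um, one frame every 30 s,
# three channels: cell tracker, fibronectin/ECM, EpCAM/tumor) and the
# Matrigel readout (single-channel nuclei Z-stack, 2 um step). Cells move
# as persistent random walks whose fixed step length is speed * dt with a
# region-dependent speed, so compartment-conditional mean-speed recovery
# is exact in expectation.

#' Configuration of a synthetic slice scene
#'
#' Defaults mirror the slice acquisition (9 planes spanning 63 um, 30 s
#' frame interval); values the acquisition does not pin down (field size,
#' cell density, intensities, noise) are fixed at testable levels.
#'
#' @param n_frames,n_planes,height,width Scene dimensions (frames, planes,
#'   pixels).
#' @param pixel_size_xy,z_spacing,frame_interval Calibration (um/px, um,
#'   seconds).
#' @param n_cells Number of cells.
#' @param cell_radius Nominal cell radius, um (blobs are rendered as 2D
#'   Gaussians with sigma = cell_radius / 2).
#' @param speed_tumor,speed_ecm Mean speeds, um/min, applied according to
#'   the compartment the cell currently occupies.
#' @param turning_persistence In `[0, 1]`; headings are perturbed each step
#'   by wrapped-normal noise with sd `(1 - persistence) * pi`.
#' @param tumor_islet_spec List with `n` (islet count) and `radius_range`
#'   (um); islets are discs, the remainder of the field is ECM.
#' @param drift_per_frame Global stage drift, c(dx, dy) px per frame,
#'   applied cumulatively to all channels.
#' @param bleed_coeff Fraction of the ECM channel added to the cell
#'   channel before noise (spectral bleed-through).
#' @param noise List with `gaussian_sd` (additive read noise) and
#'   `poisson_scale` (photons per intensity unit; 0 disables shot noise).
#' @param intensities List with `cell`, `ecm`, `tumor` peak intensities.
#' @param min_separation Minimum initial distance between cells, um.
#' @param adjacent_plane_intensity Relative intensity with which each cell
#'   also appears in the two neighbouring planes (0 = single-plane cells;
#'   positive values exercise the Z-collapse rule).
#' @param rng_seed Integer seed; identical configs give bit-identical
#'   scenes.
#' @return A `SceneConfig` list.
#' @export
scene_config <- function(n_frames = 20L, n_planes = 9L, height = 160L,
                         width = 160L, pixel_size_xy = 1, z_spacing = 63 / 8,
                         frame_interval = 30, n_cells = 30L, cell_radius = 4,
                         speed_tumor = 4, speed_ecm = 2,
                         turning_persistence = 0.7,
                         tumor_islet_spec = list(n = 2L,
                                                 radius_range = c(30, 50)),
                         drift_per_frame = c(0.5, 0.3), bleed_coeff = 0.2,
                         noise = list(gaussian_sd = 10, poisson_scale = 1),
                         intensities = list(cell = 1000, ecm = 600,
                                            tumor = 600),
                         min_separation = 0, adjacent_plane_intensity = 0,
                         rng_seed = 1L) {
  cfg <- list(n_frames = as.integer(n_frames), n_planes = as.integer(n_planes),
              height = as.integer(height), width = as.integer(width),
              pixel_size_xy = pixel_size_xy, z_spacing = z_spacing,
              frame_interval = frame_interval, n_cells = as.integer(n_cells),
              cell_radius = cell_radius, speed_tumor = speed_tumor,
              speed_ecm = speed_ecm, turning_persistence = turning_persistence,
              tumor_islet_spec = tumor_islet_spec,
              drift_per_frame = drift_per_frame, bleed_coeff = bleed_coeff,
              noise = noise, intensities = intensities,
              min_separation = min_separation,
              adjacent_plane_intensity = adjacent_plane_intensity,
              rng_seed = as.integer(rng_seed))
  with(cfg, {
    if (n_frames < 1L || n_planes < 1L || height < 1L || width < 1L)
      stop("scene_config: all dimensions must be >= 1")
    if (n_cells < 0L) stop("scene_config: n_cells must be >= 0")
    if (speed_tumor < 0 || speed_ecm < 0)
      stop("scene_config: speeds must be >= 0")
    if (bleed_coeff < 0) stop("scene_config: bleed_coeff must be >= 0")
    if (turning_persistence < 0 || turning_persistence > 1)
      stop("scene_config: turning_persistence must be in [0, 1]")
    if (pixel_size_xy <= 0 || z_spacing <= 0 || frame_interval <= 0)
      stop("scene_config: calibration values must be > 0")
    if (cell_radius / pixel_size_xy < 1)
      stop("scene_config: cell_radius is smaller than 1 px at this ",
           "calibration; cells would be unresolvable")
  })
  structure(cfg, class = "SceneConfig")
}

# Add a 2D Gaussian blob to an image, in place (window of +-4 sigma).
add_blob2d <- function(img, x_um, y_um, amplitude, sigma_um, px) {
  ny <- nrow(img)
  nx <- ncol(img)
  s <- sigma_um / px
  cx <- x_um / px - 0.5   # 0-based pixel coordinates of the center
  cy <- y_um / px - 0.5
  jlo <- max(1L, floor(cx - 4 * s) + 1L)
  jhi <- min(nx, ceiling(cx + 4 * s) + 1L)
  ilo <- max(1L, floor(cy - 4 * s) + 1L)
  ihi <- min(ny, ceiling(cy + 4 * s) + 1L)
  if (jlo > jhi || ilo > ihi) return(img)   # blob fully out of field
  j <- jlo:jhi
  i <- ilo:ihi
  gy <- exp(-((i - 1) - cy)^2 / (2 * s^2))
  gx <- exp(-((j - 1) - cx)^2 / (2 * s^2))
  img[i, j] <- img[i, j] + amplitude * outer(gy, gx)
  img
}

apply_scene_noise <- function(img, noise) {
  v <- img
  if (!is.null(noise$poisson_scale) && noise$poisson_scale > 0) {
    lam <- pmax(v, 0) * noise$poisson_scale
    v <- stats::rpois(length(lam), lam) / noise$poisson_scale
    dim(v) <- dim(img)
  }
  if (!is.null(noise$gaussian_sd) && noise$gaussian_sd > 0)
    v <- v + stats::rnorm(length(v), 0, noise$gaussian_sd)
  v
}

#' Generate a synthetic tumor-slice migration movie
#'
#' Renders a three-channel (cell tracker, ECM, tumor) time-lapse stack in
#' which cells perform persistent random walks with compartment-dependent
#' step length `speed * dt`, tumor islets are fibronectin-negative discs,
#' a global cumulative drift moves all channels, the ECM channel bleeds
#' into the cell channel, and Poisson plus Gaussian noise is added last.
#' Ground truth (specimen-frame trajectories, per-frame compartment
#' labels, applied drift, region masks) is returned alongside.
#'
#' @param config A [scene_config()].
#' @return A list of class `SliceScene` with elements `stack`
#'   (an [image_stack()]), `masks` (a [region_mask_set()], specimen
#'   frame), and `truth` (list: `tracks` data.frame with
#'   `cell_id, frame, x_um, y_um, plane, region`; `applied_drift` T x 2
#'   matrix in px; `config`).
#' @export
generate_slice_scene <- function(config) {
  stopifnot(inherits(config, "SceneConfig"))
  with_seed(config$rng_seed, {
    px <- config$pixel_size_xy
    W_um <- config$width * px
    H_um <- config$height * px
    # --- compartment geometry -------------------------------------------
    spec <- config$tumor_islet_spec
    n_islets <- spec$n
    tumor2d <- matrix(FALSE, config$height, config$width)
    xs <- (seq_len(config$width) - 0.5) * px
    ys <- (seq_len(config$height) - 0.5) * px
    islets <- NULL
    if (n_islets > 0L) {
      islets <- data.frame(
        x = stats::runif(n_islets, 0.2 * W_um, 0.8 * W_um),
        y = stats::runif(n_islets, 0.2 * H_um, 0.8 * H_um),
        r = stats::runif(n_islets, spec$radius_range[1L],
                         spec$radius_range[2L]))
      for (k in seq_len(n_islets)) {
        dx2 <- outer(rep(1, config$height), (xs - islets$x[k])^2)
        dy2 <- outer((ys - islets$y[k])^2, rep(1, config$width))
        tumor2d <- tumor2d | (dx2 + dy2 <= islets$r[k]^2)
      }
    }
    frac <- mean(tumor2d)
    if ((frac == 0 || frac == 1) && config$speed_tumor != config$speed_ecm)
      warning("generate_slice_scene: tumor islets cover ",
              round(100 * frac), "% of the field; region-dependent speed ",
              "recovery is untestable on this scene")
    ecm3d <- array(NA, c(config$n_planes, config$height, config$width))
    for (z in seq_len(config$n_planes)) ecm3d[z, , ] <- !tumor2d
    masks <- region_mask_set(ecm3d, source = "manual")
    # --- static channel textures (specimen frame) -----------------------
    tex <- smooth2d(matrix(stats::rnorm(config$height * config$width),
                           config$height, config$width), radius = 2L,
                    passes = 3L)
    tex <- 1 + 0.2 * tex / stats::sd(tex)
    tex <- pmin(pmax(tex, 0.5), 1.5)
    ecm_img <- config$intensities$ecm * tex * (!tumor2d)
    tumor_img <- config$intensities$tumor * tex * tumor2d
    # --- trajectories (specimen frame) ----------------------------------
    margin <- config$cell_radius + px
    n <- config$n_cells
    pos <- matrix(numeric(0), 0, 2)
    if (n > 0L) {
      pos <- matrix(NA_real_, n, 2)
      tries <- 0L
      placed <- 0L
      while (placed < n) {
        cand <- c(stats::runif(1, margin, W_um - margin),
                  stats::runif(1, margin, H_um - margin))
        ok <- placed == 0L || config$min_separation <= 0 ||
          min(sqrt((pos[seq_len(placed), 1L] - cand[1L])^2 +
                     (pos[seq_len(placed), 2L] - cand[2L])^2)) >=
          config$min_separation
        if (ok) {
          placed <- placed + 1L
          pos[placed, ] <- cand
        }
        tries <- tries + 1L
        if (tries > 5000L * n)
          stop("generate_slice_scene: min_separation infeasible for ",
               n, " cells in this field")
      }
    }
    planes <- if (n > 0L) sample.int(config$n_planes, n, replace = TRUE)
      else integer(0)
    heading <- stats::runif(n, 0, 2 * pi)
    sigma_h <- (1 - config$turning_persistence) * pi
    dt_min <- config$frame_interval / 60
    tracks <- vector("list", config$n_frames)
    for (t in seq_len(config$n_frames)) {
      region <- if (n > 0L)
        mask_lookup(masks, pos[, 1L], pos[, 2L], planes, px)
        else character(0)
      tracks[[t]] <- data.frame(cell_id = seq_len(n), frame = rep(t, n),
                                x_um = pos[, 1L], y_um = pos[, 2L],
                                plane = planes, region = region)
      if (t == config$n_frames || n == 0L) next
      speed <- ifelse(region == "tumor", config$speed_tumor,
                      config$speed_ecm)
      step <- speed * dt_min
      heading <- heading + stats::rnorm(n, 0, sigma_h)
      nx_pos <- pos[, 1L] + step * cos(heading)
      ny_pos <- pos[, 2L] + step * sin(heading)
      # reflect at the field margins, flipping the heading component
      lo_x <- margin; hi_x <- W_um - margin
      lo_y <- margin; hi_y <- H_um - margin
      flip_x <- nx_pos < lo_x | nx_pos > hi_x
      flip_y <- ny_pos < lo_y | ny_pos > hi_y
      nx_pos <- ifelse(nx_pos < lo_x, 2 * lo_x - nx_pos, nx_pos)
      nx_pos <- ifelse(nx_pos > hi_x, 2 * hi_x - nx_pos, nx_pos)
      ny_pos <- ifelse(ny_pos < lo_y, 2 * lo_y - ny_pos, ny_pos)
      ny_pos <- ifelse(ny_pos > hi_y, 2 * hi_y - ny_pos, ny_pos)
      heading <- ifelse(flip_x, pi - heading, heading)
      heading <- ifelse(flip_y, -heading, heading)
      pos[, 1L] <- nx_pos
      pos[, 2L] <- ny_pos
    }
    tracks <- do.call(rbind, tracks)
    tracks <- tracks[order(tracks$cell_id, tracks$frame), , drop = FALSE]
    rownames(tracks) <- NULL
    # --- rendering -------------------------------------------------------
    drift <- outer(0:(config$n_frames - 1L), config$drift_per_frame)
    colnames(drift) <- c("dx", "dy")
    data <- array(0, c(config$n_frames, config$n_planes, config$height,
                       config$width, 3L))
    sigma_um <- config$cell_radius / 2
    api <- config$adjacent_plane_intensity
    for (t in seq_len(config$n_frames)) {
      sh <- drift[t, ]
      ecm_t <- if (all(sh == 0)) ecm_img else
        translate_bilinear(ecm_img, sh, pad = "reflect")
      tum_t <- if (all(sh == 0)) tumor_img else
        translate_bilinear(tumor_img, sh, pad = "reflect")
      rows_t <- tracks[tracks$frame == t, , drop = FALSE]
      for (z in seq_len(config$n_planes)) {
        cell_t <- matrix(0, config$height, config$width)
        if (nrow(rows_t)) {
          on_plane <- rows_t$plane == z
          amp <- rep(0, nrow(rows_t))
          amp[on_plane] <- 1
          if (api > 0) amp[abs(rows_t$plane - z) == 1L] <- api
          for (k in which(amp > 0))
            cell_t <- add_blob2d(cell_t,
                                 rows_t$x_um[k] + sh[1L] * px,
                                 rows_t$y_um[k] + sh[2L] * px,
                                 amp[k] * config$intensities$cell,
                                 sigma_um, px)
        }
        cell_t <- cell_t + config$bleed_coeff * ecm_t
        data[t, z, , , 1L] <- apply_scene_noise(cell_t, config$noise)
        data[t, z, , , 2L] <- apply_scene_noise(ecm_t, config$noise)
        data[t, z, , , 3L] <- apply_scene_noise(tum_t, config$noise)
      }
    }
    stack <- image_stack(data, px, config$z_spacing, config$frame_interval,
                         c(cell = 1L, ecm = 2L, tumor = 3L))
    structure(list(stack = stack, masks = masks,
                   truth = list(tracks = tracks, applied_drift = drift,
                                islets = islets, config = config)),
              class = "SliceScene")
  })
}

#' Generate a synthetic Matrigel nuclei Z-stack
#'
#' Renders nuclei as 3D Gaussian blobs in a single-channel Z-stack with
#' the Matrigel acquisition's 2 um plane spacing, and returns the true
#' centroids in micrometres with z measured from the bottom plane.
#'
#' @param n_cells Number of nuclei.
#' @param z_extent Total depth, um.
#' @param z_step Plane spacing, um.
#' @param height,width Lateral size in pixels.
#' @param pixel_size_xy um/px.
#' @param nucleus_radius Nucleus radius, um (sigma = radius / 2).
#' @param z_positions Optional explicit z for every nucleus (um); overrides
#'   random placement along z.
#' @param positions Optional `n_cells x 3` matrix of explicit (x, y, z)
#'   centres in um; overrides all random placement (for constructed
#'   fixtures such as deliberately overlapping nuclei).
#' @param min_separation Minimum 3D centre distance, um; placement errors
#'   out when infeasible.
#' @param noise As in [scene_config()].
#' @param intensity Peak intensity.
#' @param seed Integer seed.
#' @return A list of class `MatrigelStack`: `volume` (Z x Y x X array),
#'   `z_step`, `pixel_size_xy`, `centroids` (data.frame `cell_id, x_um,
#'   y_um, z_um`).
#' @export
generate_matrigel_stack <- function(n_cells, z_extent = 150, z_step = 2,
                                    height = 128L, width = 128L,
                                    pixel_size_xy = 1, nucleus_radius = 4,
                                    z_positions = NULL, positions = NULL,
                                    min_separation = 0,
                                    noise = list(gaussian_sd = 10,
                                                 poisson_scale = 1),
                                    intensity = 1000, seed = 1L) {
  if (z_step <= 0) stop("generate_matrigel_stack: z_step must be > 0")
  if (!is.null(z_positions) && length(z_positions) != n_cells)
    stop("generate_matrigel_stack: z_positions must have length n_cells")
  with_seed(seed, {
    n_planes <- floor(z_extent / z_step) + 1L
    W_um <- width * pixel_size_xy
    H_um <- height * pixel_size_xy
    margin <- nucleus_radius + pixel_size_xy
    cent <- matrix(NA_real_, n_cells, 3)
    placed <- 0L
    tries <- 0L
    if (!is.null(positions)) {
      stopifnot(nrow(positions) == n_cells, ncol(positions) == 3L)
      cent <- as.matrix(positions)
      placed <- n_cells
    }
    while (placed < n_cells) {
      zc <- if (!is.null(z_positions)) z_positions[placed + 1L]
        else stats::runif(1, 0, z_extent)
      cand <- c(stats::runif(1, margin, W_um - margin),
                stats::runif(1, margin, H_um - margin), zc)
      ok <- placed == 0L || min_separation <= 0 ||
        min(sqrt(colSums((t(cent[seq_len(placed), , drop = FALSE]) -
                            cand)^2))) >= min_separation
      if (ok) {
        placed <- placed + 1L
        cent[placed, ] <- cand
      }
      tries <- tries + 1L
      if (tries > 5000L * max(n_cells, 1L))
        stop("generate_matrigel_stack: requested minimum separation is ",
             "infeasible for ", n_cells, " cells in this volume")
    }
    vol <- array(0, c(n_planes, height, width))
    s_xy <- nucleus_radius / 2 / pixel_size_xy
    s_z <- nucleus_radius / 2 / z_step
    if (n_cells > 0L) for (k in seq_len(n_cells)) {
      cx <- cent[k, 1L] / pixel_size_xy - 0.5
      cy <- cent[k, 2L] / pixel_size_xy - 0.5
      cz <- cent[k, 3L] / z_step           # plane 1 is z = 0
      zr <- max(1L, floor(cz - 4 * s_z) + 1L):
        min(n_planes, ceiling(cz + 4 * s_z) + 1L)
      xr <- max(1L, floor(cx - 4 * s_xy) + 1L):
        min(width, ceiling(cx + 4 * s_xy) + 1L)
      yr <- max(1L, floor(cy - 4 * s_xy) + 1L):
        min(height, ceiling(cy + 4 * s_xy) + 1L)
      gz <- exp(-((zr - 1) - cz)^2 / (2 * s_z^2))
      gy <- exp(-((yr - 1) - cy)^2 / (2 * s_xy^2))
      gx <- exp(-((xr - 1) - cx)^2 / (2 * s_xy^2))
      blob <- outer(gz, outer(gy, gx))
      vol[zr, yr, xr] <- vol[zr, yr, xr] + intensity * blob
    }
    vol <- apply_scene_noise(vol, noise)
    centroids <- data.frame(cell_id = seq_len(n_cells),
                            x_um = cent[, 1L], y_um = cent[, 2L],
                            z_um = cent[, 3L])
    structure(list(volume = vol, z_step = z_step,
                   pixel_size_xy = pixel_size_xy, centroids = centroids),
              class = "MatrigelStack")
  })
}

#' Export a synthetic slice scene to disk
#'
#' Writes the stack as a self-describing multi-page TIFF, the ground truth
#' as JSON, and the per-plane ECM masks as 8-bit TIFFs.
#'
#' @param scene A `SliceScene` from [generate_slice_scene()].
#' @param dir Output directory (created if missing).
#' @param dtype Pixel storage type for the stack TIFF.
#' @return Invisibly, the list of written paths.
#' @export
write_scene <- function(scene, dir, dtype = "float32") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stack_path <- file.path(dir, "stack.tif")
  write_stack(scene$stack, stack_path, dtype = dtype)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(list(tracks = scene$truth$tracks,
                            applied_drift = scene$truth$applied_drift,
                            config = unclass(scene$truth$config)),
                       truth_path, digits = NA, auto_unbox = TRUE)
  nZ <- dim(scene$masks$ecm)[1L]
  mask_paths <- file.path(dir, sprintf("ecm_mask_z%02d.tif", seq_len(nZ)))
  write_region_masks(scene$masks, mask_paths)
  invisible(list(stack = stack_path, truth = truth_path, masks = mask_paths))
}
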