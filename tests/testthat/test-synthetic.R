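# Generator properties: determinism, ground-truth consistency and the
# law-of-large-numbers check on emitted step lengths.

test_that("identical config and seed give bit-identical scenes", {
  cfg <- scene_config(n_frames = 5, n_planes = 2, n_cells = 6,
                      height = 96, width = 96, rng_seed = 42)
  a <- generate_slice_scene(cfg)
  b <- generate_slice_scene(cfg)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth, b$truth)
  expect_identical(a$masks$ecm, b$masks$ecm)
})

test_that("a no-cell scene has region channels only and empty truth", {
  cfg <- scene_config(n_frames = 3, n_planes = 1, n_cells = 0,
                      height = 96, width = 96, drift_per_frame = c(0, 0),
                      noise = noise_free, bleed_coeff = 0, rng_seed = 2)
  sc <- generate_slice_scene(cfg)
  expect_equal(nrow(sc$truth$tracks), 0L)
  cell <- sc$stack$data[, , , , sc$stack$channel_roles[["cell"]]]
  expect_true(all(cell == 0))
  ecm <- sc$stack$data[1, 1, , , sc$stack$channel_roles[["ecm"]]]
  expect_true(any(ecm > 0))
})

test_that("config invariants are enforced", {
  expect_error(scene_config(n_frames = 0), ">= 1")
  expect_error(scene_config(speed_ecm = -1), "speeds")
  expect_error(scene_config(bleed_coeff = -0.1), "bleed_coeff")
  expect_error(scene_config(cell_radius = 0.5, pixel_size_xy = 1),
               "smaller than 1 px")
  expect_warning(
    generate_slice_scene(scene_config(
      n_frames = 2, n_planes = 1, n_cells = 2, height = 96, width = 96,
      tumor_islet_spec = list(n = 0L, radius_range = c(10, 20)),
      rng_seed = 1)),
    "untestable")
})

test_that("mean emitted step lengths converge to speed * dt", {
  # >= 500 steps per compartment; 4 um/min in tumor and 2 in ECM at a
  # 30 s interval give expected steps of 2.0 and 1.0 um. A big field
  # keeps boundary reflections (which bend paths) negligible.
  cfg <- scene_config(n_frames = 60, n_planes = 1, n_cells = 40,
                      height = 320, width = 320,
                      tumor_islet_spec = list(n = 3L,
                                              radius_range = c(50, 70)),
                      drift_per_frame = c(0, 0), noise = noise_free,
                      rng_seed = 7)
  sc <- generate_slice_scene(cfg)
  tr <- sc$truth$tracks
  steps <- do.call(rbind, lapply(split(tr, tr$cell_id), function(d) {
    d <- d[order(d$frame), ]
    data.frame(len = sqrt(diff(d$x_um)^2 + diff(d$y_um)^2),
               region = utils::head(d$region, -1L))
  }))
  expect_gt(sum(steps$region == "tumor"), 500)
  expect_gt(sum(steps$region == "ecm"), 500)
  m <- tapply(steps$len, steps$region, mean)
  expect_equal(unname(m[["tumor"]]), 2.0, tolerance = 0.05)
  expect_equal(unname(m[["ecm"]]), 1.0, tolerance = 0.05)
})

test_that("ground-truth region labels equal mask lookups and blobs are
           rendered for every live entry", {
  sc <- clean_scene()
  tr <- sc$truth$tracks
  relabel <- slicetracks:::mask_lookup(sc$masks, tr$x_um, tr$y_um,
                                       tr$plane,
                                       sc$truth$config$pixel_size_xy)
  expect_identical(relabel, tr$region)
  # mass placement: rendered blob count equals live ground-truth entries
  cell_ch <- sc$stack$channel_roles[["cell"]]
  for (t in c(1L, 4L)) {
    n_blobs <- 0L
    for (z in seq_len(dim(sc$stack$data)[2L])) {
      img <- sc$stack$data[t, z, , , cell_ch]
      dets <- segment_frame(img, 1, frame = t, plane = z,
                            threshold = "fixed", fixed_threshold = 100)
      n_blobs <- n_blobs + length(dets)
    }
    expect_identical(n_blobs, sum(tr$frame == t))
  }
})

test_that("matrigel generator places nuclei where asked", {
  stk <- generate_matrigel_stack(1, z_extent = 60, z_step = 2,
                                 height = 48, width = 48,
                                 z_positions = 20, noise = noise_free,
                                 seed = 3)
  expect_equal(nrow(stk$centroids), 1L)
  expect_equal(stk$centroids$z_um, 20)
  expect_error(
    generate_matrigel_stack(50, z_extent = 10, height = 24, width = 24,
                            min_separation = 30, seed = 1),
    "infeasible")
  expect_error(generate_matrigel_stack(3, z_step = 0), "z_step")
})

test_that("a single bottom layer of cells yields zero invasion", {
  stk <- generate_matrigel_stack(8, z_extent = 40, z_step = 2,
                                 height = 96, width = 96,
                                 z_positions = rep(0, 8),
                                 min_separation = 14,
                                 noise = noise_free, seed = 6)
  lab <- segment_nuclei_3d(stk)
  expect_identical(attr(lab, "n_labels"), 8L)
  res <- invasion_distances(lab, stk$pixel_size_xy, stk$z_step)
  # voxel quantization leaves sub-0.1 um jitter between centroids of one
  # physical layer; invasion distances are zero up to that jitter
  expect_lt(max(res$distances), 0.1)
  expect_identical(unname(fraction_beyond(res)), c(0, 0))
})
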