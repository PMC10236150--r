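# Segmentation, size filtering and Z-collapse.

blob_img <- function(centers_um, ny = 96, nx = 96, amp = 1000,
                     sigma = 2, px = 1) {
  img <- matrix(0, ny, nx)
  for (k in seq_len(nrow(centers_um)))
    img <- slicetracks:::add_blob2d(img, centers_um[k, 1L],
                                    centers_um[k, 2L], amp, sigma, px)
  img
}

test_that("a blank frame yields no detections", {
  expect_identical(segment_frame(matrix(0, 32, 32), 1), list())
  expect_warning(
    out <- segment_frame(matrix(runif(100), 10, 10), 1,
                         threshold = "fixed", fixed_threshold = 5),
    "above image maximum")
  expect_identical(out, list())
})

test_that("noise-free blobs are counted and located exactly", {
  set.seed(9)
  centers <- cbind(runif(10, 15, 80), runif(10, 15, 80))
  # enforce separation
  keep <- rep(TRUE, 10)
  for (i in 2:10)
    if (min(sqrt(rowSums(sweep(centers[seq_len(i - 1), , drop = FALSE],
                               2, centers[i, ])^2))) < 14) keep[i] <- FALSE
  centers <- centers[keep, , drop = FALSE]
  img <- blob_img(centers)
  dets <- segment_frame(img, 1, frame = 1L, plane = 1L)
  expect_identical(length(dets), nrow(centers))
  got <- t(vapply(dets, function(d) d$centroid, numeric(2)))
  got <- got[order(got[, 1L]), , drop = FALSE]
  want <- centers[order(centers[, 1L]), , drop = FALSE]
  expect_lt(max(abs(got - want)), 0.5)
})

test_that("fused blobs become a single detection (hence the size filter)", {
  img <- blob_img(rbind(c(40, 40), c(44, 40)))
  dets <- segment_frame(img, 1)
  expect_identical(length(dets), 1L)
  # and a clump of ~2x nominal area is removed by the filter
  nominal <- dets[[1L]]$area / 2
  filtered <- filter_by_size(dets, 0.25 * nominal, 1.5 * nominal)
  expect_identical(length(filtered), 0L)
  expect_identical(attr(filtered, "removed_large"), 1L)
})

test_that("size filter keeps in-bounds detections and drops specks", {
  img <- blob_img(rbind(c(30, 30), c(70, 70)))
  img[5, 5] <- 2000  # single-pixel noise speck
  dets <- segment_frame(img, 1)
  expect_identical(length(dets), 3L)
  areas <- vapply(dets, `[[`, numeric(1), "area")
  nominal <- max(areas)
  kept <- filter_by_size(dets, 0.25 * nominal, 2.5 * nominal)
  expect_identical(length(kept), 2L)
  expect_identical(attr(kept, "removed_small"), 1L)
  # all within bounds: identity
  kept2 <- filter_by_size(kept, 0.25 * nominal, 2.5 * nominal)
  expect_identical(detections_to_df(kept2), detections_to_df(kept))
  expect_error(filter_by_size(dets, 10, 5), "min_area")
})

test_that("collapse_z keeps the maximal-area plane with documented
           tie-breaks and is idempotent", {
  d3 <- make_det(1, 10, 10, plane = 3L, area = 40)
  d4 <- make_det(1, 10.5, 10, plane = 4L, area = 25)
  out <- collapse_z(list(d3, d4), match_radius = 4)
  expect_identical(length(out), 1L)
  expect_identical(out[[1L]]$plane, 3L)
  # exact area tie: lower plane wins
  t2 <- make_det(1, 10, 10, plane = 2L, area = 30, intensity = 50)
  t3 <- make_det(1, 10, 10, plane = 3L, area = 30, intensity = 99)
  out2 <- collapse_z(list(t3, t2), match_radius = 4)
  expect_identical(out2[[1L]]$plane, 2L)
  # single-plane detection unchanged; idempotence; never grows
  single <- list(make_det(1, 50, 50, plane = 1L))
  expect_identical(collapse_z(single, 4), single)
  once <- collapse_z(list(d3, d4, make_det(1, 80, 80, plane = 1L)), 4)
  expect_identical(collapse_z(once, 4), once)
  expect_lte(length(once), 3L)
  # far-apart detections in adjacent planes are not grouped
  far <- collapse_z(list(d3, make_det(1, 60, 60, plane = 4L)), 4)
  expect_identical(length(far), 2L)
})

test_that("collapse_z is the identity on single-plane scenes and the
           full chain recovers the ground-truth count", {
  sc <- clean_scene()
  cell_ch <- sc$stack$channel_roles[["cell"]]
  dets <- list()
  for (z in seq_len(dim(sc$stack$data)[2L]))
    dets <- c(dets, segment_frame(sc$stack$data[1, z, , , cell_ch], 1,
                                  frame = 1L, plane = z))
  collapsed <- collapse_z(dets, match_radius = 4)
  expect_identical(detections_to_df(collapsed), detections_to_df(dets))
  expect_identical(length(collapsed),
                   sum(sc$truth$tracks$frame == 1L))
})

test_that("multi-plane ghosts are collapsed to the brightest plane", {
  cfg <- scene_config(n_frames = 3, n_planes = 3, n_cells = 5,
                      min_separation = 25, drift_per_frame = c(0, 0),
                      bleed_coeff = 0, noise = noise_free,
                      adjacent_plane_intensity = 0.5, rng_seed = 19)
  sc <- generate_slice_scene(cfg)
  cell_ch <- sc$stack$channel_roles[["cell"]]
  dets <- list()
  for (z in 1:3)
    dets <- c(dets, segment_frame(sc$stack$data[1, z, , , cell_ch], 1,
                                  frame = 1L, plane = z,
                                  threshold = "fixed",
                                  fixed_threshold = 100))
  expect_gt(length(dets), 5L)  # ghosts present before collapse
  collapsed <- collapse_z(dets, match_radius = 4)
  expect_identical(length(collapsed), 5L)
  truth1 <- sc$truth$tracks[sc$truth$tracks$frame == 1L, ]
  expect_setequal(vapply(collapsed, `[[`, numeric(1), "plane"),
                  truth1$plane)
})
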