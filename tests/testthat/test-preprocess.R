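# Drift estimation/correction and cell-channel preprocessing.

test_that("identical frames give identity transforms with zero residual", {
  sc <- clean_scene()
  ecm <- sc$stack$data[1, 1, , , sc$stack$channel_roles[["ecm"]]]
  frames <- array(NA_real_, c(4L, dim(ecm)))
  for (t in 1:4) frames[t, , ] <- ecm
  dm <- estimate_drift(frames)
  expect_equal(dm$dx, rep(0, 4))
  expect_equal(dm$dy, rep(0, 4))
  expect_equal(dm$residual, rep(0, 4))
})

test_that("synthetic per-frame drift is recovered within 0.5 px", {
  cfg <- scene_config(n_frames = 8, n_planes = 1, n_cells = 0,
                      drift_per_frame = c(3, 0), rng_seed = 21)
  sc <- generate_slice_scene(cfg)
  dm <- estimate_drift(sc$stack)
  err <- cbind(dm$dx, dm$dy) - sc$truth$applied_drift
  expect_lt(max(abs(err)), 0.5)
})

test_that("reversing frame order negates recovered translations", {
  cfg <- scene_config(n_frames = 6, n_planes = 1, n_cells = 0,
                      drift_per_frame = c(2, 1), rng_seed = 22)
  sc <- generate_slice_scene(cfg)
  ecm_ch <- sc$stack$channel_roles[["ecm"]]
  d <- dim(sc$stack$data)
  fwd <- array(NA_real_, d[c(1, 3, 4)])
  for (t in seq_len(d[1L])) fwd[t, , ] <- sc$stack$data[t, 1, , , ecm_ch]
  rev_ <- fwd[d[1L]:1, , , drop = FALSE]
  m_f <- estimate_drift(fwd)
  m_r <- estimate_drift(rev_)
  last <- d[1L]
  expect_equal(m_r$dx[last], -m_f$dx[last], tolerance = 0.3)
  expect_equal(m_r$dy[last], -m_f$dy[last], tolerance = 0.3)
})

test_that("apply_drift with the identity model is a no-op, and
           correction reduces residual drift below 0.25 px/frame", {
  sc <- small_scene()
  nT <- dim(sc$stack$data)[1L]
  ident <- slicetracks:::drift_model(
    data.frame(frame = seq_len(nT), dx = 0, dy = 0, theta = 0,
               residual = 0))
  expect_identical(apply_drift(sc$stack, ident)$data, sc$stack$data)
  # apply estimated drift, then re-estimate: residual per frame is small
  dm <- estimate_drift(sc$stack)
  corrected <- apply_drift(sc$stack, dm)
  dm2 <- estimate_drift(corrected)
  per_frame <- sqrt(dm2$dx^2 + dm2$dy^2) / pmax(dm2$frame - 1, 1)
  expect_lt(max(per_frame), 0.25)
  # out-of-field pixels are NA, not zero
  expect_true(anyNA(corrected$data))
  expect_error(apply_drift(sc$stack, dm[1:3, ]), "frames")
})

test_that("drift correction reduces landmark scatter", {
  # the islet pattern acts as a static specimen landmark: track the
  # centroid of the thresholded tumor channel across frames
  cfg <- scene_config(n_frames = 8, n_planes = 1, n_cells = 0,
                      drift_per_frame = c(1.5, 1), rng_seed = 31)
  sc <- generate_slice_scene(cfg)
  tum_ch <- sc$stack$channel_roles[["tumor"]]
  centroid_of <- function(img) {
    b <- !is.na(img) & img > otsu_threshold(img)
    idx <- which(b, arr.ind = TRUE)
    c(mean(idx[, 2L]), mean(idx[, 1L]))
  }
  scatter <- function(stk) {
    cc <- t(vapply(seq_len(dim(stk$data)[1L]), function(t)
      centroid_of(stk$data[t, 1, , , tum_ch]), numeric(2)))
    sqrt(mean(rowSums(sweep(cc, 2, colMeans(cc))^2)))
  }
  before <- scatter(sc$stack)
  after <- scatter(apply_drift(sc$stack, estimate_drift(sc$stack)))
  expect_lt(after, before)
})

test_that("drift recovery holds across 0.5-5 px/frame magnitudes", {
  for (dpf in list(c(0.5, 0.5), c(2, -1), c(5, 0))) {
    cfg <- scene_config(n_frames = 8, n_planes = 1, n_cells = 0,
                        drift_per_frame = dpf, rng_seed = 40)
    sc <- generate_slice_scene(cfg)
    dm <- estimate_drift(sc$stack, max_drift = 10)
    step_err <- abs(diff(as.matrix(dm[, c("dx", "dy")])) -
                      diff(sc$truth$applied_drift))
    expect_lt(mean(step_err), 0.5)
  }
})

test_that("bleed coefficient is recovered within 0.05", {
  cfg <- scene_config(n_frames = 6, n_planes = 1, n_cells = 8,
                      bleed_coeff = 0.3, drift_per_frame = c(0, 0),
                      rng_seed = 77)
  sc <- generate_slice_scene(cfg)
  est <- estimate_bleed(sc$stack$data[, , , , 1], sc$stack$data[, , , , 2])
  expect_equal(est, 0.3, tolerance = 0.05 / 0.3)
})

test_that("correct_cell_channel clips, filters, and honours bleed = 0", {
  set.seed(5)
  img <- matrix(runif(400, 100, 200), 20, 20)
  ecm <- matrix(500, 20, 20)
  # bleed 0 on a zero-background image: output = median-filtered input
  out0 <- correct_cell_channel(img, ecm, bleed_coeff = 0,
                               median_radius = 1L)
  bg <- {
    v <- as.numeric(img)
    stats::median(v[v <= stats::quantile(v, 0.25)])
  }
  manual <- slicetracks:::cpp_median_filter(pmax(img - bg, 0), 1L)
  expect_equal(unclass(out0), manual, ignore_attr = TRUE)
  # strong bleed: negatives are clipped to zero, output bounded by input
  expect_warning(
    out <- correct_cell_channel(img, ecm, bleed_coeff = 10),
    "all zero")
  expect_true(all(out >= 0))
  out2 <- correct_cell_channel(img, ecm, bleed_coeff = 0.2)
  expect_true(all(out2 <= max(img)))
  expect_error(correct_cell_channel(img, ecm, bleed_coeff = -1), ">= 0")
})
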