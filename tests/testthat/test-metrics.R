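# Momentary speed, localization, dwell and acquisition summaries.

test_that("momentary speed is displacement over elapsed time", {
  still <- make_track(1L, lapply(1:5, function(f) make_det(f, 3, 4)))
  expect_identical(momentary_speed(still, 30), rep(0, 4))
  # 5 um in one 30 s interval -> 10 um/min
  tr <- make_track(1L, list(make_det(1, 0), make_det(2, 5)))
  expect_identical(momentary_speed(tr, 30), 10)
  # 1-frame gap: 5 um over 60 s -> 5 um/min
  gap <- make_track(1L, list(make_det(1, 0), make_det(3, 5)))
  expect_identical(momentary_speed(gap, 30), 5)
  single <- make_track(1L, list(make_det(1, 0)))
  expect_identical(momentary_speed(single, 30), numeric(0))
})

test_that("speeds are translation-invariant and scale-equivariant", {
  set.seed(3)
  obs <- lapply(1:7, function(f) make_det(f, runif(1, 0, 50),
                                          runif(1, 0, 50)))
  tr <- make_track(1L, obs)
  sp <- momentary_speed(tr, 30)
  shift <- make_track(1L, lapply(obs, function(d) {
    d$centroid <- d$centroid + c(17, -8); d
  }))
  expect_equal(momentary_speed(shift, 30), sp)
  scaled <- make_track(1L, lapply(obs, function(d) {
    d$centroid <- d$centroid * 2.5; d
  }))
  expect_equal(momentary_speed(scaled, 30), sp * 2.5)
})

test_that("localization follows the strict pixel-overlap rule", {
  ecm <- array(FALSE, c(1, 20, 20))
  ecm[1, , 11:20] <- TRUE           # right half is ECM
  masks <- region_mask_set(ecm)
  inside <- make_det(1, 5, 5, pixels = cbind(4:6, 4:6))
  touching <- make_det(1, 10, 5, pixels = cbind(c(5L, 5L), c(10L, 11L)))
  tr <- make_track(1L, list(inside, touching))
  expect_identical(classify_localization(tr, masks), c("tumor", "ecm"))
  bad <- make_track(1L, list(make_det(1, 5, 5, plane = 7L)))
  expect_error(classify_localization(bad, masks), "outside the mask set")
})

test_that("dwell boundaries follow the inclusive >= 50% reading", {
  lab <- c(rep("tumor", 5), rep("ecm", 5))
  de <- dwell_and_entry(lab)
  expect_identical(de$dwell_fraction, 0.5)
  expect_true(de$high_dwell)       # 5 of 10 counts as high dwell
  expect_true(de$entered_tumor)
  none <- dwell_and_entry(rep("ecm", 4))
  expect_identical(none$dwell_fraction, 0)
  expect_false(none$entered_tumor)
  expect_false(none$high_dwell)
  full <- dwell_and_entry(rep("tumor", 3))
  expect_identical(full$dwell_fraction, 1)
  expect_true(full$entered_tumor && full$high_dwell)
  expect_error(dwell_and_entry(character(0)), "empty")
})

test_that("tumor plus ECM frame counts partition each track", {
  sc <- clean_scene()
  res <- run_slice_pipeline(sc$stack,
                            params = slice_params(min_frames = 3L))
  for (m in res$metrics) {
    n <- length(m$region_per_frame)
    expect_identical(sum(m$region_per_frame == "tumor") +
                       sum(m$region_per_frame == "ecm"), n)
    expect_identical(length(m$momentary_speeds), n - 1L)
  }
})

test_that("acquisition summary computes percentages and handles
           absent compartments", {
  masks <- region_mask_set(array(FALSE, c(1, 30, 30)))  # all tumor
  mk <- function(id, xs) make_track(id, lapply(seq_along(xs), function(f)
    make_det(f, xs[f], pixels = matrix(c(2L, 2L), 1L))))
  tracks <- list(mk(1L, c(0, 1, 2)), mk(2L, c(5, 5, 5)),
                 mk(3L, c(9, 9, 10)), mk(4L, c(2, 3, 4)))
  tm <- track_metrics(tracks, masks, 30)
  s <- summarize_acquisition(tm)
  expect_identical(s$pct_entered_tumor, 100)
  expect_identical(s$pct_high_dwell, 100)
  expect_null(s$speed_ecm)          # absent, not zero
  expect_identical(length(s$outlier_removed_ids), 0L)
  # 4 tracks, 1 entered: 25.0%
  ecm <- region_mask_set(array(TRUE, c(1, 30, 30)))
  tm2 <- track_metrics(tracks, ecm, 30)
  tm2[[2L]]$entered_tumor <- TRUE   # constructed: exactly one entered
  s2 <- summarize_acquisition(tm2)
  expect_identical(s2$pct_entered_tumor, 25)
})

test_that("MAD outlier removal flags a gross outlier and is off by
           default", {
  masks <- region_mask_set(array(TRUE, c(1, 30, 30)))
  mk <- function(id, step) make_track(id, lapply(1:5, function(f)
    make_det(f, f * step, pixels = matrix(c(2L, 2L), 1L))))
  tracks <- c(lapply(1:9, function(i) mk(i, 1 + 0.01 * i)), list(mk(10L, 40)))
  tm <- track_metrics(tracks, masks, 30)
  s_on <- summarize_acquisition(tm, outlier_policy = "mad")
  expect_identical(s_on$outlier_removed_ids, 10L)
  expect_identical(s_on$n_tracks, 9L)
  s_off <- summarize_acquisition(tm)
  expect_identical(s_off$n_tracks, 10L)
})
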