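# Linking, merging and length filtering.

test_that("one detection per frame links into a single track", {
  dets <- lapply(1:8, function(f) make_det(f, f * 2))
  tr <- link_tracks(dets, max_disp = 5)
  expect_identical(length(tr), 1L)
  expect_identical(length(tr[[1L]]$obs), 8L)
  expect_error(link_tracks(dets, max_disp = 0), "max_disp")
})

test_that("crossing cells separated beyond max_disp do not swap", {
  # verified against brute-force assignment: with max_disp = 5 um the
  # only feasible frame-to-frame links are the straight continuations
  d1 <- lapply(1:5, function(f) make_det(f, f * 2, 0))
  d2 <- lapply(1:5, function(f) make_det(f, 12 - f * 2, 20))
  tr <- link_tracks(c(d1, d2), max_disp = 5)
  expect_identical(length(tr), 2L)
  ys <- lapply(tr, function(t)
    unique(vapply(t$obs, function(d) d$centroid[2L], numeric(1))))
  expect_true(all(lengths(ys) == 1L))  # no swap: y stays constant
})

test_that("gap memory bridges a single missing frame", {
  dets <- lapply(c(1:3, 5:7), function(f) make_det(f, f * 1.5))
  tr <- link_tracks(dets, max_disp = 5, memory = 1L)
  expect_identical(length(tr), 1L)
  tr0 <- link_tracks(dets, max_disp = 5, memory = 0L)
  expect_identical(length(tr0), 2L)
})

test_that("merge gates are exact at the thresholds", {
  base <- make_track(1L, lapply(1:10, function(f) make_det(f, f, 0)))
  frag <- function(f0, x0)
    make_track(2L, lapply(f0:(f0 + 2), function(f) make_det(f, x0, 0)))
  # gap 1, 5 um: merged
  m <- merge_tracks(list(base, frag(11, 10 + 5)))
  expect_identical(length(m), 1L)
  expect_identical(length(m[[1L]]$obs), 13L)
  expect_identical(m[[1L]]$merged_from, c(1L, 2L))
  # 12 um: not merged
  expect_identical(length(merge_tracks(list(base, frag(11, 10 + 12)))), 2L)
  # gap 2: not merged
  expect_identical(length(merge_tracks(list(base, frag(12, 10 + 5)))), 2L)
  # nearest-in-space candidate wins
  m2 <- merge_tracks(list(base, frag(11, 10 + 6), frag(11, 10 + 3)))
  expect_identical(length(m2), 2L)
  winner <- which(vapply(m2, function(t) length(t$obs), integer(1)) == 13L)
  expect_identical(m2[[winner]]$obs[[11L]]$centroid[1L], 13)
})

test_that("merging conserves observations and agrees with the
           brute-force oracle on random fragment sets", {
  for (seed in 1:5) {
    set.seed(seed)
    n_frag <- sample(6:14, 1)
    tracks <- vector("list", n_frag)
    f0 <- 1L
    x <- 0
    for (i in seq_len(n_frag)) {
      len <- sample(2:5, 1)
      tracks[[i]] <- make_track(i, lapply(seq_len(len) + f0 - 1L,
                                          function(f) {
        x <<- x + runif(1, 0, 4)
        make_det(f, x, runif(1, 0, 3))
      }))
      f0 <- f0 + len + sample(0:2, 1)
    }
    merged <- merge_tracks(tracks)
    oracle <- merge_oracle(tracks)
    expect_identical(length(merged), length(oracle))
    n_obs <- function(tt) sum(vapply(tt, function(t) length(t$obs), 1L))
    expect_identical(n_obs(merged), n_obs(tracks))
    key <- function(tt) sort(vapply(tt, function(t)
      paste(vapply(t$obs, `[[`, numeric(1), "frame"), collapse = ","), ""))
    expect_identical(key(merged), key(oracle))
    # idempotent at the fixpoint
    expect_identical(key(merge_tracks(merged)), key(merged))
  }
})

test_that("minimum-length filter keeps 6 and drops 5, after merging", {
  mk <- function(n) make_track(1L, lapply(seq_len(n),
                                          function(f) make_det(f, f)))
  expect_identical(length(filter_min_length(list(mk(6)))), 1L)
  expect_identical(length(filter_min_length(list(mk(5)))), 0L)
  # two 3-observation fragments merge into 6 and survive
  a <- make_track(1L, lapply(1:3, function(f) make_det(f, f)))
  b <- make_track(2L, lapply(4:6, function(f) make_det(f, f + 2)))
  kept <- filter_min_length(merge_tracks(list(a, b)))
  expect_identical(length(kept), 1L)
  expect_identical(length(kept[[1L]]$obs), 6L)
})

test_that("fragmented synthetic tracks are restored by merging", {
  sc <- clean_scene()
  cell_ch <- sc$stack$channel_roles[["cell"]]
  dets <- list()
  for (t in seq_len(dim(sc$stack$data)[1L]))
    dets <- c(dets, segment_frame(sc$stack$data[t, 1, , , cell_ch], 1,
                                  frame = t, plane = 1L))
  whole <- link_tracks(dets, max_disp = 6)
  n_true <- length(unique(sc$truth$tracks$cell_id))
  expect_identical(length(whole), n_true)
  # break every track between frames 3 and 4, then merge
  frags <- list()
  for (tr in whole) {
    f <- vapply(tr$obs, `[[`, numeric(1), "frame")
    frags <- c(frags,
               list(make_track(length(frags) + 1L, tr$obs[f <= 3]),
                    make_track(length(frags) + 2L, tr$obs[f > 3])))
  }
  expect_identical(length(frags), 2L * n_true)
  restored <- merge_tracks(frags)
  expect_identical(length(restored), n_true)
})
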