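# helpers to build frame-level fixtures at 30 fps
fps <- 30
eth_from_runs <- function(total_s, runs_s) {
  # runs_s: list of c(start_s, end_s) grooming intervals
  lab <- integer(total_s * fps)
  for (r in runs_s) lab[(r[1] * fps + 1):(r[2] * fps)] <- 1L
  ethogram(lab, fps)
}
still_track <- function(n) ellipse_track(rep(0, n), rep(0, n),
                                         rep(3, n), rep(6, n), fps)
moving_track <- function(n, step = 0.25) {
  ellipse_track(cumsum(rep(step, n)), rep(0, n), rep(3, n), rep(6, n), fps)
}

test_that("bout qualification: merge first, then require > 3 s groomed", {
  e4 <- eth_from_runs(60, list(c(10, 14)))
  b <- segment_bouts(e4, still_track(length(e4$labels)))
  expect_equal(nrow(b), 1)
  expect_equal(b$groomed_s, 4)
  expect_equal(b$span_s, 4)

  e2 <- eth_from_runs(60, list(c(10, 12)))
  expect_equal(nrow(segment_bouts(e2, still_track(length(e2$labels)))), 0)

  # exactly 3 s does not qualify (strict >)
  e3 <- eth_from_runs(60, list(c(10, 13)))
  expect_equal(nrow(segment_bouts(e3, still_track(length(e3$labels)))), 0)
})

test_that("pause merging joins runs unless the animal locomotes", {
  e <- eth_from_runs(60, list(c(5, 10), c(18, 23)))   # 5 s + 5 s, 8 s gap
  n <- length(e$labels)
  b <- segment_bouts(e, still_track(n))
  expect_equal(nrow(b), 1)
  expect_equal(b$groomed_s, 10)
  expect_equal(b$span_s, 18)
  expect_equal(b$n_pauses, 1)

  # same gap but walking 3 body lengths during it: two segments, each 5 s
  tr <- moving_track(n, step = 3 * 6 / (8 * fps))
  b2 <- segment_bouts(e, tr)
  expect_equal(nrow(b2), 2)
  expect_equal(b2$groomed_s, c(5, 5))

  # a >= 10 s gap never merges even when still
  e10 <- eth_from_runs(60, list(c(5, 10), c(20, 25)))
  expect_equal(nrow(segment_bouts(e10, still_track(length(e10$labels)))), 2)

  # max_pause_s = 0 reduces to plain runs > 3 s
  b0 <- segment_bouts(e, still_track(n), max_pause_s = 0)
  expect_equal(nrow(b0), 2)
  expect_equal(b0$groomed_s, c(5, 5))
})

test_that("bout binning credits whole bouts to their start bin", {
  eth <- eth_from_runs(180, list(c(59.5, 149.5)))   # 90 s bout starting at 59.5 s
  b <- segment_bouts(eth, NULL)
  bins <- bin_bouts(b, bin_s = 60, total_s = 180, fps = fps)
  expect_equal(bins$groomed_s, c(90, 0, 0))
  expect_equal(bins$n_bouts, c(1L, 0L, 0L))

  empty <- segment_bouts(ethogram(rep(0L, 100), fps), NULL)
  expect_true(all(bin_bouts(empty, 60, total_s = 300)$groomed_s == 0))

  two <- eth_from_runs(120, list(c(5, 15), c(30, 40)))
  bt <- bin_bouts(segment_bouts(two, moving_track(120 * fps)), 60,
                  total_s = 120, fps = fps)
  expect_equal(bt$n_bouts, c(2L, 0L))
  # conservation: binned mass equals total groomed seconds
  expect_equal(sum(bt$groomed_s), 20)
})

test_that("grooming metrics match hand-computed cases", {
  # one 60-s bout starting at t = 0 in a full 55-min assay
  e <- eth_from_runs(3300, list(c(0, 60)))
  m <- grooming_metrics(segment_bouts(e, moving_track(length(e$labels))), e)
  expect_equal(m$GrTime5m, 60)
  expect_equal(m$GrNum5m, 1)
  expect_equal(m$GrAvgLen5m, 60)
  expect_equal(m$GrTime55m, 60)
  expect_equal(m$GrPeakMidBin, 2.5)
  expect_equal(m$GrPeakVal, 60)
  expect_equal(m$GrPeakSlope, 60 / 2.5)

  # linear ramp: minute k holds one (4 + k)-second bout -> slope 1 s/min
  ramp <- eth_from_runs(3300, lapply(0:54, function(k) c(k * 60, k * 60 + 4 + k)))
  mr <- grooming_metrics(segment_bouts(ramp, moving_track(length(ramp$labels))),
                         ramp)
  expect_equal(mr$GrTimeSlope55min, 1.0, tolerance = 1e-10)
  expect_equal(mr$GrNumSlope55min, 0.0, tolerance = 1e-10)
  expect_equal(mr$GrNum55m, 55)

  # all grooming concentrated in minutes 25-30
  pk <- eth_from_runs(3300, list(c(25 * 60, 25 * 60 + 200)))
  mp <- grooming_metrics(segment_bouts(pk, moving_track(length(pk$labels))), pk)
  expect_equal(mp$GrPeakMidBin, 27.5)
  expect_equal(mp$GrPeakVal, 200)
  expect_equal(mp$GrPeakSlope, 200 / 27.5)
  expect_equal(mp$GrTime5m, 0)
  expect_equal(mp$GrTime20m, 0)
  expect_equal(mp$GrTime55m, 200)

  # horizons beyond the recording are NA
  short <- eth_from_runs(400, list(c(10, 20)))
  ms <- grooming_metrics(segment_bouts(short, NULL), short)
  expect_equal(ms$GrTime5m, 10)
  expect_true(is.na(ms$GrTime20m))
  expect_true(is.na(ms$GrTimeSlope55min))
})

test_that("segment_bouts agrees with the brute-force segmenter", {
  set.seed(99)
  for (i in 1:400) {
    rt <- random_eth_track(n_frames = 500)
    got <- segment_bouts(rt$eth, rt$track)
    ref <- brute_force_bouts(rt$eth$labels, fps = 30,
                             xs = rt$track$x, ys = rt$track$y, Ls = rt$track$L)
    expect_equal(nrow(got), nrow(ref))
    if (nrow(ref)) {
      expect_equal(got$start, ref$start)
      expect_equal(got$end, ref$end)
      expect_equal(got$groomed_s, ref$groomed_s)
      expect_equal(got$span_s, ref$span_s)
      expect_equal(got$n_pauses, ref$n_pauses)
    }
  }
})

test_that("adding grooming frames never decreases total groomed time", {
  set.seed(13)
  for (i in 1:30) {
    rt <- random_eth_track(n_frames = 3300 * 30 / 30)  # keep runtime small
    lab <- rt$eth$labels
    e1 <- ethogram(lab, 30)
    lab2 <- lab
    lab2[sample(length(lab2), 40)] <- 1L
    e2 <- ethogram(lab2, 30)
    t1 <- sum(segment_bouts(e1, NULL)$groomed_s)
    t2 <- sum(segment_bouts(e2, NULL)$groomed_s)
    expect_gte(t2, t1)
  }
})
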