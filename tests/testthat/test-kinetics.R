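cfg <- run_config()

make_labels <- function(h, w, netotic_idx) {
  lab <- matrix(0L, h, w)
  lab[netotic_idx] <- 1L
  structure(lab, class = c("pixel_class_map", "matrix", "array"), config = cfg)
}

test_that("netotic sampling is uniform over the labelled set, seeded, and flags exhaustion", {
  st <- random_stack(30, 30, 10, seed = 2)
  idx <- withr::with_seed(4, sample(900, 500))
  lab <- make_labels(30, 30, idx)
  expect_warning(ts <- sample_netotic(st, lab, n = 1000, seed = 1), "taking all")
  expect_equal(nrow(ts$traces), 500)
  expect_true(ts$exhausted)

  ts1 <- sample_netotic(st, lab, n = 100, seed = 5)
  ts2 <- sample_netotic(st, lab, n = 100, seed = 5)
  expect_identical(ts1$pixel_coords, ts2$pixel_coords)
  # membership: every sampled coordinate is a netotic pixel
  lin <- (ts1$pixel_coords$col - 1L) * 30L + ts1$pixel_coords$row
  expect_true(all(lin %in% idx))

  empty <- make_labels(30, 30, integer(0))
  expect_error(sample_netotic(st, empty), "no NETs detected")
})

test_that("peak alignment shifts traces onto a common relative grid", {
  # a single trace: curves equal the trace, peak at rel time 0
  one <- stack_from_traces(list(c(0, 2, 10, 4, 1)))
  lab <- make_labels(1, 1, 1)
  ts <- sample_netotic(one, lab, n = 1, seed = 1)
  sc <- align_and_summarize(ts, min_coverage = 0)
  expect_equal(sc$curve$median, c(0, 2, 10, 4, 1))
  expect_equal(sc$curve$q1, sc$curve$median)
  expect_equal(sc$curve$rel_time_min, c(-30, -15, 0, 15, 30))

  # two identical shapes peaking at frames 3 and 5 collapse onto one curve
  shape <- c(0, 1, 8, 3, 1)
  tr1 <- c(shape, 0, 0)         # peak frame 3
  tr2 <- c(0, 0, shape)         # peak frame 5
  st2 <- stack_from_traces(list(tr1, tr2))
  lab2 <- make_labels(1, 2, 1:2)
  ts2 <- sample_netotic(st2, lab2, n = 2, seed = 1)
  sc2 <- align_and_summarize(ts2, min_coverage = 0.6)
  on_both <- sc2$curve$n_traces == 2
  expect_equal(sc2$curve$median[on_both], shape)

  # quartiles at the peak: traces [0,1,0] and [0,3,0] -> median 2 at t=0
  st3 <- stack_from_traces(list(c(0, 1, 0), c(0, 3, 0)))
  ts3 <- sample_netotic(st3, make_labels(1, 2, 1:2), n = 2, seed = 1)
  sc3 <- align_and_summarize(ts3)
  expect_equal(sc3$curve$median[sc3$curve$rel_time_min == 0], 2)
})

test_that("quartile ordering holds pointwise on summary curves", {
  vid <- generate_video(demo_scene(seed = 17))
  out <- classify_video(vid$sytox, cfg)
  ts <- sample_netotic(out$smoothed, out$labels, n = 300, seed = 3)
  for (curves in list(align_and_summarize(ts),
                      align_and_summarize(normalize_traces(ts)))) {
    expect_true(all(curves$curve$q1 <= curves$curve$median + 1e-12))
    expect_true(all(curves$curve$median <= curves$curve$q3 + 1e-12))
  }
})

test_that("normalization maps [pre-peak min, peak] onto [0, 1] without clipping", {
  st <- stack_from_traces(list(c(2, 4, 10, 6), c(2, 4, 10, 1)))
  ts <- sample_netotic(st, make_labels(1, 2, 1:2), n = 2, seed = 1)
  nts <- normalize_traces(ts)
  i1 <- which(ts$pixel_coords$col == 1)
  expect_equal(nts$traces[i1, ], c(0, 0.25, 1, 0.5))
  # post-peak values below the pre-peak minimum go negative, unclipped
  i2 <- which(ts$pixel_coords$col == 2)
  expect_lt(nts$traces[i2, 4], 0)
  # idempotence on an already-normalized trace
  st01 <- stack_from_traces(list(c(0, 0.25, 1, 0.5)))
  ts01 <- sample_netotic(st01, make_labels(1, 1, 1), n = 1, seed = 1)
  expect_equal(normalize_traces(ts01)$traces[1, ], c(0, 0.25, 1, 0.5))

  flat <- stack_from_traces(list(c(3, 3, 3, 3)))
  tsf <- sample_netotic(flat, make_labels(1, 1, 1), n = 1, seed = 1)
  expect_error(normalize_traces(tsf), "flat")
})

test_that("lifetime reads grid crossings exactly and interpolates linearly", {
  est <- lifetime(c(1, .75, .5, .25, 0), 0.5, 15)
  expect_false(est$censored)
  expect_equal(est$minutes, 30)
  expect_equal(lifetime(c(1, .75, .5, .25, 0), 0.2, 15)$minutes, 48)

  cens <- lifetime(c(1, .9, .8), 0.5, 15)
  expect_true(cens$censored)
  expect_equal(cens$observed_span_min, 30)

  expect_error(lifetime(c(.8, .5), 0.5, 15), "peak")
  expect_error(lifetime(c(1, .5), 0, 15), "level")
})

test_that("lifetime agrees with a dense-grid root finder on analytic decays", {
  for (T2 in c(90, 200, 360)) {
    for (level in c(0.5, 0.2)) {
      # densely sampled exponential: linear interpolation error is negligible
      dt <- 0.01
      tt <- seq(0, 4 * T2, by = dt)
      curve <- 2^(-tt / T2)
      est <- lifetime(curve, level, frame_interval = dt)
      # independent root finder on the analytic function
      root <- stats::uniroot(function(x) 2^(-x / T2) - level,
                             c(0, 4 * T2), tol = 1e-8)$root
      expect_lt(abs(est$minutes - root), 0.1)
    }
  }
})

test_that("half_life_report recovers analytic half-lives and orders quartile lifetimes", {
  # build traces that decay exponentially with slightly different rates
  tt <- seq(0, 600, by = 15)
  traces <- lapply(c(300, 360, 420, 330, 390), function(T2) {
    c(0, 0.5, 2^(-tt / T2)) * 100 + 100
  })
  st <- stack_from_traces(traces)
  ts <- sample_netotic(st, make_labels(1, 5, 1:5), n = 5, seed = 1)
  curves <- align_and_summarize(normalize_traces(ts))
  rep_ <- half_life_report(curves, cfg)
  med <- rep_[rep_$fraction == 0.5 & rep_$curve == "median", ]
  expect_false(med$censored)
  expect_equal(med$lifetime_min, 360, tolerance = 0.05)
  # slower-decay quartile must live at least as long as the faster one
  q1 <- rep_[rep_$fraction == 0.5 & rep_$curve == "q1", ]$lifetime_min
  q3 <- rep_[rep_$fraction == 0.5 & rep_$curve == "q3", ]$lifetime_min
  expect_true(q1 <= med$lifetime_min && med$lifetime_min <= q3)

  # an exact exponential with half-life 360 sampled at 15 min
  one <- stack_from_traces(list(c(0, 100 * 2^(-tt / 360)) + 100))
  tso <- sample_netotic(one, make_labels(1, 1, 1), n = 1, seed = 1)
  co <- align_and_summarize(normalize_traces(tso))
  ro <- half_life_report(co, cfg)
  expect_equal(ro$lifetime_min[ro$fraction == 0.5 & ro$curve == "median"], 360,
               tolerance = 15 / 360)

  # curves that never reach the level are censored across the board
  shallow <- stack_from_traces(list(100 + c(0, 100, 95, 90, 85)))
  tss <- sample_netotic(shallow, make_labels(1, 1, 1), n = 1, seed = 1)
  rs <- half_life_report(align_and_summarize(normalize_traces(tss)), cfg)
  expect_true(all(rs$censored))
})

test_that("endpoint NET area recovers disjoint disk areas and ignores gain", {
  fr <- matrix(10, 120, 120)
  d1 <- disk_mask(120, 120, 30, 30, sqrt(200 / pi))
  d2 <- disk_mask(120, 120, 80, 80, sqrt(300 / pi))
  fr[d1] <- 200; fr[d2] <- 220
  out <- net_area_endpoint(fr, connectivity = 8)
  expect_setequal(out$area_px, c(sum(d1), sum(d2)))

  out2 <- net_area_endpoint(fr * 3.7, connectivity = 8)
  expect_setequal(out2$area_px, out$area_px)

  expect_error(net_area_endpoint(matrix(5, 10, 10)), "degenerate")
})

test_that("net_area_endpoint picks the frame nearest the requested minute", {
  vid <- generate_video(demo_scene(seed = 23))
  areas <- net_area_endpoint(vid$sytox, at_minute = 200)
  expect_s3_class(areas, "tbl_df")
  expect_gt(nrow(areas), 0)
})
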