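test_that("distance flagging follows the next-fix rule with forced endpoints", {
  # four identical fixes: nothing moves
  tr <- toy_track(x = rep(3, 4), y = rep(3, 4))
  expect_equal(flag_fixes(tr, 8), rep("stopped", 4))

  # two fixes 100 m apart: endpoints are stopped by default
  tr2 <- toy_track(x = c(0, 100), y = c(0, 0))
  expect_equal(flag_fixes(tr2, 8), c("stopped", "stopped"))

  # five collinear fixes spaced 10 m with R_stop = 8
  tr3 <- toy_track(x = seq(0, 40, by = 10), y = rep(0, 5))
  expect_equal(flag_fixes(tr3, 8),
               c("stopped", "moving", "moving", "moving", "stopped"))
})

test_that("stops aggregate maximal stopped runs with mean-position centroid", {
  tr <- toy_track(x = c(1, 1, 1), y = c(1, 2, 3), t = c(0, 15, 30))
  st <- build_stops(tr, rep("stopped", 3))
  expect_equal(nrow(st), 1)
  expect_equal(c(st$x, st$y), c(1, 2))
  expect_equal(st$duration, 30)

  # a single stopped fix is a degenerate zero-duration stop
  st1 <- build_stops(toy_track(x = 0, y = 0, t = 0), "stopped")
  expect_equal(st1$duration, 0)

  # two stopped runs separated by a moving run give exactly two stops
  tr2 <- toy_track(x = c(0, 0, 50, 100, 100), y = rep(0, 5))
  st2 <- build_stops(tr2, c("stopped", "stopped", "moving", "stopped", "stopped"))
  expect_equal(nrow(st2), 2)
})

test_that("corridor grouping cuts flights at corridor violations", {
  # collinear moving run: zero deviation, a single flight spanning the run
  tr <- toy_track(x = seq(0, 40, by = 10), y = rep(0, 5))
  fl <- build_flights(tr, rep("moving", 5), R_flight = 2)
  expect_equal(nrow(fl), 1)
  expect_equal(fl$length, 40)

  # right-angle path with a tight corridor: two flights
  tr2 <- toy_track(x = c(0, 10, 20, 20, 20, 20), y = c(0, 0, 0, 10, 20, 30))
  fl2 <- build_flights(tr2, rep("moving", 6), R_flight = 2)
  expect_equal(nrow(fl2), 2)

  # zig-zag with all perpendicular deviations below R_flight / 2: one flight
  tr3 <- toy_track(x = seq(0, 50, by = 10), y = c(0, 0.5, -0.5, 0.5, -0.5, 0))
  fl3 <- build_flights(tr3, rep("moving", 6), R_flight = 2)
  expect_equal(nrow(fl3), 1)

  # an isolated single moving fix cannot span a chord and is dropped
  tr4 <- toy_track(x = c(0, 50, 100), y = rep(0, 3))
  expect_warning(fl4 <- build_flights(tr4, c("stopped", "moving", "stopped"), 8),
                 "single moving fix")
  expect_equal(nrow(fl4), 0)
})

test_that("segmenting composes stops and flights chronologically", {
  # purely stationary track
  seg <- segment_track(toy_track(x = rep(0, 6), y = rep(0, 6)))
  expect_equal(nrow(seg$stops), 1)
  expect_equal(nrow(seg$flights), 0)

  # straight commute between two dwell clusters: stop, flight, stop
  tr <- toy_track(x = c(0, 0, 0, 20, 40, 60, 60, 60), y = rep(0, 8))
  seg2 <- segment_track(tr, R_stop = 8, R_flight = 8)
  expect_equal(seg2$elements$type, c("stop", "flight", "stop"))
  expect_equal(seg2$elements$type[1], "stop")
  expect_equal(seg2$elements$type[nrow(seg2$elements)], "stop")
  expect_equal(seg2$flights$velocity, 60 / 45)
  expect_equal(seg2$mean_velocity, 60 / 45)
})

test_that("segmentation is deterministic and matches the brute-force oracle", {
  set.seed(42)
  for (i in 1:300) {
    n <- sample(3:12, 1)
    df <- random_grid_track(n)
    seg <- suppressWarnings(segment_track(toy_track(df$x, df$y, df$t),
                                          R_stop = 8, R_flight = 8))
    orc <- oracle_segment(df, 8, 8)
    expect_equal(nrow(seg$stops), orc$n_stops)
    n_or <- if (is.null(orc$flights)) 0 else nrow(orc$flights)
    expect_equal(nrow(seg$flights), n_or)
    if (n_or > 0) {
      expect_equal(seg$flights$t_start, df$t[orc$flights[, "start"]])
      expect_equal(seg$flights$t_end, df$t[orc$flights[, "end"]])
    }
  }
  # pure function: identical output on repeated calls
  tr <- toy_track(c(0, 0, 20, 45, 45), c(0, 1, 5, 2, 2))
  expect_identical(segment_track(tr), segment_track(tr))
})

test_that("stop count of a known path is recovered under low GPS noise", {
  # ground truth: three dwells (180 s each) joined by straight 10 m/hop moves
  xs <- c(rep(0, 12), seq(10, 90, by = 10), rep(100, 12),
          seq(110, 190, by = 10), rep(200, 13))
  n <- length(xs)
  for (s in 1:5) {
    set.seed(s)
    noisy <- toy_track(xs + rnorm(n, 0, 2), rnorm(n, 0, 2),
                       t = seq(0, by = 15, length.out = n))
    seg <- suppressWarnings(segment_track(noisy))
    n_stops <- sum(seg$stops$duration >= 15)
    expect_gte(n_stops, 2)
    expect_lte(n_stops, 4)
  }
})

test_that("stop duration and flight length pools respect their filters", {
  tr <- toy_track(x = c(0, 0, 0, 30, 60, 60), y = rep(0, 6))
  seg <- segment_track(tr)
  expect_true(all(stop_durations(seg, 15) >= 15))
  expect_equal(flight_lengths(seg), 30)   # moving run spans fixes 3..4
  expect_equal(flight_headings(seg), 0)
})
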