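open_land <- function() {
  landscape(data.frame(x = 1000, y = 1000), arena(2000, 2000))
}

test_that("speed factors follow the unit Rayleigh law", {
  set.seed(1)
  rho <- draw_speed_factor(5e5)
  expect_true(all(rho >= 0))
  expect_lt(abs(mean(rho) - sqrt(pi / 2)) / sqrt(pi / 2), 0.005)
  expect_lt(abs(median(rho) - sqrt(2 * log(2))) / sqrt(2 * log(2)), 0.01)
})

test_that("turning increments follow the Von Mises law", {
  set.seed(2)
  # kappa = 0: uniform turns, vanishing mean resultant length
  th <- draw_turn(1e5, 0, kappa = 0)
  expect_lt(sqrt(mean(cos(th))^2 + mean(sin(th))^2), 0.01)
  # extreme concentration: turns collapse to zero
  th2 <- draw_turn(1e4, 0, kappa = 1e5, dt = 0.1)   # concentration 1e6
  expect_gt(mean(abs(th2) < 0.01), 0.999)
  # mean resultant length against the Bessel-function ratio at c = 2
  th3 <- draw_turn(5e5, 0, kappa = 2, dt = 1)
  r <- besselI(2, 1) / besselI(2, 0)
  expect_lt(abs(mean(cos(th3)) - r) / r, 0.01)
  # headings are wrapped
  expect_true(all(th3 > -pi & th3 <= pi))
})

test_that("zero forces leave the walker in place", {
  cfg <- sim_config("RW", beta = 0, origin = c(1000, 1000))
  wk <- run_walker(cfg, open_land(), lifetime = 60)
  expect_equal(unique(wk$track$x), 1000)
  expect_equal(unique(wk$track$y), 1000)
})

test_that("a noiseless walker slides monotonically into the well", {
  land <- landscape(data.frame(x = 100, y = 50), arena(200, 100), V0 = 10)
  cfg <- sim_config("PRW", beta = 0, origin = c(108, 50), record_raw = TRUE)
  wk <- run_walker(cfg, land, lifetime = 30)
  d <- sqrt((wk$raw$x - 100)^2 + (wk$raw$y - 50)^2)
  expect_true(all(diff(d) < 0))
  expect_equal(wk$work_A, 0)
  expect_gt(wk$work_R, 0)
})

test_that("with no landscape the step equals the active displacement", {
  cfg <- sim_config("RW", origin = c(1000, 1000), record_raw = TRUE)
  set.seed(5)
  wk <- run_walker(cfg, open_land(), lifetime = 100)
  raw <- wk$raw
  disp <- sqrt(diff(c(1000, raw$x))^2 + diff(c(1000, raw$y))^2)
  fa <- sqrt(raw$F_Ax^2 + raw$F_Ay^2)
  # |dr| = |F_A| dt / gamma exactly, i.e. sqrt(2 beta dt) rho
  expect_equal(disp, fa * cfg$dt, tolerance = 1e-12)
  # the modulus is Rayleigh-scaled: two-sample KS against direct draws
  rho_obs <- disp / sqrt(2 * cfg$beta * cfg$dt)
  ks <- suppressWarnings(stats::ks.test(rho_obs, draw_speed_factor(1e4)))
  expect_gt(ks$p.value, 0.01)
})

test_that("sampling emits fixes every sample_every seconds from t = 0", {
  cfg <- sim_config("RW", origin = c(1000, 1000))
  set.seed(6)
  wk <- run_walker(cfg, open_land(), lifetime = 60)
  expect_equal(wk$track$t, c(0, 15, 30, 45, 60))
  expect_equal(wk$termination, "lifetime")
})

test_that("border crossing truncates the track without clamping", {
  land <- landscape(data.frame(x = 5, y = 5), arena(10, 10), V0 = 0)
  cfg <- sim_config("RW", beta = 5, origin = c(5, 5))
  set.seed(7)
  wk <- run_walker(cfg, land, lifetime = 1e4)
  expect_equal(wk$termination, "border")
  expect_true(all(wk$track$x >= 0 & wk$track$x <= 10))
  expect_true(all(wk$track$y >= 0 & wk$track$y <= 10))
  expect_lt(wk$age, 1e4)
})

test_that("visiting every well removes the walker", {
  land <- landscape(data.frame(x = 100, y = 50), arena(200, 100), V0 = 3.4)
  cfg <- sim_config("PRW")   # spawns at the only well, shallow: quick escape
  set.seed(8)
  wk <- run_walker(cfg, land, lifetime = 1e5)
  expect_equal(wk$termination, "all_visited")
  expect_equal(wk$n_visited, 1)
})

test_that("scenario bookkeeping covers the budget and is reproducible", {
  land <- make_default_landscape()
  cfg <- sim_config("CPRW", kappa = 1, total_budget = 5000)
  sc1 <- run_scenario(cfg, land, seed = 9)
  sc2 <- run_scenario(cfg, land, seed = 9)
  expect_gte(sc1$total_time, 5000)
  expect_lt(sc1$total_time - sc1$walkers$age[nrow(sc1$walkers)], 5000)
  expect_identical(lapply(sc1$tracks, as.data.frame),
                   lapply(sc2$tracks, as.data.frame))
  expect_true(all(sc1$walkers$termination %in%
                    c("lifetime", "all_visited", "border")))
})

test_that("the RW preset ignores the landscape entirely", {
  cfg <- sim_config("RW", total_budget = 3000)
  land_a <- make_default_landscape()
  land_b <- make_default_landscape(V0 = 300)
  land_b$wells$x <- rev(land_b$wells$x)
  cfg$origin <- c(165, 72.5)
  sc_a <- run_scenario(cfg, land_a, seed = 10)
  sc_b <- run_scenario(cfg, land_b, seed = 10)
  expect_identical(lapply(sc_a$tracks, as.data.frame),
                   lapply(sc_b$tracks, as.data.frame))
})

test_that("work bookkeeping satisfies the power telescoping identity", {
  land <- make_default_landscape()
  cfg <- sim_config("CPRW", kappa = 1, total_budget = 2000, record_raw = TRUE)
  sc <- run_scenario(cfg, land, seed = 11)
  expect_equal(sc$work_R + sc$work_A, sc$power_total,
               tolerance = 1e-9)
  # recompute the works from a raw path
  raw <- sc$raw[[1]]
  dt <- diff(c(0, raw$t))
  wR <- sum((raw$F_Rx * raw$vx + raw$F_Ry * raw$vy) * dt)
  expect_equal(wR, sc$walkers$work_R[1], tolerance = 1e-9 * abs(wR) + 1e-12)
})

test_that("persistence lengthens flights and wells concentrate occupancy", {
  land <- make_default_landscape()
  # CRW vs RW at matched noise: flights longer in mean under persistence
  rw <- run_scenario(sim_config("RW", dt = 15, total_budget = 6e4,
                                origin = c(165, 72.5)), land, seed = 12)
  crw <- run_scenario(sim_config("CRW", dt = 15, kappa = 150,
                                 total_budget = 6e4, origin = c(165, 72.5)),
                      land, seed = 12)
  mean_rw <- mean(flight_lengths(suppressWarnings(segment_tracks(rw$tracks))))
  mean_crw <- mean(flight_lengths(suppressWarnings(segment_tracks(crw$tracks))))
  expect_gt(mean_crw, mean_rw)

  # PRW occupancy near wells exceeds the RW baseline at identical settings
  prw <- run_scenario(sim_config("PRW", total_budget = 3e4), land, seed = 13)
  rw2 <- run_scenario(sim_config("RW", total_budget = 3e4), land, seed = 13)
  near_frac <- function(sc) {
    xs <- unlist(lapply(sc$tracks, function(tr) tr$x))
    ys <- unlist(lapply(sc$tracks, function(tr) tr$y))
    near <- rep(FALSE, length(xs))
    for (i in seq_len(nrow(land$wells))) {
      near <- near | (sqrt((xs - land$wells$x[i])^2 +
                           (ys - land$wells$y[i])^2) <= 2 * land$wells$sigma[i])
    }
    mean(near)
  }
  expect_gt(near_frac(prw), near_frac(rw2))
})

test_that("destination-selection walkers can skip wells", {
  land <- make_default_landscape()
  cfg <- sim_config("DSW", kappa = 1, p_skip = 0.9, total_budget = 4000)
  sc <- run_scenario(cfg, land, seed = 14)
  # with 90% of wells ignored, walkers visit far fewer than 14 wells
  expect_lt(max(sc$walkers$n_visited), 14)
})

test_that("in-core residence times are positive and depth-ordered", {
  t1 <- trapping_time_sample(V0 = 64, beta = 3.2, n_events = 400, seed = 15)
  t2 <- trapping_time_sample(V0 = 64, beta = 8 / 3, n_events = 400, seed = 15)
  expect_true(all(t1 > 0))
  expect_gt(mean(t2), mean(t1))   # deeper relative well: longer residence
})

test_that("invalid preset combinations are rejected", {
  expect_error(sim_config("PRW", kappa = 1), "kappa = 0")
  expect_error(sim_config("CRW", kappa = 0), "kappa > 0")
  expect_error(sim_config("RW", dt = 0.4, sample_every = 15), "multiple")
})
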