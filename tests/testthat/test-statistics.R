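test_that("the binned CCDF starts at one and tracks the analytic tail", {
  g <- ccdf(c(1, 2, 3), bin_width = 1)
  expect_equal(g$ccdf[g$threshold == 0], 1)
  expect_true(all(diff(g$ccdf) <= 0))

  # constant sample: a single step down
  g2 <- ccdf(rep(5, 100), bin_width = 2)
  expect_setequal(unique(g2$ccdf), c(0, 1))

  # exponential sample: CCDF at tau within 3 accumulated standard errors
  set.seed(1)
  tau <- 40
  x <- rexp(1e5, 1 / tau)
  g3 <- ccdf(x, bin_width = tau)
  at_tau <- g3[g3$threshold == tau, ]
  expect_lt(abs(at_tau$ccdf - exp(-1)), 3 * at_tau$stderr)

  expect_error(ccdf(numeric(0)), "empty")
})

test_that("the stop-duration mixture fit recovers known parameters", {
  # near single-exponential data: the dominant weight goes to one scale
  set.seed(2)
  d1 <- rstop_mixture(1e5, omega = 1, tau1 = 300, tau2 = 30)
  f1 <- suppressWarnings(fit_stop_mixture(d1))
  expect_gte(f1$omega, 0.95)
  expect_lt(abs(f1$tau1 - 300) / 300, 0.03)

  # scale equivariance: timescales scale, the weight does not
  set.seed(3)
  d <- rstop_mixture(2e4, omega = 0.3, tau1 = 600, tau2 = 40)
  fa <- fit_stop_mixture(d)
  fb <- fit_stop_mixture(d * 10)
  expect_equal(fb$omega, fa$omega, tolerance = 1e-4)
  expect_equal(fb$tau1, 10 * fa$tau1, tolerance = 1e-3)
  expect_equal(fb$tau2, 10 * fa$tau2, tolerance = 1e-3)
  expect_true(fa$tau1 >= fa$tau2)
})

test_that("the MLE and the binned least-squares fit agree on clean data", {
  set.seed(4)
  d <- rstop_mixture(1e5, omega = 0.308, tau1 = 617, tau2 = 37.5)
  f_mle <- fit_stop_mixture(d, "mle")
  f_lsq <- fit_stop_mixture(d, "binned_lsq")
  for (p in c("omega", "tau1", "tau2")) {
    joint_se <- 2 * sqrt(2) * f_mle$stderr[[p]]
    expect_lt(abs(f_mle[[p]] - f_lsq[[p]]), joint_se)
  }
})

test_that("mixture fitting is consistent and guards weak identifiability", {
  errs <- sapply(c(1e3, 1e5), function(n) {
    set.seed(5)
    f <- suppressWarnings(fit_stop_mixture(rstop_mixture(n, 0.308, 617, 37.5)))
    abs(f$tau1 - 617)
  })
  expect_lt(errs[2], errs[1])

  set.seed(6)
  d_close <- rstop_mixture(5000, omega = 0.5, tau1 = 45, tau2 = 40)
  expect_warning(f <- fit_stop_mixture(d_close), "weakly identified")
  expect_true(f$weakly_identified)

  expect_error(fit_stop_mixture(rep(10, 100)), "degenerate")
  expect_error(fit_stop_mixture(rexp(10)), "at least 50")
})

test_that("the flight-length fit is the mean excess over the threshold", {
  f <- fit_flight_exponential(c(rep(9, 10), rep(10, 10), rep(11, 10)), r_min = 8)
  expect_equal(f$lambda, 2)
  expect_equal(f$r_min, 8)   # fitted support starts at the stop threshold

  # translation property: shifting both threshold and lengths changes nothing
  set.seed(7)
  l <- rflight_exp(5000, lambda = 27, r_min = 8)
  f1 <- fit_flight_exponential(l, 8)
  f2 <- fit_flight_exponential(l + 5, 13)
  expect_equal(f1$lambda, f2$lambda, tolerance = 1e-12)

  # consistency in n
  errs <- sapply(c(1e3, 1e5), function(n) {
    set.seed(8)
    abs(fit_flight_exponential(rflight_exp(n), 8)$lambda - 27)
  })
  expect_lt(errs[2], errs[1])

  expect_error(fit_flight_exponential(c(1, 2, 3), 8), "above r_min")
})

test_that("orientation histograms are normalized with bin one centred east", {
  oh <- orientation_histogram(rep(0.01, 50), n_bins = 8)
  expect_equal(oh$probs[1], 1)
  expect_equal(sum(oh$probs), 1, tolerance = 1e-12)
  # due-west flights land in the opposite bin
  oh_w <- orientation_histogram(rep(pi, 50), n_bins = 8)
  expect_equal(oh_w$probs[5], 1)

  # isotropic flights: uniformity not rejected
  set.seed(9)
  oh2 <- orientation_histogram(runif(1e4, -pi, pi), n_bins = 16)
  expect_gt(chisq.test(oh2$counts)$p.value, 0.01)
  expect_error(orientation_histogram(numeric(0)), "no flights")
})

test_that("velocity statistics use flights only, with population sd", {
  mk_seg <- function(v) {
    structure(list(walker_id = "w", stops = data.frame(duration = c(100, 200)),
                   flights = data.frame(velocity = v),
                   elements = data.frame(), mean_velocity = mean(v)),
              class = "bp_segmented")
  }
  vs <- velocity_stats(mk_seg(0.5))
  expect_equal(vs$mean, 0.5)
  vs2 <- velocity_stats(mk_seg(c(0.4, 0.8)))
  expect_equal(vs2$mean, 0.6)
  expect_equal(vs2$sd, 0.2)     # population convention, divisor n
  expect_equal(vs2$n, 2)
})

test_that("the work split hits its limits and always sums to 100", {
  land <- landscape(data.frame(x = 100, y = 50), arena(200, 100), V0 = 10)
  # purely active scenario
  rw <- run_scenario(sim_config("RW", total_budget = 500,
                                origin = c(100, 50)), land, seed = 10)
  sp <- work_decomposition(rw)
  expect_equal(sp$pct_reactive, 0)
  # purely reactive scenario: noiseless slide into the well
  cfg0 <- sim_config("PRW", beta = 0, origin = c(120, 50), total_budget = 200,
                     lifetime_sampler = function(n) rep(100, n))
  pr <- run_scenario(cfg0, land, seed = 10)
  sp0 <- work_decomposition(pr)
  expect_equal(sp0$pct_reactive, 100)
  # mixed dynamics: exact complement
  cp <- run_scenario(sim_config("CPRW", kappa = 1, total_budget = 2000),
                     make_default_landscape(), seed = 10)
  spc <- work_decomposition(cp)
  expect_equal(spc$pct_reactive + spc$pct_active, 100, tolerance = 1e-9)
  expect_error(work_decomposition(data.frame(work_R = 0, work_A = 0)),
               "undefined")
})

test_that("grid calibration finds the generating parameters", {
  land <- make_default_landscape()
  sc <- run_scenario(sim_config("PRW", total_budget = 6e4), land, seed = 11)
  tgt <- coef(suppressWarnings(
    fit_stop_mixture(stop_durations(segment_tracks(sc$tracks)))))
  grid <- data.frame(V0 = c(17, 34, 34), beta = c(1.7, 1.7, 3.4))
  res <- calibrate(tgt, grid, land, budget = 6e4, seed = 12)
  expect_true(all(res$table$score >= 0))
  expect_equal(unlist(res$best[c("V0", "beta")]), c(V0 = 34, beta = 1.7))
})
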