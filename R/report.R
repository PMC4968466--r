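#' Four-panel movement report
#'
#' Regenerates the standard panel set for any track collection or simulated
#' scenario: utilization-density map with wells, polar flight-orientation
#' histogram, stop-duration CCDF with the two-timescale mixture fit, and
#' flight-length CCDF with the shifted exponential fit. A machine-readable
#' summary (fit parameters, velocity statistics, orientation uniformity
#' check, and the active/reactive work split when per-step forces are
#' available) is returned and optionally written as JSON.
#'
#' @param x A `bp_scenario` or a `bp_tracks` collection (planar).
#' @param land Landscape used for the UD overlay (taken from the scenario
#'   when available).
#' @param R_stop,R_flight Segmentation parameters (m).
#' @param min_duration Minimum stop duration (s) entering the mixture fit.
#' @param cell,delta,window Utilization raster parameters.
#' @param png_path Optional path for the four-panel PNG.
#' @param json_path Optional path for the JSON summary.
#' @param n_bins Angular bins of the orientation panel.
#' @return The summary list, invisibly.
#' @export
report <- function(x, land = NULL, R_stop = 8, R_flight = 8,
                   min_duration = 15, cell = 8, delta = 4.071, window = 11,
                   png_path = NULL, json_path = NULL, n_bins = 16) {
  if (inherits(x, "bp_scenario")) {
    tracks <- x$tracks
    if (is.null(land)) land <- x$landscape
    scenario <- x
  } else {
    tracks <- x
    scenario <- NULL
  }
  if (is.null(land)) land <- make_default_landscape()

  segs <- segment_tracks(tracks, R_stop, R_flight)
  dur <- stop_durations(segs, min_duration)
  len <- flight_lengths(segs)
  hd <- flight_headings(segs)

  mixfit <- tryCatch(suppressWarnings(fit_stop_mixture(dur)),
                     error = function(e) NULL)
  expfit <- tryCatch(fit_flight_exponential(len, R_stop),
                     error = function(e) NULL)
  orient <- tryCatch(orientation_histogram(hd, n_bins), error = function(e) NULL)
  vel <- tryCatch(velocity_stats(segs), error = function(e) NULL)
  ud <- tryCatch(population_ud(tracks, land$arena, cell, delta, window),
                 error = function(e) NULL)

  unif_p <- if (!is.null(orient)) {
    suppressWarnings(stats::chisq.test(orient$counts)$p.value)
  } else NA_real_

  split <- NULL
  if (!is.null(scenario)) {
    split <- tryCatch(work_decomposition(scenario), error = function(e) NULL)
  }
  if (is.null(split)) {
    message("no per-step force record available: work split omitted")
  }

  summary <- list(
    n_tracks = length(tracks),
    n_stops = length(dur), n_flights = length(len),
    omega = if (!is.null(mixfit)) mixfit$omega else NA,
    tau1 = if (!is.null(mixfit)) mixfit$tau1 else NA,
    tau2 = if (!is.null(mixfit)) mixfit$tau2 else NA,
    lambda = if (!is.null(expfit)) expfit$lambda else NA,
    velocity_mean = if (!is.null(vel)) vel$mean else NA,
    velocity_sd = if (!is.null(vel)) vel$sd else NA,
    orientation_uniform_p = unif_p,
    orientation_flag = if (!is.na(unif_p) && unif_p > 0.01)
      "uniform (chi-square p > 0.01)" else "non-uniform",
    pct_reactive = if (!is.null(split)) split$pct_reactive else NULL,
    pct_active = if (!is.null(split)) split$pct_active else NULL)

  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 1400, height = 1000, res = 120)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
    plot_panels(ud, land, orient, dur, len, mixfit, expfit, R_stop)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(summary)
}

# draw the four panels on the current device
plot_panels <- function(ud, land, orient, dur, len, mixfit, expfit, R_stop) {
  if (!is.null(ud)) {
    graphics::image(ud$xs + ud$cell / 2, ud$ys + ud$cell / 2, t(ud$density),
                    col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE),
                    xlab = "x (m)", ylab = "y (m)", main = "utilization density",
                    asp = 1)
    graphics::points(land$wells$x, land$wells$y, pch = 8)
  } else graphics::plot.new()
  if (!is.null(orient)) {
    r <- orient$probs
    a <- orient$centers
    lim <- max(r) * 1.1
    graphics::plot(NA, xlim = c(-lim, lim), ylim = c(-lim, lim), asp = 1,
                   xlab = "", ylab = "", main = "flight orientation")
    graphics::polygon(c(r, r[1]) * cos(c(a, a[1])),
                      c(r, r[1]) * sin(c(a, a[1])), border = "red")
  } else graphics::plot.new()
  if (length(dur) > 1) {
    g <- ccdf(dur, 15)
    graphics::plot(g$threshold, pmax(g$ccdf, 1e-6), log = "y", type = "s",
                   xlab = "stop duration (s)", ylab = "P(T > t)",
                   main = "stop-duration CCDF")
    if (!is.null(mixfit)) {
      tt <- seq(0, max(dur), length.out = 200)
      graphics::lines(tt, mixfit$omega * exp(-tt / mixfit$tau1) +
                        (1 - mixfit$omega) * exp(-tt / mixfit$tau2), col = 2)
    }
  } else graphics::plot.new()
  if (length(len) > 1) {
    g <- ccdf(len, 5)
    graphics::plot(g$threshold, pmax(g$ccdf, 1e-6), log = "y", type = "s",
                   xlab = "flight length (m)", ylab = "P(L > r)",
                   main = "flight-length CCDF")
    if (!is.null(expfit)) {
      rr <- seq(R_stop, max(len), length.out = 200)
      graphics::lines(rr, exp(-(rr - R_stop) / expfit$lambda), col = 2)
    }
  } else graphics::plot.new()
}
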