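#' Default synthetic stand landscape
#'
#' Fourteen identical attraction wells (core radius 4 m) inside the default
#' 330 x 145 m arena, concentrated in two staggered rows along the arena's
#' long axis, emulating a fair promenade. The first well doubles as the
#' walker spawn point (welcome-stand analogue). The layout is synthetic: the
#' real stand coordinates are not public, and any landscape CSV can replace
#' it via [read_landscape()].
#'
#' @param V0 Shared well strength, default 34: at the default noise amplitude
#'   this puts the Kramers dwell time at the attraction points near the
#'   ten-minute scale typical of event-stand visits.
#' @param sigma Shared core radius (m), default 4.
#' @param arena The [arena()], default 330 x 145 m.
#' @return A `bp_landscape` with exactly 14 wells.
#' @export
make_default_landscape <- function(V0 = 34, sigma = 4,
                                   arena = beepath::arena()) {
  xs <- seq(0.075, 0.925, length.out = 7) * arena$width
  wells <- data.frame(
    id = 1:14,
    x = as.vector(rbind(xs, xs + 0.04 * arena$width))[1:14],
    y = rep(c(0.40, 0.60) * arena$height, 7)[1:14])
  landscape(wells, arena, V0 = V0, sigma = sigma)
}

#' Generate noisy synthetic GPS tracks with ground truth
#'
#' Runs a simulation scenario, keeps the 15-s sampled positions as ground
#' truth, and overlays isotropic Gaussian GPS noise with a per-track accuracy
#' drawn uniformly from `gps_noise` (a single value fixes it). The noise is
#' applied independently per axis with standard deviation equal to the
#' accuracy, so the two-dimensional rms position error is `accuracy * sqrt(2)`.
#'
#' @param config A [sim_config()].
#' @param land A [landscape()].
#' @param gps_noise Accuracy range (m), default `c(2, 6)` (the GPS error band
#'   of consumer receivers in open parkland); a scalar fixes the accuracy.
#' @param seed Integer seed covering both simulation and noise.
#' @return List with `tracks` (noisy, with an `accuracy` column), `truth`
#'   (noise-free `bp_tracks`), `walkers` bookkeeping, `scenario` (the full
#'   `bp_scenario`).
#' @export
make_synthetic_gps <- function(config, land = make_default_landscape(),
                               gps_noise = c(2, 6), seed = NULL) {
  stopifnot(all(gps_noise >= 0))
  if (!is.null(seed)) set.seed(seed)
  sc <- run_scenario(config, land)
  noisy <- lapply(sc$tracks, function(tr) {
    acc <- if (length(gps_noise) == 1) gps_noise else
      stats::runif(1, gps_noise[1], gps_noise[2])
    df <- as.data.frame(tr)
    df$x <- df$x + stats::rnorm(nrow(df), 0, acc)
    df$y <- df$y + stats::rnorm(nrow(df), 0, acc)
    df$accuracy <- acc
    new_track(df, attr(tr, "walker_id"), "planar")
  })
  list(tracks = new_tracks(noisy), truth = sc$tracks,
       walkers = sc$walkers, scenario = sc)
}
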