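#' Simulation configuration
#'
#' Holds the parameters of the overdamped Langevin stop-and-run model
#' \deqn{v(t) = \frac{r(t+\Delta t) - r(t)}{\Delta t} = \frac{1}{\gamma}(F_R + F_A)}
#' where the reactive force \eqn{F_R = -\nabla V} derives from the attraction
#' landscape and the active force has Rayleigh-distributed modulus
#' \eqn{\sqrt{2\beta/\Delta t}\,\rho} and Von Mises heading increments with
#' concentration \eqn{\kappa/\Delta t}. With `kappa = 0` heading increments
#' are uniform; with `V0 = 0` the landscape is inert. The five presets are
#'
#' * `RW`   — pure random walk: `V0 = 0`, `kappa = 0` (landscape ignored);
#' * `CRW`  — correlated random walk: `V0 = 0`, `kappa > 0`;
#' * `PRW`  — potential-driven random walk: `kappa = 0`, `V0 > 0`;
#' * `CPRW` — correlated potential-driven random walk: all parameters free;
#' * `DSW`  — destination-selection walk: CPRW where each walker independently
#'   ignores each well with probability `p_skip`.
#'
#' @param variant One of `"RW"`, `"CRW"`, `"PRW"`, `"CPRW"`, `"DSW"`.
#' @param dt Integration step (s), default 0.1.
#' @param sample_every Output sampling interval (s), default 15; must be a
#'   multiple of `dt` and at least `dt`.
#' @param gamma Drag, default 1 (kept for unit transparency; a change only
#'   rescales time).
#' @param beta Noise amplitude (m^2/s), default 1.7: with 15 s sampling this
#'   puts the RW flight-velocity scale `sqrt(2 beta / 15) E[rho]` near the
#'   0.6 m/s empirically observed for strolling pedestrians.
#' @param kappa Persistence (s), default 0; the Von Mises concentration used
#'   per step is `kappa / dt`.
#' @param V0 Well strength override applied to every well; `NULL` keeps each
#'   well's own value. Forced to 0 by the RW/CRW presets.
#' @param p_skip Per-well skip probability (DSW only), in \[0, 1\].
#' @param total_budget Total simulated time for [run_scenario()] (s), default
#'   100000.
#' @param origin Walker spawn point `c(x, y)`; `NULL` means the first well's
#'   centre (the welcome-stand analogue).
#' @param lifetime_sampler Either a function `(n) -> lifetimes` (s) or a
#'   numeric vector resampled with replacement. Default: log-normal with
#'   median 1800 s and sdlog 0.6 (the order of an hour-scale visit).
#' @param record_raw Keep per-step positions, forces and velocities (memory
#'   heavy; intended for the work decomposition on small runs).
#' @return A `bp_sim_config` list.
#' @export
sim_config <- function(variant = c("RW", "CRW", "PRW", "CPRW", "DSW"),
                       dt = 0.1, sample_every = 15, gamma = 1, beta = 1.7,
                       kappa = 0, V0 = NULL, p_skip = 0,
                       total_budget = 100000, origin = NULL,
                       lifetime_sampler = NULL, record_raw = FALSE) {
  variant <- match.arg(variant)
  stopifnot(dt > 0, sample_every >= dt, gamma > 0, beta >= 0, kappa >= 0,
            p_skip >= 0, p_skip <= 1, total_budget > 0)
  if (abs(sample_every / dt - round(sample_every / dt)) > 1e-9) {
    stop("sample_every must be an integer multiple of dt")
  }
  if (variant %in% c("RW", "CRW")) V0 <- 0
  if (variant %in% c("RW", "PRW") && kappa != 0) {
    stop("preset ", variant, " requires kappa = 0")
  }
  if (variant %in% c("CRW", "CPRW", "DSW") && kappa <= 0) {
    stop("preset ", variant, " requires kappa > 0")
  }
  if (variant == "DSW" && p_skip == 0) {
    warning("DSW with p_skip = 0 is identical to CPRW")
  }
  if (is.null(lifetime_sampler)) {
    lifetime_sampler <- function(n) stats::rlnorm(n, log(1800), 0.6)
  } else if (is.numeric(lifetime_sampler)) {
    pool <- lifetime_sampler
    lifetime_sampler <- function(n) sample(pool, n, replace = TRUE)
  }
  structure(list(variant = variant, dt = dt, sample_every = sample_every,
                 gamma = gamma, beta = beta, kappa = kappa, V0 = V0,
                 p_skip = p_skip, total_budget = total_budget, origin = origin,
                 lifetime_sampler = lifetime_sampler, record_raw = record_raw),
            class = "bp_sim_config")
}

#' @export
print.bp_sim_config <- function(x, ...) {
  cat(sprintf("<%s config: dt=%g s, sample=%g s, beta=%g, kappa=%g, V0=%s, budget=%g s>\n",
              x$variant, x$dt, x$sample_every, x$beta, x$kappa,
              if (is.null(x$V0)) "wells' own" else format(x$V0),
              x$total_budget))
  invisible(x)
}

#' Draw Rayleigh speed factors
#'
#' The active-force modulus factor rho, with density `p(rho) = rho exp(-rho^2/2)`
#' (Rayleigh with unit scale; mean `sqrt(pi/2)`).
#'
#' @param n Number of draws.
#' @return Non-negative numeric vector.
#' @export
draw_speed_factor <- function(n) {
  sqrt(-2 * log(stats::runif(n)))
}

#' Draw new headings by a Von Mises turn
#'
#' Adds to `theta_prev` a turning increment drawn from the Von Mises
#' distribution with mean 0 and concentration `kappa / dt` (Best-Fisher
#' rejection sampling; `kappa = 0` gives uniform turns) and wraps the result
#' to (-pi, pi].
#'
#' @param n Number of draws.
#' @param theta_prev Previous heading(s), recycled.
#' @param kappa Persistence parameter (>= 0).
#' @param dt Step length (s).
#' @return Numeric vector of new headings in (-pi, pi].
#' @export
draw_turn <- function(n, theta_prev = 0, kappa = 0, dt = 0.1) {
  stopifnot(kappa >= 0, dt > 0)
  th <- theta_prev + cpp_vonmises(n, kappa / dt)
  ((th + pi) %% (2 * pi)) - pi
}

# wells matrix + per-walker skip mask for the C++ stepper
wells_matrix <- function(land, V0_override = NULL) {
  w <- land$wells
  V0 <- if (is.null(V0_override)) w$V0 else rep(V0_override, nrow(w))
  cbind(x = w$x, y = w$y, V0 = V0, sigma = w$sigma)
}

#' Simulate one walker
#'
#' Spawns a walker at the configured origin (the first well's centre by
#' default), integrates the Langevin dynamics at `dt`, samples its position
#' every `sample_every` seconds, and terminates on the first of: lifetime
#' reached, all (non-skipped) wells visited, or arena border crossed (the
#' track is truncated at the crossing; the outside fix is never emitted).
#'
#' @param config A [sim_config()].
#' @param land A [landscape()].
#' @param lifetime Walker lifetime (s); drawn from the config's sampler when
#'   missing.
#' @param walker_id Identifier for the emitted track.
#' @return List with `track` (a `bp_track` of sampled fixes), `age`,
#'   `termination` (`"lifetime"`, `"all_visited"` or `"border"`), `work_R`,
#'   `work_A`, `power_total`, `n_visited` and optionally `raw` (per-step
#'   data frame with forces and velocities).
#' @export
run_walker <- function(config, land, lifetime = NULL, walker_id = "w1") {
  stopifnot(inherits(config, "bp_sim_config"), inherits(land, "bp_landscape"))
  if (is.null(lifetime)) lifetime <- config$lifetime_sampler(1)
  use_wells <- config$variant %in% c("PRW", "CPRW", "DSW")
  wm <- wells_matrix(land, config$V0)
  skip <- if (config$variant == "DSW") {
    stats::runif(nrow(wm)) < config$p_skip
  } else rep(FALSE, nrow(wm))
  origin <- config$origin %||% c(land$wells$x[1], land$wells$y[1])
  theta0 <- stats::runif(1, -pi, pi)
  res <- cpp_run_walker(origin[1], origin[2], theta0, wm, skip, use_wells,
                        config$dt, config$sample_every, config$gamma,
                        config$beta, config$kappa, lifetime,
                        land$arena$width, land$arena$height,
                        config$record_raw)
  df <- data.frame(t = res$t, x = res$x, y = res$y)
  list(track = new_track(df, walker_id, "planar"),
       lifetime = lifetime, age = res$age, termination = res$termination,
       work_R = res$work_R, work_A = res$work_A,
       power_total = res$power_total, n_visited = res$n_visited,
       raw = res$raw)
}

#' Simulate a population of sequential walkers
#'
#' Walkers are created one after another (a new walker spawns when the
#' previous one is removed) until the cumulative simulated age reaches
#' `total_budget` seconds. Reproducible: the same `seed` yields identical
#' output.
#'
#' @param config A [sim_config()].
#' @param land A [landscape()].
#' @param seed Integer seed for all randomness (optional).
#' @return A `bp_scenario`: list with `tracks` (a `bp_tracks` collection),
#'   `walkers` (a bookkeeping data frame: lifetime, age, termination, works,
#'   wells visited), total `work_R`/`work_A`/`power_total`, the config and
#'   the landscape. Raw per-step paths are kept in `raw` (per walker) when
#'   `config$record_raw` is set.
#' @export
run_scenario <- function(config, land, seed = NULL) {
  stopifnot(inherits(config, "bp_sim_config"), inherits(land, "bp_landscape"))
  if (!is.null(seed)) set.seed(seed)
  tracks <- list()
  raw <- list()
  rows <- list()
  total <- 0
  i <- 0L
  while (total < config$total_budget) {
    i <- i + 1L
    id <- sprintf("sim%04d", i)
    wk <- run_walker(config, land, walker_id = id)
    tracks[[id]] <- wk$track
    if (config$record_raw) raw[[id]] <- wk$raw
    rows[[i]] <- data.frame(walker_id = id, lifetime = wk$lifetime,
                            age = wk$age, termination = wk$termination,
                            work_R = wk$work_R, work_A = wk$work_A,
                            power_total = wk$power_total,
                            n_visited = wk$n_visited,
                            stringsAsFactors = FALSE)
    total <- total + wk$age
  }
  walkers <- do.call(rbind, rows)
  structure(list(tracks = new_tracks(tracks), walkers = walkers,
                 work_R = sum(walkers$work_R), work_A = sum(walkers$work_A),
                 power_total = sum(walkers$power_total),
                 total_time = total, config = config, landscape = land,
                 raw = if (config$record_raw) raw else NULL),
            class = "bp_scenario")
}

#' @export
print.bp_scenario <- function(x, ...) {
  cat(sprintf("<%s scenario: %d walker(s), %.0f s simulated, %d sampled fixes>\n",
              x$config$variant, nrow(x$walkers), x$total_time,
              sum(vapply(x$tracks, nrow, integer(1)))))
  tab <- table(x$walkers$termination)
  cat("  terminations:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Sample in-core residence times (two-dimensional Kramers problem)
#'
#' A single particle diffuses in one attraction well with no visit memory;
#' every completed episode between entering and leaving the sigma-core is
#' recorded. For well depths a few times the noise amplitude the escape is a
#' rare event and the residence times approach the exponential law of the
#' Kramers problem.
#'
#' @param V0 Well strength.
#' @param sigma Core radius (m).
#' @param beta Noise amplitude.
#' @param dt Integration step (s).
#' @param n_events Number of episodes to collect.
#' @param max_steps Hard cap on integration steps.
#' @param seed Optional seed.
#' @return Numeric vector of residence times (s).
#' @export
trapping_time_sample <- function(V0, sigma = 4, beta = 1.7, dt = 0.1,
                                 n_events = 2000, max_steps = 5e7,
                                 seed = NULL) {
  stopifnot(V0 > 0, beta > 0)
  if (!is.null(seed)) set.seed(seed)
  cpp_trapping_times(V0, sigma, beta, dt, as.integer(n_events), max_steps)
}
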