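#' Empirical complementary cumulative distribution on a grid
#'
#' Evaluates `P(X > t)` at thresholds `0, bin_width, 2 bin_width, ...` with
#' the accumulated binomial standard error
#' `se_i = sqrt(sum_{j<=i} p_j (1 - p_j) / N)` where `p_j` is the probability
#' mass of bin j.
#'
#' @param samples Non-empty numeric vector.
#' @param bin_width Bin width (same units as `samples`), default 15.
#' @return Data frame with columns `threshold`, `ccdf`, `stderr`.
#' @export
ccdf <- function(samples, bin_width = 15) {
  if (!length(samples)) stop("ccdf of an empty sample is undefined")
  stopifnot(bin_width > 0)
  n <- length(samples)
  thr <- seq(0, max(samples) + bin_width, by = bin_width)
  cc <- vapply(thr, function(ti) mean(samples > ti), numeric(1))
  p <- c(1, cc[-length(cc)]) - cc          # mass of each bin (thr[i-1], thr[i]]
  se <- sqrt(cumsum(p * (1 - p)) / n)
  data.frame(threshold = thr, ccdf = cc, stderr = se)
}

# chi^2_red convention: mean squared residual between empirical and model
# CCDF on the binned grid, divided by (bins - n_par)
binned_chi2_red <- function(samples, model_ccdf, n_par, bin_width) {
  g <- ccdf(samples, bin_width)
  resid <- g$ccdf - model_ccdf(g$threshold)
  sum(resid^2) / max(1L, nrow(g) - n_par)
}

#' Sample from the two-timescale stop-duration mixture
#'
#' Draws from the law with CCDF
#' `P(T > t) = omega exp(-t/tau1) + (1 - omega) exp(-t/tau2)`: with
#' probability `omega` an exponential of mean `tau1`, otherwise of mean `tau2`.
#'
#' @param n Number of draws.
#' @param omega Mixture weight of the long timescale, in \[0, 1\].
#' @param tau1 Long timescale (s).
#' @param tau2 Short timescale (s).
#' @return Numeric vector of durations (s).
#' @export
rstop_mixture <- function(n, omega = 0.308, tau1 = 617, tau2 = 37.5) {
  stopifnot(omega >= 0, omega <= 1, tau1 > 0, tau2 > 0)
  long <- stats::runif(n) < omega
  stats::rexp(n, 1 / ifelse(long, tau1, tau2))
}

#' Sample from the shifted exponential flight-length law
#'
#' Draws from `P(L > r) = exp(-(r - r_min)/lambda)` for `r > r_min`.
#'
#' @param n Number of draws.
#' @param lambda Decay length (m).
#' @param r_min Support lower bound (m); the stop threshold of the
#'   segmentation imposes this bound naturally.
#' @return Numeric vector of lengths (m).
#' @export
rflight_exp <- function(n, lambda = 27, r_min = 8) {
  stopifnot(lambda > 0)
  r_min + stats::rexp(n, 1 / lambda)
}

# negative log-likelihood of the mixture in transformed coordinates
# p = (qlogis(omega), log tau1, log tau2), numerically stable
mix_nll <- function(p, t) {
  om <- stats::plogis(p[1]); lt1 <- p[2]; lt2 <- p[3]
  a <- log(om) - lt1 - t * exp(-lt1)
  b <- log1p(-om) - lt2 - t * exp(-lt2)
  m <- pmax(a, b)
  -sum(m + log(exp(a - m) + exp(b - m)))
}

#' Fit the two-timescale exponential stop-duration mixture
#'
#' Fits `P(T > t) = omega exp(-t/tau1) + (1-omega) exp(-t/tau2)` with
#' `tau1 >= tau2` enforced by relabelling. The default is maximum likelihood
#' (EM to convergence, then a quasi-Newton polish); `"binned_lsq"` instead
#' minimizes the squared distance between model and empirical CCDF on a
#' binned grid, the procedure used for the published fit. The reduced
#' chi-square is always reported from the binned comparison with
#' `dof = bins - 3`. When the two-component model does not improve on a
#' single exponential by a likelihood-ratio margin the fit collapses to the
#' `omega = 1` boundary (the mixture is unidentifiable on such data) and is
#' flagged weakly identified.
#'
#' @param durations Positive durations (s), at least 50.
#' @param method `"mle"` (default) or `"binned_lsq"`.
#' @param bin_width CCDF bin width (s) for the binned comparison, default 15.
#' @return A `bp_mixfit` with fields `omega`, `tau1`, `tau2`, `stderr`
#'   (delta-method standard errors), `chi2_red`, `logLik`, `n`,
#'   `weakly_identified` (`TRUE` when `tau1/tau2 < 2`, where the two scales
#'   are barely separable) and `method`.
#' @export
fit_stop_mixture <- function(durations, method = c("mle", "binned_lsq"),
                             bin_width = 15) {
  method <- match.arg(method)
  t <- durations[is.finite(durations) & durations > 0]
  if (length(t) < 50) stop("need at least 50 positive durations")
  if (stats::sd(t) == 0) stop("degenerate data: all durations equal")

  # EM initialization: split at the median of log-durations
  spl <- t > stats::median(t)
  tau1 <- mean(t[spl]); tau2 <- mean(t[!spl]); om <- mean(spl)
  for (it in seq_len(2000)) {
    f1 <- om * stats::dexp(t, 1 / tau1)
    f2 <- (1 - om) * stats::dexp(t, 1 / tau2)
    g <- f1 / (f1 + f2)
    om_new <- mean(g)
    tau1_new <- sum(g * t) / sum(g)
    tau2_new <- sum((1 - g) * t) / sum(1 - g)
    delta <- max(abs(om_new - om), abs(tau1_new - tau1) / tau1,
                 abs(tau2_new - tau2) / tau2)
    om <- om_new; tau1 <- tau1_new; tau2 <- tau2_new
    if (delta < 1e-10) break
  }
  p0 <- c(stats::qlogis(min(max(om, 1e-6), 1 - 1e-6)), log(tau1), log(tau2))

  if (method == "mle") {
    opt <- stats::optim(p0, mix_nll, t = t, method = "BFGS",
                        control = list(maxit = 500))
    if (opt$convergence != 0 && opt$convergence != 1) {
      stop("mixture fit did not converge (code ", opt$convergence, "); ",
           "last iterate: omega=", signif(stats::plogis(opt$par[1]), 4),
           " tau1=", signif(exp(opt$par[2]), 4),
           " tau2=", signif(exp(opt$par[3]), 4))
    }
    p <- opt$par
    nll <- opt$value
    H <- stats::optimHess(p, mix_nll, t = t)
  } else {
    g <- ccdf(t, bin_width)
    obj <- function(p) {
      om <- stats::plogis(p[1]); tau1 <- exp(p[2]); tau2 <- exp(p[3])
      mod <- om * exp(-g$threshold / tau1) + (1 - om) * exp(-g$threshold / tau2)
      sum((g$ccdf - mod)^2)
    }
    opt <- stats::optim(p0, obj, method = "BFGS", control = list(maxit = 500))
    p <- opt$par
    nll <- mix_nll(p, t)
    H <- stats::optimHess(p, mix_nll, t = t)   # likelihood-based errors
  }

  om <- stats::plogis(p[1]); tau1 <- exp(p[2]); tau2 <- exp(p[3])
  # near a flat likelihood ridge the Hessian can be indefinite: NA out
  se_t <- tryCatch({
    v <- diag(solve(H))
    ifelse(v > 0, sqrt(v), NA_real_)
  }, error = function(e) rep(NA_real_, 3))
  se <- c(omega = se_t[1] * om * (1 - om), tau1 = se_t[2] * tau1,
          tau2 = se_t[3] * tau2)
  if (tau2 > tau1) {   # relabel so tau1 is the long timescale
    tmp <- tau1; tau1 <- tau2; tau2 <- tmp
    om <- 1 - om
    se <- c(omega = unname(se["omega"]), tau1 = unname(se["tau2"]),
            tau2 = unname(se["tau1"]))
  }
  # degeneracy resolution: on (near-)single-exponential data the mixture
  # likelihood is a flat ridge in (omega, tau1, tau2); if the two-component
  # model does not beat the one-exponential sub-model by a likelihood-ratio
  # margin (chi-square, 2 df, 5%), collapse to the omega = 1 boundary
  ll1 <- sum(stats::dexp(t, 1 / mean(t), log = TRUE))
  if (2 * (-nll - ll1) < stats::qchisq(0.95, df = 2)) {
    tau1 <- mean(t); tau2 <- tau1; om <- 1
    nll <- -ll1
    se <- c(omega = NA_real_, tau1 = tau1 / sqrt(length(t)), tau2 = NA_real_)
  }
  weak <- tau1 / tau2 < 2
  if (weak) warning("timescales differ by less than a factor 2: ",
                    "mixture weakly identified", call. = FALSE)
  model_ccdf <- function(x) om * exp(-x / tau1) + (1 - om) * exp(-x / tau2)
  structure(list(omega = om, tau1 = tau1, tau2 = tau2, stderr = se,
                 chi2_red = binned_chi2_red(t, model_ccdf, 3, bin_width),
                 logLik = -nll, n = length(t), method = method,
                 bin_width = bin_width, weakly_identified = weak),
            class = "bp_mixfit")
}

#' @export
print.bp_mixfit <- function(x, ...) {
  cat("Two-timescale exponential stop-duration mixture (", x$method, ")\n",
      sep = "")
  cat(sprintf("  omega = %.4f (se %.4f)\n", x$omega, x$stderr["omega"]))
  cat(sprintf("  tau1  = %.2f s (se %.2f)\n", x$tau1, x$stderr["tau1"]))
  cat(sprintf("  tau2  = %.2f s (se %.2f)\n", x$tau2, x$stderr["tau2"]))
  cat(sprintf("  chi2_red (binned CCDF, dof = bins - 3) = %.3g;  n = %d\n",
              x$chi2_red, x$n))
  if (x$weakly_identified) cat("  [weakly identified: tau1/tau2 < 2]\n")
  invisible(x)
}

#' @export
coef.bp_mixfit <- function(object, ...) {
  c(omega = object$omega, tau1 = object$tau1, tau2 = object$tau2)
}

#' @export
logLik.bp_mixfit <- function(object, ...) {
  structure(object$logLik, df = 3, nobs = object$n, class = "logLik")
}

#' @export
summary.bp_mixfit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Fit the shifted exponential flight-length law
#'
#' Maximum likelihood for `P(L > r) = exp(-(r - r_min)/lambda)`, i.e.
#' `lambda` is the mean excess over `r_min` among lengths exceeding it.
#'
#' @param lengths Flight lengths (m); at least 20 must exceed `r_min`.
#' @param r_min Support lower bound (m); use the segmentation stop threshold.
#' @param bin_width CCDF bin width (m) for the reduced chi-square, default 5.
#' @return A `bp_expfit` with `lambda`, `stderr` (`lambda/sqrt(n)`), `r_min`,
#'   `chi2_red`, `n`.
#' @export
fit_flight_exponential <- function(lengths, r_min = 8, bin_width = 5) {
  ex <- lengths[is.finite(lengths) & lengths > r_min] - r_min
  if (!length(ex)) stop("no flight lengths above r_min = ", r_min)
  if (length(ex) < 20) stop("need at least 20 lengths above r_min")
  lambda <- mean(ex)
  model_ccdf <- function(x) exp(-x / lambda)
  structure(list(lambda = lambda, stderr = lambda / sqrt(length(ex)),
                 r_min = r_min,
                 chi2_red = binned_chi2_red(ex, model_ccdf, 1, bin_width),
                 n = length(ex)),
            class = "bp_expfit")
}

#' @export
print.bp_expfit <- function(x, ...) {
  cat("Shifted exponential flight-length fit\n")
  cat(sprintf("  lambda = %.2f m (se %.2f), support starts at r_min = %g m\n",
              x$lambda, x$stderr, x$r_min))
  cat(sprintf("  chi2_red (binned CCDF) = %.3g;  n = %d\n", x$chi2_red, x$n))
  invisible(x)
}

#' @export
coef.bp_expfit <- function(object, ...) c(lambda = object$lambda)

#' Polar histogram of flight orientations
#'
#' Probabilities over equal angular bins; bin 1 is centred on the +x
#' direction (east, the promenade axis).
#'
#' @param headings Flight headings (rad) or a `bp_segmented`/list thereof.
#' @param n_bins Number of angular bins (>= 4), default 16.
#' @return A `bp_orient` list with `centers` (rad), `probs` (sums to 1),
#'   `counts` and `n`.
#' @export
orientation_histogram <- function(headings, n_bins = 16) {
  stopifnot(n_bins >= 4)
  if (inherits(headings, "bp_segmented") ||
      (is.list(headings) && !is.numeric(headings))) {
    headings <- flight_headings(headings)
  }
  if (!length(headings)) stop("no flights to build an orientation histogram")
  w <- 2 * pi / n_bins
  # rotate by half a bin so bin 1 is centred on angle 0, then wrap to [0, 2pi)
  a <- (headings + w / 2) %% (2 * pi)
  idx <- pmin(floor(a / w) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(centers = (seq_len(n_bins) - 1L) * w,
                 probs = counts / sum(counts), counts = counts,
                 n = sum(counts)),
            class = "bp_orient")
}

#' Flight velocity summary
#'
#' Statistics over flight velocities only; stops are never counted. The
#' standard deviation is the population form (divisor n).
#'
#' @param segs `bp_segmented` or list of them.
#' @param breaks Passed to [graphics::hist()] (computed without plotting).
#' @return List with `mean`, `sd` (population), `n` and `histogram`.
#' @export
velocity_stats <- function(segs, breaks = "Sturges") {
  if (inherits(segs, "bp_segmented")) segs <- list(segs)
  v <- unlist(lapply(segs, function(s) s$flights$velocity), use.names = FALSE)
  v <- v[is.finite(v)]
  if (!length(v)) stop("no flights with finite velocity")
  m <- mean(v)
  list(mean = m, sd = sqrt(mean((v - m)^2)), n = length(v),
       histogram = graphics::hist(v, breaks = breaks, plot = FALSE))
}

#' Active/reactive work decomposition
#'
#' Accumulates the work done by the reactive (landscape) and active (noise)
#' forces, `W = sum F . v dt`, over all walkers of a scenario or over a raw
#' per-step path, and reports each component's share of the total developed
#' power as `100 |W| / (|W_R| + |W_A|)`.
#'
#' @param x A `bp_scenario`, a walker-bookkeeping data frame with `work_R`
#'   and `work_A` columns, or a raw path data frame with per-step `F_Rx`,
#'   `F_Ry`, `F_Ax`, `F_Ay`, `vx`, `vy` and `t`.
#' @return List with `pct_reactive`, `pct_active` (summing to 100), and the
#'   signed totals `work_R`, `work_A`.
#' @export
work_decomposition <- function(x) {
  if (inherits(x, "bp_scenario")) {
    wR <- x$work_R; wA <- x$work_A
  } else if (is.data.frame(x) && all(c("work_R", "work_A") %in% names(x))) {
    wR <- sum(x$work_R); wA <- sum(x$work_A)
  } else if (is.data.frame(x) && all(c("F_Rx", "vx") %in% names(x))) {
    dt <- diff(c(0, x$t))
    wR <- sum((x$F_Rx * x$vx + x$F_Ry * x$vy) * dt)
    wA <- sum((x$F_Ax * x$vx + x$F_Ay * x$vy) * dt)
  } else {
    stop("cannot extract work terms from this object")
  }
  tot <- abs(wR) + abs(wA)
  if (tot == 0) stop("total work is zero: the split is undefined")
  list(pct_reactive = 100 * abs(wR) / tot, pct_active = 100 * abs(wA) / tot,
       work_R = wR, work_A = wA)
}

#' Coarse grid calibration against target stop statistics
#'
#' For every row of the parameter grid, simulates the scenario at a reduced
#' budget, segments the sampled tracks, fits the stop-duration mixture and
#' scores the squared distance to the target in `(omega, log tau1, log tau2)`.
#' The full score table is returned for transparency; no p-values attached.
#'
#' @param target Either a named vector/list with `omega`, `tau1`, `tau2`, or a
#'   numeric vector of target stop durations (then fitted internally).
#' @param grid Data frame with columns `V0`, `beta` and optionally `kappa`.
#' @param land A [landscape()].
#' @param variant Scenario preset used for the simulations.
#' @param budget Reduced simulated time per grid point (s).
#' @param seed Seed (re-applied per grid point so points differ only by
#'   parameters).
#' @param R_stop,R_flight Segmentation parameters.
#' @param min_duration Minimum stop duration (s) entering the fit.
#' @return List with `best` (grid row + score at the argmin) and `table`
#'   (grid with fitted parameters and scores; failed fits score `Inf`).
#' @export
calibrate <- function(target, grid, land, variant = "PRW", budget = 20000,
                      seed = 1, R_stop = 8, R_flight = 8, min_duration = 15) {
  if (is.numeric(target) && is.null(names(target)) && length(target) > 3) {
    ft <- fit_stop_mixture(target)
    target <- coef(ft)
  }
  target <- as.list(target)
  stopifnot(all(c("omega", "tau1", "tau2") %in% names(target)),
            all(c("V0", "beta") %in% names(grid)))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    V0 <- grid$V0[i]; beta <- grid$beta[i]
    kappa <- if ("kappa" %in% names(grid)) grid$kappa[i] else 0
    cfg <- sim_config(variant, beta = beta, kappa = kappa, V0 = V0,
                      total_budget = budget)
    sc <- run_scenario(cfg, land, seed = seed)
    segs <- suppressWarnings(segment_tracks(sc$tracks, R_stop, R_flight))
    dur <- stop_durations(segs, min_duration)
    fit <- tryCatch(suppressWarnings(fit_stop_mixture(dur)),
                    error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(V0 = V0, beta = beta, kappa = kappa,
                        omega = NA, tau1 = NA, tau2 = NA,
                        n_stops = length(dur), score = Inf))
    }
    score <- (fit$omega - target$omega)^2 +
      (log(fit$tau1) - log(target$tau1))^2 +
      (log(fit$tau2) - log(target$tau2))^2
    data.frame(V0 = V0, beta = beta, kappa = kappa, omega = fit$omega,
               tau1 = fit$tau1, tau2 = fit$tau2, n_stops = length(dur),
               score = score)
  })
  tab <- do.call(rbind, rows)
  if (all(!is.finite(tab$score))) {
    stop("calibration failed: no grid point produced enough stops to fit")
  }
  list(best = tab[which.min(tab$score), ], table = tab)
}
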