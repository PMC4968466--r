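#' Per-bridge Brownian motion variance by sliding-window likelihood
#'
#' Simplified dynamic-Brownian-bridge variance estimation: for each bridge
#' (pair of consecutive fixes) a window of `window` fixes centred on the
#' bridge is taken and the Brownian motion variance `sigma_m^2` is estimated
#' by leave-one-out maximum likelihood: each interior fix of the window is
#' compared with the Brownian bridge spanned by its two neighbours, with the
#' location error `delta` entering the bridge variance. Tracks shorter than
#' `window` fixes are excluded by the caller.
#'
#' @param track A planar track (data frame with `t`, `x`, `y`).
#' @param window Sliding window size (fixes), odd, default 11.
#' @param delta Location error (m), default 4.071.
#' @return Numeric vector of `sigma_m^2` values (m^2/s), one per bridge
#'   (length `nrow(track) - 1`), all strictly positive.
#' @export
motion_variance <- function(track, window = 11, delta = 4.071) {
  n <- nrow(track)
  if (n < window) stop("track shorter than the sliding window (", n, " < ",
                       window, " fixes)")
  half <- (window - 1L) %/% 2L
  t <- track$t; x <- track$x; y <- track$y

  # leave-one-out negative log-likelihood of sigma_m^2 over window [lo, hi]
  nll_window <- function(s2, lo, hi) {
    kk <- (lo + 1L):(hi - 1L)
    a <- (t[kk] - t[kk - 1L]) / (t[kk + 1L] - t[kk - 1L])
    Tt <- t[kk + 1L] - t[kk - 1L]
    vv <- s2 * Tt * a * (1 - a) + ((1 - a)^2 + a^2) * delta^2
    mx <- x[kk - 1L] + a * (x[kk + 1L] - x[kk - 1L])
    my <- y[kk - 1L] + a * (y[kk + 1L] - y[kk - 1L])
    sum(log(2 * pi * vv) + ((x[kk] - mx)^2 + (y[kk] - my)^2) / (2 * vv))
  }
  vapply(seq_len(n - 1L), function(i) {
    lo <- max(1L, min(i - half + 1L, n - window + 1L))
    hi <- lo + window - 1L
    opt <- stats::optimize(nll_window, c(1e-8, 1e4), lo = lo, hi = hi)
    max(opt$minimum, 1e-8)
  }, numeric(1))
}

# empty raster over an arena
new_ud <- function(arena, cell) {
  nx <- as.integer(ceiling(arena$width / cell))
  ny <- as.integer(ceiling(arena$height / cell))
  structure(list(density = matrix(0, nrow = ny, ncol = nx),
                 cell = cell, arena = arena,
                 xs = (seq_len(nx) - 1) * cell,   # west edges of columns
                 ys = (seq_len(ny) - 1) * cell),  # south edges of rows
            class = "bp_ud")
}

#' Add one Brownian-bridge density contribution to a raster
#'
#' The bridge between two fixes is integrated over `n_alpha` equally spaced
#' interior time fractions; at each fraction the position is Gaussian with
#' mean on the chord and total variance
#' `sigma_m^2 T alpha (1 - alpha) + ((1-alpha)^2 + alpha^2) delta^2`.
#' Cell masses are exact Gaussian integrals over the half-open cells
#' (separable in x and y). The contributed mass equals the bridge duration,
#' so bridges weigh in proportion to the time they represent.
#'
#' @param ud A `bp_ud` raster (modified copy returned).
#' @param fix_a,fix_b Lists/rows with `t`, `x`, `y`; `fix_b$t > fix_a$t`.
#' @param sigma_m2 Brownian motion variance for this bridge (m^2/s).
#' @param delta Location error (m).
#' @param n_alpha Interior integration points, default 10.
#' @return The raster with the bridge's mass added (unnormalized).
#' @export
bridge_density <- function(ud, fix_a, fix_b, sigma_m2, delta = 4.071,
                           n_alpha = 10) {
  T <- fix_b$t - fix_a$t
  if (T <= 0) {
    warning("zero-duration bridge skipped")
    return(ud)
  }
  alphas <- (seq_len(n_alpha) - 0.5) / n_alpha
  cell <- ud$cell
  xe <- c(ud$xs, ud$xs[length(ud$xs)] + cell)   # column edges
  ye <- c(ud$ys, ud$ys[length(ud$ys)] + cell)   # row edges
  wgt <- T / n_alpha
  for (a in alphas) {
    mx <- fix_a$x + a * (fix_b$x - fix_a$x)
    my <- fix_a$y + a * (fix_b$y - fix_a$y)
    s <- sqrt(sigma_m2 * T * a * (1 - a) + ((1 - a)^2 + a^2) * delta^2)
    px <- diff(stats::pnorm(xe, mx, s))
    py <- diff(stats::pnorm(ye, my, s))
    ud$density <- ud$density + wgt * (py %o% px)
  }
  ud
}

#' Population-level utilization density raster
#'
#' Simplified dynamic Brownian bridge movement model: every track with at
#' least `window` fixes contributes one Brownian bridge per pair of
#' consecutive fixes, with per-bridge motion variance from
#' [motion_variance()] and a fixed location error `delta`; contributions are
#' summed over all tracks and normalized to total mass 1. Mass falling
#' outside the arena raster is truncated before normalization.
#'
#' @param tracks A `bp_tracks` collection (planar) or list of track data
#'   frames.
#' @param arena The [arena()] the raster covers.
#' @param cell Cell size (m), default 8.
#' @param delta Location error (m), default 4.071.
#' @param window Sliding window (fixes) for the motion variance, default 11.
#' @param n_alpha Interior integration points per bridge.
#' @return A `bp_ud` raster: `density` matrix (rows = south to north, columns
#'   = west to east) summing to 1, with `cell`, `arena`, cell edge vectors
#'   and metadata `delta`, `window`, `n_excluded`.
#' @export
population_ud <- function(tracks, arena = beepath::arena(), cell = 8,
                          delta = 4.071, window = 11, n_alpha = 10) {
  ud <- new_ud(arena, cell)
  n_excl <- 0L
  for (tr in tracks) {
    if (nrow(tr) < window) { n_excl <- n_excl + 1L; next }
    s2 <- motion_variance(tr, window, delta)
    for (i in seq_len(nrow(tr) - 1L)) {
      ud <- bridge_density(ud, tr[i, ], tr[i + 1L, ], s2[i], delta, n_alpha)
    }
  }
  if (sum(ud$density) <= 0) {
    stop("no track has at least ", window, " fixes: utilization density empty")
  }
  ud$density <- ud$density / sum(ud$density)
  ud$delta <- delta; ud$window <- window; ud$n_excluded <- n_excl
  ud
}

#' @export
print.bp_ud <- function(x, ...) {
  cat(sprintf("<utilization density: %d x %d cells of %g m, mass %.6f, %d track(s) excluded>\n",
              nrow(x$density), ncol(x$density), x$cell, sum(x$density),
              x$n_excluded %||% 0L))
  invisible(x)
}

#' Highest-density isopleth mask
#'
#' The smallest set of highest-density cells whose summed mass reaches
#' `level` — the raster analogue of a home-range contour.
#'
#' @param ud A `bp_ud`.
#' @param level Mass fraction in (0, 1\].
#' @return Logical matrix of the same shape as `ud$density` (zero-density
#'   cells are never included).
#' @export
isopleth <- function(ud, level = 0.95) {
  stopifnot(level > 0, level <= 1)
  d <- as.vector(ud$density)
  o <- order(d, decreasing = TRUE)
  cs <- cumsum(d[o])
  k <- which(cs >= level - 1e-12)[1]
  keep <- o[seq_len(k)]
  keep <- keep[d[keep] > 0]
  m <- matrix(FALSE, nrow = nrow(ud$density), ncol = ncol(ud$density))
  m[keep] <- TRUE
  m
}

#' Fraction of utilization mass near well centres
#'
#' Sums the density of cells whose centre lies within `radius` of any well —
#' the summary used to compare how strongly different dynamics concentrate
#' space use on the attraction points.
#'
#' @param ud A `bp_ud`.
#' @param land A [landscape()].
#' @param radius Distance threshold (m), e.g. twice the core radius.
#' @return Scalar mass fraction in \[0, 1\].
#' @export
ud_mass_near_wells <- function(ud, land, radius = 8) {
  cx <- ud$xs + ud$cell / 2
  cy <- ud$ys + ud$cell / 2
  near <- matrix(FALSE, nrow = length(cy), ncol = length(cx))
  for (i in seq_len(nrow(land$wells))) {
    dd <- outer((cy - land$wells$y[i])^2, (cx - land$wells$x[i])^2, `+`)
    near <- near | (dd <= radius^2)
  }
  sum(ud$density[near])
}

#' Write a utilization raster as an ESRI ASCII grid
#'
#' @param ud A `bp_ud`.
#' @param path Output `.asc` file.
#' @export
write_asc <- function(ud, path) {
  d <- ud$density
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(d)),
               sprintf("nrows %d", nrow(d)),
               "xllcorner 0", "yllcorner 0",
               sprintf("cellsize %g", ud$cell),
               "NODATA_value -9999"), con)
  for (i in rev(seq_len(nrow(d)))) {     # .asc rows run north to south
    writeLines(paste(formatC(d[i, ], format = "g", digits = 10),
                     collapse = " "), con)
  }
  invisible(path)
}
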