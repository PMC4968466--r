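#' Flag track fixes as stopped or moving
#'
#' Every fix is stopped by default; a fix becomes `moving` when the *next* fix
#' in the time sequence lies further away than `R_stop`. The first and last
#' fixes of a track are always stopped.
#'
#' @param track A `bp_track` (planar) or data frame with `t`, `x`, `y`.
#' @param R_stop Distance threshold (m), default 8.
#' @param compare `"next"` (default) compares each fix to the following fix;
#'   `"centroid"` compares the next fix to the running centroid of the current
#'   stopped run (alternative reading of the flagging rule).
#' @return Character vector, one of `"stopped"`/`"moving"` per fix.
#' @export
flag_fixes <- function(track, R_stop = 8, compare = c("next", "centroid")) {
  compare <- match.arg(compare)
  stopifnot(R_stop > 0)
  x <- track$x; y <- track$y
  n <- length(x)
  if (n == 0L) stop("track has no fixes")
  flags <- rep("stopped", n)
  if (n <= 2L) return(flags)
  if (compare == "next") {
    d <- sqrt(diff(x)^2 + diff(y)^2)           # d[i] = |x_{i+1} - x_i|
    mv <- which(d > R_stop)                     # fix i moving iff next is far
    mv <- mv[mv != 1L & mv != n]
    flags[mv] <- "moving"
  } else {
    # running-centroid variant: a fix becomes moving when it falls further
    # than R_stop from the centroid of the current stopped run; centroid kept
    # as running sums
    sx <- x[1]; sy <- y[1]; m <- 1L
    for (i in 2:(n - 1L)) {
      if (sqrt((x[i] - sx / m)^2 + (y[i] - sy / m)^2) > R_stop) {
        flags[i] <- "moving"
        sx <- x[i]; sy <- y[i]; m <- 1L
      } else {
        sx <- sx + x[i]; sy <- sy + y[i]; m <- m + 1L
      }
    }
  }
  flags
}

# maximal runs of a logical vector, as a list of index ranges
runs_of <- function(keep) {
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  lapply(idx, function(i) starts[i]:ends[i])
}

#' Build stops from flagged fixes
#'
#' Each maximal run of consecutive `stopped` fixes becomes one stop with
#' centroid equal to the arithmetic mean of member positions and duration
#' `t_end - t_start` (a single-fix stop has zero duration).
#'
#' @param track A planar track.
#' @param flags Flags from [flag_fixes()].
#' @return Data frame with one row per stop: `x`, `y`, `t_start`, `t_end`,
#'   `duration`, `n_fixes`, `first_fix`, `last_fix`.
#' @export
build_stops <- function(track, flags) {
  stopifnot(length(flags) == nrow(track))
  runs <- runs_of(flags == "stopped")
  rows <- lapply(runs, function(ix) {
    data.frame(x = mean(track$x[ix]), y = mean(track$y[ix]),
               t_start = track$t[ix[1]], t_end = track$t[ix[length(ix)]],
               duration = track$t[ix[length(ix)]] - track$t[ix[1]],
               n_fixes = length(ix),
               first_fix = ix[1], last_fix = ix[length(ix)])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(x = numeric(), y = numeric(),
                                      t_start = numeric(), t_end = numeric(),
                                      duration = numeric(), n_fixes = integer(),
                                      first_fix = integer(), last_fix = integer())
  out
}

# perpendicular distances of points (px, py) from the chord (x1,y1)->(x2,y2);
# for a degenerate chord (coincident endpoints) the plain distance is used
perp_dist <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  L <- sqrt(dx^2 + dy^2)
  if (L == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  abs(dy * (px - x1) - dx * (py - y1)) / L
}

#' Group moving fixes into flights by the rectangular corridor rule
#'
#' Within each maximal run of `moving` fixes, flights are cut greedily from the
#' run start: the current flight ends at the largest index N such that every
#' interior point lies within perpendicular distance `R_flight / 2` of the
#' chord from the flight's first to its N-th fix (a corridor of total width
#' `R_flight`); the next flight starts at that fix. A moving run consisting of
#' a single fix cannot define a chord and is dropped with a warning.
#'
#' @param track A planar track.
#' @param flags Flags from [flag_fixes()].
#' @param R_flight Corridor width (m).
#' @return Data frame with one row per flight: start/end coordinates and time,
#'   `length` (Euclidean, m), `duration` (s), `velocity` (m/s), `heading`
#'   (rad, counter-clockwise from +x), `n_fixes`.
#' @export
build_flights <- function(track, flags, R_flight = 8) {
  stopifnot(length(flags) == nrow(track), R_flight > 0)
  x <- track$x; y <- track$y; t <- track$t
  runs <- runs_of(flags == "moving")
  rows <- list()
  n_dropped <- 0L
  for (ix in runs) {
    if (length(ix) == 1L) {
      n_dropped <- n_dropped + 1L
      next
    }
    s <- 1L
    while (s < length(ix)) {
      # largest end index whose chord keeps every interior point inside the
      # corridor; scanned from the run end downward (the corridor test is not
      # monotone in the end index, so the first hit from above is the maximum)
      N <- s + 1L
      for (cand in rev(seq(s + 1L, length(ix)))) {
        if (cand == s + 1L) { N <- cand; break }
        interior <- ix[(s + 1L):(cand - 1L)]
        pd <- perp_dist(x[interior], y[interior],
                        x[ix[s]], y[ix[s]], x[ix[cand]], y[ix[cand]])
        if (all(pd <= R_flight / 2)) { N <- cand; break }
      }
      i1 <- ix[s]; i2 <- ix[N]
      len <- sqrt((x[i2] - x[i1])^2 + (y[i2] - y[i1])^2)
      dur <- t[i2] - t[i1]
      rows[[length(rows) + 1L]] <- data.frame(
        x = x[i1], y = y[i1], x_end = x[i2], y_end = y[i2],
        t_start = t[i1], t_end = t[i2],
        length = len, duration = dur,
        velocity = if (dur > 0) len / dur else NA_real_,
        heading = atan2(y[i2] - y[i1], x[i2] - x[i1]),
        n_fixes = N - s + 1L)
      s <- N
    }
  }
  if (n_dropped > 0L) {
    warning("dropped ", n_dropped, " isolated single moving fix(es): no ",
            "chord can be formed", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(x = numeric(), y = numeric(),
                                      x_end = numeric(), y_end = numeric(),
                                      t_start = numeric(), t_end = numeric(),
                                      length = numeric(), duration = numeric(),
                                      velocity = numeric(), heading = numeric(),
                                      n_fixes = integer())
  out
}

#' Segment a track into alternating stops and flights
#'
#' Two-step procedure: distance flagging with threshold `R_stop`, then corridor
#' grouping of moving runs with width `R_flight`. The first and last elements
#' are always stops (track endpoints are stopped by construction). The track
#' mean velocity is the average of flight velocities; stops are never counted.
#'
#' @inheritParams flag_fixes
#' @inheritParams build_flights
#' @return A `bp_segmented` object: list with `walker_id`, `stops`, `flights`,
#'   `elements` (both interleaved chronologically), `mean_velocity` and the
#'   parameters used.
#' @export
segment_track <- function(track, R_stop = 8, R_flight = 8,
                          compare = c("next", "centroid")) {
  compare <- match.arg(compare)
  flags <- flag_fixes(track, R_stop, compare)
  stops <- build_stops(track, flags)
  flights <- build_flights(track, flags, R_flight)
  el <- rbind(
    if (nrow(stops)) cbind(type = "stop", stops[c("x", "y", "t_start", "t_end",
                                                  "duration", "n_fixes")],
                           x_end = NA_real_, y_end = NA_real_,
                           length = NA_real_, velocity = NA_real_,
                           heading = NA_real_),
    if (nrow(flights)) cbind(type = "flight",
                             flights[c("x", "y", "t_start", "t_end", "duration",
                                       "n_fixes", "x_end", "y_end", "length",
                                       "velocity", "heading")])
  )
  if (is.null(el)) el <- data.frame()
  if (nrow(el)) {
    el <- el[order(el$t_start, el$type != "stop"), ]
    rownames(el) <- NULL
  }
  structure(list(walker_id = attr(track, "walker_id") %||% "walker",
                 stops = stops, flights = flights, elements = el,
                 mean_velocity = if (nrow(flights))
                   mean(flights$velocity, na.rm = TRUE) else NA_real_,
                 R_stop = R_stop, R_flight = R_flight),
            class = "bp_segmented")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bp_segmented <- function(x, ...) {
  cat(sprintf("<segmented track '%s': %d stop(s), %d flight(s), mean v = %s m/s>\n",
              x$walker_id, nrow(x$stops), nrow(x$flights),
              formatC(x$mean_velocity, digits = 3)))
  invisible(x)
}

#' Segment every track in a collection
#'
#' @param tracks A `bp_tracks` collection (planar).
#' @inheritParams segment_track
#' @return List of `bp_segmented` objects (class `bp_segmented_list`).
#' @export
segment_tracks <- function(tracks, R_stop = 8, R_flight = 8) {
  out <- lapply(tracks, segment_track, R_stop = R_stop, R_flight = R_flight)
  structure(out, class = "bp_segmented_list")
}

#' Pool stop durations from segmented tracks
#'
#' Single-fix stops have zero duration and are removed by the minimum-duration
#' filter (default one sampling interval, 15 s) before distribution fitting.
#'
#' @param segs `bp_segmented` or list of them.
#' @param min_duration Minimum stop duration retained (s).
#' @return Numeric vector of durations (s).
#' @export
stop_durations <- function(segs, min_duration = 15) {
  if (inherits(segs, "bp_segmented")) segs <- list(segs)
  d <- unlist(lapply(segs, function(s) s$stops$duration), use.names = FALSE)
  d[d >= min_duration]
}

#' Pool flight lengths from segmented tracks
#'
#' @param segs `bp_segmented` or list of them.
#' @return Numeric vector of flight lengths (m).
#' @export
flight_lengths <- function(segs) {
  if (inherits(segs, "bp_segmented")) segs <- list(segs)
  unlist(lapply(segs, function(s) s$flights$length), use.names = FALSE)
}

#' Pool flight headings from segmented tracks
#'
#' @param segs `bp_segmented` or list of them.
#' @return Numeric vector of headings (rad).
#' @export
flight_headings <- function(segs) {
  if (inherits(segs, "bp_segmented")) segs <- list(segs)
  unlist(lapply(segs, function(s) s$flights$heading), use.names = FALSE)
}
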