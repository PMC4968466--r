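# Independent brute-force reimplementation of the stop-and-run segmentation,
# used as a regression oracle. Deliberately coded along a different route than
# the package: rotation into chord-aligned coordinates instead of the cross
# product, and a downward scan for the flight end instead of an upward one.

oracle_flags <- function(x, y, R_stop) {
  n <- length(x)
  fl <- rep("stopped", n)
  if (n > 2) {
    for (i in 2:(n - 1)) {
      if (sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2) > R_stop) {
        fl[i] <- "moving"
      }
    }
  }
  fl
}

# within one moving run (index vector), cut greedy flights: the end of the
# current flight is the largest candidate index whose interior points all fall
# in the corridor. Exhaustive: validity is evaluated for EVERY candidate and
# the maximum of the valid set is taken.
oracle_flights_in_run <- function(x, y, run, R_flight) {
  corridor_ok <- function(s, cand) {
    if (cand == s + 1) return(TRUE)
    x1 <- x[run[s]]; y1 <- y[run[s]]
    x2 <- x[run[cand]]; y2 <- y[run[cand]]
    L <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    for (j in seq(s + 1, cand - 1)) {
      px <- x[run[j]] - x1; py <- y[run[j]] - y1
      if (L == 0) {
        dev <- sqrt(px^2 + py^2)
      } else {
        # rotate so the chord lies on the x axis; deviation is |y'|
        ca <- (x2 - x1) / L; sa <- (y2 - y1) / L
        dev <- abs(-sa * px + ca * py)
      }
      if (dev > R_flight / 2) return(FALSE)
    }
    TRUE
  }
  out <- list()
  s <- 1
  while (s < length(run)) {
    valid <- Filter(function(cand) corridor_ok(s, cand),
                    seq(s + 1, length(run)))
    N <- max(unlist(valid))
    out[[length(out) + 1]] <- c(start = run[s], end = run[N])
    s <- N
  }
  out
}

oracle_segment <- function(df, R_stop, R_flight) {
  fl <- oracle_flags(df$x, df$y, R_stop)
  r <- rle(fl == "moving")
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  flights <- list()
  for (k in which(r$values)) {
    run <- starts[k]:ends[k]
    if (length(run) >= 2) {
      flights <- c(flights, oracle_flights_in_run(df$x, df$y, run, R_flight))
    }
  }
  n_stops <- sum(rle(fl == "stopped")$values)
  list(flags = fl, n_stops = n_stops,
       flights = do.call(rbind, flights))
}

# random track on a small integer grid
random_grid_track <- function(n, grid = 6, step = 5) {
  data.frame(t = seq(0, by = 15, length.out = n),
             x = sample(0:grid, n, replace = TRUE) * step,
             y = sample(0:grid, n, replace = TRUE) * step)
}

# plain planar track constructor for fixtures built in tests
toy_track <- function(x, y, t = seq(0, by = 15, length.out = length(x)),
                      id = "toy") {
  beepath::as_tracks(data.frame(walker_id = id, t = t, x = x, y = y))[[1]]
}
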