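#' Gravitational-like attraction well potential
#'
#' A stand is modelled as a non-punctual spherical attractive mass of core
#' radius `sigma` and strength `V0`. Outside the core the potential is
#' Keplerian, `-V0 sigma / d`; inside it is harmonic,
#' `-(3/2) V0 + (1/2) V0 d^2 / sigma^2`. The two branches join continuously
#' (value `-V0`, force magnitude `V0 / sigma`) at `d = sigma`.
#'
#' @param d Distance from the well centre (m), vectorized.
#' @param V0 Well strength (energy units, >= 0).
#' @param sigma Core radius (m, > 0), default 4.
#' @return Potential energy at each distance.
#' @export
#' @examples
#' well_potential(c(0, 4, 8), V0 = 1, sigma = 4)  # -1.5, -1, -0.5
well_potential <- function(d, V0, sigma = 4) {
  stopifnot(all(d >= 0), V0 >= 0, sigma > 0)
  ifelse(d >= sigma, -V0 * sigma / d,
         -1.5 * V0 + 0.5 * V0 * d^2 / sigma^2)
}

#' Construct an attraction well
#'
#' @param x,y Centre coordinates (m).
#' @param V0 Well strength (>= 0).
#' @param sigma Core radius (m).
#' @param id Integer identifier.
#' @return A `bp_well` list.
#' @export
well <- function(x, y, V0 = 34, sigma = 4, id = 1L) {
  stopifnot(V0 >= 0, sigma > 0)
  structure(list(id = as.integer(id), x = as.numeric(x), y = as.numeric(y),
                 V0 = as.numeric(V0), sigma = as.numeric(sigma)),
            class = "bp_well")
}

#' Attractive force exerted by one well
#'
#' The reactive force is minus the gradient of [well_potential()], pointing
#' toward the centre: magnitude `V0 sigma / d^2` outside the core and
#' `V0 d / sigma^2` inside; the force at the exact centre is the zero vector.
#'
#' @param r Numeric `c(x, y)` position (m).
#' @param w A `bp_well`.
#' @return Numeric `c(Fx, Fy)`.
#' @export
well_force <- function(r, w) {
  dx <- w$x - r[1]; dy <- w$y - r[2]
  d <- sqrt(dx^2 + dy^2)
  if (d == 0) return(c(0, 0))
  mag <- if (d >= w$sigma) w$V0 * w$sigma / d^2 else w$V0 * d / w$sigma^2
  mag * c(dx, dy) / d
}

#' Landscape of attraction wells in an arena
#'
#' @param wells Data frame with columns `x`, `y` and optionally `id`, `V0`,
#'   `sigma` (missing parameters take the shared defaults), or a list of
#'   `bp_well` objects.
#' @param arena A [arena()].
#' @param V0,sigma Shared defaults for wells that do not override them.
#' @return A `bp_landscape`: list with `arena` and a `wells` data frame.
#' @export
landscape <- function(wells, arena = beepath::arena(), V0 = 34, sigma = 4) {
  if (is.list(wells) && !is.data.frame(wells) && length(wells) &&
      inherits(wells[[1]], "bp_well")) {
    wells <- do.call(rbind, lapply(wells, function(w)
      data.frame(id = w$id, x = w$x, y = w$y, V0 = w$V0, sigma = w$sigma)))
  }
  wells <- as.data.frame(wells)
  stopifnot(all(c("x", "y") %in% names(wells)))
  if (!"id" %in% names(wells)) wells$id <- seq_len(nrow(wells))
  if (!"V0" %in% names(wells)) wells$V0 <- V0
  if (!"sigma" %in% names(wells)) wells$sigma <- sigma
  wells <- wells[c("id", "x", "y", "V0", "sigma")]
  if (any(wells$x < 0 | wells$x > arena$width |
          wells$y < 0 | wells$y > arena$height)) {
    stop("well centre(s) outside the arena")
  }
  stopifnot(all(wells$V0 >= 0), all(wells$sigma > 0))
  structure(list(arena = arena, wells = wells), class = "bp_landscape")
}

#' @export
print.bp_landscape <- function(x, ...) {
  cat(sprintf("<landscape: %d well(s) in %g x %g m arena; V0 in [%g, %g], sigma in [%g, %g]>\n",
              nrow(x$wells), x$arena$width, x$arena$height,
              min(x$wells$V0), max(x$wells$V0),
              min(x$wells$sigma), max(x$wells$sigma)))
  invisible(x)
}

#' Read a landscape from a CSV of wells
#'
#' Expected columns: `id`, `x`, `y` and optionally `V0`, `sigma`.
#'
#' @param path CSV file.
#' @param arena Arena the wells live in.
#' @inheritParams landscape
#' @export
read_landscape <- function(path, arena = beepath::arena(), V0 = 34, sigma = 4) {
  landscape(utils::read.csv(path), arena, V0 = V0, sigma = sigma)
}

#' Write a landscape's wells to CSV
#'
#' @param land A `bp_landscape`.
#' @param path Output file.
#' @export
write_landscape <- function(land, path) {
  utils::write.csv(land$wells, path, row.names = FALSE)
  invisible(path)
}

#' Fresh attention state
#'
#' Attention bookkeeping for one walker: the set of permanently deactivated
#' (visited) wells and the identity of the well currently trapping the walker,
#' if any.
#'
#' @return A `bp_attention` list with `visited` (integer ids) and `trapped_in`
#'   (id or `NA`).
#' @export
new_attention <- function() {
  structure(list(visited = integer(0), trapped_in = NA_integer_),
            class = "bp_attention")
}

#' Total reactive force from a landscape
#'
#' Sums [well_force()] over wells not yet visited. While the walker is trapped
#' only the trapping well contributes (all other potentials deactivate while
#' attention is focused on that stand).
#'
#' @param r Numeric `c(x, y)`.
#' @param land A `bp_landscape`.
#' @param attention A `bp_attention`.
#' @return Numeric `c(Fx, Fy)`.
#' @export
landscape_force <- function(r, land, attention = new_attention()) {
  w <- land$wells
  if (!is.na(attention$trapped_in)) {
    i <- match(attention$trapped_in, w$id)
    return(well_force(r, list(x = w$x[i], y = w$y[i], V0 = w$V0[i],
                              sigma = w$sigma[i])))
  }
  act <- !(w$id %in% attention$visited)
  F <- c(0, 0)
  for (i in which(act)) {
    F <- F + well_force(r, list(x = w$x[i], y = w$y[i], V0 = w$V0[i],
                                sigma = w$sigma[i]))
  }
  F
}

#' Update trapping/memory state after a move
#'
#' Entering the core (`d < sigma`) of an unvisited well while free traps the
#' walker there (nearest centre wins on simultaneous entry; ties break to the
#' lowest well id). Leaving the core (`d > sigma`) of the trapping well frees
#' the walker and permanently deactivates that well: visited wells never
#' re-trap and exert no force.
#'
#' @param attention A `bp_attention`.
#' @param r Numeric `c(x, y)` current position.
#' @param land A `bp_landscape`.
#' @return The updated `bp_attention`.
#' @export
update_attention <- function(attention, r, land) {
  w <- land$wells
  d <- sqrt((w$x - r[1])^2 + (w$y - r[2])^2)
  if (!is.na(attention$trapped_in)) {
    i <- match(attention$trapped_in, w$id)
    if (d[i] > w$sigma[i]) {
      attention$visited <- sort(unique(c(attention$visited, w$id[i])))
      attention$trapped_in <- NA_integer_
    }
    return(attention)
  }
  inside <- which(d < w$sigma & !(w$id %in% attention$visited))
  if (length(inside)) {
    # nearest centre wins; ties to lowest id (order() breaks ties by position,
    # wells are stored id-sorted on construction order)
    pick <- inside[order(d[inside], w$id[inside])][1L]
    attention$trapped_in <- w$id[pick]
  }
  attention
}
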