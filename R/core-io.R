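#' Rectangular study arena
#'
#' The bounded planar domain in which walkers move and over which the
#' utilization raster is laid out. The origin (0, 0) is the south-west corner;
#' x points east and y points north, both in metres. The default dimensions
#' are those of a 4-ha park promenade (330 x 145 m).
#'
#' @param width Arena extent along x (m).
#' @param height Arena extent along y (m).
#' @return An object of class `bp_arena` with fields `width` and `height`.
#' @export
#' @examples
#' a <- arena()
#' a$width
arena <- function(width = 330, height = 145) {
  stopifnot(is.numeric(width), is.numeric(height), width > 0, height > 0)
  structure(list(width = as.numeric(width), height = as.numeric(height)),
            class = "bp_arena")
}

#' @export
print.bp_arena <- function(x, ...) {
  cat(sprintf("<arena %g x %g m, origin at SW corner>\n", x$width, x$height))
  invisible(x)
}

# internal: validate a single track data frame (t strictly increasing, coords
# finite, accuracy non-negative), naming the walker and offending index.
validate_track <- function(df, walker_id) {
  if (nrow(df) < 1L) stop("track '", walker_id, "' has no fixes")
  dt <- diff(df$t)
  if (length(dt) && any(dt <= 0)) {
    i <- which(dt <= 0)[1L] + 1L
    stop("non-monotone timestamps for walker '", walker_id,
         "' at fix index ", i, call. = FALSE)
  }
  coord_cols <- intersect(c("x", "y", "lon", "lat"), names(df))
  for (cc in coord_cols) {
    if (any(!is.finite(df[[cc]]))) {
      stop("non-finite coordinate '", cc, "' for walker '", walker_id, "'")
    }
  }
  if ("accuracy" %in% names(df) && any(df$accuracy < 0, na.rm = TRUE)) {
    stop("negative accuracy for walker '", walker_id, "'")
  }
  invisible(df)
}

new_track <- function(df, walker_id, crs = c("planar", "geographic")) {
  crs <- match.arg(crs)
  validate_track(df, walker_id)
  structure(df, walker_id = as.character(walker_id), crs = crs,
            class = c("bp_track", "data.frame"))
}

new_tracks <- function(lst) {
  names(lst) <- vapply(lst, function(tr) attr(tr, "walker_id"), character(1))
  structure(lst, class = "bp_tracks")
}

#' @export
print.bp_tracks <- function(x, ...) {
  n <- vapply(x, nrow, integer(1))
  cat(sprintf("<%d track(s), %d fixes total, coordinates: %s>\n",
              length(x), sum(n),
              if (length(x)) attr(x[[1]], "crs") else "?"))
  invisible(x)
}

#' Build a track collection from a data frame of fixes
#'
#' @param df Data frame with a `walker_id` column, a numeric `t` column
#'   (seconds), coordinate columns (`x`/`y` planar metres or `lon`/`lat`
#'   degrees) and optionally `accuracy` (m).
#' @param crs Either `"planar"` (x/y in metres) or `"geographic"` (lon/lat).
#' @return A `bp_tracks` list of per-walker `bp_track` data frames. Time is
#'   re-expressed in seconds relative to each track's first fix.
#' @export
as_tracks <- function(df, crs = c("planar", "geographic")) {
  crs <- match.arg(crs)
  need <- c("walker_id", "t", if (crs == "planar") c("x", "y") else c("lon", "lat"))
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  ids <- unique(as.character(df$walker_id))
  out <- lapply(ids, function(id) {
    sub <- df[as.character(df$walker_id) == id, setdiff(names(df), "walker_id"),
              drop = FALSE]
    rownames(sub) <- NULL
    sub$t <- as.numeric(sub$t)
    validate_track(sub, id)      # order must already be monotone: error if not
    sub$t <- sub$t - sub$t[1L]   # durations are what matter downstream
    new_track(sub, id, crs)
  })
  new_tracks(out)
}

#' Read GPS tracks from CSV or GPX
#'
#' CSV files must have columns `walker_id`, a time column (`t` in epoch/relative
#' seconds, or `timestamp` in ISO-8601), and either `lon`/`lat` (degrees) or
#' `x`/`y` (planar metres); `accuracy` (m) is optional. GPX 1.1 files are read
#' with one walker per `<trk>` (named by the `<name>` element when present).
#'
#' @param path File path.
#' @param format `"csv"` or `"gpx"`.
#' @return A `bp_tracks` collection; geographic coordinates are retained until
#'   [project_to_plane()] is applied.
#' @export
read_tracks <- function(path, format = c("csv", "gpx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "csv") {
    df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                   error = function(e) stop("cannot parse CSV '", path, "': ",
                                            conditionMessage(e), call. = FALSE))
    if (!"t" %in% names(df)) {
      if (!"timestamp" %in% names(df)) stop("CSV needs a 't' or 'timestamp' column")
      tt <- as.POSIXct(df$timestamp, tz = "UTC",
                       tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
      if (any(is.na(tt))) stop("unparseable timestamp(s) in '", path, "'")
      df$t <- as.numeric(tt)
    }
    crs <- if (all(c("x", "y") %in% names(df))) "planar" else "geographic"
    as_tracks(df, crs)
  } else {
    doc <- tryCatch(xml2::read_xml(path),
                    error = function(e) stop("cannot parse GPX '", path, "': ",
                                             conditionMessage(e), call. = FALSE))
    xml2::xml_ns_strip(doc)
    trks <- xml2::xml_find_all(doc, ".//trk")
    if (!length(trks)) stop("GPX file '", path, "' contains no <trk>")
    rows <- lapply(seq_along(trks), function(i) {
      nm <- xml2::xml_text(xml2::xml_find_first(trks[[i]], "./name"))
      if (is.na(nm) || !nzchar(nm)) nm <- paste0("trk", i)
      pts <- xml2::xml_find_all(trks[[i]], ".//trkpt")
      if (!length(pts)) return(NULL)
      tim <- xml2::xml_text(xml2::xml_find_first(pts, "./time"))
      tt <- as.numeric(as.POSIXct(tim, tz = "UTC",
                                  tryFormats = c("%Y-%m-%dT%H:%M:%OS")))
      if (any(is.na(tt))) tt <- seq_along(pts) - 1  # untimed points: unit spacing
      data.frame(walker_id = nm,
                 t = tt,
                 lon = as.numeric(xml2::xml_attr(pts, "lon")),
                 lat = as.numeric(xml2::xml_attr(pts, "lat")),
                 stringsAsFactors = FALSE)
    })
    as_tracks(do.call(rbind, rows), "geographic")
  }
}

# mean Earth radius used by the haversine convention (m)
EARTH_RADIUS <- 6378137

#' Project geographic tracks onto a local tangent plane
#'
#' Equirectangular projection about a reference origin: x = R cos(lat0) dlon,
#' y = R dlat (radians). At park scale (~1 km) the distortion is sub-centimetre,
#' which is far below GPS accuracy.
#'
#' @param tracks A `bp_tracks` collection in geographic coordinates.
#' @param origin Numeric `c(lon, lat)` of the plane's (0, 0).
#' @return The collection with planar `x`/`y` columns (m, x east / y north);
#'   projection metadata is stored in attributes `projection` and `origin`.
#' @export
project_to_plane <- function(tracks, origin) {
  stopifnot(inherits(tracks, "bp_tracks"), length(origin) == 2)
  if (abs(origin[2]) > 90 || abs(origin[1]) > 180) {
    stop("projection origin outside valid lon/lat range")
  }
  k <- pi / 180
  coslat0 <- cos(origin[2] * k)
  out <- lapply(tracks, function(tr) {
    if (attr(tr, "crs") != "geographic") stop("tracks are already planar")
    if (any(abs(tr$lat) > 90) || any(abs(tr$lon) > 180)) {
      stop("lon/lat outside valid range for walker '", attr(tr, "walker_id"), "'")
    }
    df <- as.data.frame(tr)
    df$x <- EARTH_RADIUS * coslat0 * (df$lon - origin[1]) * k
    df$y <- EARTH_RADIUS * (df$lat - origin[2]) * k
    df$lon <- NULL; df$lat <- NULL
    tr2 <- new_track(df, attr(tr, "walker_id"), "planar")
    attr(tr2, "projection") <- "equirectangular"
    attr(tr2, "origin") <- origin
    tr2
  })
  res <- new_tracks(out)
  attr(res, "projection") <- "equirectangular"
  attr(res, "origin") <- origin
  res
}

#' Inverse of [project_to_plane()]
#'
#' @param tracks Planar `bp_tracks` carrying projection metadata (or supply
#'   `origin` explicitly).
#' @param origin Numeric `c(lon, lat)`; defaults to the stored metadata.
#' @return The collection in geographic coordinates.
#' @export
project_to_lonlat <- function(tracks, origin = attr(tracks, "origin")) {
  stopifnot(inherits(tracks, "bp_tracks"), length(origin) == 2)
  k <- pi / 180
  coslat0 <- cos(origin[2] * k)
  out <- lapply(tracks, function(tr) {
    df <- as.data.frame(tr)
    df$lon <- origin[1] + df$x / (EARTH_RADIUS * coslat0 * k)
    df$lat <- origin[2] + df$y / (EARTH_RADIUS * k)
    df$x <- NULL; df$y <- NULL
    new_track(df, attr(tr, "walker_id"), "geographic")
  })
  new_tracks(out)
}

#' Write planar tracks to CSV
#'
#' @param tracks A `bp_tracks` collection.
#' @param path Output file.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(inherits(tracks, "bp_tracks"))
  rows <- lapply(tracks, function(tr) {
    df <- as.data.frame(tr)
    cbind(walker_id = attr(tr, "walker_id"), df)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

# flatten a segmented-track collection into one data frame of elements
segmented_as_df <- function(segs) {
  if (inherits(segs, "bp_segmented")) segs <- list(segs)
  rows <- lapply(segs, function(s) {
    el <- s$elements
    if (!nrow(el)) return(NULL)
    cbind(walker_id = s$walker_id, el)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) {
    out <- data.frame(walker_id = character(), type = character(),
                      t_start = numeric(), t_end = numeric(),
                      duration = numeric(), x = numeric(), y = numeric(),
                      x_end = numeric(), y_end = numeric(), length = numeric(),
                      velocity = numeric(), heading = numeric(),
                      n_fixes = integer())
  }
  rownames(out) <- NULL
  out
}

#' Serialize segmented tracks to CSV or GeoJSON
#'
#' CSV writes one row per element (stop or flight) with all fields at full
#' precision. GeoJSON (RFC 7946) writes stops as Point features and flights as
#' LineString features in the planar coordinate space.
#'
#' @param segs A `bp_segmented` object or list of them (see [segment_track()]).
#' @param path Output file.
#' @param format `"csv"` or `"geojson"`.
#' @export
write_segmented <- function(segs, path, format = c("csv", "geojson")) {
  format <- match.arg(format)
  df <- segmented_as_df(segs)
  if (format == "csv") {
    # format() keeps full double precision so durations round-trip exactly
    num <- vapply(df, is.numeric, logical(1))
    out <- df
    out[num] <- lapply(df[num], function(v) formatC(v, digits = 17, format = "g"))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    feats <- lapply(seq_len(nrow(df)), function(i) {
      r <- df[i, ]
      if (r$type == "stop") {
        geom <- list(type = "Point", coordinates = c(r$x, r$y))
      } else {
        geom <- list(type = "LineString",
                     coordinates = list(c(r$x, r$y), c(r$x_end, r$y_end)))
      }
      props <- as.list(r[setdiff(names(r), c("x", "y", "x_end", "y_end"))])
      list(type = "Feature", geometry = geom, properties = props)
    })
    fc <- list(type = "FeatureCollection", features = feats)
    writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA, null = "null"),
               path)
  }
  invisible(path)
}

#' Read a segmented-track CSV written by [write_segmented()]
#'
#' @param path CSV file.
#' @return Data frame with one row per stop/flight element.
#' @export
read_segmented <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
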