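#' Write GPS fixes as GPX 1.1
#'
#' @param fixes Data frame with `timestamp` (POSIXct UTC), `lat`, `lon`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gpx <- function(fixes, path) {
  doc <- xml2::xml_new_root("gpx", version = "1.1", creator = "modeshift",
                            xmlns = "http://www.topografix.com/GPX/1/1")
  trk <- xml2::xml_add_child(doc, "trk")
  seg <- xml2::xml_add_child(trk, "trkseg")
  for (i in seq_len(nrow(fixes))) {
    pt <- xml2::xml_add_child(seg, "trkpt",
                              lat = sprintf("%.7f", fixes$lat[i]),
                              lon = sprintf("%.7f", fixes$lon[i]))
    xml2::xml_add_child(pt, "time",
                        format(fixes$timestamp[i], "%Y-%m-%dT%H:%M:%SZ",
                               tz = "UTC"))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# GeoJSON helpers: geometries leave the package in lon/lat (WGS84); the
# planar metre CRS is internal
.feature <- function(geometry, properties)
  list(type = "Feature", geometry = geometry, properties = properties)

.rect_poly <- function(xmin, ymin, xmax, ymax) {
  c1 <- unproject_xy(c(xmin, xmax, xmax, xmin, xmin),
                     c(ymin, ymin, ymax, ymax, ymin))
  list(type = "Polygon", coordinates = list(lapply(seq_len(5), function(i)
    c(c1[i, "lon"], c1[i, "lat"]))))
}

.point_geom <- function(x, y) {
  ll <- unproject_xy(x, y)
  list(type = "Point", coordinates = c(ll[1, "lon"], ll[1, "lat"]))
}

#' Write city layers as GeoJSON (one file per layer)
#'
#' @param city A `ms_city`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_city_geojson <- function(city, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wj <- function(x, f) jsonlite::write_json(
    x, file.path(dir, f), auto_unbox = TRUE, digits = 10)
  streets <- lapply(seq_len(nrow(city$edges)), function(i) {
    e <- city$edges[i, ]
    ll <- unproject_xy(c(e$x1, e$x2), c(e$y1, e$y2))
    .feature(list(type = "LineString",
                  coordinates = list(c(ll[1, "lon"], ll[1, "lat"]),
                                     c(ll[2, "lon"], ll[2, "lat"]))),
             list(edge = e$edge, from = e$from, to = e$to,
                  length_m = e$length))
  })
  wj(list(type = "FeatureCollection", features = streets),
     "streets.geojson")
  parcels <- lapply(seq_len(nrow(city$parcels)), function(i) {
    p <- city$parcels[i, ]
    .feature(.rect_poly(p$xmin, p$ymin, p$xmax, p$ymax),
             list(parcel = p$parcel, class = p$class,
                  floor_area = p$floor_area, res_units = p$res_units,
                  in_ev_district = p$in_ev_district))
  })
  wj(list(type = "FeatureCollection", features = parcels),
     "parcels.geojson")
  parks <- lapply(seq_len(nrow(city$parks)), function(i) {
    p <- city$parks[i, ]
    .feature(.rect_poly(p$xmin, p$ymin, p$xmax, p$ymax),
             list(park = p$park, class = p$class))
  })
  wj(list(type = "FeatureCollection", features = parks), "parks.geojson")
  pts <- function(df, props) lapply(seq_len(nrow(df)), function(i)
    .feature(.point_geom(df$x[i], df$y[i]),
             as.list(df[i, props, drop = FALSE])))
  wj(list(type = "FeatureCollection",
          features = pts(city$park_entrances, c("park", "node"))),
     "park_entrances.geojson")
  wj(list(type = "FeatureCollection",
          features = pts(city$underground_stations, c("station", "node"))),
     "underground_stations.geojson")
  wj(list(type = "FeatureCollection",
          features = pts(city$overground_stations, c("station", "node"))),
     "overground_stations.geojson")
  wj(list(type = "FeatureCollection",
          features = pts(city$ptal_points, c("point", "score"))),
     "ptal.geojson")
  meta <- list(extent_m = city$extent_m, block_m = city$block_m,
               ev_district = as.list(city$ev_district))
  wj(meta, "city_meta.json")
  invisible(dir)
}

#' Read underground-station points from a GeoJSON file
#'
#' @param path GeoJSON point layer written by [write_city_geojson()] (or
#'   any point FeatureCollection with lon/lat coordinates).
#' @return Data frame `station`, `x`, `y` (projected metres).
#' @export
read_stations_geojson <- function(path) {
  j <- jsonlite::read_json(path)
  rows <- lapply(seq_along(j$features), function(i) {
    f <- j$features[[i]]
    cc <- unlist(f$geometry$coordinates)
    xy <- project_lonlat(cc[1], cc[2])
    data.frame(station = i, x = xy[1, "x"], y = xy[1, "y"])
  })
  do.call(rbind, rows)
}

#' Read a JSON run configuration
#'
#' Nested key/value configuration; recognised keys mirror the arguments of
#' [sim_config()].
#'
#' @param path JSON file.
#' @return A `ms_config`.
#' @export
read_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(j$true_effects) && !is.null(dim(j$true_effects)))
    rownames(j$true_effects) <- MS_HOUSING
  do.call(sim_config, j)
}

#' Write a delimited table
#'
#' Plain-text comma-separated writer used for all tabular outputs
#' (epochs, labels, gaps, day profiles, summaries, estimates).
#'
#' @param x Data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_delim_table <- function(x, path) {
  x <- as.data.frame(x)
  x$path <- NULL  # list columns are not serialisable
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
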