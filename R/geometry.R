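# planar geometry helpers; all coordinates are metres in one local projected
# CRS (lat/lon appears only at the GPX boundary)

# reference origin for the equirectangular local projection (London-like)
.MS_LAT0 <- 51.54
.MS_LON0 <- -0.01
.MS_M_PER_DEG_LAT <- 111320
.MS_M_PER_DEG_LON <- 111320 * cos(.MS_LAT0 * pi / 180)

#' Project lon/lat to local planar metres (and back)
#'
#' Small-area equirectangular projection about a fixed local origin; adequate
#' at city scale (<10 km) where distortion is far below GPS noise.
#'
#' @param lon,lat,x,y Coordinate vectors.
#' @return Two-column matrix (`x`,`y` in metres, or `lon`,`lat`).
#' @export
project_lonlat <- function(lon, lat) {
  cbind(x = (lon - .MS_LON0) * .MS_M_PER_DEG_LON,
        y = (lat - .MS_LAT0) * .MS_M_PER_DEG_LAT)
}

#' @rdname project_lonlat
#' @export
unproject_xy <- function(x, y) {
  cbind(lon = x / .MS_M_PER_DEG_LON + .MS_LON0,
        lat = y / .MS_M_PER_DEG_LAT + .MS_LAT0)
}

# distance from points (px,py) to segment (x1,y1)-(x2,y2); vectorised over
# points
dist_point_seg <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  l2 <- dx * dx + dy * dy
  # when l2 == 0 the segment is a point and t is irrelevant (dx = dy = 0)
  t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / pmax(l2, 1e-12)))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

# min distance between two segments
dist_seg_seg <- function(ax1, ay1, ax2, ay2, bx1, by1, bx2, by2) {
  if (.segs_intersect(ax1, ay1, ax2, ay2, bx1, by1, bx2, by2)) return(0)
  min(dist_point_seg(ax1, ay1, bx1, by1, bx2, by2),
      dist_point_seg(ax2, ay2, bx1, by1, bx2, by2),
      dist_point_seg(bx1, by1, ax1, ay1, ax2, ay2),
      dist_point_seg(bx2, by2, ax1, ay1, ax2, ay2))
}

.segs_intersect <- function(ax1, ay1, ax2, ay2, bx1, by1, bx2, by2) {
  d <- function(x1, y1, x2, y2, x3, y3)
    sign((x2 - x1) * (y3 - y1) - (y2 - y1) * (x3 - x1))
  d1 <- d(bx1, by1, bx2, by2, ax1, ay1)
  d2 <- d(bx1, by1, bx2, by2, ax2, ay2)
  d3 <- d(ax1, ay1, ax2, ay2, bx1, by1)
  d4 <- d(ax1, ay1, ax2, ay2, bx2, by2)
  (d1 != d2 && d3 != d4) ||
    (d1 == 0 && d2 == 0 && max(min(ax1, ax2), min(bx1, bx2)) <=
       min(max(ax1, ax2), max(bx1, bx2)) &&
       max(min(ay1, ay2), min(by1, by2)) <= min(max(ay1, ay2), max(by1, by2)))
}

# min distance from segment to axis-aligned rectangle (0 if touching/inside)
dist_seg_rect <- function(x1, y1, x2, y2, rxmin, rymin, rxmax, rymax) {
  inside <- function(x, y) x >= rxmin && x <= rxmax && y >= rymin && y <= rymax
  if (inside(x1, y1) || inside(x2, y2)) return(0)
  edges <- rbind(c(rxmin, rymin, rxmax, rymin), c(rxmax, rymin, rxmax, rymax),
                 c(rxmax, rymax, rxmin, rymax), c(rxmin, rymax, rxmin, rymin))
  min(apply(edges, 1, function(e)
    dist_seg_seg(x1, y1, x2, y2, e[1], e[2], e[3], e[4])))
}

# nearest point on a polyline (matrix of xy rows) plus offset bookkeeping
.nearest_on_edges <- function(px, py, edges) {
  d <- dist_point_seg(rep(px, nrow(edges)), rep(py, nrow(edges)),
                      edges$x1, edges$y1, edges$x2, edges$y2)
  i <- which.min(d)
  e <- edges[i, ]
  dx <- e$x2 - e$x1; dy <- e$y2 - e$y1
  l2 <- dx * dx + dy * dy
  t <- if (l2 == 0) 0 else
    min(1, max(0, ((px - e$x1) * dx + (py - e$y1) * dy) / l2))
  list(edge = i, dist = d[i], t = t, len = sqrt(l2),
       x = e$x1 + t * dx, y = e$y1 + t * dy)
}
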