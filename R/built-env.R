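#' 1-km street-network buffer around an address
#'
#' Snaps the address to the nearest street edge (error beyond `snap_tol_m`),
#' runs shortest paths over the street network from the snap point, and
#' returns the reachable edge portions with partial edges cut at exactly the
#' radius.  The "buffer polygon" used for parcel inclusion is the set of
#' reachable segments dilated by `width_m`.
#'
#' @param address Numeric `c(x, y)` in metres.
#' @param city A `ms_city` (or any list with `nodes` and `edges` in the same
#'   shape).
#' @param radius_m Network radius (default 1000 m).
#' @param snap_tol_m Maximum address-to-network snap distance.
#' @param width_m Dilation width for parcel inclusion (default 25 m).
#' @return Object of class `ms_netbuffer`: snap point, per-node network
#'   distances, reachable sub-segments, total reachable length (m).
#' @export
network_buffer <- function(address, city, radius_m = 1000,
                           snap_tol_m = 100, width_m = 25) {
  stopifnot(length(address) == 2, radius_m >= 0)
  snap <- .nearest_on_edges(address[1], address[2], city$edges)
  if (snap$dist > snap_tol_m)
    stop(sprintf(
      "address does not snap to the street network: nearest edge is %.1f m away (tolerance %.0f m)",
      snap$dist, snap_tol_m), call. = FALSE)
  g <- city_graph(city)
  e <- city$edges[snap$edge, ]
  off_u <- snap$t * snap$len
  off_v <- (1 - snap$t) * snap$len
  dm <- igraph::distances(g, v = as.character(c(e$from, e$to)))
  nd <- pmin(off_u + dm[1, ], off_v + dm[2, ])
  names(nd) <- colnames(dm)
  node_dist <- nd[as.character(city$nodes$node)]

  segs <- NULL
  total <- 0
  ee <- city$edges
  a_all <- pmax(0, radius_m - node_dist[as.character(ee$from)])
  b_all <- pmax(0, radius_m - node_dist[as.character(ee$to)])
  touch <- which(a_all > 0 | b_all > 0 | seq_len(nrow(ee)) == snap$edge)
  for (i in touch) {
    ed <- ee[i, ]
    len <- ed$length
    ivals <- list()
    a <- max(0, radius_m - node_dist[[as.character(ed$from)]])
    bb <- max(0, radius_m - node_dist[[as.character(ed$to)]])
    if (a > 0) ivals <- c(ivals, list(c(0, min(a, len))))
    if (bb > 0) ivals <- c(ivals, list(c(max(0, len - bb), len)))
    if (i == snap$edge && radius_m > 0)
      ivals <- c(ivals, list(c(max(0, off_u - radius_m),
                               min(len, off_u + radius_m))))
    if (!length(ivals)) next
    m <- do.call(rbind, ivals)
    m <- m[order(m[, 1]), , drop = FALSE]
    merged <- m[1, , drop = FALSE]
    for (r in seq_len(nrow(m))[-1]) {
      if (m[r, 1] <= merged[nrow(merged), 2])
        merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], m[r, 2])
      else merged <- rbind(merged, m[r, ])
    }
    ux <- (ed$x2 - ed$x1) / len; uy <- (ed$y2 - ed$y1) / len
    for (r in seq_len(nrow(merged))) {
      s0 <- merged[r, 1]; s1 <- merged[r, 2]
      if (s1 <= s0) next
      segs <- rbind(segs, data.frame(
        edge = ed$edge, x1 = ed$x1 + ux * s0, y1 = ed$y1 + uy * s0,
        x2 = ed$x1 + ux * s1, y2 = ed$y1 + uy * s1, length = s1 - s0))
      total <- total + (s1 - s0)
    }
  }
  structure(list(address = address, snap = snap, node_dist = node_dist,
                 segments = segs, reachable_len = total,
                 radius_m = radius_m, width_m = width_m),
            class = "ms_netbuffer")
}

# parcels whose rectangle lies within width_m of any reachable segment
.parcels_in_buffer <- function(buffer, parcels) {
  if (is.null(buffer$segments) || !nrow(parcels))
    return(parcels[0, ])
  ax <- buffer$address[1]; ay <- buffer$address[2]
  rmax <- buffer$radius_m + buffer$width_m + buffer$snap$dist
  cx <- pmin(pmax(ax, parcels$xmin), parcels$xmax)
  cy <- pmin(pmax(ay, parcels$ymin), parcels$ymax)
  cand <- which(sqrt((cx - ax)^2 + (cy - ay)^2) <= rmax)
  keep <- logical(length(cand))
  sg <- buffer$segments
  w <- buffer$width_m
  for (k in seq_along(cand)) {
    p <- parcels[cand[k], ]
    # fast accept: either segment endpoint within width of the rectangle
    pr <- function(x, y) sqrt(pmax(pmax(p$xmin - x, x - p$xmax), 0)^2 +
                                pmax(pmax(p$ymin - y, y - p$ymax), 0)^2)
    in_dil <- pr(sg$x1, sg$y1) <= w | pr(sg$x2, sg$y2) <= w
    if (any(in_dil)) {
      keep[k] <- TRUE
      next
    }
    # fast reject: segment bounding box farther than width from rect
    bb_far <- pmax(p$xmin - pmax(sg$x1, sg$x2), 0) > w |
      pmax(pmin(sg$x1, sg$x2) - p$xmax, 0) > w |
      pmax(p$ymin - pmax(sg$y1, sg$y2), 0) > w |
      pmax(pmin(sg$y1, sg$y2) - p$ymax, 0) > w
    hit <- which(!bb_far)
    for (s in hit) {
      if (dist_seg_rect(sg$x1[s], sg$y1[s], sg$x2[s], sg$y2[s],
                        p$xmin, p$ymin, p$xmax, p$ymax) <= w) {
        keep[k] <- TRUE
        break
      }
    }
  }
  parcels[cand[keep], ]
}

#' Land-use mix entropy within a network buffer
#'
#' Shannon entropy of the five land-use classes' floor-area shares among
#' parcels intersecting the buffer, normalised by `ln 5` so 0 means single
#' use and 1 a perfectly even split of square footage.
#'
#' @param buffer From [network_buffer()].
#' @param parcels City parcel table.
#' @return Value in `[0, 1]`, or `NA` (flagged missing) when no floor area
#'   falls inside the buffer.
#' @export
land_use_mix <- function(buffer, parcels) {
  inb <- .parcels_in_buffer(buffer, parcels)
  tot <- sum(inb$floor_area)
  if (!nrow(inb) || tot <= 0) return(NA_real_)
  classes <- c("residential", "commercial", "office", "entertainment",
               "institutional")
  p <- vapply(classes, function(k)
    sum(inb$floor_area[inb$class == k]) / tot, numeric(1))
  p <- p[p > 0]
  -sum(p * log(p)) / log(5)
}

#' Residential density within a network buffer
#'
#' Residential units per km^2 of land devoted to residential use (parcel
#' footprint including attached gardens), expressed in 1000 RU/km^2.
#'
#' @inheritParams land_use_mix
#' @return Density in 1000 RU/km^2, or `NA` when the buffer contains no
#'   residential land.
#' @export
residential_density <- function(buffer, parcels) {
  inb <- .parcels_in_buffer(buffer, parcels)
  res <- inb[inb$class == "residential", ]
  if (!nrow(res)) return(NA_real_)
  area_km2 <- sum((res$xmax - res$xmin) * (res$ymax - res$ymin)) / 1e6
  if (area_km2 <= 0) return(NA_real_)
  sum(res$res_units) / area_km2 / 1000
}

#' Street connectivity within a network buffer
#'
#' Number of true intersections (street nodes of degree >= 3) whose network
#' distance from the address is within the radius, divided by the kilometres
#' of road reachable in the buffer.  Cul-de-sac ends (degree 1) and mid-block
#' nodes (degree 2) are not intersections.
#'
#' @param buffer From [network_buffer()].
#' @param city The city the buffer was computed on.
#' @return Intersections per km of road, or `NA` with zero road length.
#' @export
street_connectivity <- function(buffer, city) {
  if (buffer$reachable_len <= 0) return(NA_real_)
  g <- city_graph(city)
  deg <- igraph::degree(g)
  names(deg) <- igraph::V(g)$name
  nd <- buffer$node_dist
  inside <- names(nd)[nd <= buffer$radius_m]
  n_int <- sum(deg[inside] >= 3, na.rm = TRUE)
  n_int / (buffer$reachable_len / 1000)
}

#' Walkability z-sum
#'
#' Adds a `walkability` column: the sum of the z-scores of land-use mix,
#' residential density and street connectivity.  Components are standardised
#' against the baseline-wave cohort distribution, and the baseline mean/sd
#' are frozen and reused for follow-up rows so change scores are on one
#' scale.
#'
#' @param exposures Data frame with columns `wave`, `land_use_mix`,
#'   `residential_density`, `street_connectivity` (one row per
#'   address-wave).
#' @return `exposures` with `walkability` appended; baseline reference
#'   means/sds in `attr(, "reference")`.
#' @export
walkability <- function(exposures) {
  comps <- c("land_use_mix", "residential_density", "street_connectivity")
  base <- exposures[exposures$wave == "baseline", comps, drop = FALSE]
  if (nrow(base) < 2)
    stop("need >= 2 baseline addresses with all components", call. = FALSE)
  mu <- colMeans(base, na.rm = TRUE)
  sdv <- vapply(base, stats::sd, numeric(1), na.rm = TRUE)
  if (any(sdv == 0 | is.na(sdv)))
    stop("zero baseline sd in walkability component(s): ",
         paste(comps[sdv == 0 | is.na(sdv)], collapse = ", "), call. = FALSE)
  z <- sweep(sweep(as.matrix(exposures[comps]), 2, mu), 2, sdv, "/")
  exposures$walkability <- rowSums(z)
  attr(exposures, "reference") <- list(mean = mu, sd = sdv)
  exposures
}

#' Network distance to the nearest park entrance
#'
#' Shortest street-network distance from the address (including the
#' perpendicular leg to its snap point) to the nearest entrance of the
#' closest park, over all park classes.
#'
#' @param address Numeric `c(x, y)`.
#' @param city A `ms_city` with a nonempty `park_entrances` layer.
#' @param snap_tol_m Snap tolerance, as in [network_buffer()].
#' @return Metres, or `NA` when no entrance is reachable.
#' @export
park_distance <- function(address, city, snap_tol_m = 100) {
  if (!nrow(city$park_entrances)) stop("city has no park entrances",
                                       call. = FALSE)
  snap <- .nearest_on_edges(address[1], address[2], city$edges)
  if (snap$dist > snap_tol_m)
    stop(sprintf("address %.1f m from network (tolerance %.0f m)",
                 snap$dist, snap_tol_m), call. = FALSE)
  g <- city_graph(city)
  e <- city$edges[snap$edge, ]
  dm <- igraph::distances(g, v = as.character(c(e$from, e$to)),
                          to = as.character(city$park_entrances$node))
  d <- pmin(snap$t * snap$len + dm[1, ], (1 - snap$t) * snap$len + dm[2, ])
  best <- suppressWarnings(min(d))
  if (!is.finite(best)) return(NA_real_)
  snap$dist + best
}

#' Assign the nearest PTAL score
#'
#' Score of the Euclidean-nearest public-transport-accessibility sample
#' point; exact ties resolved to the lowest point id.
#'
#' @param address Numeric `c(x, y)`.
#' @param ptal_points Data frame `point`, `x`, `y`, `score`.
#' @return The assigned score, or `NA` for an empty layer.
#' @export
assign_ptal <- function(address, ptal_points) {
  if (!nrow(ptal_points)) return(NA_real_)
  d <- sqrt((ptal_points$x - address[1])^2 + (ptal_points$y - address[2])^2)
  ord <- order(d, ptal_points$point)
  ptal_points$score[ord[1]]
}

#' Built-environment exposures for a set of address-waves
#'
#' Computes every exposure component plus the walkability z-sum (baseline
#' reference) for a table of home addresses.
#'
#' @param addresses Data frame `id`, `wave`, `x`, `y`.
#' @param city A `ms_city`.
#' @param radius_m,snap_tol_m,width_m Passed to [network_buffer()].
#' @return Data frame, one row per address-wave, with `land_use_mix`,
#'   `residential_density`, `street_connectivity`, `walkability`,
#'   `park_distance_m`, `ptal`.
#' @export
built_env_exposures <- function(addresses, city, radius_m = 1000,
                                snap_tol_m = 100, width_m = 25) {
  out <- addresses
  n <- nrow(addresses)
  out$land_use_mix <- out$residential_density <-
    out$street_connectivity <- out$park_distance_m <- out$ptal <- NA_real_
  for (i in seq_len(n)) {
    a <- c(addresses$x[i], addresses$y[i])
    buf <- network_buffer(a, city, radius_m, snap_tol_m, width_m)
    out$land_use_mix[i] <- land_use_mix(buf, city$parcels)
    out$residential_density[i] <- residential_density(buf, city$parcels)
    out$street_connectivity[i] <- street_connectivity(buf, city)
    out$park_distance_m[i] <- if (nrow(city$park_entrances))
      park_distance(a, city, snap_tol_m) else NA_real_
    out$ptal[i] <- assign_ptal(a, city$ptal_points)
  }
  walkability(out)
}
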