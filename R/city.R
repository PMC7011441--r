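#' Generate a synthetic vector city
#'
#' Builds a seeded grid city on a single local projected CRS (metres): a
#' connected street network, one land-use parcel per block (five classes with
#' floor area and residential-unit counts), parks (Metropolitan / District /
#' Local) whose entrances are street-network nodes, underground and overground
#' stations, rail lines, and a lattice of public-transport accessibility
#' (PTAL) sample points whose scores decay with distance to the nearest
#' station.  A designated "East Village" district in the north-east corner is
#' denser, more mixed-use, park-adjacent and station-rich, so movers into it
#' experience the built-environment changes the design intends.
#'
#' @param seed Integer seed; output is deterministic given `seed` and
#'   `config`.
#' @param extent_m Side of the square city in metres (>= 2000 so 1-km
#'   buffers fit).
#' @param config Optional list overriding `block_m` (200), `n_parks` (6),
#'   `n_underground` (5, three of which sit inside the East Village
#'   district), `ev_size_m` (1000), `parcel_inset_m` (15).
#' @return Object of class `ms_city`: data frames `nodes`, `edges`,
#'   `parcels`, `parks`, `park_entrances`, `underground_stations`,
#'   `overground_stations`, `rail_edges`, `ptal_points`, plus `extent_m`,
#'   `block_m` and the `ev_district` rectangle.
#' @export
generate_city <- function(seed, extent_m = 4000, config = list()) {
  if (extent_m < 2000)
    stop("extent_m must be >= 2000 so 1-km network buffers fit",
         call. = FALSE)
  cfg <- utils::modifyList(list(block_m = 200, n_parks = 6, n_underground = 5,
                                ev_size_m = 1000, parcel_inset_m = 15),
                           config)
  b <- cfg$block_m
  n <- floor(extent_m / b)
  withr::with_seed(as.integer(seed) + 3000L, {
    gx <- rep(0:n, each = n + 1) * b
    gy <- rep(0:n, times = n + 1) * b
    nodes <- data.frame(node = seq_along(gx), x = gx, y = gy)
    key <- function(i, j) i * (n + 1) + j + 1  # i,j in 0..n
    h <- expand.grid(i = 0:(n - 1), j = 0:n)
    v <- expand.grid(i = 0:n, j = 0:(n - 1))
    edges <- rbind(
      data.frame(from = key(h$i, h$j), to = key(h$i + 1, h$j)),
      data.frame(from = key(v$i, v$j), to = key(v$i, v$j + 1)))
    edges$x1 <- nodes$x[edges$from]; edges$y1 <- nodes$y[edges$from]
    edges$x2 <- nodes$x[edges$to];   edges$y2 <- nodes$y[edges$to]
    edges$length <- sqrt((edges$x2 - edges$x1)^2 + (edges$y2 - edges$y1)^2)
    edges$edge <- seq_len(nrow(edges))

    ev <- c(xmin = extent_m - cfg$ev_size_m, ymin = extent_m - cfg$ev_size_m,
            xmax = extent_m, ymax = extent_m)
    cells <- expand.grid(ci = 0:(n - 1), cj = 0:(n - 1))
    cells$xmin <- cells$ci * b; cells$ymin <- cells$cj * b
    cells$xmax <- cells$xmin + b; cells$ymax <- cells$ymin + b
    cx <- (cells$xmin + cells$xmax) / 2; cy <- (cells$ymin + cells$ymax) / 2
    in_ev <- cx >= ev["xmin"] & cy >= ev["ymin"]

    # parks occupy whole cells; at least one inside the EV district
    park_rows <- integer(0)
    if (cfg$n_parks > 0) {
      ev_cells <- which(in_ev)
      park_rows <- sample(ev_cells, 1)
      other <- sample(which(!in_ev), cfg$n_parks - 1)
      park_rows <- c(park_rows, other)
    } else {
      warning("city generated with no parks", call. = FALSE)
    }
    parks <- if (length(park_rows)) data.frame(
      park = seq_along(park_rows),
      class = sample(c("Metropolitan", "District", "Local"),
                     length(park_rows), replace = TRUE,
                     prob = c(0.15, 0.35, 0.5)),
      cells[park_rows, c("xmin", "ymin", "xmax", "ymax")],
      row.names = NULL) else
      data.frame(park = integer(0), class = character(0), xmin = numeric(0),
                 ymin = numeric(0), xmax = numeric(0), ymax = numeric(0))
    # entrances: two sampled corner nodes per park (corners are grid nodes)
    park_entrances <- do.call(rbind, lapply(seq_len(nrow(parks)), function(i) {
      p <- parks[i, ]
      corners <- rbind(c(p$xmin, p$ymin), c(p$xmax, p$ymin),
                       c(p$xmin, p$ymax), c(p$xmax, p$ymax))
      pick <- corners[sample(4, 2), , drop = FALSE]
      nid <- vapply(seq_len(nrow(pick)), function(r)
        nodes$node[which.min((nodes$x - pick[r, 1])^2 +
                               (nodes$y - pick[r, 2])^2)], numeric(1))
      data.frame(park = p$park, node = nid,
                 x = nodes$x[nid], y = nodes$y[nid])
    }))
    if (is.null(park_entrances))
      park_entrances <- data.frame(park = integer(0), node = integer(0),
                                   x = numeric(0), y = numeric(0))

    # parcels on the remaining cells
    pc <- cells[setdiff(seq_len(nrow(cells)), park_rows), ]
    p_in_ev <- in_ev[setdiff(seq_len(nrow(cells)), park_rows)]
    classes <- c("residential", "commercial", "office", "entertainment",
                 "institutional")
    cls <- character(nrow(pc))
    cls[p_in_ev] <- sample(classes, sum(p_in_ev), replace = TRUE,
                           prob = c(0.35, 0.2, 0.15, 0.15, 0.15))
    cls[!p_in_ev] <- sample(classes, sum(!p_in_ev), replace = TRUE,
                            prob = c(0.70, 0.12, 0.08, 0.05, 0.05))
    ins <- cfg$parcel_inset_m
    area <- (b - 2 * ins)^2
    plot_ratio <- ifelse(p_in_ev, stats::runif(nrow(pc), 0.8, 1.2),
                         stats::runif(nrow(pc), 0.3, 0.6))
    floor_area <- area * plot_ratio
    res_units <- ifelse(cls == "residential",
                        round(floor_area / ifelse(p_in_ev, 60, 100)), 0L)
    parcels <- data.frame(
      parcel = seq_len(nrow(pc)),
      xmin = pc$xmin + ins, ymin = pc$ymin + ins,
      xmax = pc$xmax - ins, ymax = pc$ymax - ins,
      class = cls, floor_area = floor_area, res_units = as.integer(res_units),
      in_ev_district = p_in_ev, row.names = NULL)

    # underground stations: the EV district is deliberately station-rich
    # (centre + two corners), the rest are spread at random
    ev_nodes <- which(nodes$x >= ev["xmin"] & nodes$y >= ev["ymin"])
    other_nodes <- setdiff(seq_len(nrow(nodes)), ev_nodes)
    nearest_ev_node <- function(px, py)
      ev_nodes[which.min((nodes$x[ev_nodes] - px)^2 +
                           (nodes$y[ev_nodes] - py)^2)]
    ev_st <- unique(c(
      nearest_ev_node((ev["xmin"] + ev["xmax"]) / 2,
                      (ev["ymin"] + ev["ymax"]) / 2),
      nearest_ev_node(ev["xmin"] + 0.15 * (ev["xmax"] - ev["xmin"]),
                      ev["ymin"] + 0.85 * (ev["ymax"] - ev["ymin"])),
      nearest_ev_node(ev["xmin"] + 0.85 * (ev["xmax"] - ev["xmin"]),
                      ev["ymin"] + 0.15 * (ev["ymax"] - ev["ymin"]))))
    und_nodes <- c(ev_st,
                   sample(other_nodes,
                          max(0, cfg$n_underground - length(ev_st))))
    underground_stations <- data.frame(
      station = seq_along(und_nodes), node = und_nodes,
      x = nodes$x[und_nodes], y = nodes$y[und_nodes])

    # overground line: stations along the mid row plus an EV terminus
    mid_j <- floor(n / 2)
    ov_i <- unique(round(seq(1, n - 1, length.out = 4)))
    ov_nodes <- key(ov_i, mid_j)
    ov_nodes <- c(ov_nodes, ev_nodes[which.min(nodes$y[ev_nodes])])
    overground_stations <- data.frame(
      station = seq_along(ov_nodes), node = ov_nodes,
      x = nodes$x[ov_nodes], y = nodes$y[ov_nodes])
    os <- overground_stations[order(overground_stations$x,
                                    overground_stations$y), ]
    # the rail corridor runs offset 60 m from the street grid (rail is not
    # road), touching the grid only at stations, so road traffic is outside
    # the 50-m rail corridor except right at stations
    off_m <- 60
    verts <- matrix(c(os$x[1], os$y[1]), ncol = 2)
    for (i in seq_len(nrow(os) - 1)) {
      pa <- c(os$x[i], os$y[i]); pb <- c(os$x[i + 1], os$y[i + 1])
      u <- (pb - pa) / sqrt(sum((pb - pa)^2))
      nrm <- c(-u[2], u[1]) * off_m
      verts <- rbind(verts, pa + nrm, pb + nrm, pb)
    }
    rail_edges <- data.frame(x1 = verts[-nrow(verts), 1],
                             y1 = verts[-nrow(verts), 2],
                             x2 = verts[-1, 1], y2 = verts[-1, 2])
    rail_line <- verts

    # PTAL lattice: accessibility rises with the number of stations within
    # walking reach (800 m) plus a proximity bonus for the nearest one, so
    # the station-dense EV district scores high and isolated stations
    # elsewhere score moderate
    pt <- expand.grid(x = seq(b, extent_m - b, by = 2 * b),
                      y = seq(b, extent_m - b, by = 2 * b))
    all_st <- rbind(underground_stations[c("x", "y")],
                    overground_stations[c("x", "y")])
    score <- vapply(seq_len(nrow(pt)), function(i) {
      d <- sqrt((all_st$x - pt$x[i])^2 + (all_st$y - pt$y[i])^2)
      min(8, 1.5 * sum(d <= 800) + max(0, 2 - min(d) / 500))
    }, numeric(1))
    ptal_points <- data.frame(point = seq_len(nrow(pt)), x = pt$x, y = pt$y,
                              score = score)

    structure(list(extent_m = extent_m, block_m = b, ev_district = ev,
                   nodes = nodes, edges = edges, parcels = parcels,
                   parks = parks, park_entrances = park_entrances,
                   underground_stations = underground_stations,
                   overground_stations = overground_stations,
                   rail_edges = rail_edges, rail_line = rail_line,
                   ptal_points = ptal_points),
              class = "ms_city")
  })
}

#' @export
print.ms_city <- function(x, ...) {
  cat("<ms_city>", x$extent_m, "m grid,", nrow(x$nodes), "nodes,",
      nrow(x$edges), "street edges,", nrow(x$parcels), "parcels,",
      nrow(x$parks), "parks,", nrow(x$underground_stations),
      "underground stations\n")
  invisible(x)
}

#' Street network as an igraph
#'
#' @param city A `ms_city`.
#' @return Undirected `igraph` with edge `weight` = length in metres and
#'   vertex coordinates.
#' @export
city_graph <- function(city) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = city$edges$from, to = city$edges$to,
               weight = city$edges$length, edge = city$edges$edge),
    directed = FALSE,
    vertices = data.frame(name = city$nodes$node, x = city$nodes$x,
                          y = city$nodes$y))
  g
}
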