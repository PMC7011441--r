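mk_parcel <- function(xmin, ymin, xmax, ymax, class, floor_area,
                      res_units = 0L)
  data.frame(parcel = 1, xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax,
             class = class, floor_area = floor_area,
             res_units = as.integer(res_units), in_ev_district = FALSE)

test_that("network buffer truncates partial edges at exactly the radius", {
  lc <- line_city(c(0, 500))
  b <- network_buffer(c(250, 0), lc, radius_m = 1000)
  expect_equal(b$reachable_len, 500)
  b0 <- network_buffer(c(250, 0), lc, radius_m = 0)
  expect_equal(b0$reachable_len, 0)
  b100 <- network_buffer(c(250, 0), lc, radius_m = 100)
  expect_equal(b100$reachable_len, 200)  # 100 m each way from the snap
  expect_error(network_buffer(c(250, 500), lc), "snap")
})

test_that("buffer and park distance agree with brute-force shortest paths", {
  for (s in 1:8) {
    lc <- random_graph_city(s, n_nodes = sample(10:40, 1))
    D <- fw_distances(as.character(lc$nodes$node), lc$edges)
    start <- lc$nodes$node[1 + (s %% nrow(lc$nodes))]
    addr <- c(lc$nodes$x[start], lc$nodes$y[start])
    r <- c(300, 800, 1500)[1 + (s %% 3)]
    b <- network_buffer(addr, lc, radius_m = r)
    expect_equal(b$reachable_len,
                 reach_oracle(D, lc$edges, as.character(start), r),
                 tolerance = 1e-9)
    # park entrances at two random nodes; network distance oracle
    ent <- sample(lc$nodes$node, 2)
    lc$park_entrances <- data.frame(park = 1:2, node = ent,
                                    x = lc$nodes$x[ent],
                                    y = lc$nodes$y[ent])
    got <- park_distance(addr, lc)
    want <- min(D[as.character(start), as.character(ent)])
    expect_equal(got, want, tolerance = 1e-9)
    # network distance dominates the straight line
    eu <- min(sqrt((lc$nodes$x[ent] - addr[1])^2 +
                     (lc$nodes$y[ent] - addr[2])^2))
    expect_gte(got + 1e-9, eu)
  }
})

test_that("land-use mix hits its closed-form endpoints", {
  lc <- line_city(c(0, 500))
  b <- network_buffer(c(250, 0), lc)
  single <- mk_parcel(0, 0, 100, 10, "commercial", 1000)
  expect_equal(land_use_mix(b, single), 0)
  five <- do.call(rbind, lapply(
    c("residential", "commercial", "office", "entertainment",
      "institutional"),
    function(k) mk_parcel(0, 0, 100, 10, k, 500)))
  expect_equal(land_use_mix(b, five), 1)
  two <- five[1:2, ]
  expect_equal(land_use_mix(b, two), log(2) / log(5), tolerance = 1e-12)
  # invariant to uniform scaling of all footages
  five2 <- five
  five2$floor_area <- five2$floor_area * 37.5
  expect_equal(land_use_mix(b, five), land_use_mix(b, five2))
  # nothing in buffer -> missing
  far <- mk_parcel(4000, 4000, 4100, 4100, "commercial", 1000)
  expect_true(is.na(land_use_mix(b, far)))
})

test_that("residential density is RU per residential km^2, in thousands", {
  lc <- line_city(c(0, 1000))
  b <- network_buffer(c(500, 0), lc)
  # 0.5 km^2 of residential land with 2000 RU -> 4.0
  p <- mk_parcel(0, 0, 1000, 500, "residential", 1e5, 2000)
  expect_equal(residential_density(b, p), 4)
  p2 <- p
  p2$res_units <- p2$res_units * 2L
  expect_equal(residential_density(b, p2), 8)
  expect_true(is.na(residential_density(
    b, mk_parcel(0, 0, 10, 10, "office", 100))))
})

test_that("street connectivity counts degree >= 3 junctions per road km", {
  # single segment: no junctions
  lc <- line_city(c(0, 500))
  b <- network_buffer(c(250, 0), lc)
  expect_equal(street_connectivity(b, lc), 0)
  # plus-shaped network: one 4-way junction, cul-de-sac ends not counted
  nodes <- data.frame(node = 1:5, x = c(0, 200, 400, 200, 200),
                      y = c(0, 0, 0, 200, -200))
  edges <- data.frame(from = c(1, 2, 2, 2), to = c(2, 3, 4, 5))
  edges$x1 <- nodes$x[edges$from]; edges$y1 <- nodes$y[edges$from]
  edges$x2 <- nodes$x[edges$to]; edges$y2 <- nodes$y[edges$to]
  edges$length <- sqrt((edges$x2 - edges$x1)^2 + (edges$y2 - edges$y1)^2)
  edges$edge <- 1:4
  plus <- structure(list(nodes = nodes, edges = edges), class = "ms_city")
  b2 <- network_buffer(c(200, 0), plus, radius_m = 1000)
  expect_equal(b2$reachable_len, 800)
  expect_equal(street_connectivity(b2, plus), 1 / 0.8)
  # hand count on the interior of a 100-m grid city
  city <- generate_city(31, extent_m = 2000, config = list(block_m = 100))
  bg <- network_buffer(c(1000, 1000), city, radius_m = 250)
  deg4 <- sum(bg$node_dist <= 250)  # all interior grid nodes are 4-way
  expect_equal(street_connectivity(bg, city),
               deg4 / (bg$reachable_len / 1000))
})

test_that("walkability is a baseline-referenced z-sum", {
  ex <- data.frame(
    id = rep(c("a", "b", "c", "d"), 2),
    wave = rep(c("baseline", "followup"), each = 4),
    land_use_mix = c(0.2, 0.4, 0.6, 0.8, 0.2, 0.4, 0.6, 0.9),
    residential_density = c(1, 2, 3, 4, 1, 2, 3, 6),
    street_connectivity = c(5, 6, 7, 8, 5, 6, 7, 9))
  w <- walkability(ex)
  base <- w[w$wave == "baseline", ]
  expect_equal(mean(base$walkability), 0, tolerance = 1e-12)
  # an address at the baseline means scores exactly 0
  ex0 <- rbind(ex, data.frame(id = "m", wave = "followup",
                              land_use_mix = 0.5,
                              residential_density = 2.5,
                              street_connectivity = 6.5))
  w0 <- walkability(ex0)
  expect_equal(w0$walkability[w0$id == "m"], 0, tolerance = 1e-12)
  # non-movers in an unchanged city change by exactly zero
  chg <- w$walkability[w$wave == "followup"] -
    w$walkability[w$wave == "baseline"]
  expect_identical(chg[1:3], rep(0, 3))
  # zero-sd component errors
  exc <- ex
  exc$street_connectivity <- 5
  expect_error(walkability(exc), "zero baseline sd")
})

test_that("park distance takes the minimum over all entrances", {
  lc <- line_city(c(0, 300, 800, 1100))
  lc$park_entrances <- data.frame(park = 1:2, node = c(2, 3),
                                  x = c(300, 800), y = 0)
  expect_equal(park_distance(c(0, 0), lc), 300)
  expect_equal(park_distance(c(300, 0), lc), 0)
  lc0 <- lc
  lc0$park_entrances <- lc$park_entrances[0, ]
  expect_error(park_distance(c(0, 0), lc0), "no park entrances")
})

test_that("PTAL assignment is nearest-point with low-id tie-breaking", {
  pts <- data.frame(point = 1:3, x = c(0, 100, 500), y = 0,
                    score = c(2, 6.5, 8))
  expect_equal(assign_ptal(c(0, 0), pts), 2)
  expect_equal(assign_ptal(c(50, 0), pts), 2)  # tie -> lowest id
  for (s in 1:10) {
    withr::with_seed(s, {
      p <- data.frame(point = 1:5, x = runif(5, 0, 1000),
                      y = runif(5, 0, 1000), score = runif(5, 0, 8))
      a <- c(runif(1, 0, 1000), runif(1, 0, 1000))
      d <- sqrt((p$x - a[1])^2 + (p$y - a[2])^2)
      expect_equal(assign_ptal(a, p), p$score[which.min(d)])
    })
  }
  expect_true(is.na(assign_ptal(c(0, 0), pts[0, ])))
})

test_that("movers into the denser district gain walkability, parks, PTAL", {
  cfg <- sim_config(seed = 33, n_participants = 16, n_households = 12,
                    fidelity = "epoch")
  city <- generate_city(33)
  coh <- generate_cohort(city, cfg)
  hh <- coh[!duplicated(coh$household), ]
  addr <- rbind(
    data.frame(id = hh$id, wave = "baseline", x = hh$home_x_baseline,
               y = hh$home_y_baseline),
    data.frame(id = hh$id, wave = "followup", x = hh$home_x_followup,
               y = hh$home_y_followup))
  ex <- built_env_exposures(addr, city)
  b <- ex[ex$wave == "baseline", ]
  f <- ex[ex$wave == "followup", ]
  mv <- hh$group == "EastVillage"
  expect_gt(mean(f$walkability[mv] - b$walkability[mv]), 0)
  expect_lt(mean(f$park_distance_m[mv] - b$park_distance_m[mv]), 0)
  expect_gt(mean(f$ptal[mv] - b$ptal[mv]), 0)
  # non-movers: all exposures exactly unchanged
  stay <- !mv
  for (v in c("land_use_mix", "residential_density", "street_connectivity",
              "walkability", "park_distance_m", "ptal"))
    expect_equal(f[[v]][stay], b[[v]][stay])
})
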