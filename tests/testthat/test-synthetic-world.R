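test_that("sim_config validates its inputs", {
  expect_error(sim_config(n_participants = 10, n_households = 11),
               "n_households")
  expect_error(sim_config(wear_days = 8), "wear_days")
  expect_error(sim_config(indoor_dropout = 1.5), "probability")
  expect_error(sim_config(cv_day = -0.1), ">= 0")
  cfg <- sim_config()
  expect_s3_class(cfg, "ms_config")
  expect_identical(cfg$underground_dropout, 1)
})

test_that("city generation is seeded, deterministic and seed-sensitive", {
  c1 <- generate_city(1)
  c2 <- generate_city(1)
  c3 <- generate_city(2)
  expect_identical(c1, c2)
  expect_false(identical(c1$parcels$class, c3$parcels$class))
  expect_error(generate_city(1, extent_m = 1500), "extent")
  expect_warning(c0 <- generate_city(1, config = list(n_parks = 0)),
                 "no parks")
  expect_identical(nrow(c0$parks), 0L)
})

test_that("city invariants hold: connectivity, park entrances on network", {
  city <- generate_city(5)
  g <- city_graph(city)
  expect_true(igraph::is_connected(g))
  # every park has >= 1 entrance, and entrances are street nodes
  expect_true(all(city$parks$park %in% city$park_entrances$park))
  expect_true(all(city$park_entrances$node %in% city$nodes$node))
  expect_true(all(city$ptal_points$score >= 0 & city$ptal_points$score <= 8))
  cls <- unique(city$parcels$class)
  expect_setequal(cls, c("residential", "commercial", "office",
                         "entertainment", "institutional"))
})

test_that("cohort marginals follow the configured mixing proportions", {
  cfg <- sim_config(seed = 1, fidelity = "day")
  coh <- generate_cohort(NULL, cfg)
  expect_identical(nrow(coh), 578L)
  expect_identical(length(unique(coh$household)), 400L)
  # housing-group counts close to 201/283/94 (household-level sampling)
  n_h <- table(coh$housing_group)
  expect_true(all(abs(n_h - c(201, 283, 94)) < 45))
  # group and housing shared within household
  hh <- split(coh, coh$household)
  expect_true(all(vapply(hh, function(h)
    length(unique(h$group)) == 1 && length(unique(h$housing_group)) == 1,
    logical(1))))
})

test_that("all-Control cohorts never move into the East Village district", {
  cfg <- sim_config(seed = 3, n_participants = 40, n_households = 30,
                    ev_frac_by_housing = c(social = 0, intermediate = 0,
                                           `market-rent` = 0))
  city <- generate_city(3)
  coh <- generate_cohort(city, cfg)
  expect_true(all(coh$group == "Control"))
  expect_identical(coh$home_x_baseline, coh$home_x_followup)
  ev <- city$ev_district
  expect_false(any(coh$home_x_followup >= ev["xmin"] &
                     coh$home_y_followup >= ev["ymin"]))
})

test_that("two-person households yield n/2 households of size two", {
  cfg <- sim_config(seed = 2, n_participants = 60, n_households = 30)
  coh <- generate_cohort(NULL, cfg)
  expect_identical(length(unique(coh$household)), 30L)
  expect_true(all(table(coh$household) == 2))
})

test_that("day-level generator matches configured category means", {
  cfg <- sim_config(seed = 4, n_participants = 1500, n_households = 1000,
                    fidelity = "day", wear_days = 3,
                    true_effects = default_true_effects("zero"))
  coh <- generate_cohort(NULL, cfg)
  dp <- generate_day_level(coh, cfg)
  base <- dp[dp$wave == "baseline" & dp$group == "Control", ]
  # Control baseline vehicle mean ~ 37.3 (truncation < 1%)
  expect_equal(mean(base$vehicle), 37.3, tolerance = 0.02)
  expect_equal(mean(base$walking), 39.7, tolerance = 0.02)
  expect_true(all(dp[MS_CATEGORIES] >= 0))
  expect_equal(dp$active_travel, dp$walking + dp$cycling)
  expect_equal(dp$total_gps_min, rowSums(dp[MS_CATEGORIES]))
})

test_that("zero variances and zero effects reproduce the means exactly", {
  cfg <- sim_config(seed = 5, n_participants = 20, n_households = 15,
                    fidelity = "day", cv_household = 0,
                    cv_household_wave = 0, cv_person = 0, cv_day = 0,
                    true_effects = default_true_effects("zero"))
  dp <- generate_day_level(generate_cohort(NULL, cfg), cfg)
  for (k in MS_CATEGORIES)
    expect_true(all(dp[[k]] == default_category_means()[[k]]))
})

test_that("generator output is byte-identical under one seed", {
  cfg <- sim_config(seed = 6, n_participants = 50, n_households = 40,
                    fidelity = "day", wear_days = 2)
  coh <- generate_cohort(NULL, cfg)
  expect_identical(generate_day_level(coh, cfg),
                   generate_day_level(coh, cfg))
})

test_that("effect injection matches the truncation-aware analytic oracle", {
  # analytic oracle: expected raw difference in change per category under
  # the truncated-Gaussian day model
  cfg <- sim_config(seed = 8, n_participants = 5000, n_households = 3400,
                    fidelity = "day", wear_days = 2)
  coh <- generate_cohort(NULL, cfg)
  dp <- generate_day_level(coh, cfg)
  mu <- cfg$category_means
  sd_tot <- sqrt(cfg$cv_household^2 + cfg$cv_household_wave^2 +
                   cfg$cv_person^2 + cfg$cv_day^2) * mu
  agg <- stats::aggregate(dp[MS_CATEGORIES],
                          by = list(id = dp$id, wave = dp$wave,
                                    group = dp$group), mean)
  for (k in MS_CATEGORIES) {
    w <- reshape(agg[c("id", "wave", "group", k)], idvar = c("id", "group"),
                 timevar = "wave", direction = "wide")
    ch <- w[[paste0(k, ".followup")]] - w[[paste0(k, ".baseline")]]
    emp <- mean(ch[w$group == "EastVillage"]) - mean(ch[w$group == "Control"])
    eff <- default_true_effects("all")[[k]]
    oracle <- modeshift:::truncated_mean(mu[[k]] + eff, sd_tot[[k]]) -
      modeshift:::truncated_mean(mu[[k]], sd_tot[[k]])
    se <- sqrt(stats::var(ch[w$group == "EastVillage"]) /
                 sum(w$group == "EastVillage") +
                 stats::var(ch[w$group == "Control"]) /
                 sum(w$group == "Control"))
    expect_lt(abs(emp - oracle), 3 * se)
    # for the travel modes the truncation distortion is negligible
    if (k %in% c("walking", "cycling", "vehicle", "overground_train",
                 "underground_train"))
      expect_lt(abs(oracle - eff), 0.05)
  }
})

test_that("diaries tile the waking day and respect network anchoring", {
  w <- epoch_world()
  di <- w$diaries
  key <- paste(di$id, di$wave, di$day)
  for (d in split(di, key)) {
    expect_equal(d$start_s[1], w$cfg$day_start_min * 60)
    expect_equal(d$end_s[nrow(d)], w$cfg$day_end_min * 60)
    if (nrow(d) > 1)
      expect_equal(d$start_s[-1], d$end_s[-nrow(d)])
  }
  # underground episodes start and end at underground-station points
  ug <- di[di$true_mode == "underground_train", ]
  st <- w$city$underground_stations
  for (i in seq_len(nrow(ug))) {
    p <- ug$path[[i]]
    d0 <- min(sqrt((st$x - p[1, 1])^2 + (st$y - p[1, 2])^2))
    d1 <- min(sqrt((st$x - p[nrow(p), 1])^2 + (st$y - p[nrow(p), 2])^2))
    expect_lt(d0, 1e-6)
    expect_lt(d1, 1e-6)
  }
})

test_that("impossible travel demand errors out", {
  cfg <- sim_config(seed = 9, n_participants = 2, n_households = 2,
                    fidelity = "epoch", wear_days = 1,
                    category_means = c(walking = 2000, cycling = 6.1,
                                       vehicle = 37.3,
                                       overground_train = 14.6,
                                       underground_train = 14.3,
                                       stationary = 440))
  city <- generate_city(9)
  coh <- generate_cohort(city, cfg)
  expect_error(generate_diaries(coh, city, cfg), "exceeds the waking day")
})

test_that("sensor emulation honours dropout and cadence", {
  w <- epoch_world()
  di <- w$diaries
  gps <- w$sensors$gps
  # no fixes during underground episodes
  ug <- di[di$true_mode == "underground_train", ][1, ]
  d0 <- as.numeric(as.POSIXct(paste(ug$date, "00:00:00"), tz = "UTC"))
  secs <- as.numeric(gps$timestamp[gps$id == ug$id & gps$wave == ug$wave])
  expect_identical(sum(secs >= d0 + ug$start_s & secs < d0 + ug$end_s), 0L)
  # fixes are on a strict 10-s grid
  expect_true(all(as.numeric(gps$timestamp) %% 10 == 0))
  # accelerometer stream covers every waking epoch
  acc <- w$sensors$accel
  per_day <- table(paste(acc$id, acc$wave,
                         as.Date(acc$timestamp, tz = "UTC")))
  expect_true(all(per_day ==
                    (w$cfg$day_end_min - w$cfg$day_start_min) * 6))
})

test_that("noiseless stationary and walking streams look right", {
  cfg <- sim_config(seed = 12, n_participants = 2, n_households = 2,
                    fidelity = "epoch", wear_days = 1, gps_noise_sd_m = 0,
                    indoor_dropout = 0, count_cv = 0)
  city <- generate_city(12)
  coh <- generate_cohort(city, cfg)
  di <- generate_diaries(coh, city, cfg)
  sens <- emulate_sensors(di, cfg)
  p <- coh$id[1]
  g1 <- sens$gps[sens$gps$id == p & sens$gps$wave == "baseline", ]
  tru <- truth_at(di, p, "baseline", g1$timestamp)
  # stationary: zero displacement within one episode
  de <- di[di$id == p & di$wave == "baseline" &
             di$true_mode == "stationary_in", ]
  ep1 <- de[which.max(de$end_s - de$start_s), ]
  d0 <- as.numeric(as.POSIXct(paste(ep1$date, "00:00:00"), tz = "UTC"))
  secs <- as.numeric(g1$timestamp)
  inside <- secs >= d0 + ep1$start_s & secs < d0 + ep1$end_s
  expect_gt(sum(inside), 5)
  expect_lt(max(abs(diff(g1$x[inside]))), 1e-9)
  # walking: consecutive-fix speed equals the episode's drawn speed (3-6 km/h)
  wi <- which(tru == "walking")
  runs <- split(wi, cumsum(c(1, diff(wi) != 1)))
  run <- runs[[which.max(lengths(runs))]]
  spd <- sqrt(diff(g1$x[run])^2 + diff(g1$y[run])^2) / 10 * 3.6
  expect_true(stats::median(spd) > 2.9 && stats::median(spd) < 6.1)
})
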