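# shared zero-noise world for oracle-equivalence checks
noiseless_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 21, n_participants = 3, n_households = 3,
                        fidelity = "epoch", wear_days = 1,
                        gps_noise_sd_m = 0, indoor_dropout = 0,
                        count_cv = 0)
      city <- generate_city(21)
      coh <- generate_cohort(city, cfg)
      di <- generate_diaries(coh, city, cfg)
      sens <- emulate_sensors(di, cfg)
      eps <- list()
      for (p in coh$id) {
        gp <- sens$gps[sens$gps$id == p & sens$gps$wave == "baseline", ]
        ac <- sens$accel[sens$accel$id == p &
                           sens$accel$wave == "baseline", ]
        e <- mark_nonwear(fuse_epochs(gp, ac))
        e$id <- p; e$wave <- "baseline"
        eps[[p]] <- e
      }
      cache <<- list(cfg = cfg, city = city, cohort = coh, diaries = di,
                     epochs = eps)
    }
    cache
  }
})

test_that("features recover constant speed and respect window bounds", {
  t0 <- as.POSIXct("2014-05-05 08:00:00", tz = "UTC")
  n <- 60L
  ep <- data.frame(timestamp = t0 + seq(0, by = 10, length.out = n),
                   counts = 400, x = 14 * seq_len(n), y = 0,
                   has_fix = TRUE, speed = NA_real_, worn = TRUE)
  ep$speed[-1] <- 1.4
  f <- extract_features(ep)
  expect_identical(nrow(f), n)
  expect_true(all(abs(f$median_speed[5:55] - 1.4) < 1e-9))
  expect_true(all(f$fix_frac == 1))
  # single fix: features defined only around it
  ep2 <- ep
  ep2$has_fix <- c(rep(FALSE, 30), TRUE, rep(FALSE, 29))
  ep2$x[!ep2$has_fix] <- NA
  ep2$speed <- NA_real_
  f2 <- extract_features(ep2)
  expect_true(all(abs(which(ep2$has_fix) -
                        match(f2$timestamp, ep2$timestamp)) <= 3))
  expect_error(extract_features(ep, window_s = 25), "multiple of 10")
})

test_that("rule classifier applies the banded thresholds", {
  f <- data.frame(median_speed = c(1.2, 15, 0, 4, 4, 15, 1.2),
                  p95_speed = c(1.4, 16, 0, 5, 5, 16, 1.4),
                  accel = 0, counts = c(500, 30, 5, 250, 30, 30, 30),
                  counts_win = c(500, 30, 5, 250, 30, 30, 30),
                  rail_dist = c(1e4, 40, 1e4, 1e4, 1e4, 900, 1e4),
                  fix_frac = 1)
  got <- as.character(rule_classify(f)$mode)
  expect_identical(got, c("walking", "overground_train", "stationary",
                          "cycling", "vehicle", "vehicle", "stationary"))
})

test_that("synthetic cycling episodes hit the configured speed band", {
  w <- noiseless_world()
  di <- w$diaries
  for (p in names(w$epochs)) {
    ep <- w$epochs[[p]]
    f <- extract_features(ep, w$city$rail_edges)
    tru <- truth_at(di, p, "baseline", f$timestamp)
    cyc <- f$median_speed[!is.na(tru) & tru == "cycling"]
    if (!length(cyc)) next
    mid <- cyc[cyc > 0]
    expect_true(stats::median(mid) * 3.6 > 9.5 &&
                  stats::median(mid) * 3.6 < 25.5)
  }
})

test_that("rule classifier recovers >= 99% of zero-noise labels", {
  w <- noiseless_world()
  acc <- integer(0); tot <- integer(0)
  for (p in names(w$epochs)) {
    lab <- classify(w$epochs[[p]], "rule", rail_edges = w$city$rail_edges)
    lab <- smooth_labels(lab)
    tru <- truth_at(w$diaries, p, "baseline", lab$timestamp)
    keep <- !is.na(tru) & tru != "underground_train"
    acc <- c(acc, sum(tru[keep] == as.character(lab$mode[keep])))
    tot <- c(tot, sum(keep))
  }
  expect_gte(sum(acc) / sum(tot), 0.99)
})

test_that("gradient boosting learns the synthetic epoch labels", {
  w <- noiseless_world()
  # assemble a labelled feature set from a noisier twin world
  cfg <- sim_config(seed = 22, n_participants = 3, n_households = 3,
                    fidelity = "epoch", wear_days = 1)
  city <- generate_city(22)
  coh <- generate_cohort(city, cfg)
  di <- generate_diaries(coh, city, cfg)
  sens <- emulate_sensors(di, cfg)
  feats <- list()
  for (p in coh$id) {
    gp <- sens$gps[sens$gps$id == p & sens$gps$wave == "baseline", ]
    ac <- sens$accel[sens$accel$id == p & sens$accel$wave == "baseline", ]
    ep <- mark_nonwear(fuse_epochs(gp, ac))
    f <- extract_features(ep[ep$worn, ], city$rail_edges)
    f$mode <- truth_at(di, p, "baseline", f$timestamp)
    feats[[p]] <- f[!is.na(f$mode) & f$mode != "underground_train", ]
  }
  feats <- do.call(rbind, feats)
  # balance classes (stationary dominates raw epochs) and thin for speed
  withr::with_seed(1, {
    idx <- unlist(lapply(split(seq_len(nrow(feats)), feats$mode),
                         function(i) sample(i, min(length(i), 450))))
  })
  feats <- feats[sort(idx), ]
  expect_gte(length(unique(feats$mode)), 4)
  fit <- train_model(feats, seed = 1, n_trees = 60)
  expect_gte(fit$report$accuracy, 0.9)
  # determinism
  fit2 <- train_model(feats, seed = 1, n_trees = 60)
  expect_identical(predict(fit, feats[1:200, ]),
                   predict(fit2, feats[1:200, ]))
  # permuted labels learn nothing much beyond chance
  perm <- feats
  withr::with_seed(2, perm$mode <- sample(perm$mode))
  fit_p <- train_model(perm, seed = 1, n_trees = 25)
  expect_lt(fit_p$report$accuracy, 0.65)
  # single-class input errors
  expect_error(train_model(feats[feats$mode == "stationary", ]),
               ">= 2 classes")
  # model agrees with the rule oracle on zero-noise data
  wn <- noiseless_world()
  p1 <- names(wn$epochs)[1]
  labs_m <- classify(wn$epochs[[p1]], fit, rail_edges = wn$city$rail_edges)
  labs_r <- classify(wn$epochs[[p1]], "rule",
                     rail_edges = wn$city$rail_edges)
  expect_gte(mean(as.character(labs_m$mode) == as.character(labs_r$mode)),
             0.95)
})

test_that("classify labels every worn epoch and handles empty input", {
  w <- noiseless_world()
  p <- names(w$epochs)[1]
  ep <- w$epochs[[p]]
  lab <- classify(ep, "rule", rail_edges = w$city$rail_edges)
  expect_identical(nrow(lab), sum(ep$worn))
  expect_false(anyNA(lab$mode))
  expect_identical(nrow(classify(ep[0, ], "rule")), 0L)
  expect_error(classify(ep, model = list()), "rule")
})

test_that("confusion structure: walking-cycling exceeds walking-vehicle", {
  cfg <- sim_config(seed = 23, n_participants = 4, n_households = 4,
                    fidelity = "epoch", wear_days = 1, gps_noise_sd_m = 12)
  city <- generate_city(23)
  coh <- generate_cohort(city, cfg)
  di <- generate_diaries(coh, city, cfg)
  sens <- emulate_sensors(di, cfg)
  conf <- matrix(0, 2, 2)
  wc <- wv <- 0
  for (p in coh$id) {
    gp <- sens$gps[sens$gps$id == p & sens$gps$wave == "baseline", ]
    ac <- sens$accel[sens$accel$id == p & sens$accel$wave == "baseline", ]
    ep <- mark_nonwear(fuse_epochs(gp, ac))
    lab <- classify(ep, "rule", rail_edges = city$rail_edges)
    tru <- truth_at(di, p, "baseline", lab$timestamp)
    walkish <- !is.na(tru) & tru == "walking"
    wc <- wc + sum(lab$mode[walkish] == "cycling")
    wv <- wv + sum(lab$mode[walkish] == "vehicle")
  }
  expect_gt(wc, wv)
})

test_that("label smoothing absorbs short runs deterministically", {
  mk <- function(modes) data.frame(
    timestamp = as.POSIXct("2014-05-05 08:00:00", tz = "UTC") +
      seq(0, by = 10, length.out = length(modes)),
    mode = factor(modes, MS_EPOCH_MODES), source = "rule")
  s <- smooth_labels(mk(c("walking", "walking", "vehicle", "walking",
                          "walking")))
  expect_true(all(s$mode == "walking"))
  expect_identical(s$source[3], "smoothed")
  # run >= min_run_s unchanged
  keep <- mk(rep(c("walking", "vehicle"), c(4, 3)))
  expect_identical(as.character(smooth_labels(keep)$mode),
                   as.character(keep$mode))
  expect_error(smooth_labels(keep, min_run_s = 25), "multiple")
  # idempotence on random sequences, plus no short runs remain
  for (s_ in 1:20) {
    withr::with_seed(s_, {
      lab <- mk(sample(MS_EPOCH_MODES, 10, replace = TRUE))
      once <- smooth_labels(lab)
      twice <- smooth_labels(once)
      expect_identical(as.character(once$mode), as.character(twice$mode))
      r <- rle(as.character(once$mode))
      if (length(r$lengths) > 1) expect_true(all(r$lengths >= 3))
    })
  }
})
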