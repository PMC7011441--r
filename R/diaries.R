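#' Generate ground-truth travel diaries (epoch fidelity)
#'
#' For every participant-wave-day, draws true minute totals per travel mode
#' from the same additive effect-injection model as the day-level generator,
#' then lays out contiguous, non-overlapping episodes tiling the waking day:
#' home stationary blocks interleaved with one episode per active mode.
#' Walking, cycling and vehicle episodes follow shortest street-network
#' paths; overground episodes follow the rail line; underground episodes run
#' station to station and are book-ended by short station-access walks so
#' the surrounding fixes lie near the stations.  Episode durations are
#' rounded to 10-s multiples.
#'
#' @param cohort From [generate_cohort()] (addresses required, so the city
#'   must have been supplied there).
#' @param city The `ms_city` the cohort lives in.
#' @param config [sim_config()] with `fidelity = "epoch"`.
#' @return Data frame of episodes: `id`, `wave`, `day`, `date`,
#'   `true_mode`, `start_s`, `end_s` (seconds from midnight UTC),
#'   `speed_mps`, and a `path` list-column of x-y matrices (a single point
#'   for stationary episodes).
#' @export
generate_diaries <- function(cohort, city, config) {
  stopifnot(inherits(config, "ms_config"))
  if (config$fidelity != "epoch")
    stop("generate_diaries requires fidelity = 'epoch'", call. = FALSE)
  if (anyNA(cohort$home_x_baseline))
    stop("cohort has no addresses; generate it with a city", call. = FALSE)
  g <- city_graph(city)
  nodes <- city$nodes
  mu <- config$category_means
  day_len <- config$day_end_min - config$day_start_min
  travel_modes <- c("walking", "cycling", "vehicle", "overground_train",
                    "underground_train")
  # rail polyline (vertex chain) for overground trips
  rail_line <- if (!is.null(city$rail_line) && nrow(city$rail_line) > 1)
    city$rail_line else NULL
  hh <- as.integer(factor(cohort$household))
  withr::with_seed(config$seed + 4000L, {
    b_house <- sapply(travel_modes, function(k)
      stats::rnorm(max(hh), 0, config$cv_household * mu[k]))
    b_hw <- lapply(MS_WAVES, function(w) sapply(travel_modes, function(k)
      stats::rnorm(max(hh), 0, config$cv_household_wave * mu[k])))
    names(b_hw) <- MS_WAVES
    b_pers <- sapply(travel_modes, function(k)
      stats::rnorm(nrow(cohort), 0, config$cv_person * mu[k]))
    eps <- list()
    for (p in seq_len(nrow(cohort))) {
      for (w in MS_WAVES) {
        home <- c(cohort[[paste0("home_x_", w)]][p],
                  cohort[[paste0("home_y_", w)]][p])
        home_node <- nodes$node[which.min((nodes$x - home[1])^2 +
                                            (nodes$y - home[2])^2)]
        date0 <- as.Date(if (w == "baseline") "2014-05-05" else "2016-05-02")
        for (d in seq_len(config$wear_days)) {
          eff_on <- cohort$group[p] == "EastVillage" && w == "followup"
          mins <- vapply(travel_modes, function(k) {
            e <- .effects_for_housing(config,
                                      as.character(cohort$housing_group[p]))
            v <- mu[[k]] + b_house[hh[p], k] + b_hw[[w]][hh[p], k] +
              b_pers[p, k] +
              stats::rnorm(1, 0, config$cv_day * mu[[k]]) +
              e[[k]] * eff_on
            max(round(v * 6) / 6, 0)
          }, numeric(1))
          mins[mins < 1] <- 0
          if (sum(mins) >= day_len)
            stop("requested daily travel exceeds the waking day",
                 call. = FALSE)
          eps[[length(eps) + 1]] <-
            .layout_day(cohort$id[p], w, d, date0 + d - 1L, mins, home,
                        home_node, g, nodes, city, rail_line, config)
        }
      }
    }
    out <- do.call(rbind, eps)
    rownames(out) <- NULL
    out
  })
}

# build one day's contiguous episode list
.layout_day <- function(id, wave, day, date, mins, home, home_node, g,
                        nodes, city, rail_line, config) {
  day_s0 <- config$day_start_min * 60
  day_s1 <- config$day_end_min * 60
  active <- names(mins)[mins > 0]
  n_blocks <- length(active) + 1L
  stat_total <- (day_s1 - day_s0) / 60 - sum(mins)
  # stationary filler split across blocks, first block largest (morning home)
  stat_w <- c(2, rep(1, n_blocks - 1))
  stat_mins <- floor(stat_total * stat_w / sum(stat_w) * 6) / 6
  stat_mins[1] <- stat_mins[1] + (stat_total - sum(stat_mins))
  rows <- list()
  cur <- day_s0
  add <- function(mode, dur_min, path, speed) {
    if (dur_min <= 0) return(invisible())
    rows[[length(rows) + 1]] <<- data.frame(
      id = id, wave = wave, day = day, date = date, true_mode = mode,
      start_s = cur, end_s = cur + dur_min * 60, speed_mps = speed,
      stringsAsFactors = FALSE)
    attr(rows[[length(rows)]], "path") <<- path
    cur <<- cur + dur_min * 60
    invisible()
  }
  speed_of <- function(mode) {
    rng <- switch(mode, walking = config$speeds_kmh$walking,
                  cycling = config$speeds_kmh$cycling,
                  vehicle = config$speeds_kmh$vehicle,
                  config$speeds_kmh$train)
    stats::runif(1, rng[1], rng[2]) / 3.6
  }
  street_path <- function() {
    dest <- sample(nodes$node, 1)
    vp <- igraph::shortest_paths(g, from = as.character(home_node),
                                 to = as.character(dest))$vpath[[1]]
    ids <- as.integer(igraph::V(g)$name[vp])
    m <- cbind(nodes$x[match(ids, nodes$node)],
               nodes$y[match(ids, nodes$node)])
    if (nrow(m) < 2) m <- rbind(m, m + c(1, 0))
    m
  }
  add("stationary_in", stat_mins[1], rbind(home), 0)
  bi <- 1L
  for (mode in active) {
    bi <- bi + 1L
    if (mode == "underground_train" && nrow(city$underground_stations) >= 2) {
      st <- city$underground_stations[
        sample(nrow(city$underground_stations), 2), ]
      a <- c(st$x[1], st$y[1]); b <- c(st$x[2], st$y[2])
      acc <- floor(min(2, mins[[mode]] / 4) * 6) / 6
      main <- mins[[mode]] - 2 * acc
      add("walking", acc, rbind(a, a + c(30, 0)), 1.4)
      add("underground_train", main, rbind(a, b), 0)
      add("walking", acc, rbind(b, b + c(30, 0)), 1.4)
    } else if (mode == "overground_train" && !is.null(rail_line)) {
      add(mode, mins[[mode]], rail_line, speed_of(mode))
    } else {
      add(if (mode == "underground_train") "vehicle" else mode,
          mins[[mode]], street_path(), speed_of(mode))
    }
    anchor <- if (bi %% 2 == 0) rbind(home) else {
      nd <- sample(nrow(nodes), 1)
      rbind(c(nodes$x[nd], nodes$y[nd]))
    }
    stat_mode <- if (bi %% 2 == 0) "stationary_in" else "stationary_out"
    add(stat_mode, stat_mins[bi], anchor, 0)
  }
  left <- (day_s1 - cur) / 60
  if (left > 0) add("stationary_in", left, rbind(home), 0)
  out <- do.call(rbind, rows)
  out$path <- lapply(rows, attr, "path")
  out
}

# position along a polyline at arc distance s, reflecting at the ends
.path_pos <- function(path, s) {
  seg <- sqrt(diff(path[, 1])^2 + diff(path[, 2])^2)
  L <- sum(seg)
  if (L <= 0) return(path[1, ])
  s <- s %% (2 * L)
  if (s > L) s <- 2 * L - s
  cs <- cumsum(c(0, seg))
  i <- findInterval(s, cs, rightmost.closed = TRUE)
  i <- min(i, length(seg))
  f <- (s - cs[i]) / seg[i]
  path[i, ] + f * (path[i + 1, ] - path[i, ])
}

#' Emulate raw GPS and accelerometer streams from diaries
#'
#' Emits 10-s cadence GPS fixes with Gaussian positional noise and 10-s
#' accelerometer count epochs drawn from each mode's configured lognormal
#' count distribution.  Fixes are suppressed with probability 1 during
#' underground episodes and with the configured indoor dropout probability
#' while stationary indoors.  Optionally inserts a zero-count non-wear bout
#' per day.
#'
#' @param diaries From [generate_diaries()].
#' @param config The same [sim_config()].
#' @param nonwear_min_per_day Minutes of a single zero-count (device off)
#'   bout inserted at a random time each day (default 0).
#' @return List of `gps` (`id, wave, timestamp, lat, lon, x, y`) and
#'   `accel` (`id, wave, timestamp, axis1, vm`) data frames.
#' @export
emulate_sensors <- function(diaries, config, nonwear_min_per_day = 0) {
  withr::with_seed(config$seed + 5000L, {
    gps <- list(); acc <- list()
    cm <- config$count_means
    count_of <- function(mode) switch(mode,
      walking = cm[["walking"]], cycling = cm[["cycling"]],
      vehicle = cm[["vehicle"]],
      overground_train = cm[["train"]], underground_train = cm[["train"]],
      cm[["stationary"]])
    sdlog <- sqrt(log(1 + config$count_cv^2))
    key <- paste(diaries$id, diaries$wave, diaries$day)
    for (kd in unique(key)) {
      de <- diaries[key == kd, , drop = FALSE]
      paths <- diaries$path[key == kd]
      day0 <- as.numeric(as.POSIXct(paste(de$date[1], "00:00:00"),
                                    tz = "UTC"))
      nw0 <- -1; nw1 <- -1
      if (nonwear_min_per_day > 0) {
        nw0 <- de$start_s[1] +
          floor(stats::runif(1, 0, max(1, (de$end_s[nrow(de)] - de$start_s[1] -
                                             nonwear_min_per_day * 60))) /
                  10) * 10
        nw1 <- nw0 + nonwear_min_per_day * 60
      }
      for (r in seq_len(nrow(de))) {
        ts <- seq(de$start_s[r], de$end_s[r] - 10, by = 10)
        if (!length(ts)) next
        n <- length(ts)
        mode <- de$true_mode[r]
        mu_c <- count_of(mode)
        cnt <- if (config$count_cv > 0)
          stats::rlnorm(n, log(mu_c) - sdlog^2 / 2, sdlog) else rep(mu_c, n)
        off <- ts >= nw0 & ts < nw1
        cnt[off] <- 0
        tt <- as.POSIXct(day0 + ts, tz = "UTC", origin = "1970-01-01")
        acc[[length(acc) + 1]] <- data.frame(
          id = de$id[r], wave = de$wave[r], timestamp = tt,
          axis1 = round(cnt * 0.7), vm = round(cnt))
        drop_p <- if (mode == "underground_train") 1 else
          if (mode == "stationary_in") config$indoor_dropout else 0
        keep <- stats::runif(n) >= drop_p & !off
        if (!any(keep)) next
        pos <- t(vapply(ts[keep] - de$start_s[r] + 5, function(s)
          .path_pos(paths[[r]], de$speed_mps[r] * s), numeric(2)))
        pos <- pos + matrix(stats::rnorm(2 * nrow(pos), 0,
                                         config$gps_noise_sd_m),
                            ncol = 2)
        ll <- unproject_xy(pos[, 1], pos[, 2])
        gps[[length(gps) + 1]] <- data.frame(
          id = de$id[r], wave = de$wave[r], timestamp = tt[keep],
          lat = ll[, "lat"], lon = ll[, "lon"],
          x = pos[, 1], y = pos[, 2])
      }
    }
    list(gps = do.call(rbind, gps), accel = do.call(rbind, acc))
  })
}
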