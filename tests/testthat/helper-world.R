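# shared fixtures and independent oracles, built in code at test time

covariates_of <- function(cohort)
  cohort[c("id", "household", "group", "sex", "age_group", "ethnic_group",
           "housing_group", "working_studying")]

# one replicate of the day-level recovery harness
recover_effect <- function(seed, outcome, config_args = list(),
                           stratum = NULL) {
  cfg <- do.call(sim_config, c(list(seed = seed, fidelity = "day"),
                               config_args))
  coh <- generate_cohort(NULL, cfg)
  dp <- generate_day_level(coh, cfg)
  summ <- wave_summaries(dp, categories = outcome, method = "mean")
  suppressWarnings(
    fit_change_model(summ, covariates_of(coh), outcome,
                     stratum = stratum)$estimate)
}

# hand-built epoch-record stream (counts per 10 s; optional fixes)
make_epochs <- function(n, counts, x = NA_real_, y = NA_real_,
                        start = "2014-05-05 08:00:00", worn = TRUE) {
  t0 <- as.POSIXct(start, tz = "UTC")
  data.frame(timestamp = t0 + seq(0, by = 10, length.out = n),
             counts = rep_len(counts, n), x = rep_len(x, n),
             y = rep_len(y, n), has_fix = !is.na(rep_len(x, n)),
             speed = NA_real_, worn = rep_len(worn, n))
}

# brute-force wear-time oracle: scan all zero-count minute runs
wear_oracle <- function(minute_counts, nonwear_min = 60) {
  zero <- minute_counts == 0
  r <- rle(zero)
  sum(r$lengths) - sum(r$lengths[r$values & r$lengths >= nonwear_min])
}

# brute-force all-pairs shortest paths (Floyd-Warshall) on a small edge list
fw_distances <- function(nodes, edges) {
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  for (i in seq_len(nrow(edges))) {
    a <- as.character(edges$from[i]); b <- as.character(edges$to[i])
    D[a, b] <- min(D[a, b], edges$length[i])
    D[b, a] <- D[a, b]
  }
  for (k in seq_len(n)) for (i in seq_len(n)) {
    nd <- D[i, k] + D[k, ]
    upd <- nd < D[i, ]
    D[i, upd] <- nd[upd]
  }
  D
}

# brute-force reachable street length within radius r of a start node,
# walking every edge from both ends (the truncation rule network_buffer
# implements)
reach_oracle <- function(D, edges, start, r) {
  tot <- 0
  for (i in seq_len(nrow(edges))) {
    a <- as.character(edges$from[i]); b <- as.character(edges$to[i])
    len <- edges$length[i]
    fa <- max(0, r - D[start, a])
    fb <- max(0, r - D[start, b])
    tot <- tot + min(len, fa + fb)
  }
  tot
}

# minimal city-like street network (list with nodes/edges) for graph tests
line_city <- function(xs, ys = rep(0, length(xs))) {
  nodes <- data.frame(node = seq_along(xs), x = xs, y = ys)
  edges <- data.frame(from = seq_len(length(xs) - 1),
                      to = seq_len(length(xs) - 1) + 1)
  edges$x1 <- nodes$x[edges$from]; edges$y1 <- nodes$y[edges$from]
  edges$x2 <- nodes$x[edges$to]; edges$y2 <- nodes$y[edges$to]
  edges$length <- sqrt((edges$x2 - edges$x1)^2 + (edges$y2 - edges$y1)^2)
  edges$edge <- seq_len(nrow(edges))
  structure(list(nodes = nodes, edges = edges), class = "ms_city")
}

# random connected graph city with <= n_nodes nodes
random_graph_city <- function(seed, n_nodes = 20) {
  withr::with_seed(seed, {
    nodes <- data.frame(node = seq_len(n_nodes),
                        x = runif(n_nodes, 0, 2000),
                        y = runif(n_nodes, 0, 2000))
    # spanning chain plus random extra edges
    perm <- sample(n_nodes)
    edges <- data.frame(from = perm[-n_nodes], to = perm[-1])
    extra <- matrix(sample(n_nodes, 2 * n_nodes, replace = TRUE), ncol = 2)
    extra <- extra[extra[, 1] != extra[, 2], , drop = FALSE]
    edges <- rbind(edges, data.frame(from = extra[, 1], to = extra[, 2]))
    edges <- edges[!duplicated(paste(pmin(edges$from, edges$to),
                                     pmax(edges$from, edges$to))), ]
    edges$x1 <- nodes$x[edges$from]; edges$y1 <- nodes$y[edges$from]
    edges$x2 <- nodes$x[edges$to]; edges$y2 <- nodes$y[edges$to]
    edges$length <- sqrt((edges$x2 - edges$x1)^2 + (edges$y2 - edges$y1)^2)
    edges$edge <- seq_len(nrow(edges))
    structure(list(nodes = nodes, edges = edges), class = "ms_city")
  })
}

# small epoch-fidelity world shared by sensor-stage tests (built once)
epoch_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 11, n_participants = 3, n_households = 3,
                        fidelity = "epoch", wear_days = 2)
      city <- generate_city(11)
      coh <- generate_cohort(city, cfg)
      di <- generate_diaries(coh, city, cfg)
      sens <- emulate_sensors(di, cfg)
      cache <<- list(cfg = cfg, city = city, cohort = coh, diaries = di,
                     sensors = sens)
    }
    cache
  }
})

# epoch-level ground-truth mode at given timestamps from a diary table
truth_at <- function(diaries, id, wave, timestamps) {
  secs <- as.numeric(timestamps)
  out <- rep(NA_character_, length(secs))
  de <- diaries[diaries$id == id & diaries$wave == wave, ]
  for (r in seq_len(nrow(de))) {
    d0 <- as.numeric(as.POSIXct(paste(de$date[r], "00:00:00"), tz = "UTC"))
    sel <- secs >= d0 + de$start_s[r] & secs < d0 + de$end_s[r]
    out[sel] <- de$true_mode[r]
  }
  out[out %in% c("stationary_in", "stationary_out")] <- "stationary"
  out
}
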