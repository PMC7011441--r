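#' Sliding-window epoch features for mode classification
#'
#' For every 10-s epoch with at least one GPS fix in its symmetric window
#' (truncated at day bounds), computes: median and 95th-percentile of epoch
#' speeds in the window, acceleration (first difference of epoch speed over
#' 10 s), epoch counts and window mean counts, Euclidean distance from the
#' epoch's (or nearest in-window) fix to the closest rail line, and the
#' fraction of window epochs carrying a fix.
#'
#' @param epochs Epoch records from [fuse_epochs()] for one
#'   participant-wave, plus optional `id`/`wave`/`true_mode` columns carried
#'   through.
#' @param rail_edges Rail segments (`x1,y1,x2,y2`) or `NULL` (rail distance
#'   then `Inf`).
#' @param window_s Window width in seconds, a multiple of 10 (default 60).
#' @return Feature data frame, one row per epoch with >= 1 in-window fix.
#' @export
extract_features <- function(epochs, rail_edges = NULL, window_s = 60) {
  if (window_s %% 10 != 0) stop("window_s must be a multiple of 10",
                                call. = FALSE)
  if (!nrow(epochs)) return(epochs[0, ])
  half <- window_s / 2 / 10
  date <- as.Date(epochs$timestamp, tz = "UTC")
  n <- nrow(epochs)
  spd <- epochs$speed
  cnt <- epochs$counts
  hf <- epochs$has_fix
  out <- vector("list", n)
  day_start <- match(date, unique(date))
  first_of_day <- c(TRUE, date[-1] != date[-n])
  day_lo <- cummax(seq_len(n) * first_of_day)
  # day upper bound per index
  day_hi <- rev(cummax(rev(seq_len(n) * c(first_of_day[-1], TRUE))))
  med <- p95 <- acc <- cw <- ff <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- max(day_lo[i], i - half)
    hi <- min(day_hi[i], i + half)
    w <- lo:hi
    if (!any(hf[w])) next
    sw <- spd[w]
    sw <- sw[!is.na(sw)]
    med[i] <- if (length(sw)) stats::median(sw) else 0
    p95[i] <- if (length(sw)) stats::quantile(sw, 0.95, names = FALSE) else 0
    acc[i] <- if (i > day_lo[i] && !is.na(spd[i]) && !is.na(spd[i - 1]))
      (spd[i] - spd[i - 1]) / 10 else 0
    cw[i] <- mean(cnt[w])
    ff[i] <- mean(hf[w])
  }
  has_feat <- !is.na(med)
  f <- epochs[has_feat, , drop = FALSE]
  f$median_speed <- med[has_feat]
  f$p95_speed <- p95[has_feat]
  f$accel <- acc[has_feat]
  f$counts_win <- cw[has_feat]
  f$fix_frac <- ff[has_feat]
  # rail distance from the epoch's own fix, else nearest in-window fix
  f$rail_dist <- Inf
  if (!is.null(rail_edges) && nrow(rail_edges)) {
    idx_all <- which(has_feat)
    px <- f$x; py <- f$y
    miss <- !f$has_fix
    if (any(miss)) {
      fix_idx <- which(hf)
      for (j in which(miss)) {
        i <- idx_all[j]
        cand <- fix_idx[abs(fix_idx - i) <= half]
        if (length(cand)) {
          k <- cand[which.min(abs(cand - i))]
          px[j] <- epochs$x[k]; py[j] <- epochs$y[k]
        }
      }
    }
    ok <- !is.na(px)
    d <- rep(Inf, sum(ok))
    for (r in seq_len(nrow(rail_edges)))
      d <- pmin(d, dist_point_seg(px[ok], py[ok],
                                  rail_edges$x1[r], rail_edges$y1[r],
                                  rail_edges$x2[r], rail_edges$y2[r]))
    f$rail_dist[ok] <- d
  }
  rownames(f) <- NULL
  f
}

MS_FEATURES <- c("median_speed", "p95_speed", "accel", "counts",
                 "counts_win", "rail_dist", "fix_frac")

#' Deterministic rule-based mode classifier (oracle / fallback)
#'
#' Threshold rules standing in for the published machine-learning classifier,
#' applied in a fixed order on window-median speed, counts and rail
#' proximity:
#' stationary below `v_still`; `v_still`-`v_walk` m/s is walking when counts
#' clear the walking floor, else vehicle (slow traffic); `v_walk`-`v_cycle`
#' m/s is cycling when counts clear the cycling floor, else vehicle; above
#' `v_cycle` m/s is overground train within the rail corridor and vehicle
#' otherwise.
#'
#' @param features From [extract_features()].
#' @param thresholds Named list: `v_still` 0.2, `v_walk` 2, `v_cycle` 7
#'   (m/s), `walk_counts` 150, `cycle_counts` 100, `still_counts` 50
#'   (counts/10 s), `rail_corridor_m` 50.  The `still_counts` rule absorbs
#'   GPS-noise-inflated apparent movement: a sedentary device shows
#'   near-zero counts, so sub-walking-speed epochs with counts below it are
#'   stationary, not slow vehicle travel.
#' @return Data frame of labels (`mode`, `source = "rule"`) aligned to
#'   `features` rows.
#' @export
rule_classify <- function(features,
                          thresholds = list(v_still = 0.2, v_walk = 2,
                                            v_cycle = 7, walk_counts = 150,
                                            cycle_counts = 100,
                                            still_counts = 50,
                                            rail_corridor_m = 50)) {
  th <- thresholds
  v <- features$median_speed
  mode <- rep("stationary", nrow(features))
  noise_still <- v >= th$v_still & v < th$v_walk &
    features$counts_win < th$still_counts
  band_walk <- v >= th$v_still & v < th$v_walk & !noise_still
  band_cycle <- v >= th$v_walk & v < th$v_cycle
  fast <- v >= th$v_cycle
  mode[band_walk] <- ifelse(features$counts[band_walk] >= th$walk_counts,
                            "walking", "vehicle")
  mode[band_cycle] <- ifelse(features$counts[band_cycle] >= th$cycle_counts,
                             "cycling", "vehicle")
  mode[fast] <- ifelse(features$rail_dist[fast] <= th$rail_corridor_m,
                       "overground_train", "vehicle")
  out <- features[intersect(c("id", "wave", "timestamp"), names(features))]
  out$mode <- factor(mode, MS_EPOCH_MODES)
  out$source <- "rule"
  out
}
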