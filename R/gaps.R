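#' Find GPS signal-loss gaps
#'
#' A gap is a maximal run of consecutive worn epochs without fixes, bounded
#' by fix-bearing epochs on both sides (runs touching the start or end of the
#' record are not emitted).  Duration is measured between the bounding
#' fixes' epoch timestamps; only gaps of at least `min_gap_s` are returned.
#'
#' @param epochs Epoch records from [fuse_epochs()] for one
#'   participant-wave.
#' @param min_gap_s Minimum gap duration, seconds (default 120, the lower
#'   bound of the underground rule).
#' @return Data frame, one row per gap: `start`, `end` (bounding-fix
#'   timestamps), `duration_min`, `start_x/y`, `end_x/y`.
#' @export
find_gaps <- function(epochs, min_gap_s = 120) {
  worn <- epochs[epochs$worn, , drop = FALSE]
  empty <- data.frame(start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      duration_min = numeric(0), start_x = numeric(0),
                      start_y = numeric(0), end_x = numeric(0),
                      end_y = numeric(0))
  if (!nrow(worn)) return(empty)
  r <- rle(!worn$has_fix)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- empty
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    if (starts[k] == 1 || ends[k] == nrow(worn)) next  # unbounded
    i0 <- starts[k] - 1
    i1 <- ends[k] + 1
    dur_s <- as.numeric(worn$timestamp[i1]) - as.numeric(worn$timestamp[i0])
    if (dur_s < min_gap_s) next
    out <- rbind(out, data.frame(
      start = worn$timestamp[i0], end = worn$timestamp[i1],
      duration_min = dur_s / 60,
      start_x = worn$x[i0], start_y = worn$y[i0],
      end_x = worn$x[i1], end_y = worn$y[i1]))
  }
  rownames(out) <- NULL
  out
}

#' Classify qualifying signal gaps as underground travel
#'
#' A gap is underground when its duration lies in `[2 min, 2 h]` (inclusive)
#' and its endpoints satisfy the station condition: under
#' `"both_endpoints_distinct"` (the default, per the stricter published
#' footnote) the signal must be lost within 200 m of an underground station
#' and regained within 200 m of a *different* underground station; under
#' `"either_endpoint"` it suffices that either endpoint is within 200 m of
#' any station.
#'
#' @param gaps From [find_gaps()].
#' @param stations Underground-station points (`x`, `y`).
#' @param mode Endpoint condition switch.
#' @param radius_m Station proximity (200 m, inclusive).
#' @param min_min,max_min Duration bounds in minutes (2 and 120, inclusive).
#' @return `gaps` with `start_station_dist`, `end_station_dist` and logical
#'   `underground` appended.  An empty station layer flags nothing, with a
#'   warning.
#' @export
classify_underground <- function(gaps, stations,
                                 mode = c("both_endpoints_distinct",
                                          "either_endpoint"),
                                 radius_m = 200, min_min = 2,
                                 max_min = 120) {
  mode <- match.arg(mode)
  gaps$start_station_dist <- gaps$end_station_dist <- NA_real_
  gaps$underground <- FALSE
  if (!nrow(gaps)) return(gaps)
  if (is.null(stations) || !nrow(stations)) {
    warning("empty underground-station layer: no gaps flagged",
            call. = FALSE)
    return(gaps)
  }
  dur_ok <- gaps$duration_min >= min_min & gaps$duration_min <= max_min
  for (i in seq_len(nrow(gaps))) {
    ds <- sqrt((stations$x - gaps$start_x[i])^2 +
                 (stations$y - gaps$start_y[i])^2)
    de <- sqrt((stations$x - gaps$end_x[i])^2 +
                 (stations$y - gaps$end_y[i])^2)
    gaps$start_station_dist[i] <- min(ds)
    gaps$end_station_dist[i] <- min(de)
    if (!dur_ok[i]) next
    near_s <- which(ds <= radius_m)
    near_e <- which(de <= radius_m)
    gaps$underground[i] <- if (mode == "either_endpoint")
      length(near_s) > 0 || length(near_e) > 0
    else
      length(near_s) > 0 && length(near_e) > 0 &&
        length(union(near_s, near_e)) >= 2 &&
        any(outer(near_s, near_e, "!="))
  }
  gaps
}

# minutes of flagged gaps attributed to each calendar day (split at
# midnight UTC)
gap_minutes_by_day <- function(gaps) {
  flagged <- gaps[gaps$underground, , drop = FALSE]
  if (!nrow(flagged))
    return(data.frame(date = as.Date(character()), minutes = numeric(0)))
  out <- list()
  for (i in seq_len(nrow(flagged))) {
    t0 <- as.numeric(flagged$start[i])
    t1 <- as.numeric(flagged$end[i])
    while (t0 < t1) {
      day_end <- (floor(t0 / 86400) + 1) * 86400
      seg_end <- min(t1, day_end)
      out[[length(out) + 1]] <- data.frame(
        date = as.Date(as.POSIXct(t0, tz = "UTC", origin = "1970-01-01")),
        minutes = (seg_end - t0) / 60)
      t0 <- seg_end
    }
  }
  agg <- do.call(rbind, out)
  stats::aggregate(minutes ~ date, agg, sum)
}
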