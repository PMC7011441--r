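#' Read GPS fixes (GPX 1.1 or delimited table)
#'
#' Accepts a GPX 1.1 track file or a delimited table with columns
#' `id, wave, timestamp, lat, lon` (ISO-8601 UTC timestamps).  Fixes are
#' sorted by time, duplicate timestamps are collapsed to the first occurrence
#' (a message reports the count), and coordinates are projected to the
#' working planar CRS.  Unparseable records are skipped with a logged count.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"gpx"` or `"delim"`.
#' @param sep Field separator for delimited input.
#' @return Data frame `timestamp` (POSIXct UTC), `lon`, `lat`, `x`, `y`,
#'   plus `id`/`wave` when present in the input.
#' @export
read_gps <- function(path, format = c("auto", "gpx", "delim"), sep = ",") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read GPS file: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.gpx$", path, ignore.case = TRUE)) "gpx" else
      "delim"
  if (format == "gpx") {
    doc <- xml2::read_xml(path)
    pts <- xml2::xml_find_all(doc, ".//*[local-name()='trkpt']")
    if (!length(pts)) {
      warning("no trackpoints in ", path, call. = FALSE)
      return(data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
                        lon = numeric(0), lat = numeric(0),
                        x = numeric(0), y = numeric(0)))
    }
    lat <- as.numeric(xml2::xml_attr(pts, "lat"))
    lon <- as.numeric(xml2::xml_attr(pts, "lon"))
    tstr <- xml2::xml_text(
      xml2::xml_find_first(pts, ".//*[local-name()='time']"))
    tt <- as.POSIXct(tstr, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    d <- data.frame(timestamp = tt, lon = lon, lat = lat)
  } else {
    d <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
    if (!nrow(d)) {
      warning("empty GPS table: ", path, call. = FALSE)
      return(data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
                        lon = numeric(0), lat = numeric(0),
                        x = numeric(0), y = numeric(0)))
    }
    d$timestamp <- as.POSIXct(d$timestamp, tz = "UTC",
                              tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                             "%Y-%m-%d %H:%M:%S"))
    d$lat <- as.numeric(d$lat)
    d$lon <- as.numeric(d$lon)
  }
  bad <- is.na(d$timestamp) | is.na(d$lat) | is.na(d$lon)
  if (any(bad)) {
    message(sum(bad), " unparseable GPS record(s) skipped")
    d <- d[!bad, ]
  }
  d <- d[order(d$timestamp), ]
  dup <- duplicated(d$timestamp)
  if (any(dup)) {
    message(sum(dup), " duplicate-timestamp fix(es) collapsed to the first")
    d <- d[!dup, ]
  }
  xy <- project_lonlat(d$lon, d$lat)
  d$x <- xy[, "x"]; d$y <- xy[, "y"]
  rownames(d) <- NULL
  d
}

#' Read accelerometer epochs (delimited table)
#'
#' Columns `id, wave, timestamp, axis1, vm` (vector-magnitude counts per
#' 10-s epoch).
#'
#' @param path File path.
#' @param sep Field separator.
#' @return Data frame sorted by time with POSIXct UTC timestamps.
#' @export
read_accel <- function(path, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  d$timestamp <- as.POSIXct(d$timestamp, tz = "UTC",
                            tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                           "%Y-%m-%d %H:%M:%S"))
  d[order(d$timestamp), ]
}

#' Fuse GPS fixes and accelerometer epochs into 10-s records
#'
#' Builds one record per 10-s slot (aligned to midnight local time, half-open
#' `[t, t+10)`) from the first to the last accelerometer epoch.  A fix is
#' attached to the slot containing its timestamp; speed is planar distance
#' from the previously attached fix divided by the inter-fix time.
#'
#' @param fixes From [read_gps()] (columns `timestamp`, `x`, `y`).
#' @param accel From [read_accel()] (columns `timestamp`, counts in `vm` or
#'   `axis1`).
#' @param epoch_s Epoch length, seconds (default 10).
#' @return Epoch-record data frame: `timestamp`, `counts`, `x`, `y`,
#'   `has_fix`, `speed` (m/s; present only on fix-bearing epochs that have a
#'   previous fix to difference against), `worn`.
#' @export
fuse_epochs <- function(fixes, accel, epoch_s = 10) {
  if (!nrow(accel))
    return(data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
                      counts = numeric(0), x = numeric(0), y = numeric(0),
                      has_fix = logical(0), speed = numeric(0),
                      worn = logical(0)))
  counts_col <- if ("vm" %in% names(accel)) "vm" else "axis1"
  t0 <- as.numeric(min(accel$timestamp))
  t1 <- as.numeric(max(accel$timestamp))
  slot0 <- floor(t0 / epoch_s) * epoch_s
  slots <- seq(slot0, floor(t1 / epoch_s) * epoch_s, by = epoch_s)
  rec <- data.frame(timestamp = as.POSIXct(slots, tz = "UTC",
                                           origin = "1970-01-01"))
  ai <- floor(as.numeric(accel$timestamp) / epoch_s) * epoch_s
  csum <- tapply(accel[[counts_col]], ai, sum)
  rec$counts <- as.numeric(csum[as.character(slots)])
  rec$counts[is.na(rec$counts)] <- 0
  rec$x <- rec$y <- NA_real_
  rec$has_fix <- FALSE
  if (nrow(fixes)) {
    fi <- floor(as.numeric(fixes$timestamp) / epoch_s) * epoch_s
    keep <- !duplicated(fi) & fi >= slot0 & fi <= max(slots)
    idx <- match(fi[keep], slots)
    rec$x[idx] <- fixes$x[keep]
    rec$y[idx] <- fixes$y[keep]
    rec$has_fix[idx] <- TRUE
  }
  rec$speed <- NA_real_
  fidx <- which(rec$has_fix)
  if (length(fidx) > 1) {
    dx <- diff(rec$x[fidx]); dy <- diff(rec$y[fidx])
    dt <- diff(slots[fidx])
    rec$speed[fidx[-1]] <- sqrt(dx^2 + dy^2) / dt
  }
  rec$worn <- TRUE
  rec
}

#' Mark non-wear epochs
#'
#' Flags `worn = FALSE` for epochs inside zero-count bouts of at least
#' `nonwear_min` consecutive minutes (the same rule [wear_time()] uses), so
#' device-off periods are excluded from classification and gap detection.
#'
#' @param epochs From [fuse_epochs()].
#' @param nonwear_min Minimum zero-count bout length in minutes.
#' @return `epochs` with the `worn` flag updated.
#' @export
mark_nonwear <- function(epochs, nonwear_min = 60) {
  if (!nrow(epochs)) return(epochs)
  minute <- floor(as.numeric(epochs$timestamp) / 60)
  zero_min <- tapply(epochs$counts, minute, function(z) all(z == 0))
  r <- rle(as.logical(zero_min))
  bad <- rep(r$values & r$lengths >= nonwear_min, r$lengths)
  bad_minutes <- as.numeric(names(zero_min))[bad]
  epochs$worn <- !(minute %in% bad_minutes)
  epochs
}

#' Wear time and valid-day flag for one calendar day
#'
#' Wear minutes are minutes of the day covered by the accelerometer stream
#' and not inside a non-wear bout, defined (Troiano-style, config-exposed) as
#' `>= nonwear_min` consecutive minutes of zero counts.  A day is valid with
#' `>= 540` wear minutes.
#'
#' @param epochs Epoch records from [fuse_epochs()].
#' @param date A `Date` (records are filtered to it, UTC).
#' @param nonwear_min Minimum zero-count bout length counting as non-wear.
#' @param valid_min Wear minutes required for a valid day (540).
#' @return One-row data frame `date`, `accel_wear_min`, `gps_min`, `valid`.
#' @export
wear_time <- function(epochs, date, nonwear_min = 60, valid_min = 540) {
  day <- epochs[as.Date(epochs$timestamp, tz = "UTC") == date, ]
  if (!nrow(day))
    return(data.frame(date = date, accel_wear_min = 0, gps_min = 0,
                      valid = FALSE))
  minute <- floor(as.numeric(day$timestamp) / 60)
  zero_min <- tapply(day$counts, minute, function(z) all(z == 0))
  r <- rle(as.logical(zero_min))
  nonwear <- sum(r$lengths[r$values & r$lengths >= nonwear_min])
  wear <- length(zero_min) - nonwear
  data.frame(date = date, accel_wear_min = wear,
             gps_min = sum(day$has_fix) * 10 / 60,
             valid = wear >= valid_min)
}

#' Retain participant-days whose accelerometry is valid
#'
#' A day's GPS data is retained if and only if that day has >= 540 valid
#' accelerometer wear minutes; a valid accelerometer day with no GPS fixes is
#' retained with `gps_min = 0` (the inclusion rule conditions only on
#' accelerometry).
#'
#' @param validity Data frame of per-day [wear_time()] rows, optionally with
#'   `id`/`wave` columns.
#' @return The valid rows only.
#' @export
filter_valid_days <- function(validity) {
  validity[validity$valid, , drop = FALSE]
}
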