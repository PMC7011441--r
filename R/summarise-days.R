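#' Sum labelled epochs and flagged gaps into day profiles
#'
#' Converts 10-s epoch labels to daily minutes per motion category for the
#' valid days only.  Epochs falling strictly inside a flagged underground
#' gap are re-assigned from stationary to underground travel, so gap minutes
#' are never double-counted and total time is conserved.  Walking + cycling
#' is reported as `active_travel`; `total_gps_min` is the sum of the six
#' categories.
#'
#' @param labels Epoch labels from [classify()] with `id`, `wave`,
#'   `timestamp`, `mode`.
#' @param gaps Flagged gaps from [classify_underground()] with `id`, `wave`
#'   columns (the pipeline adds them).
#' @param validity Per-day validity table with `id`, `wave`, `date`,
#'   `valid`; only valid days are profiled.
#' @return Day-profile data frame, one row per valid participant-wave-day,
#'   with the six category columns, `active_travel`, `total_gps_min`,
#'   `day_order`, `day_of_week`, `month`, `weekend`.
#' @export
summarise_days <- function(labels, gaps, validity) {
  stopifnot(all(c("id", "wave", "timestamp", "mode") %in% names(labels)))
  labels$date <- as.Date(labels$timestamp, tz = "UTC")
  labels$category <- as.character(labels$mode)
  if (!is.null(gaps) && nrow(gaps)) {
    flagged <- gaps[gaps$underground, , drop = FALSE]
    for (i in seq_len(nrow(flagged))) {
      inside <- labels$id == flagged$id[i] &
        labels$wave == flagged$wave[i] &
        labels$timestamp > flagged$start[i] &
        labels$timestamp < flagged$end[i]
      if ("has_fix" %in% names(labels) && any(labels$has_fix[inside]))
        stop("internal error: fix-bearing epoch inside a flagged gap",
             call. = FALSE)
      labels$category[inside] <- "underground_train"
    }
  }
  vd <- validity[validity$valid, c("id", "wave", "date"), drop = FALSE]
  key <- paste(labels$id, labels$wave, labels$date)
  vkey <- paste(vd$id, vd$wave, vd$date)
  labels <- labels[key %in% vkey, , drop = FALSE]
  out <- list()
  for (k in vkey) {
    sel <- labels[paste(labels$id, labels$wave, labels$date) == k, ]
    if (!nrow(sel)) next
    row <- data.frame(id = sel$id[1], wave = sel$wave[1], date = sel$date[1],
                      stringsAsFactors = FALSE)
    for (cat_ in MS_CATEGORIES)
      row[[cat_]] <- sum(sel$category == cat_) * 10 / 60
    out[[length(out) + 1]] <- row
  }
  prof <- do.call(rbind, out)
  if (is.null(prof)) return(NULL)
  prof$active_travel <- prof$walking + prof$cycling
  prof$total_gps_min <- rowSums(prof[MS_CATEGORIES])
  ord <- order(prof$id, prof$wave, prof$date)
  prof <- prof[ord, ]
  prof$day_order <- stats::ave(seq_len(nrow(prof)),
                               paste(prof$id, prof$wave),
                               FUN = seq_along)
  prof$day_of_week <- weekdays(prof$date, abbreviate = TRUE)
  prof$month <- format(prof$date, "%b")
  prof$weekend <- prof$day_of_week %in% c("Sat", "Sun")
  rownames(prof) <- NULL
  prof
}
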