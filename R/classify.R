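#' Label every worn epoch with a motion category
#'
#' Computes window features and applies either the fitted gradient-boosted
#' model or the deterministic rule classifier.  Worn epochs with no GPS fix
#' anywhere in their window carry no features and are labelled stationary;
#' re-assigning qualifying signal-loss intervals to underground travel is the
#' job of [find_gaps()] / [classify_underground()].
#'
#' @param epochs Epoch records from [fuse_epochs()].
#' @param model A `ms_gbt` from [train_model()], or `"rule"`.
#' @param rail_edges Rail segments for the corridor feature.
#' @param window_s Feature window (s).
#' @param thresholds Rule thresholds, see [rule_classify()].
#' @return Label data frame aligned to worn epochs: `timestamp`, `mode`,
#'   `source`.
#' @export
classify <- function(epochs, model = "rule", rail_edges = NULL,
                     window_s = 60, thresholds = NULL) {
  worn <- epochs[epochs$worn, , drop = FALSE]
  if (!nrow(worn))
    return(data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
                      mode = factor(character(), MS_EPOCH_MODES),
                      source = character()))
  feats <- extract_features(worn, rail_edges, window_s)
  if (identical(model, "rule")) {
    lab <- if (is.null(thresholds)) rule_classify(feats) else
      rule_classify(feats, thresholds)
    src <- "rule"
  } else {
    if (!inherits(model, "ms_gbt"))
      stop("model must be 'rule' or a trained ms_gbt", call. = FALSE)
    lab <- feats[intersect(c("id", "wave", "timestamp"), names(feats))]
    lab$mode <- factor(as.character(predict(model, feats)), MS_EPOCH_MODES)
    lab$source <- "model"
    src <- "model"
  }
  out <- worn[intersect(c("id", "wave", "timestamp"), names(worn))]
  i <- match(as.numeric(out$timestamp), as.numeric(lab$timestamp))
  out$mode <- lab$mode[i]
  out$source <- ifelse(is.na(i), src, lab$source[i])
  out$mode[is.na(i)] <- "stationary"
  out
}

#' Absorb short label runs into their longer neighbour
#'
#' Repeatedly takes the shortest run below `min_run_s` (earliest first on
#' ties) and merges it into the longer of its two neighbouring runs (earlier
#' neighbour on ties), until every run is at least `min_run_s` or one run
#' remains.  The procedure is deterministic and idempotent.
#'
#' @param labels Label data frame from [classify()] (consecutive epochs).
#' @param min_run_s Minimum run length in seconds, a multiple of 10
#'   (default 30).
#' @param epoch_s Epoch length (s).
#' @return `labels` with short runs re-assigned and `source = "smoothed"`
#'   on changed rows.
#' @export
smooth_labels <- function(labels, min_run_s = 30, epoch_s = 10) {
  if (min_run_s %% epoch_s != 0)
    stop("min_run_s must be a multiple of the epoch length", call. = FALSE)
  if (!nrow(labels)) return(labels)
  m <- as.character(labels$mode)
  min_len <- min_run_s / epoch_s
  repeat {
    r <- rle(m)
    if (length(r$lengths) <= 1) break
    short <- which(r$lengths < min_len)
    if (!length(short)) break
    s <- short[which.min(r$lengths[short])]
    left_len <- if (s > 1) r$lengths[s - 1] else -1
    right_len <- if (s < length(r$lengths)) r$lengths[s + 1] else -1
    take <- if (left_len >= right_len) s - 1 else s + 1
    ends <- cumsum(r$lengths)
    idx <- (ends[s] - r$lengths[s] + 1):ends[s]
    m[idx] <- r$values[take]
  }
  changed <- m != as.character(labels$mode)
  labels$mode <- factor(m, levels(labels$mode))
  labels$source[changed] <- "smoothed"
  labels
}
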