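#' Residual-adjusted average daily minutes for one wave and category
#'
#' Fits a two-level day-within-individual model: daily minutes regressed on
#' day-order-of-wear, day-of-week and month as fixed effects with a
#' participant random intercept.  Each participant's estimate is the grand
#' population mean (mean of the fixed-effects predictions over all observed
#' days) plus the mean of that participant's residuals from the fixed-effects
#' prediction.  This removes imbalance in which weekdays or months a
#' participant happened to wear the devices while averaging residuals to
#' exactly zero over the cohort.
#'
#' Fixed-effect factors that are constant in the data (e.g. month within a
#' one-week wear window) are dropped automatically.  A singular or failed
#' mixed fit falls back to the fixed-effects-only linear model with a
#' warning.  Negative adjusted estimates are floored at zero; the number
#' floored is reported via `attr(, "n_floored")`.
#'
#' @param days Day-profile rows for a single wave.
#' @param category Column name of the daily outcome (one of
#'   [MS_CATEGORIES] or `"active_travel"`, `"total_gps_min"`).
#' @return Data frame `id`, `estimate` (min/day), with attribute
#'   `n_floored`.
#' @export
adjusted_daily_average <- function(days, category) {
  stopifnot(category %in% names(days), "id" %in% names(days))
  if (length(unique(days$id)) < 2)
    stop("need >= 2 participants", call. = FALSE)
  d <- data.frame(id = days$id, y = days[[category]],
                  day_order = factor(days$day_order),
                  day_of_week = factor(days$day_of_week),
                  month = factor(days$month))
  terms <- c("day_order", "day_of_week", "month")
  terms <- terms[vapply(d[terms], function(f) nlevels(droplevels(f)) > 1,
                        logical(1))]
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fixed_fml <- stats::as.formula(paste("y ~", rhs))
  fe_pred <- NULL
  if (length(terms)) {
    fit <- tryCatch(
      lme4::lmer(stats::as.formula(paste("y ~", rhs, "+ (1 | id)")),
                 data = d, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE)),
      error = function(e) NULL)
    if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-5)) {
      X <- stats::model.matrix(fixed_fml, d)
      cf <- lme4::fixef(fit)  # rank-deficient columns are dropped by lmer
      fe_pred <- drop(X[, names(cf), drop = FALSE] %*% cf)
    } else {
      warning("singular or failed day-level mixed fit for '", category,
              "'; using fixed-effects-only fallback", call. = FALSE)
    }
  }
  if (is.null(fe_pred)) fe_pred <- stats::fitted(stats::lm(fixed_fml, d))
  grand <- mean(fe_pred)
  res <- d$y - fe_pred
  est <- grand + tapply(res, d$id, mean)
  n_floored <- sum(est < 0)
  if (n_floored > 0)
    message(n_floored, " adjusted '", category,
            "' estimate(s) floored at 0")
  out <- data.frame(id = names(est), estimate = pmax(unname(est), 0),
                    stringsAsFactors = FALSE)
  attr(out, "n_floored") <- n_floored
  out
}

#' Per-participant wave summaries for all categories
#'
#' Applies [adjusted_daily_average()] (or a plain day mean) per wave and
#' category and returns a wide table with one row per participant-wave.
#' `method = "mean"` is exact under a balanced design with no day-of-week or
#' month effects and is used by large replicate studies for speed.
#'
#' @param day_profiles Day-profile data frame covering one or both waves.
#' @param categories Outcome columns to summarise.
#' @param method `"adjusted"` (residual-adjusted, the analysis default) or
#'   `"mean"` (raw day mean).
#' @return Data frame `id`, `wave`, one column per category.
#' @export
wave_summaries <- function(day_profiles,
                           categories = c(MS_CATEGORIES, "active_travel"),
                           method = c("adjusted", "mean")) {
  method <- match.arg(method)
  out <- NULL
  for (w in intersect(MS_WAVES, unique(day_profiles$wave))) {
    dw <- day_profiles[day_profiles$wave == w, ]
    ids <- sort(unique(dw$id))
    res <- data.frame(id = ids, wave = w, stringsAsFactors = FALSE)
    for (k in categories) {
      if (method == "adjusted") {
        a <- adjusted_daily_average(dw, k)
        res[[k]] <- a$estimate[match(ids, a$id)]
      } else {
        m <- tapply(dw[[k]], dw$id, mean)
        res[[k]] <- pmax(unname(m[match(ids, names(m))]), 0)
      }
    }
    out <- rbind(out, res)
  }
  rownames(out) <- NULL
  out
}
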