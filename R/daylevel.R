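#' Day-level synthetic day profiles (statistical-recovery generator)
#'
#' Bypasses diaries and sensors: draws per participant-wave-day minutes for
#' each motion category directly from the additive model
#' `mean + household + person + day noise + (group x wave) true effect`,
#' truncating negatives at zero.  Household and person effects are shared
#' across waves so the change model's clustering structure is mirrored; the
#' injected effect applies to East Village participants at follow-up only
#' (optionally restricted to weekdays or weekend days).
#'
#' @param cohort From [generate_cohort()].
#' @param config An [sim_config()]; `fidelity` must be `"day"`.
#' @return Day-profile data frame: one row per participant-wave-day with the
#'   six category minute columns, `active_travel`, `total_gps_min`,
#'   `day_order`, `date`, `day_of_week`, `month`, `weekend`, plus cohort
#'   covariates.
#' @export
generate_day_level <- function(cohort, config) {
  stopifnot(inherits(config, "ms_config"))
  if (config$fidelity != "day")
    stop("generate_day_level requires fidelity = 'day'", call. = FALSE)
  n_p <- nrow(cohort)
  hh <- as.integer(factor(cohort$household))
  n_h <- max(hh)
  nd <- config$wear_days
  mu <- config$category_means
  withr::with_seed(config$seed + 2000L, {
    b_house <- sapply(MS_CATEGORIES, function(k)
      stats::rnorm(n_h, 0, config$cv_household * mu[k]))
    b_house_wave <- lapply(MS_WAVES, function(w) sapply(
      MS_CATEGORIES, function(k)
        stats::rnorm(n_h, 0, config$cv_household_wave * mu[k])))
    names(b_house_wave) <- MS_WAVES
    b_pers <- sapply(MS_CATEGORIES, function(k)
      stats::rnorm(n_p, 0, config$cv_person * mu[k]))

    idx_p <- rep(seq_len(n_p), each = 2L * nd)
    wave <- rep(rep(MS_WAVES, each = nd), n_p)
    day_order <- rep(rep(seq_len(nd), 2L), n_p)
    # wear weeks two years apart; start weekday staggered across participants
    start0 <- as.Date(ifelse(wave == "baseline", "2014-05-05", "2016-05-02"))
    date <- start0 + (idx_p - 1L) %% 7L + day_order - 1L
    dow <- weekdays(date, abbreviate = TRUE)
    weekend <- dow %in% c("Sat", "Sun")

    n_row <- length(idx_p)
    eff_on <- cohort$group[idx_p] == "EastVillage" & wave == "followup"
    if (config$effect_days == "weekday") eff_on <- eff_on & !weekend
    if (config$effect_days == "weekend") eff_on <- eff_on & weekend

    out <- data.frame(id = cohort$id[idx_p], wave = wave,
                      day_order = day_order, date = date,
                      day_of_week = dow, month = format(date, "%b"),
                      weekend = weekend, stringsAsFactors = FALSE)
    te <- config$true_effects
    for (k in MS_CATEGORIES) {
      eff_k <- if (is.matrix(te))
        te[as.character(cohort$housing_group[idx_p]), k] else te[[k]]
      bw <- ifelse(wave == "baseline",
                   b_house_wave$baseline[hh[idx_p], k],
                   b_house_wave$followup[hh[idx_p], k])
      y <- mu[[k]] + b_house[hh[idx_p], k] + bw + b_pers[idx_p, k] +
        stats::rnorm(n_row, 0, config$cv_day * mu[[k]]) +
        eff_k * eff_on
      out[[k]] <- pmax(y, 0)
    }
    out$active_travel <- out$walking + out$cycling
    out$total_gps_min <- rowSums(out[MS_CATEGORIES])
    cov_cols <- c("household", "group", "housing_group", "sex", "age_group",
                  "ethnic_group", "working_studying")
    out[cov_cols] <- cohort[idx_p, cov_cols]
    out
  })
}

# analytic mean of max(N(mu, sd), 0); oracle for truncation bias in tests
truncated_mean <- function(mu, sd) {
  if (sd == 0) return(max(mu, 0))
  z <- mu / sd
  sd * stats::dnorm(z) + mu * stats::pnorm(z)
}
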