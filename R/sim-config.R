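#' Default motion-category means (min/day)
#'
#' Average daily minutes per motion category used as the synthetic-world
#' defaults.  Values are the all-housing Control-group baseline means from the
#' source cohort's descriptive table: walking 39.7, cycling 6.1, motorised
#' vehicle 37.3, overground train 14.6, underground train 14.3, stationary
#' 440 (totalling 552 GPS minutes/day).
#'
#' @return Named numeric vector over [MS_CATEGORIES].
#' @export
default_category_means <- function() {
  c(walking = 39.7, cycling = 6.1, vehicle = 37.3,
    overground_train = 14.6, underground_train = 14.3, stationary = 440)
}

#' Default true intervention effects (min/day difference in change)
#'
#' East Village minus Control difference in baseline-to-follow-up change per
#' motion category, used as the generator's injected truth.  Defaults are the
#' published all-housing change-model estimates; `which = "stratum"` returns
#' the housing-group-stratified estimates as a 3 x 6 matrix (rows social,
#' intermediate, market-rent).
#'
#' @param which `"all"` for the all-housing vector, `"stratum"` for the
#'   stratum matrix, `"zero"` for a null configuration.
#' @return Named numeric vector (length 6) or 3 x 6 numeric matrix.
#' @export
default_true_effects <- function(which = c("all", "stratum", "zero")) {
  which <- match.arg(which)
  all_eff <- c(walking = -1.4, cycling = 1.1, vehicle = -8.3,
               overground_train = -0.8, underground_train = 3.9,
               stationary = -247)
  if (which == "all") return(all_eff)
  if (which == "zero") return(all_eff * 0)
  m <- rbind(
    social         = c(-1.8, 0.3, -6.2, -1.7, 4.0, -354),
    intermediate   = c(-1.9, 1.0, -9.6, -1.5, 1.6, -205),
    `market-rent`  = c(-4.2, 1.9, -6.9, 0.2, 11.5, -127))
  colnames(m) <- MS_CATEGORIES
  m
}

#' Synthetic-world configuration
#'
#' Builds and validates the configuration object shared by all generators.
#' Day-level noise standard deviations are expressed as coefficients of
#' variation relative to each category mean; the defaults (household 0.10,
#' person 0.20, day-to-day 0.20, total CV 0.3) keep the zero-truncation mass
#' of the Gaussian day model negligible so generated means match the stated
#' category means.  Mode speeds and per-10-s accelerometer count levels are
#' config-exposed because the measurement protocol does not state them.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param n_participants,n_households Cohort size; `n_households <=
#'   n_participants`.
#' @param fidelity `"day"` (statistical-recovery generator) or `"epoch"`
#'   (full diary + sensor emulation).
#' @param wear_days Wear days per wave (1-7).
#' @param true_effects Named vector over [MS_CATEGORIES], or a 3 x 6 matrix
#'   with rows `social`, `intermediate`, `market-rent` for stratum-specific
#'   effects.  Minutes/day difference in change, East Village - Control.
#' @param effect_days `"all"`, `"weekday"` or `"weekend"`: which days the
#'   injected effect applies to (targeted simulations).
#' @param category_means Named vector of baseline daily minutes per category.
#' @param cv_household,cv_household_wave,cv_person,cv_day Noise CVs
#'   (sd = cv * category mean) for the stable household component, the
#'   household-by-wave component (households relocate together, so their
#'   changes co-vary; this keeps the change model's household variance
#'   positive), the stable person component, and day-to-day noise.
#' @param housing_n Participant counts per housing group used as mixing
#'   proportions (defaults 201/283/94).
#' @param ev_frac_by_housing Probability a household in each housing group is
#'   in the East Village (mover) group.
#' @param speeds_kmh List of `c(min, max)` cruise-speed ranges per mode.
#' @param count_means Mean accelerometer counts per 10-s epoch by mode.
#' @param count_cv Lognormal CV of epoch counts (0 = noiseless).
#' @param gps_noise_sd_m GPS positional noise sd (m).
#' @param indoor_dropout Probability a fix is suppressed while stationary
#'   indoors; underground dropout is always 1.
#' @param day_start_min,day_end_min Waking-day window, minutes after
#'   midnight.
#' @return Object of class `ms_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_participants = 578L,
                       n_households = 400L,
                       fidelity = c("day", "epoch"),
                       wear_days = 7L,
                       true_effects = default_true_effects("all"),
                       effect_days = c("all", "weekday", "weekend"),
                       category_means = default_category_means(),
                       cv_household = 0.10,
                       cv_household_wave = 0.08,
                       cv_person = 0.20,
                       cv_day = 0.20,
                       housing_n = c(social = 201, intermediate = 283,
                                     `market-rent` = 94),
                       ev_frac_by_housing = c(social = 127 / 201,
                                              intermediate = 142 / 283,
                                              `market-rent` = 24 / 94),
                       speeds_kmh = list(walking = c(3, 6),
                                         cycling = c(10, 25),
                                         vehicle = c(15, 60),
                                         train = c(30, 80)),
                       count_means = c(stationary = 20, walking = 500,
                                       cycling = 250, vehicle = 30,
                                       train = 30),
                       count_cv = 0.3,
                       gps_noise_sd_m = 5,
                       indoor_dropout = 0.5,
                       day_start_min = 360,
                       day_end_min = 1320) {
  fidelity <- match.arg(fidelity)
  effect_days <- match.arg(effect_days)
  stopifnot(is.numeric(seed), length(seed) == 1, seed == floor(seed))
  n_participants <- as.integer(n_participants)
  n_households <- as.integer(n_households)
  if (n_households > n_participants)
    stop("n_households must not exceed n_participants", call. = FALSE)
  if (wear_days < 1 || wear_days > 7)
    stop("wear_days must be in 1..7", call. = FALSE)
  if (is.matrix(true_effects)) {
    stopifnot(identical(rownames(true_effects), MS_HOUSING),
              ncol(true_effects) == 6)
    colnames(true_effects) <- MS_CATEGORIES
  } else {
    true_effects <- true_effects[MS_CATEGORIES]
    stopifnot(!anyNA(true_effects))
  }
  category_means <- category_means[MS_CATEGORIES]
  stopifnot(!anyNA(category_means), all(category_means >= 0))
  for (v in c(cv_household, cv_household_wave, cv_person, cv_day))
    if (!is.numeric(v) || v < 0) stop("noise CVs must be >= 0", call. = FALSE)
  if (indoor_dropout < 0 || indoor_dropout > 1)
    stop("indoor_dropout must be a probability", call. = FALSE)
  stopifnot(day_end_min > day_start_min)
  structure(list(
    seed = as.integer(seed), n_participants = n_participants,
    n_households = n_households, fidelity = fidelity,
    wear_days = as.integer(wear_days), true_effects = true_effects,
    effect_days = effect_days, category_means = category_means,
    cv_household = cv_household, cv_household_wave = cv_household_wave,
    cv_person = cv_person, cv_day = cv_day,
    housing_n = housing_n, ev_frac_by_housing = ev_frac_by_housing,
    speeds_kmh = speeds_kmh, count_means = count_means, count_cv = count_cv,
    gps_noise_sd_m = gps_noise_sd_m, indoor_dropout = indoor_dropout,
    underground_dropout = 1,
    day_start_min = day_start_min, day_end_min = day_end_min),
    class = "ms_config")
}

#' @export
print.ms_config <- function(x, ...) {
  cat("<ms_config> seed", x$seed, "|", x$n_participants, "participants in",
      x$n_households, "households |", x$fidelity, "fidelity |",
      x$wear_days, "wear days/wave\n")
  invisible(x)
}

# effect for one housing group as a named length-6 vector
.effects_for_housing <- function(config, housing) {
  te <- config$true_effects
  if (is.matrix(te)) te[housing, ] else te
}
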