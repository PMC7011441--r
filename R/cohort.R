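#' Generate the synthetic cohort
#'
#' Builds participants nested in households.  Group membership (East Village
#' mover vs Control), housing group and addresses are household-level by
#' construction; housing-group sizes follow the configured mixing proportions
#' (defaults 201/283/94 of 578) and the East Village fraction within each
#' housing group follows the configured conditional proportions.  At
#' follow-up, East Village households' addresses lie in the city's designated
#' East Village district; Control households keep their baseline address.
#'
#' @param city A `ms_city` from [generate_city()], or `NULL` for day-fidelity
#'   simulations that need no geography (addresses are then `NA`).
#' @param config An [sim_config()] object.
#' @return Data frame, one row per participant: `id`, `household`, `sex`,
#'   `age_group`, `ethnic_group`, `housing_group`, `group`,
#'   `working_studying`, and address coordinates `home_x/home_y` per wave.
#' @export
generate_cohort <- function(city, config) {
  stopifnot(inherits(config, "ms_config"))
  n_p <- config$n_participants
  n_h <- config$n_households
  withr::with_seed(config$seed + 1000L, {
    # household sizes: start at 1, distribute remaining members (cap 4)
    sizes <- rep(1L, n_h)
    extra <- n_p - n_h
    while (extra > 0L) {
      open <- which(sizes < 4L)
      take <- sample(open, min(extra, length(open)))
      sizes[take] <- sizes[take] + 1L
      extra <- extra - length(take)
    }
    # quota allocation at household level: participant counts per housing
    # group (and the mover fraction within each) match the configured
    # design as closely as household sizes allow, rather than only in
    # expectation
    p_housing <- config$housing_n / sum(config$housing_n)
    quota <- p_housing * n_p
    hh_housing <- character(n_h)
    for (i in sample.int(n_h)) {
      pick <- names(quota)[which.max(quota)]
      hh_housing[i] <- pick
      quota[pick] <- quota[pick] - sizes[i]
    }
    ev_quota <- config$ev_frac_by_housing *
      tapply(sizes, hh_housing, sum)[names(config$ev_frac_by_housing)]
    hh_group <- character(n_h)
    for (i in sample.int(n_h)) {
      g <- hh_housing[i]
      if (ev_quota[g] >= sizes[i] / 2) {
        hh_group[i] <- "EastVillage"
        ev_quota[g] <- ev_quota[g] - sizes[i]
      } else hh_group[i] <- "Control"
    }

    if (!is.null(city)) {
      res <- city$parcels[city$parcels$class == "residential", ]
      ctr <- res[!res$in_ev_district, ]
      evd <- res[res$in_ev_district, ]
      base_idx <- sample(nrow(ctr), n_h, replace = TRUE)
      bx <- (ctr$xmin + ctr$xmax)[base_idx] / 2
      by <- (ctr$ymin + ctr$ymax)[base_idx] / 2
      fu_idx <- sample(nrow(evd), n_h, replace = TRUE)
      fx <- ifelse(hh_group == "EastVillage",
                   (evd$xmin + evd$xmax)[fu_idx] / 2, bx)
      fy <- ifelse(hh_group == "EastVillage",
                   (evd$ymin + evd$ymax)[fu_idx] / 2, by)
    } else {
      bx <- by <- fx <- fy <- rep(NA_real_, n_h)
    }

    hh_of <- rep(seq_len(n_h), sizes)
    # female share differs slightly by group, as observed
    p_f <- ifelse(hh_group[hh_of] == "EastVillage", 0.54, 0.61)
    cohort <- data.frame(
      id = sprintf("P%04d", seq_len(n_p)),
      household = sprintf("H%04d", hh_of),
      sex = ifelse(stats::runif(n_p) < p_f, "female", "male"),
      age_group = sample(c("16-24", "25-34", "35-49", "50+"), n_p,
                         replace = TRUE, prob = c(0.19, 0.43, 0.31, 0.07)),
      ethnic_group = sample(c("White", "Black", "Asian", "Other"), n_p,
                            replace = TRUE, prob = c(0.54, 0.22, 0.15, 0.09)),
      housing_group = hh_housing[hh_of],
      group = hh_group[hh_of],
      working_studying = stats::runif(n_p) <
        ifelse(hh_group[hh_of] == "EastVillage", 0.82, 0.86),
      home_x_baseline = bx[hh_of], home_y_baseline = by[hh_of],
      home_x_followup = fx[hh_of], home_y_followup = fy[hh_of],
      stringsAsFactors = FALSE)
    cohort$sex <- factor(cohort$sex, c("female", "male"))
    cohort$age_group <- factor(cohort$age_group,
                               c("16-24", "25-34", "35-49", "50+"))
    cohort$ethnic_group <- factor(cohort$ethnic_group,
                                  c("White", "Black", "Asian", "Other"))
    cohort$housing_group <- factor(cohort$housing_group, MS_HOUSING)
    cohort$group <- factor(cohort$group, MS_GROUPS)
    cohort
  })
}
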