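#' Cohort flow counts and percentages
#'
#' Tabulates the attrition flow from recruitment to the longitudinal
#' analysis set, with integer percentages (rounded half-up) against each
#' stage's natural denominator: follow-up and baseline-GPS stages against
#' recruited, follow-up GPS and the longitudinal set against those
#' followed up.
#'
#' @param recruited,followed_up,gps_baseline,valid_baseline,gps_followup,valid_followup,longitudinal
#'   Stage counts; any may be `NA` to omit the row.
#' @return Data frame `stage`, `n`, `denominator`, `pct`.
#' @export
cohort_flow <- function(recruited, followed_up, gps_baseline = NA,
                        valid_baseline = NA, gps_followup = NA,
                        valid_followup = NA, longitudinal = NA) {
  rows <- list(
    c("recruited", recruited, recruited),
    c("gps_baseline", gps_baseline, recruited),
    c("valid_baseline", valid_baseline, recruited),
    c("followed_up", followed_up, recruited),
    c("gps_followup", gps_followup, followed_up),
    c("valid_followup", valid_followup, followed_up),
    c("longitudinal", longitudinal, followed_up))
  out <- data.frame(stage = vapply(rows, `[`, character(1), 1),
                    n = as.numeric(vapply(rows, `[`, character(1), 2)),
                    denominator = as.numeric(vapply(rows, `[`,
                                                    character(1), 3)),
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$n), ]
  out$pct <- round_half_up(100 * out$n / out$denominator)
  rownames(out) <- NULL
  out
}

# round half away from zero to integers (presentation rule)
round_half_up <- function(x) trunc(x + sign(x) * 0.5)

#' Baseline characteristics table (Table-1 shape)
#'
#' Counts and percentages per categorical covariate, and mean (sd) per GPS
#' motion category, split by East Village/Control group, with between-group
#' p-values: chi-square for categorical rows, household-clustered mixed-model
#' Wald tests for GPS means (documented choice; the source does not state
#' its tests).  p-values are suppressed when only one group is present.
#'
#' @param summaries Baseline participant summaries from [wave_summaries()].
#' @param covariates Cohort covariate table.
#' @param cat_vars Categorical covariates to tabulate.
#' @return List of `categorical` (long data frame) and `gps` (per-category
#'   mean/sd/p by group).
#' @export
table1 <- function(summaries, covariates,
                   cat_vars = c("age_group", "sex", "ethnic_group")) {
  sb <- summaries[summaries$wave == "baseline", ]
  d <- merge(sb, covariates, by = "id")
  two_groups <- length(unique(d$group)) > 1
  cat_rows <- list()
  for (v in cat_vars) {
    tab <- table(d[[v]], d$group)
    pct <- round_half_up(100 * prop.table(tab, 2))
    p <- if (two_groups && all(dim(tab) > 1))
      tryCatch(suppressWarnings(stats::chisq.test(tab)$p.value),
               error = function(e) NA_real_) else NA_real_
    for (lev in rownames(tab))
      cat_rows[[length(cat_rows) + 1]] <- data.frame(
        variable = v, level = lev,
        n_control = tab[lev, "Control"],
        pct_control = pct[lev, "Control"],
        n_eastvillage = if ("EastVillage" %in% colnames(tab))
          tab[lev, "EastVillage"] else NA,
        pct_eastvillage = if ("EastVillage" %in% colnames(tab))
          pct[lev, "EastVillage"] else NA,
        p = p, stringsAsFactors = FALSE)
  }
  cats <- intersect(c(MS_CATEGORIES, "active_travel", "total_gps_min"),
                    names(sb))
  gps_rows <- lapply(cats, function(k) {
    m <- tapply(d[[k]], d$group, mean)
    s <- tapply(d[[k]], d$group, stats::sd)
    p <- NA_real_
    if (two_groups) {
      fit <- tryCatch(
        lme4::lmer(stats::as.formula(paste(k, "~ group + (1 | household)")),
                   data = d, REML = TRUE,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular =
                                                 "ignore")),
        error = function(e) NULL)
      if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-5)) {
        cf <- lme4::fixef(fit)
        se <- sqrt(diag(as.matrix(stats::vcov(fit))))
      } else {
        lmfit <- stats::lm(stats::as.formula(paste(k, "~ group")), d)
        cf <- stats::coef(lmfit)
        se <- sqrt(diag(stats::vcov(lmfit)))
      }
      p <- 2 * stats::pnorm(-abs(cf[2] / se[2]))
    }
    data.frame(category = k,
               mean_control = unname(m["Control"]),
               sd_control = unname(s["Control"]),
               mean_eastvillage = unname(m["EastVillage"]),
               sd_eastvillage = unname(s["EastVillage"]),
               p = unname(p), stringsAsFactors = FALSE)
  })
  list(categorical = do.call(rbind, cat_rows), gps = do.call(rbind, gps_rows))
}

#' Change-in-environment table (Table-2 shape)
#'
#' Mean baseline-to-follow-up change with a normal-theory 95% CI and
#' one-sample t-test p-value for every exposure variable, by group (and
#' optionally by group x housing group).
#'
#' @param exposures Address-wave exposure table from
#'   [built_env_exposures()] with an `id` column, optionally merged with
#'   perception scores.
#' @param covariates Cohort covariates (for `group`/`housing_group`).
#' @param vars Exposure columns to summarise.
#' @param by_housing Also stratify by housing group.
#' @return Long data frame `variable`, `group`, (`housing_group`), `n`,
#'   `mean_change`, `ci_lo`, `ci_hi`, `p`.
#' @export
table2 <- function(exposures, covariates,
                   vars = c("park_distance_m", "ptal", "walkability",
                            "land_use_mix", "residential_density",
                            "street_connectivity"),
                   by_housing = FALSE) {
  b <- exposures[exposures$wave == "baseline", ]
  f <- exposures[exposures$wave == "followup", ]
  d <- merge(b, f, by = "id", suffixes = c("_b", "_f"))
  d <- merge(d, covariates, by = "id")
  strata <- if (by_housing) split(d, list(d$group, d$housing_group),
                                  drop = TRUE) else split(d, d$group)
  out <- list()
  for (nm in names(strata)) {
    s <- strata[[nm]]
    for (v in vars) {
      ch <- s[[paste0(v, "_f")]] - s[[paste0(v, "_b")]]
      ch <- ch[!is.na(ch)]
      n <- length(ch)
      if (!n) next
      m <- mean(ch)
      se <- if (n > 1) stats::sd(ch) / sqrt(n) else NA
      p <- if (n > 1 && se > 0) 2 * stats::pt(-abs(m / se), n - 1) else NA
      q <- if (n > 1) stats::qt(0.975, n - 1) else NA
      out[[length(out) + 1]] <- data.frame(
        variable = v, stratum = nm, n = n, mean_change = m,
        ci_lo = m - q * se, ci_hi = m + q * se, p = p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
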