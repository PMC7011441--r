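#' Household-clustered change model for one motion category
#'
#' The evaluation model: average daily minutes at follow-up regressed on the
#' baseline average, East Village/Control group, sex, age group, ethnic group
#' and housing group as fixed effects, with a household random intercept.
#' The group coefficient estimates the average within-person change in the
#' East Village group relative to the Control group.  Estimation is REML with
#' Wald 95% confidence intervals.  Factor covariates that are constant in the
#' analysed rows are dropped (so stratified fits automatically drop housing
#' group); a singular household variance triggers a fixed-effects-only
#' fallback with a warning.
#'
#' @param summaries Participant-wave summary table from [wave_summaries()].
#' @param covariates Cohort covariate table (`id`, `household`, `group`,
#'   `sex`, `age_group`, `ethnic_group`, `housing_group`, and optionally
#'   `working_studying`).
#' @param outcome Summary column to model.
#' @param stratum Optional housing group to restrict to (drops the housing
#'   covariate).
#' @param subset_working If `TRUE`, restrict to participants working or
#'   studying at baseline.
#' @return One-row data frame of class `ms_effect`: `outcome`, `stratum`,
#'   `n`, `n_households`, `estimate` (min/day, East Village - Control
#'   difference in change), `se`, `ci_lo`, `ci_hi`, `p`, `method`.  The
#'   fitted model and a residual-normality diagnostic (correlation of the
#'   residual QQ plot) are attached as attributes `model` and `qq_cor`.
#' @export
fit_change_model <- function(summaries, covariates, outcome,
                             stratum = NULL, subset_working = FALSE) {
  d <- .change_data(summaries, covariates, outcome)
  if (!is.null(stratum)) d <- d[d$housing_group == stratum, ]
  if (subset_working) {
    if (!"working_studying" %in% names(d))
      stop("covariates lack working_studying", call. = FALSE)
    d <- d[d$working_studying, ]
  }
  d <- d[stats::complete.cases(d[c("baseline", "followup")]), ]
  if (length(unique(d$household)) < 2)
    stop("need >= 2 households", call. = FALSE)
  if (length(unique(d$group)) < 2)
    stop("both groups required", call. = FALSE)
  fit <- .fit_lmm_change(d)
  .effect_row(fit, d, outcome,
              stratum = if (is.null(stratum)) "all" else stratum)
}

.change_data <- function(summaries, covariates, outcome) {
  sb <- summaries[summaries$wave == "baseline", c("id", outcome)]
  sf <- summaries[summaries$wave == "followup", c("id", outcome)]
  names(sb)[2] <- "baseline"
  names(sf)[2] <- "followup"
  d <- merge(merge(sb, sf, by = "id", all.x = TRUE), covariates, by = "id")
  d$group <- droplevels(factor(d$group, MS_GROUPS))
  d
}

# fixed-effect covariates retained only when they vary in the analysed rows
.change_formula <- function(d, lhs = "followup") {
  cand <- c("group", "sex", "age_group", "ethnic_group", "housing_group")
  keep <- cand[vapply(cand, function(v)
    v %in% names(d) && length(unique(d[[v]])) > 1, logical(1))]
  stats::as.formula(paste(lhs, "~ baseline +", paste(keep, collapse = " + ")))
}

.fit_lmm_change <- function(d) {
  fml <- .change_formula(d)
  mix <- stats::update(fml, . ~ . + (1 | household))
  fit <- tryCatch(
    lme4::lmer(mix, data = d, REML = TRUE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore")),
    error = function(e) NULL)
  if (is.null(fit) || lme4::isSingular(fit, tol = 1e-5)) {
    warning("singular household variance; fixed-effects fallback",
            call. = FALSE)
    fit <- stats::lm(fml, data = d)
  }
  fit
}

.effect_row <- function(fit, d, outcome, stratum) {
  if (inherits(fit, "merMod")) {
    cf <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    method <- "lmm"
    resid_v <- stats::residuals(fit)
  } else {
    cf <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    method <- "lm"
    resid_v <- stats::residuals(fit)
  }
  term <- grep("^groupEastVillage$", names(cf), value = TRUE)
  if (!length(term)) stop("group term missing from fit", call. = FALSE)
  est <- unname(cf[term]); s <- unname(se[term])
  z <- stats::qnorm(0.975)
  qq <- stats::qqnorm(resid_v, plot.it = FALSE)
  out <- data.frame(outcome = outcome, stratum = stratum, n = nrow(d),
                    n_households = length(unique(d$household)),
                    estimate = est, se = s,
                    ci_lo = est - z * s, ci_hi = est + z * s,
                    p = 2 * stats::pnorm(-abs(est / s)),
                    method = method, stringsAsFactors = FALSE)
  class(out) <- c("ms_effect", class(out))
  attr(out, "model") <- fit
  attr(out, "qq_cor") <- stats::cor(qq$x, qq$y)
  out
}

#' Overall and housing-group-stratified effects
#'
#' Fits the change model overall and separately within each housing group.
#' Strata in which only one group or a single household is present are
#' skipped with a warning.
#'
#' @inheritParams fit_change_model
#' @param strata Housing groups to fit (default all three).
#' @return `ms_effect` data frame with rows `all`, then one per stratum.
#' @export
stratified_effects <- function(summaries, covariates, outcome,
                               strata = MS_HOUSING) {
  rows <- list(fit_change_model(summaries, covariates, outcome))
  for (s in strata) {
    r <- tryCatch(fit_change_model(summaries, covariates, outcome,
                                   stratum = s),
                  error = function(e) {
                    warning("stratum '", s, "' skipped: ",
                            conditionMessage(e), call. = FALSE)
                    NULL
                  })
    if (!is.null(r)) rows <- c(rows, list(r))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ms_effect", "data.frame")
  out
}

#' Weekday-only and weekend-only effects
#'
#' Recomputes participant-wave summaries restricted to weekdays or weekend
#' days and refits the change model on each subset.  Participants without any
#' qualifying day at both waves are excluded from that subset (count
#' reported via message).
#'
#' @param day_profiles Day-level profiles covering both waves.
#' @inheritParams fit_change_model
#' @param method Summary method passed to [wave_summaries()].
#' @return `ms_effect` data frame with rows labelled `weekday`/`weekend` in
#'   a `day_filter` column.
#' @export
weekday_weekend <- function(day_profiles, covariates, outcome,
                            method = "adjusted") {
  out <- NULL
  for (f in c("weekday", "weekend")) {
    dp <- day_profiles[if (f == "weekday") !day_profiles$weekend
                       else day_profiles$weekend, ]
    has_both <- names(which(tapply(dp$wave, dp$id,
                                   function(w) length(unique(w)) == 2)))
    dropped <- length(unique(day_profiles$id)) - length(has_both)
    if (dropped > 0)
      message(dropped, " participant(s) without ", f,
              " days at both waves excluded")
    if (!length(has_both)) stop("no participants with ", f,
                                " days at both waves", call. = FALSE)
    summ <- wave_summaries(dp[dp$id %in% has_both, ],
                           categories = outcome, method = method)
    r <- fit_change_model(summ, covariates, outcome)
    r$day_filter <- f
    out <- rbind(out, r)
  }
  class(out) <- c("ms_effect", "data.frame")
  out
}

#' Multiple imputation of missing follow-up outcomes
#'
#' Proper (Bayesian-draw) linear-regression imputation of follow-up averages
#' that are missing while baseline is observed, conditional on the change
#' model's variables; each completed data set is analysed with the
#' household-clustered change model and results are pooled by Rubin's rules.
#' With no missing data every imputation is identical and the pooled result
#' equals the complete-case fit exactly.
#'
#' @inheritParams fit_change_model
#' @param m Number of imputations (default 40).
#' @param seed Integer seed for the imputation draws.
#' @return One-row `ms_effect` data frame with extra columns `m` and
#'   `between_var` (Rubin between-imputation variance).
#' @export
impute_missing_followup <- function(summaries, covariates, outcome,
                                    m = 40L, seed = 1L) {
  if (m < 2) stop("m must be >= 2", call. = FALSE)
  d <- .change_data(summaries, covariates, outcome)
  d <- d[!is.na(d$baseline), ]
  miss <- is.na(d$followup)
  fml <- .change_formula(d)
  withr::with_seed(as.integer(seed), {
    ests <- ses <- numeric(m)
    suppressWarnings(for (i in seq_len(m)) {
      di <- d
      if (any(miss)) {
        fit0 <- stats::lm(fml, data = d[!miss, ])
        X <- stats::model.matrix(stats::delete.response(stats::terms(fit0)),
                                 d[miss, ])
        n0 <- length(stats::residuals(fit0)); p0 <- fit0$rank
        sigma2 <- sum(stats::residuals(fit0)^2) /
          stats::rchisq(1, df = n0 - p0)
        R <- chol(stats::vcov(fit0) / stats::sigma(fit0)^2 * sigma2)
        beta <- stats::coef(fit0) +
          drop(t(R) %*% stats::rnorm(length(stats::coef(fit0))))
        di$followup[miss] <- drop(X %*% beta) +
          stats::rnorm(sum(miss), 0, sqrt(sigma2))
      }
      fit <- .fit_lmm_change(di)
      r <- .effect_row(fit, di, outcome, "all")
      ests[i] <- r$estimate; ses[i] <- r$se
    })
  })
  qbar <- mean(ests)
  B <- if (any(miss)) stats::var(ests) else 0
  W <- mean(ses^2)
  Tv <- W + (1 + 1 / m) * B
  if (B > 0) {
    r <- (1 + 1 / m) * B / W
    df <- (m - 1) * (1 + 1 / r)^2
    p <- 2 * stats::pt(-abs(qbar / sqrt(Tv)), df)
    q <- stats::qt(0.975, df)
  } else {
    p <- 2 * stats::pnorm(-abs(qbar / sqrt(Tv)))
    q <- stats::qnorm(0.975)
  }
  out <- data.frame(outcome = outcome, stratum = "all", n = nrow(d),
                    n_households = length(unique(d$household)),
                    estimate = qbar, se = sqrt(Tv),
                    ci_lo = qbar - q * sqrt(Tv), ci_hi = qbar + q * sqrt(Tv),
                    p = p, method = "mi", m = m, between_var = B,
                    stringsAsFactors = FALSE)
  class(out) <- c("ms_effect", class(out))
  out
}

#' @export
print.ms_effect <- function(x, ...) {
  y <- as.data.frame(x)
  y$estimate <- round(y$estimate, 2)
  y$ci <- sprintf("(%.2f, %.2f)", x$ci_lo, x$ci_hi)
  y$p <- signif(x$p, 2)
  print(y[, c("outcome", "stratum", "n", "estimate", "ci", "p")],
        row.names = FALSE)
  invisible(x)
}
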