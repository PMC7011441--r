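#' Simulate 14-item neighbourhood perception responses
#'
#' Two correlated latent factors (perceived safety-from-crime and
#' neighbourhood quality) drive 7 items each on a 4-point ordinal scale;
#' higher responses always mean a safer / better perception.  East Village
#' participants receive a latent improvement at follow-up.
#'
#' @param cohort From [generate_cohort()].
#' @param seed Integer seed.
#' @param loading Common standardised loading of items on their factor.
#' @param factor_cor Latent inter-factor correlation.
#' @param ev_shift Latent follow-up improvement (sd units) for movers,
#'   `c(crime, quality)`.
#' @return Data frame `id`, `wave`, items `crime1..crime7`,
#'   `quality1..quality7` (integers 1-4).
#' @export
simulate_perception_responses <- function(cohort, seed = 1L, loading = 0.75,
                                          factor_cor = 0.3,
                                          ev_shift = c(1.2, 1.6)) {
  n <- nrow(cohort)
  items <- c(paste0("crime", 1:7), paste0("quality", 1:7))
  withr::with_seed(as.integer(seed) + 6000L, {
    out <- list()
    f_base <- matrix(stats::rnorm(2 * n), n, 2)
    f_base[, 2] <- factor_cor * f_base[, 1] +
      sqrt(1 - factor_cor^2) * f_base[, 2]
    for (w in MS_WAVES) {
      f <- f_base
      if (w == "followup") {
        mv <- cohort$group == "EastVillage"
        f[mv, 1] <- f[mv, 1] + ev_shift[1]
        f[mv, 2] <- f[mv, 2] + ev_shift[2]
        f <- f + matrix(stats::rnorm(2 * n, 0, 0.5), n, 2)
      }
      lat <- cbind(f[, rep(1, 7)], f[, rep(2, 7)]) * loading +
        matrix(stats::rnorm(14 * n, 0, sqrt(1 - loading^2)), n, 14)
      resp <- matrix(cut(lat, c(-Inf, -1, 0, 1, Inf), labels = FALSE),
                     n, 14)
      d <- data.frame(id = cohort$id, wave = w)
      d[items] <- as.data.frame(resp)
      out[[w]] <- d
    }
    do.call(rbind, c(out, make.row.names = FALSE))
  })
}

#' Fit the baseline perception factor model
#'
#' Exploratory factor analysis (maximum likelihood, two factors, oblique
#' promax rotation) on the 14 baseline items.  Factors are named by which
#' item group (crime vs quality) carries the larger absolute loading mass,
#' signs are oriented so a higher score means less perceived crime / higher
#' quality, and regression-method scoring weights are returned together
#' with the baseline item means/sds used for standardisation.
#'
#' @param responses Baseline rows of a response table (14 item columns).
#' @param item_groups Named list mapping `crime` and `quality` to item
#'   column names.
#' @return Object of class `ms_factors`: `loadings`, `weights`,
#'   `item_means`, `item_sds`, `factor_names`, `items`.
#' @export
fit_perception_factors <- function(responses,
                                   item_groups = list(
                                     crime = paste0("crime", 1:7),
                                     quality = paste0("quality", 1:7))) {
  items <- unlist(item_groups, use.names = FALSE)
  X <- as.matrix(responses[items])
  if (nrow(X) < 5 * length(items))
    stop("need >= 5 respondents per item", call. = FALSE)
  fa <- tryCatch(
    stats::factanal(stats::na.omit(X), factors = 2, rotation = "promax"),
    error = function(e)
      stop("factor analysis did not converge: ", conditionMessage(e),
           call. = FALSE))
  L <- unclass(fa$loadings)
  # name each factor by the item group dominating its loadings
  mass <- sapply(item_groups, function(g)
    colSums(abs(L[g, , drop = FALSE])))
  # mass: 2 x 2 (factor x group); assign greedily
  f1_group <- names(item_groups)[which.max(mass[1, ])]
  f2_group <- setdiff(names(item_groups), f1_group)[1]
  ord <- match(c("crime", "quality"), c(f1_group, f2_group))
  L <- L[, ord, drop = FALSE]
  colnames(L) <- c("crime", "quality")
  # orient: mean loading of a factor on its own item group must be positive
  for (k in c("crime", "quality"))
    if (mean(L[item_groups[[k]], k]) < 0) L[, k] <- -L[, k]
  R <- stats::cor(X, use = "pairwise.complete.obs")
  W <- solve(R, L)  # regression-method scoring weights
  structure(list(loadings = L, weights = W,
                 item_means = colMeans(X, na.rm = TRUE),
                 item_sds = apply(X, 2, stats::sd, na.rm = TRUE),
                 factor_names = c("crime", "quality"), items = items),
            class = "ms_factors")
}

#' Score perception responses with baseline weights
#'
#' Applies the frozen baseline standardisation and regression weights to any
#' wave's responses (the same items measured at follow-up are scored on the
#' baseline scale).  Up to 2 missing items per respondent are imputed at the
#' baseline item mean; responses with more are scored `NA` (count reported).
#'
#' @param responses Response table (any wave).
#' @param fit A `ms_factors` from [fit_perception_factors()].
#' @return Data frame `id`, `wave`, `crime_score`, `quality_score`; higher
#'   scores mean less perceived crime and higher quality.
#' @export
score_perceptions <- function(responses, fit) {
  X <- as.matrix(responses[fit$items])
  n_miss <- rowSums(is.na(X))
  Z <- sweep(sweep(X, 2, fit$item_means), 2, fit$item_sds, "/")
  Z[is.na(Z)] <- 0  # baseline item mean => z = 0
  S <- Z %*% fit$weights
  S[n_miss > 2, ] <- NA
  if (any(n_miss > 2))
    message(sum(n_miss > 2),
            " respondent(s) with >2 missing items scored NA")
  data.frame(id = responses$id, wave = responses$wave,
             crime_score = S[, "crime"], quality_score = S[, "quality"],
             stringsAsFactors = FALSE)
}
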