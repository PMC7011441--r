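#' Run the full pipeline end to end
#'
#' Orchestrates simulate -> fuse -> classify -> gaps -> exposures ->
#' aggregate -> models -> tables for an epoch-fidelity synthetic run, or the
#' day-level short-cut (`fidelity = "day"`), writing delimited outputs and a
#' JSON manifest (seed, stage row counts, content hashes) to `out_dir`.
#' Any stage failure aborts with the stage name in the error.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param classifier `"rule"` (default) or a trained `ms_gbt`.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, classifier = "rule") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, fidelity = config$fidelity,
                   stages = list())
  note <- function(stage, df) {
    manifest$stages[[stage]] <<- list(
      rows = nrow(df),
      hash = .df_hash(df))
    invisible(df)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cov_cols <- c("id", "household", "group", "housing_group", "sex",
                "age_group", "ethnic_group", "working_studying")

  if (config$fidelity == "day") {
    cohort <- run_stage("cohort", generate_cohort(NULL, config))
    note("cohort", cohort)
    dp <- run_stage("day_level", generate_day_level(cohort, config))
    note("day_profiles", dp)
  } else {
    city <- run_stage("city", generate_city(config$seed))
    write_city_geojson(city, file.path(out_dir, "city"))
    cohort <- run_stage("cohort", generate_cohort(city, config))
    note("cohort", cohort)
    diaries <- run_stage("diaries", generate_diaries(cohort, city, config))
    sensors <- run_stage("sensors", emulate_sensors(diaries, config))
    note("gps_fixes", sensors$gps)
    note("accel_epochs", sensors$accel)
    labels_all <- list(); gaps_all <- list(); valid_all <- list()
    run_stage("classify_gaps", for (pid in unique(cohort$id)) {
      for (w in MS_WAVES) {
        gp <- sensors$gps[sensors$gps$id == pid & sensors$gps$wave == w, ]
        ac <- sensors$accel[sensors$accel$id == pid &
                              sensors$accel$wave == w, ]
        if (!nrow(ac)) next
        ep <- mark_nonwear(fuse_epochs(gp, ac))
        ep$id <- pid; ep$wave <- w
        for (dt in unique(as.Date(ep$timestamp, tz = "UTC"))) {
          v <- wear_time(ep, as.Date(dt, origin = "1970-01-01"))
          v$id <- pid; v$wave <- w
          valid_all[[length(valid_all) + 1]] <- v
        }
        lab <- classify(ep, classifier, rail_edges = city$rail_edges)
        gg <- find_gaps(ep)
        if (nrow(gg)) { gg$id <- pid; gg$wave <- w }
        labels_all[[length(labels_all) + 1]] <- lab
        gaps_all[[length(gaps_all) + 1]] <- gg
      }
    })
    labels <- do.call(rbind, labels_all)
    gaps <- do.call(rbind, gaps_all)
    validity <- do.call(rbind, valid_all)
    gaps <- run_stage("underground",
                      classify_underground(gaps, city$underground_stations))
    note("gaps", gaps)
    dp <- run_stage("summarise", summarise_days(labels, gaps, validity))
    note("day_profiles", dp)
    addr <- rbind(
      data.frame(id = cohort$id, wave = "baseline",
                 x = cohort$home_x_baseline, y = cohort$home_y_baseline),
      data.frame(id = cohort$id, wave = "followup",
                 x = cohort$home_x_followup, y = cohort$home_y_followup))
    addr <- addr[!duplicated(paste(cohort$household[match(addr$id, cohort$id)],
                                   addr$wave)), ]
    expo <- run_stage("exposures", built_env_exposures(addr, city))
    note("exposures", expo)
    write_delim_table(expo, file.path(out_dir, "exposures.csv"))
    write_delim_table(table2(expo, cohort[cov_cols]),
                      file.path(out_dir, "table2.csv"))
  }
  write_delim_table(dp, file.path(out_dir, "day_profiles.csv"))
  summ <- run_stage("aggregate", wave_summaries(dp))
  note("summaries", summ)
  write_delim_table(summ, file.path(out_dir, "summaries.csv"))
  covs <- cohort[intersect(cov_cols, names(cohort))]
  t1 <- run_stage("table1", table1(summ, covs))
  write_delim_table(t1$gps, file.path(out_dir, "table1_gps.csv"))
  write_delim_table(t1$categorical, file.path(out_dir, "table1_cat.csv"))
  est <- run_stage("models", {
    rows <- lapply(c(MS_CATEGORIES, "active_travel"), function(k)
      suppressWarnings(stratified_effects(summ, covs, k)))
    do.call(rbind, rows)
  })
  note("estimates", est)
  write_delim_table(est, file.path(out_dir, "table3.csv"))
  manifest$package_version <- as.character(utils::packageVersion("modeshift"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10)
  invisible(manifest)
}

# order-stable numeric hash of a data frame (no digest dependency)
.df_hash <- function(df) {
  df <- as.data.frame(df)
  df$path <- NULL
  s <- paste(utils::capture.output(utils::write.csv(
    df, stdout(), row.names = FALSE)), collapse = "\n")
  b <- as.numeric(utf8ToInt(s))
  # vectorised position-weighted checksum of the serialised text
  h <- sum(b * ((seq_along(b) %% 97) + 1)) %% 2147483647
  sprintf("%.0f", h)
}
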