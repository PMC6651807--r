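# The full replication battery: everything the package computes, in one
# seeded run -- activity battery through the engine, treadmill scenarios,
# paired heart-rate agreement, geolocation error, dispatch timing and
# battery life.

#' Run the full replication battery
#'
#' One seeded end-to-end run of every analysis in the package:
#' \itemize{
#'   \item the 120-trial activity battery (15 trials of each of 8 types)
#'     through the FDB-HRT engine, with confusion counts and
#'     classification metrics;
#'   \item `n_treadmill` treadmill stand/run/fall scenarios through the
#'     engine (fall-alert count, triggering heart rate and dip magnitude
#'     per scenario);
#'   \item paired device-vs-benchmark heart-rate readings (250 adult +
#'     250 elderly) with group and overall mean absolute error;
#'   \item 17 jittered GPS fix pairs with per-coordinate mean absolute
#'     error;
#'   \item mission timing (average savings, percent saved) from the
#'     bundled mission table, and battery-life blocks.
#' }
#' All randomness derives from `seed`; identical seeds give identical
#' reports.
#'
#' @param seed master seed.
#' @param cfg a [detector_config()].
#' @param missions mission timing data frame (default: the bundled
#'   two-row urban mission table).
#' @param n_treadmill number of treadmill scenarios.
#' @param out_path optional path; when given, the report is also written
#'   as JSON.
#' @return A nested `fdbhrt_report` list.
#' @export
report_all <- function(seed = 42L, cfg = detector_config(),
                       missions = NULL, n_treadmill = 3L,
                       out_path = NULL) {
  cfg <- as_detector_config(cfg)
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(.Machine$integer.max %/% 2, 6))

  battery <- run_battery_evaluation(seeds[1], cfg)

  treadmill <- lapply(seq_len(n_treadmill), function(i) {
    tr <- gen_treadmill_scenario(seeds[2] + i, cfg)
    ev <- events_df(run_stream(tr, cfg, fix_source = c(36.19, 44.01)))
    falls <- ev[ev$kind == "FALL_ALERT", , drop = FALSE]
    list(seed = seeds[2] + i,
         n_hr_samples = sum(!is.na(tr$hr_bpm)),
         n_fall_alerts = nrow(falls),
         fall_alert_t = if (nrow(falls)) falls$t[1] else NA_real_,
         fall_hr = attr(tr, "fall_hr"),
         dip_mag = attr(tr, "dip_mag"))
  })

  adults <- gen_paired_hr_readings(250, seed = seeds[3])
  elderly <- gen_paired_hr_readings(250, seed = seeds[4])
  hr <- list(
    adult_mae = mean_absolute_error(adults$estimated, adults$actual)$mae,
    elderly_mae = mean_absolute_error(elderly$estimated, elderly$actual)$mae,
    overall_mae = mean_absolute_error(
      c(adults$estimated, elderly$estimated),
      c(adults$actual, elderly$actual))$mae,
    n = 500L
  )

  geo_pairs <- gen_geo_fixes(seed = seeds[5])
  geo <- geolocation_error(geo_pairs)

  if (is.null(missions)) {
    path <- system.file("extdata", "missions.csv", package = "fdbhrt")
    missions <- read_missions(path)
  }
  logistics <- logistics_report(missions)

  report <- structure(list(
    seed = seed,
    config = unclass(cfg),
    battery = list(per_type = battery$per_type,
                   counts = unclass(battery$counts),
                   metrics = unclass(battery$metrics)),
    treadmill = treadmill,
    hr_agreement = hr,
    geolocation = list(lat_mae = geo$lat_mae, lon_mae = geo$lon_mae,
                       n = nrow(geo_pairs)),
    logistics = list(
      average_t_uav = logistics$mean_t_uav,
      average_t_ambulance = logistics$mean_t_ambulance,
      average_savings = logistics$average_savings,
      percent_saved = logistics$percent_saved,
      battery = lapply(logistics$battery, unclass)
    )
  ), class = "fdbhrt_report")

  if (!is.null(out_path))
    jsonlite::write_json(unclass(report), out_path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  report
}

#' @export
print.fdbhrt_report <- function(x, ...) {
  cat("FDB-HRT replication report (seed", x$seed, ")\n\n")
  cat(sprintf("Activity battery: %d/%d falls detected, %d false alarm(s)\n",
              x$battery$counts$tp, x$battery$counts$tp + x$battery$counts$fn,
              x$battery$counts$fp))
  cat(sprintf("  sensitivity %.2f%%  specificity %.2f%%  accuracy %.1f%%\n",
              x$battery$metrics$sensitivity, x$battery$metrics$specificity,
              x$battery$metrics$accuracy))
  cat("Treadmill scenarios:\n")
  for (s in x$treadmill)
    cat(sprintf("  %d fall alert(s); HR at fall %.0f bpm; dip %.2f g\n",
                s$n_fall_alerts, s$fall_hr, s$dip_mag))
  cat(sprintf("HR agreement MAE: adult %.3f, elderly %.3f, overall %.3f bpm\n",
              x$hr_agreement$adult_mae, x$hr_agreement$elderly_mae,
              x$hr_agreement$overall_mae))
  cat(sprintf("Geolocation MAE: lat %.3g deg, lon %.3g deg (n=%d)\n",
              x$geolocation$lat_mae, x$geolocation$lon_mae,
              x$geolocation$n))
  cat(sprintf("Dispatch: average savings %g s, %.2f%% of ambulance time saved\n",
              x$logistics$average_savings, x$logistics$percent_saved))
  cat(sprintf("Battery: %d days (low power) vs %d days (traditional)\n",
              x$logistics$battery$low_power$whole_days,
              x$logistics$battery$traditional$whole_days))
  invisible(x)
}
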