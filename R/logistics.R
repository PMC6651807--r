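# Dispatch-side arithmetic: UAV-versus-ambulance time savings and
# wearable battery-life estimation.

.check_missions <- function(missions) {
  missions <- as.data.frame(missions)
  if (nrow(missions) < 1L) stop("empty missions input")
  if (!all(c("t_uav", "t_ambulance") %in% names(missions)))
    stop("missions must have columns t_uav and t_ambulance (seconds)")
  if (any(!is.finite(missions$t_uav)) || any(!is.finite(missions$t_ambulance)) ||
      any(missions$t_uav <= 0) || any(missions$t_ambulance <= 0))
    stop("arrival times must be positive and finite")
  missions
}

#' Per-mission time savings of the UAV over the ambulance
#'
#' `t_ambulance - t_uav` in seconds; negative when the UAV is slower
#' (surfaced, not clamped).
#'
#' @param missions data frame with columns `t_uav`, `t_ambulance`
#'   (seconds) and optionally `location_id`.
#' @return Numeric vector of savings in seconds, one per mission.
#' @examples
#' time_savings(data.frame(t_uav = 210, t_ambulance = 300))  # 90
#' @export
time_savings <- function(missions) {
  m <- .check_missions(missions)
  m$t_ambulance - m$t_uav
}

#' Average time savings over a set of missions
#'
#' @inheritParams time_savings
#' @return Mean per-mission savings in seconds.
#' @export
average_time_savings <- function(missions) {
  mean(time_savings(missions))
}

#' Percentage of time saved by the UAV
#'
#' `100 * (mean(t_ambulance) - mean(t_uav)) / mean(t_ambulance)`,
#' truncated (toward zero) to two decimals for reporting -- the convention
#' used when a ratio like 31.8181... is printed as 31.81.
#'
#' @inheritParams time_savings
#' @return Percentage, truncated to 2 decimals.
#' @export
percent_time_saved <- function(missions) {
  m <- .check_missions(missions)
  mean_amb <- mean(m$t_ambulance)
  if (mean_amb <= 0) stop("mean ambulance time must be > 0")
  pct <- 100 * (mean_amb - mean(m$t_uav)) / mean_amb
  trunc(pct * 100) / 100
}

#' Battery life from capacity and average draw
#'
#' `hours = capacity_mah / current_ma`; whole days are the floor of
#' `hours / 24` (a battery that lasts 36.7 days is reported as 36).
#'
#' @param capacity_mah battery capacity in mAh.
#' @param current_ma average current draw in mA.
#' @return List with `hours` and `whole_days`.
#' @examples
#' battery_life(8400, 9.54)   # about 880 h, 36 whole days
#' battery_life(8400, 85.85)  # about 98 h, 4 whole days
#' @export
battery_life <- function(capacity_mah, current_ma) {
  if (!is.numeric(capacity_mah) || !is.numeric(current_ma) ||
      !is.finite(capacity_mah) || !is.finite(current_ma) ||
      capacity_mah <= 0 || current_ma <= 0)
    stop("capacity_mah and current_ma must be positive and finite")
  hours <- capacity_mah / current_ma
  list(hours = hours, whole_days = floor(hours / 24))
}

#' Read a mission timing CSV
#'
#' Expected header: `location_id,t_uav_s,t_ambulance_s`.
#'
#' @param path CSV path.
#' @return Data frame with columns `location_id`, `t_uav`, `t_ambulance`.
#' @export
read_missions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("location_id", "t_uav_s", "t_ambulance_s")
  if (!all(need %in% names(df)))
    stop("mission CSV must have columns ", paste(need, collapse = ","))
  data.frame(location_id = as.character(df$location_id),
             t_uav = as.numeric(df$t_uav_s),
             t_ambulance = as.numeric(df$t_ambulance_s),
             stringsAsFactors = FALSE)
}

#' Mission timing and battery report
#'
#' Tabulates per-mission savings, the average UAV/ambulance arrival times,
#' average savings and percentage saved, plus battery-life blocks for the
#' given operating currents.
#'
#' @inheritParams time_savings
#' @param capacity_mah wearable battery capacity in mAh.
#' @param currents_ma named vector of average current draws in mA, one
#'   battery block per element.
#' @return A `logistics_report` list.
#' @export
logistics_report <- function(missions, capacity_mah = 8400,
                             currents_ma = c(low_power = 9.54,
                                             traditional = 85.85)) {
  m <- .check_missions(missions)
  m$savings <- time_savings(m)
  battery <- lapply(currents_ma, function(i) battery_life(capacity_mah, i))
  structure(list(
    missions = m,
    mean_t_uav = mean(m$t_uav),
    mean_t_ambulance = mean(m$t_ambulance),
    average_savings = mean(m$savings),
    percent_saved = percent_time_saved(m),
    capacity_mah = capacity_mah,
    battery = battery
  ), class = "logistics_report")
}

#' @export
print.logistics_report <- function(x, ...) {
  cat("UAV vs ambulance timing\n")
  m <- x$missions
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-14s UAV %5.0f s  ambulance %5.0f s  savings %5.0f s\n",
                if (!is.null(m$location_id)) m$location_id[i] else i,
                m$t_uav[i], m$t_ambulance[i], m$savings[i]))
  cat(sprintf("  average        UAV %5.0f s  ambulance %5.0f s\n",
              x$mean_t_uav, x$mean_t_ambulance))
  cat(sprintf("  average time savings = %g s\n", x$average_savings))
  cat(sprintf("  percentage of time saved = %.2f%%\n", x$percent_saved))
  cat(sprintf("Battery (%g mAh)\n", x$capacity_mah))
  for (nm in names(x$battery))
    cat(sprintf("  %-12s %8.1f h  (%d whole days)\n", nm,
                x$battery[[nm]]$hours, x$battery[[nm]]$whole_days))
  invisible(x)
}
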