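# Evaluation statistics: confusion-matrix metrics for the activity battery,
# mean absolute error for device-vs-benchmark agreement, histogram binning,
# and per-coordinate geolocation error.

#' Confusion counts for a set of labelled trials
#'
#' Fall trials (`F*`) with an alert count as true positives, without as
#' false negatives; normal-activity trials (`NA*`) without an alert count
#' as true negatives, with as false positives.
#'
#' @param trials data frame with columns `label` (activity label) and
#'   `alert` (logical: did the detector emit a fall alert?).
#' @return A `confusion_counts` list with fields `tp`, `fn`, `tn`, `fp`.
#' @examples
#' confusion_counts(data.frame(label = c("F1", "F3", "NA1"),
#'                             alert = c(TRUE, FALSE, FALSE)))
#' @export
confusion_counts <- function(trials) {
  trials <- as.data.frame(trials)
  if (nrow(trials) == 0L) stop("empty trials input")
  lab <- as.character(trials$label)
  if (!all(lab %in% .activity_labels))
    stop("invalid activity label(s): ",
         paste(unique(setdiff(lab, .activity_labels)), collapse = ", "))
  alert <- as.logical(trials$alert)
  is_fall <- grepl("^F", lab)
  structure(list(
    tp = sum(is_fall & alert),
    fn = sum(is_fall & !alert),
    tn = sum(!is_fall & !alert),
    fp = sum(!is_fall & alert)
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP=%d FN=%d TN=%d FP=%d (n=%d)\n",
              x$tp, x$fn, x$tn, x$fp, x$tp + x$fn + x$tn + x$fp))
  invisible(x)
}

#' Sensitivity, specificity and accuracy (percent)
#'
#' `sensitivity = 100 tp/(tp+fn)`, `specificity = 100 tn/(tn+fp)`,
#' `accuracy = 100 (tp+tn)/(tp+fn+tn+fp)`. A metric whose denominator is
#' zero is returned as `NA` with a warning; the other metrics are
#' unaffected.
#'
#' @param counts a [confusion_counts()] object (or a list with `tp`, `fn`,
#'   `tn`, `fp`).
#' @return List of class `classification_metrics` with `sensitivity`,
#'   `specificity`, `accuracy` in percent (full precision; the print
#'   method rounds to 2, 2 and 1 decimals respectively).
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; fn <- counts$fn; tn <- counts$tn; fp <- counts$fp
  if (any(c(tp, fn, tn, fp) < 0)) stop("counts must be non-negative")
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else {
    warning("sensitivity undefined: no fall trials"); NA_real_
  }
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else {
    warning("specificity undefined: no normal-activity trials"); NA_real_
  }
  total <- tp + fn + tn + fp
  acc <- if (total > 0) 100 * (tp + tn) / total else {
    warning("accuracy undefined: no trials"); NA_real_
  }
  structure(list(sensitivity = sens, specificity = spec, accuracy = acc),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("sensitivity %.2f%%  specificity %.2f%%  accuracy %.1f%%\n",
              x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' Mean absolute error between paired series
#'
#' `MAE = (1/n) * sum(|estimated_i - actual_i|)`, in the units of the
#' input.
#'
#' @param estimated,actual equal-length numeric series.
#' @return An `error_summary` list with `mae`, `n` and
#'   `per_item_abs_errors`.
#' @examples
#' mean_absolute_error(c(72, 75), c(70, 76))$mae  # 1.5
#' @export
mean_absolute_error <- function(estimated, actual) {
  if (length(estimated) != length(actual))
    stop("estimated and actual must have the same length")
  if (length(estimated) < 1L) stop("series must have length >= 1")
  if (!is.numeric(estimated) || !is.numeric(actual))
    stop("series must be numeric")
  err <- abs(estimated - actual)
  structure(list(mae = mean(err), n = length(err),
                 per_item_abs_errors = err),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("MAE = %.4g over n = %d samples (max abs error %.4g)\n",
              x$mae, x$n, max(x$per_item_abs_errors)))
  invisible(x)
}

#' Equal-width histogram binning
#'
#' Splits the data range `[min, max]` into `bin_count` equal-width bins,
#' right-open except for the last bin which is closed, and reports each
#' bin's centre (rounded to 2 decimals) and frequency. Frequencies always
#' sum to the number of input values.
#'
#' @param values non-empty numeric series.
#' @param bin_count number of bins (>= 1).
#' @return Data frame with columns `bin_center`, `frequency`.
#' @examples
#' histogram(1:10, 2)  # frequencies 5 and 5
#' @export
histogram <- function(values, bin_count) {
  if (length(values) == 0L) stop("empty values input")
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("values must be finite numbers")
  bin_count <- as.integer(bin_count)
  if (is.na(bin_count) || bin_count < 1L) stop("bin_count must be >= 1")
  lo <- min(values); hi <- max(values)
  if (lo == hi) {
    freq <- c(length(values), rep(0L, bin_count - 1L))
    centers <- rep(lo, bin_count)
  } else {
    breaks <- seq(lo, hi, length.out = bin_count + 1L)
    idx <- findInterval(values, breaks, rightmost.closed = TRUE)
    freq <- tabulate(idx, nbins = bin_count)
    centers <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  }
  data.frame(bin_center = round(centers, 2), frequency = freq)
}

#' Per-coordinate geolocation error
#'
#' Mean absolute error between device and benchmark fixes, computed
#' independently for latitude and longitude in decimal degrees (the
#' standard way consumer GPS module error is reported). For a metric
#' distance see [haversine_distance_m()].
#'
#' @param pairs data frame with columns `device_lat`, `device_lon`,
#'   `bm_lat`, `bm_lon` in decimal degrees.
#' @return A `geo_error` list with `lat_mae`, `lon_mae` (degrees) and a
#'   `per_location` data frame of absolute errors.
#' @export
geolocation_error <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) < 1L) stop("need at least one fix pair")
  need <- c("device_lat", "device_lon", "bm_lat", "bm_lon")
  if (!all(need %in% names(pairs)))
    stop("pairs must have columns ", paste(need, collapse = ", "))
  lats <- c(pairs$device_lat, pairs$bm_lat)
  lons <- c(pairs$device_lon, pairs$bm_lon)
  if (any(!is.finite(lats)) || any(abs(lats) > 90) ||
      any(!is.finite(lons)) || any(abs(lons) > 180))
    stop("invalid coordinates: lat must be in [-90,90], lon in [-180,180]")
  lat_err <- abs(pairs$device_lat - pairs$bm_lat)
  lon_err <- abs(pairs$device_lon - pairs$bm_lon)
  structure(list(
    lat_mae = mean(lat_err),
    lon_mae = mean(lon_err),
    per_location = data.frame(lat_abs_error = lat_err,
                              lon_abs_error = lon_err)
  ), class = "geo_error")
}

#' @export
print.geo_error <- function(x, ...) {
  cat(sprintf("geolocation MAE: lat %.3g deg, lon %.3g deg over %d locations\n",
              x$lat_mae, x$lon_mae, nrow(x$per_location)))
  invisible(x)
}

#' Haversine distance between fixes (metres)
#'
#' Supplementary great-circle distance helper (via `geosphere`); the
#' primary geolocation error metric is per-coordinate degrees, see
#' [geolocation_error()].
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return Distance(s) in metres.
#' @export
haversine_distance_m <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2))
}

#' Run the full activity battery through the detector
#'
#' Generates `trials_per_type` seeded trials of each of the eight activity
#' types (see [battery_manifest()]), runs each through the FDB-HRT engine
#' at the given configuration, and tabulates per-type detections, the
#' confusion counts, and classification metrics.
#'
#' @param seed master seed for the battery.
#' @param cfg a [detector_config()].
#' @param trials_per_type trials per activity type (default 15).
#' @return A `battery_evaluation` list: `manifest` (with a `detected`
#'   column), `per_type` (data frame of detections per type), `counts`
#'   ([confusion_counts()]), `metrics` ([classification_metrics()]).
#' @export
run_battery_evaluation <- function(seed = 42L, cfg = detector_config(),
                                   trials_per_type = 15L) {
  cfg <- as_detector_config(cfg)
  man <- battery_manifest(seed, trials_per_type)
  man$detected <- vapply(seq_len(nrow(man)), function(i) {
    tr <- gen_activity_trace(man$label[i], man$seed[i], cfg,
                             arrested = man$arrested[i])
    ev <- run_stream(tr, cfg)
    any(vapply(ev, function(e) e$kind == "FALL_ALERT", logical(1)))
  }, logical(1))

  per_type <- do.call(rbind, lapply(.activity_labels, function(l) {
    rows <- man[man$label == l, , drop = FALSE]
    data.frame(label = l,
               description = unname(.activity_descriptions[l]),
               trials = nrow(rows),
               alerts = sum(rows$detected),
               stringsAsFactors = FALSE)
  }))

  counts <- confusion_counts(data.frame(label = man$label,
                                        alert = man$detected))
  structure(list(manifest = man, per_type = per_type, counts = counts,
                 metrics = classification_metrics(counts)),
            class = "battery_evaluation")
}

#' @export
print.battery_evaluation <- function(x, ...) {
  cat("Activity battery evaluation\n")
  for (i in seq_len(nrow(x$per_type))) {
    p <- x$per_type[i, ]
    res <- if (grepl("^F", p$label)) sprintf("%d/%d detected", p$alerts, p$trials)
           else sprintf("%d/%d flagged", p$alerts, p$trials)
    cat(sprintf("  %-3s %-48s %s\n", p$label, p$description, res))
  }
  print(x$counts)
  print(x$metrics)
  invisible(x)
}
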