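# Seeded generators for labelled vital-sign traces. These stand in for the
# volunteer experiments the detector is evaluated against: four fall types
# and four activities of daily living, a treadmill stand/run/fall scenario,
# paired device-vs-benchmark heart-rate readings, and jittered GPS fixes.
# Every generator is deterministic given (arguments, seed).

.activity_labels <- c("F1", "F2", "F3", "F4", "NA1", "NA2", "NA3", "NA4")

.activity_descriptions <- c(
  F1  = "Forward fall, lying on ground",
  F2  = "Fall to the right, lying on ground",
  F3  = "Backward fall from a seated position on a chair",
  F4  = "Forward fall, landing on knees",
  NA1 = "Walking",
  NA2 = "Ascending stairs",
  NA3 = "Descending stairs",
  NA4 = "Sitting on chair"
)

# Decompose a magnitude series onto three axes with a fixed, slightly
# tilted device orientation so accel_magnitude() recovers it exactly.
.axis_decompose <- function(mag) {
  d <- c(stats::rnorm(2, 0, 0.08), 1)
  d <- d / sqrt(sum(d^2))
  list(ax = mag * d[1], ay = mag * d[2], az = mag * d[3])
}

# Assemble the trace data frame: acceleration at accel_rate_hz, heart rate
# co-sampled at whole seconds (hr_rate_hz is fixed at 1 Hz logging).
.assemble_trace <- function(duration_s, mag, hr_per_sec, cfg, label, seed,
                            extra_attrs = list()) {
  rate <- cfg$accel_rate_hz
  n <- length(mag)
  t <- (seq_len(n) - 1) / rate
  hr <- rep(NA_real_, n)
  sec_idx <- (seq_len(duration_s) - 1) * rate + 1
  hr[sec_idx] <- hr_per_sec
  axes <- .axis_decompose(mag)
  tr <- data.frame(t = t, hr_bpm = hr,
                   ax_g = axes$ax, ay_g = axes$ay, az_g = axes$az)
  attr(tr, "label") <- label
  attr(tr, "seed") <- seed
  for (nm in names(extra_attrs)) attr(tr, nm) <- extra_attrs[[nm]]
  class(tr) <- c("vital_trace", "data.frame")
  tr
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a labelled fall / daily-activity trace
#'
#' Produces one synthetic trial of the eight-type activity battery. Fall
#' traces (`F1`--`F4`) show roughly 1 g of pre-fall movement, a free-fall
#' dip drawn uniformly from 0.10--0.40 g lasting 60--200 ms, an impact
#' spike above the activity threshold, then motionless lying at about 1 g;
#' heart rate turns tachycardic early enough before the dip to satisfy the
#' sustained-abnormal-HR gate. Normal activities (`NA1`--`NA4`) oscillate
#' in 0.7--1.8 g with a normal heart rate (65--95 bpm) and so cross no
#' detector threshold. The backward chair fall `F3` can occur as an
#' *arrested* variant (the person catches the chair arm) whose dip bottoms
#' out at 0.55--0.70 g, above the free-fall threshold -- the one fall the
#' detector by design cannot see.
#'
#' @param label one of `F1..F4`, `NA1..NA4`.
#' @param seed integer seed; identical arguments reproduce the trace
#'   exactly.
#' @param cfg a [detector_config()].
#' @param arrested logical; force the arrested variant (only meaningful for
#'   `F3`). Default `NULL` draws it with probability `p_arrest`.
#' @param p_arrest probability of the arrested `F3` variant when
#'   `arrested = NULL` (default 1/15, one expected miss per 15 chair
#'   trials).
#' @return A `vital_trace` data frame (`t`, `hr_bpm`, `ax_g`, `ay_g`,
#'   `az_g`) with attributes `label`, `seed`, `arrested`, and for falls
#'   `dip_mag`, `dip_start`.
#' @examples
#' tr <- gen_activity_trace("F1", seed = 7)
#' attr(tr, "dip_mag")
#' @export
gen_activity_trace <- function(label, seed = 1L, cfg = detector_config(),
                               arrested = NULL, p_arrest = 1 / 15) {
  if (!is.character(label) || length(label) != 1L ||
      !(label %in% .activity_labels))
    stop("unknown activity label: ", paste(label, collapse = ", "))
  cfg <- as_detector_config(cfg)
  is_fall <- grepl("^F", label)
  withr::with_seed(as.integer(seed), {
    if (is_fall) {
      if (is.null(arrested))
        arrested <- (label == "F3") && (stats::runif(1) < p_arrest)
      .gen_fall_trace(label, seed, cfg, arrested)
    } else {
      .gen_adl_trace(label, seed, cfg)
    }
  })
}

.gen_fall_trace <- function(label, seed, cfg, arrested) {
  duration <- 45L
  rate <- cfg$accel_rate_hz
  n <- duration * rate
  t <- (seq_len(n) - 1) / rate

  dip_start <- 12 + stats::runif(1)
  dip_dur <- stats::runif(1, 0.06, 0.20)
  dip_mag <- if (arrested) stats::runif(1, 0.55, 0.70)
             else stats::runif(1, 0.10, 0.40)
  imp_dur <- stats::runif(1, 0.04, 0.08)
  imp_amp <- if (arrested) stats::runif(1, 1.2, 2.0)
             else stats::runif(1, 2.6, 6.0)

  # pre-fall movement; the seated chair fall starts quieter
  base_amp <- if (label == "F3") 0.05 else 0.12
  phase <- stats::runif(1, 0, 2 * pi)
  mag <- 1 + base_amp * sin(2 * pi * 1.2 * t + phase) +
    stats::rnorm(n, 0, 0.03)
  mag <- .clip(mag, 0.8, 1.6)

  in_dip <- t >= dip_start & t < dip_start + dip_dur
  mag[in_dip] <- .clip(dip_mag + stats::rnorm(sum(in_dip), 0, 0.01),
                       if (arrested) 0.52 else 0.05,
                       if (arrested) 0.75 else 0.45)
  imp_start <- dip_start + dip_dur
  in_imp <- t >= imp_start & t < imp_start + imp_dur
  mag[in_imp] <- pmax(imp_amp + stats::rnorm(sum(in_imp), 0, 0.2),
                      if (arrested) 1.0 else 2.6)
  after <- t >= imp_start + imp_dur
  mag[after] <- 1 + stats::rnorm(sum(after), 0, 0.01)  # motionless lying

  # tachycardia begins comfortably before the dip so the 5 s sustained
  # abnormal-HR confirmation completes before free fall
  hr_ab_from <- ceiling(dip_start - (cfg$hr_confirm_delay + 2))
  secs <- seq_len(duration) - 1
  hr <- .clip(78 + cumsum(stats::rnorm(duration, 0, 1.2)), 70, 95)
  ab <- secs >= hr_ab_from
  hr[ab] <- .clip(106 + cumsum(stats::rnorm(sum(ab), 0.3, 0.8)), 103, 118)

  .assemble_trace(duration, mag, hr, cfg, label, seed,
                  list(arrested = arrested, dip_mag = dip_mag,
                       dip_start = dip_start))
}

.gen_adl_trace <- function(label, seed, cfg) {
  duration <- 30L
  rate <- cfg$accel_rate_hz
  n <- duration * rate
  t <- (seq_len(n) - 1) / rate

  amp <- switch(label, NA1 = 0.30, NA2 = 0.40, NA3 = 0.40, NA4 = 0.12)
  freq <- switch(label, NA1 = 1.8, NA2 = 1.4, NA3 = 1.6, NA4 = 0.5)
  phase <- stats::runif(1, 0, 2 * pi)
  mag <- 1 + amp * sin(2 * pi * freq * t + phase) + stats::rnorm(n, 0, 0.05)
  mag <- .clip(mag, 0.7, 1.8)

  secs <- seq_len(duration) - 1
  hr <- .clip(stats::runif(1, 70, 85) + cumsum(stats::rnorm(duration, 0, 1.5)),
              65, 95)

  .assemble_trace(duration, mag, hr, cfg, label, seed,
                  list(arrested = FALSE))
}

#' Manifest for the full activity battery
#'
#' Derives per-trial seeds for `trials_per_type` trials of each of the
#' eight activity types. Exactly one chair-fall (`F3`) trial per battery is
#' constructed as the arrested variant, so the battery reproduces the
#' expected one-miss pattern by construction rather than by chance.
#'
#' @param seed master seed.
#' @param trials_per_type trials per activity type (default 15).
#' @return Data frame with columns `label`, `trial`, `seed`, `arrested`.
#' @export
battery_manifest <- function(seed = 42L, trials_per_type = 15L) {
  withr::with_seed(as.integer(seed), {
    man <- expand.grid(trial = seq_len(trials_per_type),
                       label = .activity_labels,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    man <- man[, c("label", "trial")]
    man$seed <- sample.int(.Machine$integer.max %/% 2, nrow(man))
    man$arrested <- FALSE
    man$arrested[man$label == "F3" &
                   man$trial == sample.int(trials_per_type, 1)] <- TRUE
    man
  })
}

#' Generate the treadmill stand/run/fall scenario
#'
#' A 300 s trace with exactly 300 heart-rate samples (1 Hz): a standing
#' segment (HR 70--85 bpm), a 3 min run during which HR ramps monotonically
#' above 100 bpm, a further minute of running, and a fall near the end
#' whose free-fall dip magnitude is drawn from 0.10--0.40 g. Acceleration
#' is co-sampled at `cfg$accel_rate_hz`.
#'
#' @param seed integer seed.
#' @param cfg a [detector_config()].
#' @return A `vital_trace` with attributes `dip_mag`, `fall_t`, `fall_hr`.
#' @export
gen_treadmill_scenario <- function(seed = 1L, cfg = detector_config()) {
  cfg <- as_detector_config(cfg)
  withr::with_seed(as.integer(seed), {
    duration <- 300L
    rate <- cfg$accel_rate_hz
    n <- duration * rate
    t <- (seq_len(n) - 1) / rate

    stand_end <- 60
    ramp_end <- 240
    fall_t <- 294 + stats::runif(1)
    dip_dur <- stats::runif(1, 0.06, 0.20)
    dip_mag <- stats::runif(1, 0.10, 0.40)
    imp_dur <- stats::runif(1, 0.04, 0.08)
    imp_amp <- stats::runif(1, 2.6, 6.0)

    mag <- numeric(n)
    standing <- t < stand_end
    mag[standing] <- 1 + stats::rnorm(sum(standing), 0, 0.02)
    running <- t >= stand_end & t < fall_t
    phase <- stats::runif(1, 0, 2 * pi)
    mag[running] <- .clip(
      1 + 0.35 * sin(2 * pi * 2 * t[running] + phase) +
        stats::rnorm(sum(running), 0, 0.05), 0.7, 1.8)
    in_dip <- t >= fall_t & t < fall_t + dip_dur
    mag[in_dip] <- .clip(dip_mag + stats::rnorm(sum(in_dip), 0, 0.01),
                         0.05, 0.45)
    in_imp <- t >= fall_t + dip_dur & t < fall_t + dip_dur + imp_dur
    mag[in_imp] <- pmax(imp_amp + stats::rnorm(sum(in_imp), 0, 0.2), 2.6)
    after <- t >= fall_t + dip_dur + imp_dur
    mag[after] <- 1 + stats::rnorm(sum(after), 0, 0.01)

    secs <- seq_len(duration) - 1
    hr <- numeric(duration)
    hr_stand <- .clip(stats::runif(1, 72, 82) +
                        cumsum(stats::rnorm(stand_end, 0, 0.6)), 70, 85)
    hr[secs < stand_end] <- hr_stand
    peak <- stats::runif(1, 106, 112)
    ramp_secs <- secs >= stand_end & secs < ramp_end
    w <- stats::runif(sum(ramp_secs), 0.2, 1)        # positive increments:
    ramp <- hr_stand[stand_end] +                     # monotone by design
      (peak - hr_stand[stand_end]) * cumsum(w) / sum(w)
    hr[ramp_secs] <- ramp
    cont_secs <- secs >= ramp_end
    extra <- stats::runif(1, 1, 3)
    hr[cont_secs] <- .clip(peak + extra * cumsum(stats::runif(sum(cont_secs),
                                                              0, 1)) /
                             sum(cont_secs), 101, 115)
    fall_hr <- hr[floor(fall_t) + 1]

    .assemble_trace(duration, mag, hr, cfg, "treadmill", seed,
                    list(dip_mag = dip_mag, fall_t = fall_t,
                         fall_hr = fall_hr))
  })
}

#' Generate paired device-vs-benchmark heart-rate readings
#'
#' The benchmark series is taken as truth; the device reading adds
#' integer-rounded Gaussian noise. The default noise scale (sd 1.25 bpm)
#' yields an expected mean absolute error of about 1 bpm.
#'
#' @param n number of paired samples.
#' @param true_hr_series benchmark heart rates in bpm; default is a seeded
#'   resting-range random walk in 60--100 bpm. Recycled to length `n`.
#' @param device_noise_sd standard deviation of the device noise in bpm.
#' @param seed integer seed.
#' @return Data frame with columns `estimated` (device) and `actual`
#'   (benchmark), both length `n`.
#' @export
gen_paired_hr_readings <- function(n = 250L, true_hr_series = NULL,
                                   device_noise_sd = 1.25, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  if (device_noise_sd < 0) stop("device_noise_sd must be >= 0")
  withr::with_seed(as.integer(seed), {
    if (is.null(true_hr_series))
      true_hr_series <- round(.clip(75 + cumsum(stats::rnorm(n, 0, 0.9)),
                                    60, 100))
    actual <- rep_len(as.numeric(true_hr_series), n)
    estimated <- actual + round(stats::rnorm(n, 0, device_noise_sd))
    data.frame(estimated = estimated, actual = actual)
  })
}

#' Generate paired device-vs-benchmark GPS fixes
#'
#' The benchmark fix repeats the true location; the device fix adds
#' independent uniform jitter in `[-jitter_deg, +jitter_deg]` to each
#' coordinate (clamped to valid latitude/longitude ranges). The default
#' jitter of 2e-5 degrees puts the per-coordinate mean absolute error on
#' the 1e-5-degree scale of consumer GPS modules.
#'
#' @param true_fix `c(lat, lon)` in decimal degrees WGS84.
#' @param jitter_deg uniform jitter half-width in degrees.
#' @param n number of locations.
#' @param seed integer seed.
#' @return Data frame with columns `device_lat`, `device_lon`, `bm_lat`,
#'   `bm_lon`.
#' @export
gen_geo_fixes <- function(true_fix = c(36.19, 44.01), jitter_deg = 2e-5,
                          n = 17L, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  if (jitter_deg < 0) stop("jitter_deg must be >= 0")
  lat <- as.numeric(true_fix[1]); lon <- as.numeric(true_fix[2])
  if (abs(lat) > 90 || abs(lon) > 180)
    stop("true_fix must be valid (lat in [-90,90], lon in [-180,180])")
  withr::with_seed(as.integer(seed), {
    data.frame(
      device_lat = .clip(lat + stats::runif(n, -jitter_deg, jitter_deg),
                         -90, 90),
      device_lon = .clip(lon + stats::runif(n, -jitter_deg, jitter_deg),
                         -180, 180),
      bm_lat = rep(lat, n),
      bm_lon = rep(lon, n)
    )
  })
}

#' Write a vital-sign trace as CSV
#'
#' Header `t_s,hr_bpm,ax_g,ay_g,az_g`; the heart-rate field is empty on
#' acceleration-only rows.
#'
#' @param trace a trace data frame.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  out <- data.frame(t_s = df$t, hr_bpm = df$hr_bpm, ax_g = df$ax_g,
                    ay_g = df$ay_g, az_g = df$az_g)
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read a vital-sign trace CSV
#'
#' @param path CSV with header `t_s,hr_bpm,ax_g,ay_g,az_g`.
#' @return A trace data frame with columns `t`, `hr_bpm`, `ax_g`, `ay_g`,
#'   `az_g`.
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t_s", "ax_g", "ay_g", "az_g")
  if (!all(need %in% names(df)))
    stop("trace CSV must have columns t_s,hr_bpm,ax_g,ay_g,az_g")
  if (is.null(df$hr_bpm)) df$hr_bpm <- NA_real_
  tr <- data.frame(t = df$t_s, hr_bpm = as.numeric(df$hr_bpm),
                   ax_g = df$ax_g, ay_g = df$ay_g, az_g = df$az_g)
  class(tr) <- c("vital_trace", "data.frame")
  tr
}
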