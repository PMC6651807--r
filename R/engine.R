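# The FDB-HRT streaming state machine.
#
# Two-stage logic: a preparation stage that announces the device online,
# then a monitoring stage in which free-fall detection is *gated* on a
# sustained abnormal heart rate. Only after the heart rate has been outside
# the normal range continuously for hr_confirm_delay seconds does the
# engine start testing the acceleration magnitude against the free-fall
# threshold; a fall alert is followed by a post-fall activity check and an
# optional heart-rate recheck. All timing is driven by sample timestamps,
# never the wall clock, so replays are bit-identical.

.kind_status <- c(
  ONLINE                   = "online",
  FALL_ALERT               = "HR abnormal, patient fall",
  INACTIVE_ALERT           = "patient inactive",
  ACTIVE_HR_ABNORMAL_ALERT = "HR abnormal, patient active"
)

#' Create a patient record
#'
#' @param patient_id non-empty identifier string.
#' @param health_history free-text health history forwarded in the online
#'   message.
#' @return A `patient_record` list.
#' @export
patient_record <- function(patient_id = "P-000", health_history = "") {
  if (!is.character(patient_id) || length(patient_id) != 1L || !nzchar(patient_id))
    stop("patient_id must be a non-empty string")
  structure(list(patient_id = patient_id,
                 health_history = as.character(health_history)[1L]),
            class = "patient_record")
}

#' Initial engine state
#'
#' The engine starts in `PREP` mode; its first processed sample emits the
#' one-off `ONLINE` event and moves it to `MONITORING`.
#'
#' @param cfg a [detector_config()].
#' @param patient a [patient_record()].
#' @return An `engine_state` list (mode, configuration, timers, activity
#'   counter).
#' @export
engine_state <- function(cfg = detector_config(), patient = patient_record()) {
  cfg <- as_detector_config(cfg)
  structure(list(
    mode             = "PREP",
    cfg              = cfg,
    patient          = patient,
    hr_abnormal_since = NA_real_,
    low_mag_since    = NA_real_,
    fall_time        = NA_real_,
    ac_m             = 0L,
    last_ac_m        = NA_integer_,
    active_secs      = integer(0),
    window_start     = NA_real_,
    recheck_start    = NA_real_,
    last_t           = -Inf
  ), class = "engine_state")
}

.mk_event <- function(t, kind, fix_fun) {
  lat <- NA_real_; lon <- NA_real_
  if (kind != "ONLINE") {
    fix <- tryCatch(
      if (is.function(fix_fun)) fix_fun() else fix_fun,
      error = function(e) {
        warning("geolocation fix unavailable for ", kind, " at t=", t,
                ": ", conditionMessage(e), call. = FALSE)
        NULL
      })
    if (!is.null(fix)) {
      fix <- unlist(fix, use.names = FALSE)
      lat <- as.numeric(fix[1L]); lon <- as.numeric(fix[2L])
    }
  }
  list(t = t, kind = kind, status_text = unname(.kind_status[kind]),
       lat = lat, lon = lon)
}

# Core transition on scalar (t, hr, mag). `st` is the plain state list;
# returns list(state, events). Kept branch-lean: it runs once per sample.
.engine_step <- function(st, t, hr, mag, fix_fun) {
  events <- NULL
  cfg <- st$cfg
  mode <- st$mode

  if (mode == "PREP") {
    events <- list(.mk_event(t, "ONLINE", fix_fun))
    mode <- "MONITORING"
  }

  hr_ok <- !is.na(hr)
  abn <- if (hr_ok) (hr < cfg$nhr_low || hr > cfg$nhr_high) else FALSE

  if (mode == "MONITORING") {
    if (hr_ok && abn) {
      st$hr_abnormal_since <- t
      mode <- if (cfg$hr_confirm_delay <= 0) "FALL_CHECK" else "HR_ABNORMAL_PENDING"
    }
  } else if (mode == "HR_ABNORMAL_PENDING") {
    if (hr_ok) {
      if (!abn) {
        st$hr_abnormal_since <- NA_real_
        mode <- "MONITORING"
      } else if (t - st$hr_abnormal_since >= cfg$hr_confirm_delay) {
        st$low_mag_since <- NA_real_
        mode <- "FALL_CHECK"
      }
    }
  }

  if (mode == "FALL_CHECK") {
    if (hr_ok && !abn) {
      st$hr_abnormal_since <- NA_real_
      st$low_mag_since <- NA_real_
      mode <- "MONITORING"
    } else if (mag < cfg$fam_t) {
      if (is.na(st$low_mag_since)) st$low_mag_since <- t
      if (t - st$low_mag_since > cfg$ft_t) {
        events <- c(events, list(.mk_event(t, "FALL_ALERT", fix_fun)))
        st$fall_time <- t
        st$low_mag_since <- NA_real_
        st$hr_abnormal_since <- NA_real_
        mode <- "POST_FALL_WAIT"
      }
    } else {
      st$low_mag_since <- NA_real_
    }
  } else if (mode == "POST_FALL_WAIT") {
    if (t - st$fall_time >= cfg$post_fall_delay) {
      mode <- "ACTIVITY_CHECK"
      st$window_start <- t
      st$active_secs <- integer(0)
    }
  }

  if (mode == "ACTIVITY_CHECK") {
    if (t - st$window_start < cfg$ac_window) {
      if (mag > cfg$aam_t) {
        s <- as.integer(floor(t))
        if (!(s %in% st$active_secs)) st$active_secs <- c(st$active_secs, s)
      }
    } else {
      st$last_ac_m <- length(st$active_secs)
      if (st$last_ac_m >= cfg$ac_t) {
        st$recheck_start <- t
        mode <- "HR_RECHECK_WAIT"
      } else {
        events <- c(events, list(.mk_event(t, "INACTIVE_ALERT", fix_fun)))
        mode <- "AWAITING_HELP"
      }
      st$active_secs <- integer(0)
      st$ac_m <- 0L
      st$window_start <- NA_real_
      st$fall_time <- NA_real_
    }
  } else if (mode == "HR_RECHECK_WAIT") {
    if (hr_ok && t - st$recheck_start >= cfg$hr_recheck_delay) {
      if (abn)
        events <- c(events, list(.mk_event(t, "ACTIVE_HR_ABNORMAL_ALERT", fix_fun)))
      st$recheck_start <- NA_real_
      mode <- "MONITORING"
    }
  }

  if (mode == "ACTIVITY_CHECK") st$ac_m <- length(st$active_secs)
  st$mode <- mode
  st$last_t <- t
  list(state = st, events = events)
}

#' Advance the engine by one sample
#'
#' Feeds one time-stamped sample (heart rate may be absent on
#' acceleration-only rows) to the state machine and returns the updated
#' state together with any alert events it emitted.
#'
#' @param state an [engine_state()].
#' @param sample a named list or one-row data frame with `t` (s), optional
#'   `hr`/`hr_bpm` (bpm, `NA` when not sampled), and either `ax`/`ay`/`az`
#'   (`*_g` suffixes accepted) or a precomputed `magnitude` in g.
#' @param fix_source geolocation source for alerts: a `c(lat, lon)` vector
#'   or a zero-argument function returning one. A failing source downgrades
#'   the alert's fix to absent with a warning; the alert itself is never
#'   suppressed.
#' @return `list(state = <engine_state>, events = <list of alert events>)`.
#' @seealso [run_stream()] for whole traces.
#' @export
step <- function(state, sample, fix_source = NULL) {
  stopifnot(inherits(state, "engine_state"))
  sample <- as.list(sample)
  pick <- function(...) {
    for (nm in c(...)) if (!is.null(sample[[nm]])) return(as.numeric(sample[[nm]]))
    NA_real_
  }
  t <- pick("t", "t_s")
  if (!is.finite(t)) stop("sample must carry a finite timestamp 't'")
  if (t < state$last_t)
    stop("sample timestamps must be non-decreasing (got ", t,
         " after ", state$last_t, ")")
  hr <- pick("hr", "hr_bpm")
  mag <- pick("magnitude", "mag")
  if (is.na(mag))
    mag <- accel_magnitude(pick("ax", "ax_g"), pick("ay", "ay_g"),
                           pick("az", "az_g"))
  res <- .engine_step(unclass(state), t, hr, mag, fix_source)
  res$state <- structure(res$state, class = "engine_state")
  res
}

.trace_columns <- function(trace) {
  trace <- as.data.frame(trace)
  get <- function(...) {
    for (nm in c(...)) if (nm %in% names(trace)) return(as.numeric(trace[[nm]]))
    NULL
  }
  t <- get("t", "t_s")
  if (is.null(t)) stop("trace must have a time column 't' or 't_s'")
  hr <- get("hr", "hr_bpm")
  if (is.null(hr)) hr <- rep(NA_real_, length(t))
  mag <- get("magnitude", "mag")
  if (is.null(mag)) {
    ax <- get("ax", "ax_g"); ay <- get("ay", "ay_g"); az <- get("az", "az_g")
    if (is.null(ax) || is.null(ay) || is.null(az))
      stop("trace must have ax/ay/az (or *_g) columns or a 'magnitude' column")
    mag <- accel_magnitude(ax, ay, az)
  }
  list(t = t, hr = hr, mag = mag)
}

#' Run the detector over a whole sample stream
#'
#' Folds [step()] over a time-ordered stream and returns every alert event
#' emitted. Deterministic: identical inputs give identical event lists. An
#' empty stream still yields the one-off `ONLINE` event.
#'
#' @param samples data frame with columns `t` (s), optional `hr`/`hr_bpm`
#'   and either `ax`,`ay`,`az` (`*_g` accepted) or `magnitude` (g).
#' @param cfg a [detector_config()].
#' @param patient a [patient_record()].
#' @param fix_source see [step()].
#' @return List of alert events, each `list(t, kind, status_text, lat, lon)`.
#' @export
run_stream <- function(samples, cfg = detector_config(),
                       patient = patient_record(), fix_source = NULL) {
  cfg <- as_detector_config(cfg)
  cols <- .trace_columns(samples)
  t <- cols$t; hr <- cols$hr; mag <- cols$mag
  n <- length(t)
  if (n && any(diff(t) < 0))
    stop("sample timestamps must be non-decreasing")

  st <- unclass(engine_state(cfg, patient))
  events <- list()
  if (n == 0L)
    return(list(.mk_event(0, "ONLINE", fix_source)))

  for (i in seq_len(n)) {
    mode <- st$mode
    # accel-only samples cannot change state while no fall arming is active
    if (is.na(hr[i]) &&
        (mode == "MONITORING" || mode == "HR_ABNORMAL_PENDING" ||
         mode == "AWAITING_HELP"))
      next
    res <- .engine_step(st, t[i], hr[i], mag[i], fix_source)
    st <- res$state
    if (!is.null(res$events)) events <- c(events, res$events)
  }
  events
}

#' Detect falls in a vital-sign trace
#'
#' High-level front end to the FDB-HRT engine: runs the state machine over
#' a trace and returns a classed result holding the emitted alerts, the
#' trace and the configuration, with `print`, `summary` and `plot` methods.
#'
#' @inheritParams run_stream
#' @return An object of class `fdb_hrt` with elements `events` (data frame:
#'   `t`, `kind`, `status_text`, `lat`, `lon`), `trace`, `cfg`, `patient`.
#' @examples
#' tr <- gen_activity_trace("F1", seed = 1)
#' fit <- detect_falls(tr)
#' summary(fit)
#' @export
detect_falls <- function(samples, cfg = detector_config(),
                         patient = patient_record(),
                         fix_source = c(36.19, 44.01)) {
  cfg <- as_detector_config(cfg)
  ev <- run_stream(samples, cfg, patient, fix_source)
  structure(list(events = events_df(ev), trace = as.data.frame(samples),
                 cfg = cfg, patient = patient),
            class = "fdb_hrt")
}

#' Convert an event list to a data frame
#'
#' @param events list of alert events as returned by [run_stream()].
#' @return Data frame with columns `t`, `kind`, `status_text`, `lat`, `lon`.
#' @export
events_df <- function(events) {
  if (is.data.frame(events)) return(events)
  data.frame(
    t           = vapply(events, function(e) e$t, numeric(1)),
    kind        = vapply(events, function(e) e$kind, character(1)),
    status_text = vapply(events, function(e) e$status_text, character(1)),
    lat         = vapply(events, function(e) e$lat, numeric(1)),
    lon         = vapply(events, function(e) e$lon, numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.fdb_hrt <- function(x, ...) {
  ev <- x$events
  cat("FDB-HRT detection run: ", nrow(x$trace), " samples, ",
      nrow(ev), " event(s)\n", sep = "")
  alerts <- ev[ev$kind != "ONLINE", , drop = FALSE]
  if (nrow(alerts) == 0) {
    cat("  no alerts (online only)\n")
  } else {
    for (i in seq_len(nrow(alerts)))
      cat(sprintf("  t=%8.2f s  %-24s (%s)\n", alerts$t[i], alerts$kind[i],
                  alerts$status_text[i]))
  }
  invisible(x)
}

#' @export
summary.fdb_hrt <- function(object, ...) {
  ev <- object$events
  out <- list(
    n_samples = nrow(object$trace),
    duration_s = if (nrow(object$trace)) diff(range(object$trace$t)) else 0,
    counts = table(factor(ev$kind, levels = names(.kind_status))),
    first_fall_t = if (any(ev$kind == "FALL_ALERT"))
      min(ev$t[ev$kind == "FALL_ALERT"]) else NA_real_
  )
  class(out) <- "summary.fdb_hrt"
  out
}

#' @export
print.summary.fdb_hrt <- function(x, ...) {
  cat("FDB-HRT run summary\n")
  cat(sprintf("  samples : %d (%.1f s)\n", x$n_samples, x$duration_s))
  for (k in names(x$counts))
    cat(sprintf("  %-25s %d\n", k, x$counts[[k]]))
  if (!is.na(x$first_fall_t))
    cat(sprintf("  first fall alert at t = %.2f s\n", x$first_fall_t))
  invisible(x)
}

#' @export
plot.fdb_hrt <- function(x, ...) {
  cols <- .trace_columns(x$trace)
  op <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(cols$t, cols$mag, type = "l", xlab = "", ylab = "|a| (g)",
                 main = "Acceleration magnitude", ...)
  graphics::abline(h = c(x$cfg$fam_t, x$cfg$aam_t), lty = 3, col = "grey40")
  alerts <- x$events[x$events$kind != "ONLINE", , drop = FALSE]
  if (nrow(alerts)) graphics::abline(v = alerts$t, col = "red", lty = 2)
  hr_idx <- !is.na(cols$hr)
  graphics::plot(cols$t[hr_idx], cols$hr[hr_idx], type = "l",
                 xlab = "time (s)", ylab = "HR (bpm)", main = "Heart rate")
  graphics::abline(h = c(x$cfg$nhr_low, x$cfg$nhr_high), lty = 3, col = "grey40")
  if (nrow(alerts)) graphics::abline(v = alerts$t, col = "red", lty = 2)
  invisible(x)
}

#' Stand-alone free-fall test on a magnitude window
#'
#' `TRUE` iff the window contains a contiguous run of samples with magnitude
#' below the free-fall threshold whose time span exceeds the falling-time
#' threshold. This is the same criterion the streaming engine applies, in
#' batch form.
#'
#' @param window data frame with columns `t` (s) and `magnitude` (g).
#' @param cfg a [detector_config()].
#' @return Logical scalar.
#' @examples
#' w <- data.frame(t = seq(0, 0.1, by = 0.01), magnitude = 0.16)
#' detect_free_fall(w)  # TRUE: 100 ms below 0.5 g
#' @export
detect_free_fall <- function(window, cfg = detector_config()) {
  cfg <- as_detector_config(cfg)
  window <- as.data.frame(window)
  t <- as.numeric(window$t)
  mag <- as.numeric(if (!is.null(window$magnitude)) window$magnitude else window$mag)
  if (length(t) == 0L) return(FALSE)
  if (any(diff(t) < 0)) stop("window timestamps must be non-decreasing")
  below <- mag < cfg$fam_t
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values))
    if (t[ends[j]] - t[starts[j]] > cfg$ft_t) return(TRUE)
  FALSE
}

#' Post-fall activity classification over an observation window
#'
#' Counts the activity counter `AC_m`: the number of distinct whole seconds
#' in the window containing at least one sample with magnitude above the
#' activity threshold. The patient is classified active iff
#' `AC_m >= ac_t`.
#'
#' @param window data frame with columns `t` (s) and `magnitude` (g),
#'   spanning at least `cfg$ac_window` whole seconds.
#' @param cfg a [detector_config()].
#' @return `list(activity = "active"|"inactive", ac_m = <integer>)`.
#' @export
classify_post_fall_activity <- function(window, cfg = detector_config()) {
  cfg <- as_detector_config(cfg)
  window <- as.data.frame(window)
  t <- as.numeric(window$t)
  mag <- as.numeric(if (!is.null(window$magnitude)) window$magnitude else window$mag)
  if (length(t) == 0L) stop("insufficient data: empty activity window")
  if (any(diff(t) < 0)) stop("window timestamps must be non-decreasing")
  secs <- unique(floor(t))
  if (length(secs) < cfg$ac_window)
    stop("insufficient data: window covers ", length(secs),
         " whole second(s), needs ", cfg$ac_window)
  ac_m <- length(unique(floor(t[mag > cfg$aam_t])))
  list(activity = if (ac_m >= cfg$ac_t) "active" else "inactive",
       ac_m = as.integer(ac_m))
}

#' Write alert events as JSON Lines
#'
#' One JSON object per event with keys `t`, `kind`, `status_text`, `lat`,
#' `lon`, `patient_id`.
#'
#' @param events event list or data frame.
#' @param path output file path.
#' @param patient a [patient_record()].
#' @return The path, invisibly.
#' @export
write_events_jsonl <- function(events, path, patient = patient_record()) {
  ev <- events_df(events)
  ev$patient_id <- patient$patient_id
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(ev)))
    writeLines(jsonlite::toJSON(as.list(ev[i, , drop = FALSE]),
                                auto_unbox = TRUE, digits = NA, na = "null"),
               con)
  invisible(path)
}

#' Read a JSON Lines event log
#'
#' @param path file written by [write_events_jsonl()].
#' @return Data frame of events.
#' @export
read_events_jsonl <- function(path) {
  lines <- readLines(path)
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    x[vapply(x, is.null, logical(1))] <- NA
    as.data.frame(x, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
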