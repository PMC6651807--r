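# Alert-message composition and parsing: the text payload the wearable
# sends to the call emergency centre. The grammar is line-oriented so that
# compose and parse are exact inverses; the location travels as a map link
# whose query string carries the coordinates to 6 decimal places (finer
# than consumer GPS error).

.map_link <- function(lat, lon) {
  sprintf("https://maps.google.com/?q=%.6f,%.6f", lat, lon)
}

#' Compose an alert message
#'
#' Renders an engine alert event as the line-oriented text block sent to
#' the emergency centre: `ID`, `HISTORY` (online message only), `STATUS`,
#' `LOCATION` (map link, alerts only) and `TIME` lines. Location-bearing
#' alerts must carry a fix.
#'
#' @param event an alert event (`list(t, kind, status_text, lat, lon)`)
#'   as produced by [run_stream()].
#' @param patient a [patient_record()].
#' @return A single string (lines separated by `\n`).
#' @examples
#' ev <- list(t = 295, kind = "FALL_ALERT",
#'            status_text = "HR abnormal, patient fall",
#'            lat = 36.19, lon = 44.01)
#' cat(compose_alert(ev, patient_record("P-001")))
#' @export
compose_alert <- function(event, patient = patient_record()) {
  kind <- event$kind
  if (!kind %in% names(.kind_status)) stop("unknown event kind: ", kind)
  lines <- c(sprintf("ID: %s", patient$patient_id))
  if (kind == "ONLINE")
    lines <- c(lines, sprintf("HISTORY: %s", patient$health_history))
  lines <- c(lines, sprintf("STATUS: %s", .kind_status[[kind]]))
  if (kind != "ONLINE") {
    if (is.null(event$lat) || is.null(event$lon) ||
        is.na(event$lat) || is.na(event$lon))
      stop("composition error: ", kind, " requires a geolocation fix")
    lines <- c(lines, sprintf("LOCATION: %s", .map_link(event$lat, event$lon)))
  }
  lines <- c(lines, sprintf("TIME: %s",
                            format(event$t, scientific = FALSE, trim = TRUE)))
  paste(lines, collapse = "\n")
}

#' Parse an alert message
#'
#' Inverse of [compose_alert()]: extracts the patient id, status text,
#' coordinates (when a `LOCATION` line is present) and timestamp. Tolerant
#' of `\r\n` line endings; a malformed location link is an error naming
#' the offending line.
#'
#' @param text message text as produced by [compose_alert()].
#' @return An `alert_message` list with `patient_id`, `status_text`,
#'   `lat`, `lon` (both `NA` for online messages), `t`, and
#'   `health_history` (`NA` unless present).
#' @export
parse_alert <- function(text) {
  if (!is.character(text) || length(text) != 1L)
    stop("message text must be a single string")
  lines <- strsplit(gsub("\r\n?", "\n", text), "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  field <- function(key) {
    hit <- grep(paste0("^", key, ": "), lines, value = TRUE)
    if (length(hit) == 0L) return(NA_character_)
    sub(paste0("^", key, ": "), "", hit[1L])
  }
  id <- field("ID")
  status <- field("STATUS")
  time_s <- field("TIME")
  if (is.na(id) || is.na(status) || is.na(time_s))
    stop("parse error: message must carry ID, STATUS and TIME lines")
  if (!status %in% .kind_status)
    stop("parse error: unknown STATUS '", status, "'")

  lat <- NA_real_; lon <- NA_real_
  loc <- field("LOCATION")
  if (status != "online") {
    if (is.na(loc))
      stop("parse error: status '", status, "' requires a LOCATION line")
  }
  if (!is.na(loc)) {
    m <- regmatches(loc, regexec(
      "\\?q=(-?[0-9]+\\.[0-9]+),(-?[0-9]+\\.[0-9]+)$", loc))[[1]]
    if (length(m) != 3L)
      stop("parse error: malformed location link in line 'LOCATION: ",
           loc, "'")
    lat <- as.numeric(m[2]); lon <- as.numeric(m[3])
  }
  structure(list(
    patient_id = id,
    status_text = status,
    lat = lat, lon = lon,
    t = as.numeric(time_s),
    health_history = field("HISTORY")
  ), class = "alert_message")
}

#' @export
print.alert_message <- function(x, ...) {
  cat("alert message from", x$patient_id, "\n")
  cat("  status:", x$status_text, "\n")
  if (!is.na(x$lat))
    cat(sprintf("  location: %.6f, %.6f\n", x$lat, x$lon))
  cat("  time:", x$t, "s\n")
  invisible(x)
}
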