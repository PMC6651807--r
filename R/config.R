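# Detector configuration: every threshold and timing window of the FDB-HRT
# algorithm lives here so the engine itself carries no magic numbers.

.config_defaults <- list(
  nhr_low          = 60,    # lower bound of the normal heart-rate range [bpm]
  nhr_high         = 100,   # upper bound of the normal heart-rate range [bpm]
  fam_t            = 0.5,   # fall acceleration magnitude threshold FAM_t [g]
  ft_t             = 0.040, # falling time threshold FT_t [s]
  aam_t            = 2.5,   # activity acceleration magnitude threshold AAM_t [g]
  ac_window        = 10,    # post-fall activity observation window [s]
  ac_t             = 10,    # activity counter threshold AC_t [counts]
  hr_confirm_delay = 5,     # sustained-abnormal-HR confirmation time [s]
  post_fall_delay  = 20,    # wait between fall alert and activity check [s]
  hr_recheck_delay = 10,    # wait before the post-activity HR recheck [s]
  accel_rate_hz    = 100,   # accelerometer sampling rate [Hz]
  hr_rate_hz       = 1      # heart-rate sampling rate [Hz]
)

#' Detector configuration for the FDB-HRT engine
#'
#' Builds a validated set of thresholds and timing windows for the hybrid
#' fall detector. Defaults are the selected operating values of the device
#' the engine emulates: a normal heart-rate range of 60--100 bpm, a free-fall
#' threshold of 0.5 g sustained for more than 40 ms, a post-fall activity
#' threshold of 2.5 g, and confirmation/observation delays of 5 s, 20 s and
#' 10 s.
#'
#' @param ... named overrides of any default field. Fields:
#'   `nhr_low`, `nhr_high` (bpm); `fam_t`, `aam_t` (g); `ft_t` (s;
#'   `ft_t_ms` is accepted as a millisecond alias); `ac_window`,
#'   `hr_confirm_delay`, `post_fall_delay`, `hr_recheck_delay` (s);
#'   `ac_t` (counts); `accel_rate_hz`, `hr_rate_hz` (Hz).
#'
#' @return An object of class `detector_config`: a named list of the twelve
#'   validated fields.
#'
#' @examples
#' detector_config()
#' detector_config(nhr_low = 50, ft_t_ms = 60)
#' @export
detector_config <- function(...) {
  load_config(list(...))
}

#' Load and validate a detector configuration
#'
#' Reads a configuration from a JSON or YAML file, or from a named list,
#' fills absent fields with the defaults, and validates every invariant
#' (e.g. `fam_t < aam_t`, positive rates). Unknown keys raise a warning but
#' are ignored; invariant violations are errors.
#'
#' @param source path to a `.json`/`.yaml`/`.yml` file, or a named list.
#' @return A validated `detector_config` object.
#' @seealso [detector_config()]
#' @export
load_config <- function(source = list()) {
  if (is.character(source)) {
    if (length(source) != 1L || !file.exists(source))
      stop("config file not found: ", paste(source, collapse = ", "))
    source <- if (grepl("\\.ya?ml$", source, ignore.case = TRUE))
      yaml::read_yaml(source)
    else
      jsonlite::read_json(source, simplifyVector = TRUE)
  }
  if (is.null(source)) source <- list()
  if (!is.list(source)) stop("config source must be a file path or a named list")

  src <- as.list(source)
  if (length(src) && (is.null(names(src)) || any(names(src) == "")))
    stop("all config entries must be named")

  # millisecond alias for the falling-time threshold
  if ("ft_t_ms" %in% names(src)) {
    if ("ft_t" %in% names(src))
      stop("specify only one of 'ft_t' (s) and 'ft_t_ms' (ms)")
    src$ft_t <- as.numeric(src$ft_t_ms) / 1000
    src$ft_t_ms <- NULL
  }

  unknown <- setdiff(names(src), names(.config_defaults))
  if (length(unknown))
    warning("ignoring unknown config key(s): ", paste(unknown, collapse = ", "))
  src <- src[intersect(names(src), names(.config_defaults))]

  cfg <- utils::modifyList(.config_defaults, lapply(src, as.numeric))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  num1 <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("config field '", field, "' must be a single finite number")
    v
  }
  for (f in names(.config_defaults)) cfg[[f]] <- num1(f)

  if (cfg$fam_t <= 0)
    stop("config error: fam_t must be > 0")
  if (cfg$fam_t >= cfg$aam_t)
    stop("config error: fam_t (", cfg$fam_t, ") must be < aam_t (", cfg$aam_t, ")")
  if (cfg$ft_t <= 0)
    stop("config error: ft_t must be > 0")
  if (cfg$nhr_low >= cfg$nhr_high)
    stop("config error: nhr_low (", cfg$nhr_low, ") must be < nhr_high (",
         cfg$nhr_high, ")")
  if (cfg$ac_window <= 0)
    stop("config error: ac_window must be > 0")
  if (cfg$ac_t < 1)
    stop("config error: ac_t must be >= 1")
  for (f in c("hr_confirm_delay", "post_fall_delay", "hr_recheck_delay"))
    if (cfg[[f]] < 0) stop("config error: ", f, " must be >= 0")
  for (f in c("accel_rate_hz", "hr_rate_hz"))
    if (cfg[[f]] <= 0) stop("config error: ", f, " must be > 0")

  structure(cfg, class = "detector_config")
}

#' @export
print.detector_config <- function(x, ...) {
  cat("FDB-HRT detector configuration\n")
  cat(sprintf("  normal HR range : [%g, %g] bpm\n", x$nhr_low, x$nhr_high))
  cat(sprintf("  free fall       : |a| < %g g for > %g ms\n",
              x$fam_t, x$ft_t * 1000))
  cat(sprintf("  activity        : |a| > %g g, >= %g active s in %g s window\n",
              x$aam_t, x$ac_t, x$ac_window))
  cat(sprintf("  delays          : HR confirm %g s, post-fall %g s, HR recheck %g s\n",
              x$hr_confirm_delay, x$post_fall_delay, x$hr_recheck_delay))
  cat(sprintf("  sampling        : accel %g Hz, HR %g Hz\n",
              x$accel_rate_hz, x$hr_rate_hz))
  invisible(x)
}

as_detector_config <- function(cfg) {
  if (inherits(cfg, "detector_config")) cfg else load_config(cfg)
}
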