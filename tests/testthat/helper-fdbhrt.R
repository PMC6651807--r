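# Shared fixtures: independent brute-force oracles and random-trace
# builders used across the test files.

# Brute-force free-fall oracle: scans every contiguous sub-run of
# below-threshold samples, independent of the rle-based implementation.
brute_force_free_fall <- function(t, mag, fam_t, ft_t) {
  n <- length(t)
  for (i in seq_len(n)) {
    if (mag[i] >= fam_t) next
    j <- i
    while (j < n && mag[j + 1] < fam_t) j <- j + 1
    if (t[j] - t[i] > ft_t) return(TRUE)
  }
  FALSE
}

# Random magnitude window at a fixed rate; magnitudes span both sides of
# the free-fall threshold so below-runs of varying lengths occur.
random_mag_window <- function(n = 60, rate = 100) {
  data.frame(t = (seq_len(n) - 1) / rate,
             magnitude = stats::runif(n, 0, 1.5))
}

# A stream whose HR never leaves the normal range but whose magnitude
# contains genuine free-fall dips: the hybrid gate must suppress alerts.
normal_hr_dip_stream <- function(duration = 20, rate = 100) {
  n <- duration * rate
  t <- (seq_len(n) - 1) / rate
  mag <- 1 + stats::rnorm(n, 0, 0.05)
  dip_at <- stats::runif(1, 5, duration - 2)
  mag[t >= dip_at & t < dip_at + 1] <- 0.1   # a full second of free fall
  hr <- rep(NA_real_, n)
  hr[(seq_len(duration) - 1) * rate + 1] <- stats::runif(duration, 60, 100)
  data.frame(t = t, hr_bpm = hr, magnitude = mag)
}
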