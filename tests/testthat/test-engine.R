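cfg <- detector_config()

test_that("free-fall window test follows the run-length criterion", {
  # 100 ms at free-fall magnitude: detected
  w <- data.frame(t = seq(0, 0.09, by = 0.01), magnitude = 0.16)
  expect_true(detect_free_fall(w, cfg))

  # equilibrium standing: never detected
  w2 <- data.frame(t = seq(0, 1, by = 0.01), magnitude = 1.0)
  expect_false(detect_free_fall(w2, cfg))

  # a 20 ms dip does not exceed the 40 ms falling-time threshold
  t <- seq(0, 1, by = 0.01)
  mag <- rep(1.0, length(t))
  mag[t >= 0.5 & t <= 0.52] <- 0.2
  expect_false(detect_free_fall(data.frame(t = t, magnitude = mag), cfg))
  expect_true(brute_force_free_fall(t, mag, cfg$fam_t, cfg$ft_t) ==
                detect_free_fall(data.frame(t = t, magnitude = mag), cfg))

  expect_error(detect_free_fall(data.frame(t = c(1, 0), magnitude = c(1, 1)),
                                cfg), "non-decreasing")
})

test_that("free-fall detector agrees with the brute-force scan on random traces", {
  set.seed(31)
  for (i in 1:300) {
    w <- random_mag_window()
    expect_identical(detect_free_fall(w, cfg),
                     brute_force_free_fall(w$t, w$magnitude,
                                           cfg$fam_t, cfg$ft_t))
  }
})

test_that("post-fall activity counter counts active whole seconds", {
  t <- seq(0, 9.99, by = 0.01)

  r <- classify_post_fall_activity(data.frame(t = t, magnitude = 1.0), cfg)
  expect_equal(r$activity, "inactive")
  expect_equal(r$ac_m, 0L)

  # one 3 g spike in every second: fully active
  mag <- rep(1.0, length(t))
  mag[(0:9) * 100 + 50] <- 3.0
  r2 <- classify_post_fall_activity(data.frame(t = t, magnitude = mag), cfg)
  expect_equal(r2$activity, "active")
  expect_equal(r2$ac_m, 10L)

  # spikes in 4 of 10 seconds: inactive, counter verified per-second
  mag3 <- rep(1.0, length(t))
  mag3[c(0, 2, 5, 9) * 100 + 10] <- 2.8
  r3 <- classify_post_fall_activity(data.frame(t = t, magnitude = mag3), cfg)
  expect_equal(r3$activity, "inactive")
  brute <- sum(vapply(0:9, function(s)
    any(mag3[floor(t) == s] > cfg$aam_t), logical(1)))
  expect_equal(r3$ac_m, brute)

  expect_error(
    classify_post_fall_activity(data.frame(t = seq(0, 4.99, by = 0.01),
                                           magnitude = 1), cfg),
    "insufficient")
})

test_that("single-step interface walks the preparation and monitoring stages", {
  st <- engine_state(cfg)
  expect_equal(st$mode, "PREP")
  r <- step(st, list(t = 0, hr = 75, ax = 0, ay = 0, az = 1))
  expect_equal(r$state$mode, "MONITORING")
  expect_equal(vapply(r$events, `[[`, "", "kind"), "ONLINE")

  # abnormal reading arms the pending state; a normal one disarms it
  r2 <- step(r$state, list(t = 1, hr = 110, magnitude = 1))
  expect_equal(r2$state$mode, "HR_ABNORMAL_PENDING")
  r3 <- step(r2$state, list(t = 2, hr = 80, magnitude = 1))
  expect_equal(r3$state$mode, "MONITORING")
  expect_length(r3$events, 0)

  expect_error(step(r3$state, list(t = 1, hr = 80, magnitude = 1)),
               "non-decreasing")
})

test_that("a fully normal stream yields only the online event", {
  n <- 3000
  t <- (seq_len(n) - 1) / 100
  hr <- rep(NA_real_, n); hr[(0:29) * 100 + 1] <- 75
  ev <- run_stream(data.frame(t = t, hr_bpm = hr, magnitude = 1.0), cfg)
  expect_equal(vapply(ev, `[[`, "", "kind"), "ONLINE")
})

test_that("fall detection is gated on abnormal heart rate", {
  set.seed(41)
  for (i in 1:25) {
    stream <- normal_hr_dip_stream()
    ev <- run_stream(stream, cfg)
    kinds <- vapply(ev, `[[`, "", "kind")
    expect_false(any(kinds == "FALL_ALERT"))
  }
})

test_that("a fall with sustained abnormal HR emits one fall alert then inactivity", {
  tr <- gen_activity_trace("F1", seed = 5, cfg)
  ev <- events_df(run_stream(tr, cfg, fix_source = c(36.19, 44.01)))
  expect_equal(sum(ev$kind == "FALL_ALERT"), 1)
  expect_equal(sum(ev$kind == "INACTIVE_ALERT"), 1)
  fall_t <- ev$t[ev$kind == "FALL_ALERT"]
  inact_t <- ev$t[ev$kind == "INACTIVE_ALERT"]
  # inactivity decision comes after the post-fall delay plus the window
  expect_gte(inact_t - fall_t, cfg$post_fall_delay + cfg$ac_window)
  # alerts carry the fix, online does not
  expect_true(all(!is.na(ev$lat[ev$kind != "ONLINE"])))
  expect_true(all(is.na(ev$lat[ev$kind == "ONLINE"])))
})

test_that("an active patient with persisting abnormal HR triggers the recheck alert", {
  # fall, then vigorous movement during the activity window, HR abnormal
  rate <- cfg$accel_rate_hz
  dur <- 60
  n <- dur * rate
  t <- (seq_len(n) - 1) / rate
  mag <- 1 + stats::rnorm(n, 0, 0.01)
  mag[t >= 10 & t < 10.15] <- 0.2             # free fall
  mag[t >= 10.15 & t < 10.2] <- 3.5           # impact
  active <- t >= 30 & t < 41                   # activity window ~30.x-40.x
  mag[active][seq(1, sum(active), by = 20)] <- 3.0
  hr <- rep(NA_real_, n)
  hr[(seq_len(dur) - 1) * rate + 1] <- 110     # abnormal throughout
  ev <- events_df(run_stream(data.frame(t = t, hr_bpm = hr, magnitude = mag),
                             cfg, fix_source = c(1, 2)))
  expect_equal(sum(ev$kind == "FALL_ALERT"), 1)
  expect_equal(sum(ev$kind == "INACTIVE_ALERT"), 0)
  expect_equal(sum(ev$kind == "ACTIVE_HR_ABNORMAL_ALERT"), 1)
})

test_that("streams replay deterministically and scenarios compose", {
  tr <- gen_activity_trace("F2", seed = 6, cfg)
  ev1 <- run_stream(tr, cfg, fix_source = c(1, 2))
  ev2 <- run_stream(tr, cfg, fix_source = c(1, 2))
  expect_identical(ev1, ev2)

  # two independent fall scenarios in one stream: two fall alerts with
  # increasing timestamps. The first patient recovers (activity in the
  # window, HR back to normal at the recheck), so monitoring re-arms
  # before the second fall; a patient declared inactive stays in the
  # terminal awaiting-help state instead.
  rate <- cfg$accel_rate_hz
  dur <- 55
  n <- dur * rate
  t <- (seq_len(n) - 1) / rate
  mag <- 1 + stats::rnorm(n, 0, 0.01)
  mag[t >= 10 & t < 10.15] <- 0.2
  mag[t >= 10.15 & t < 10.2] <- 3.2
  active <- t >= 30 & t < 41
  mag[active][seq(1, sum(active), by = 20)] <- 3.0
  hr_sec <- rep(110, dur)
  hr_sec[46:dur] <- 75                        # HR normal again by recheck
  hr <- rep(NA_real_, n)
  hr[(seq_len(dur) - 1) * rate + 1] <- hr_sec
  first <- data.frame(t = t, hr_bpm = hr, magnitude = mag)

  tr2 <- gen_activity_trace("F4", seed = 7, cfg)
  second <- data.frame(t = tr2$t + dur + 1, hr_bpm = tr2$hr_bpm,
                       magnitude = accel_magnitude(tr2$ax_g, tr2$ay_g,
                                                   tr2$az_g))
  ev <- events_df(run_stream(rbind(first, second), cfg, fix_source = c(1, 2)))
  falls <- ev$t[ev$kind == "FALL_ALERT"]
  expect_length(falls, 2)
  expect_true(all(diff(falls) > 0))
  # only one online event even across the concatenation
  expect_equal(sum(ev$kind == "ONLINE"), 1)
})

test_that("empty stream emits the online event only", {
  ev <- run_stream(data.frame(t = numeric(0), magnitude = numeric(0)), cfg)
  expect_equal(vapply(ev, `[[`, "", "kind"), "ONLINE")
})

test_that("a failing fix source downgrades the fix but never suppresses the alert", {
  tr <- gen_activity_trace("F1", seed = 8, cfg)
  w <- capture_warnings(
    ev <- events_df(run_stream(tr, cfg,
                               fix_source = function() stop("gps timeout"))))
  expect_match(w, "fix unavailable", all = TRUE)
  expect_length(w, 2)  # one per location-bearing alert
  expect_equal(sum(ev$kind == "FALL_ALERT"), 1)
  expect_true(all(is.na(ev$lat)))
})

test_that("event logs round-trip through JSON lines", {
  tr <- gen_activity_trace("F1", seed = 9, cfg)
  ev <- events_df(run_stream(tr, cfg, fix_source = c(36.19, 44.01)))
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_events_jsonl(ev, f, patient_record("P-007"))
  back <- read_events_jsonl(f)
  expect_equal(nrow(back), nrow(ev))
  expect_equal(back$kind, ev$kind)
  expect_equal(back$t, ev$t)
  expect_true(all(back$patient_id == "P-007"))
})
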