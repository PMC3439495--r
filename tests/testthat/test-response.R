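test_that("level estimation is exact on noiseless plateaus and mode-seeking on ripple", {
  proto <- transition_protocol(0, 255, 10)
  block <- round(10 / RR * FS)
  sq <- rep(c(rep(0.2, block), rep(0.8, block)), 3)
  lv <- estimate_levels(sq, proto, FS, RR)
  expect_equal(lv$level_low, 0.2)
  expect_equal(lv$level_high, 0.8)
  # symmetric two-tone ripple (center-weighted dwell): level = center
  tt <- seq_along(sq) / FS
  rip <- 0.03 * sin(2 * pi * 121 * tt) + 0.03 * sin(2 * pi * 89 * tt)
  lv2 <- estimate_levels(sq + rip, proto, FS, RR)
  expect_lt(abs(lv2$level_low - 0.2), 5e-3)
  expect_lt(abs(lv2$level_high - 0.8), 5e-3)
  # skewed PWM-like plateau (duty 0.8): mode = high dwell level, not mean
  t <- seq_along(sq) / FS
  duty_ripple <- ifelse(((121 * t) %% 1) < 0.8, 0.02, -0.08)
  lv3 <- estimate_levels(sq + duty_ripple, proto, FS, RR)
  # brute-force density-scan oracle on the same plateau samples
  plateau_idx <- which(rep(rep(c(TRUE, FALSE), each = block), 3) &
                         (seq_along(sq) - 1) %% block >= block / 2)
  xs <- (sq + duty_ripple)[plateau_idx]
  h <- 1.144 * sd(xs) * length(xs)^(-0.2)
  grid <- seq(min(xs) - h, max(xs) + h, length.out = 4000)
  dens <- vapply(grid,
                 function(g) sum(dnorm((g - xs) / h)), numeric(1))
  expect_equal(lv3$level_low, grid[which.max(dens)], tolerance = 2 * h)
  expect_gt(lv3$level_low, 0.2)    # pulled to the high dwell, not the mean
  expect_error(estimate_levels(sq[1:100], proto, FS, RR),
               "protocol period")
  expect_error(estimate_levels(sq, transition_protocol(0, 255, 1), FS, RR),
               "2 frames")
})

test_that("response_time matches closed forms: ramp, exponential, step", {
  fs <- FS
  # linear ramp of duration D: rt = 0.8 * D
  D <- 0.05
  ramp <- c(rep(0, 500), seq(0, 1, length.out = D * fs), rep(1, 500))
  expect_equal(response_time(ramp, 0, 1, "rising", fs), 0.8 * D * 1000,
               tolerance = 1e-2)
  # exponential: rt = tau * ln 9 within one sample interval
  for (tau_ms in c(2, 7, 21)) {
    t <- seq(0, 0.4, by = 1 / fs)
    y <- c(rep(0, 300), 1 - exp(-t / (tau_ms / 1000)))
    expect_lt(abs(response_time(y, 0, 1, "rising", fs) - tau_ms * log(9)),
              1000 / fs)
  }
  # step: rt below one sample interval
  stp <- c(rep(0, 400), rep(1, 400))
  expect_lt(response_time(stp, 0, 1, "rising", fs), 1000 / fs)
  # falling direction mirrors
  fall <- c(rep(1, 300), exp(-seq(0, 0.3, by = 1 / fs) / 0.005),
            rep(0, 100))
  expect_lt(abs(response_time(fall, 0, 1, "falling", fs) - 5 * log(9)),
            1000 / fs)
  expect_error(response_time(rep(0.5, 1000), 0, 1, "rising", fs),
               "no transition")
})

test_that("overshoot-extended RT reproduces the printed worked example arithmetic", {
  # a 5 ms ISO RT extended to 51 ms is an increase of 920%
  expect_equal(rt_increase_percent(5, 51), 920)
  # extended RT always >= ISO RT on a synthetic overshoot
  m <- display_model(tau_rise_ms = 3, tau_fall_ms = 3,
                     dcc = dcc_config("overdrive", overshoot_fraction = 0.3,
                                      overshoot_decay_ms = 2000 / 60))
  proto <- transition_protocol(0, 63, 10)
  sim <- simulate_transition(m, proto, 1, FS, RR, seed = 5)
  sig <- m$max_luminance * sim$truth$transparency
  lv <- estimate_levels(sig, proto, FS, RR)
  win <- extract_transition_window(sig, proto, FS, RR)
  rt <- response_time(win$signal, lv$level_low, lv$level_high, "rising", FS)
  ov <- overshoot_response_time(win$signal, lv$level_low, lv$level_high, FS)
  expect_gte(ov$rt_extended_ms, rt)
  expect_lt(abs(ov$overshoot_peak_fraction - 0.3), 0.02)
  # monotone exponential: no extended RT, zero peak fraction
  clean <- clean_transition_window(5)
  lvc <- range(clean)
  ovc <- overshoot_response_time(clean, lvc[1], lvc[2], FS)
  expect_true(is.na(ovc$rt_extended_ms))
  expect_equal(ovc$overshoot_peak_fraction, 0)
})

test_that("stepping detector flags staircase transitions and recovers plateaus", {
  proto <- transition_protocol(63, 127, 10)
  m <- display_model(tau_rise_ms = 2, tau_fall_ms = 2,
                     dcc = dcc_config(stepping = c(0.6, 0.9, 1.0)))
  sim <- simulate_transition(m, proto, 1, FS, RR, seed = 5)
  sig <- m$max_luminance * sim$truth$transparency
  st <- detect_stepping(sig, proto, FS, RR)
  expect_true(st$stepping_detected)
  expect_equal(st$per_frame_plateaus[1:2], c(0.6, 0.9), tolerance = 0.02)
  # clean exponentials of various speeds are not flagged
  for (tau in c(3, 8, 20)) {
    mc <- display_model(tau_rise_ms = tau, tau_fall_ms = tau)
    simc <- simulate_transition(mc, proto, 1, FS, RR, seed = 5)
    stc <- detect_stepping(mc$max_luminance * simc$truth$transparency,
                           proto, FS, RR)
    expect_false(stc$stepping_detected)
  }
  # detection is invariant to added PWM once decomposed
  mp <- display_model(tau_rise_ms = 2, tau_fall_ms = 2,
                      dcc = dcc_config(stepping = c(0.6, 0.9, 1.0)),
                      backlight = backlight_config("pwm", frequency = 131,
                                                   duty_cycle = 0.6,
                                                   modulation_depth = 0.4))
  simp <- simulate_transition(mp, proto, 1, FS, RR, seed = 5)
  static <- simulate_static(mp, 255, 1, FS, RR, seed = 6)
  dec <- decompose_trace(simp$trace, static)
  stp <- detect_stepping(dec$transition, proto, FS, RR)
  expect_true(stp$stepping_detected)
  expect_equal(stp$per_frame_plateaus[1:2], c(0.6, 0.9), tolerance = 0.02)
})

test_that("onset-advance detector reads pre-tilt and pulse duration exceeds 11 frames", {
  proto <- transition_protocol(0, 127, 10)
  m <- display_model(tau_rise_ms = 4, tau_fall_ms = 4,
                     dcc = dcc_config("pre_tilt", pre_tilt_advance = 1))
  sim <- simulate_transition(m, proto, 1, FS, RR, seed = 5)
  sig <- m$max_luminance * sim$truth$transparency
  lv <- estimate_levels(sig, proto, FS, RR)
  amp <- lv$level_high - lv$level_low
  expect_equal(
    detect_onset_advance(sig, 10 / RR, lv$level_low, amp, FS, RR), 1)
  # the 10-frame commanded pulse lasts > 11 frames above baseline
  pulse <- sig[seq_len(round(2.2 * 10 / RR * FS))]
  expect_gt(duration_above_baseline(pulse, lv$level_low, amp, FS) * RR, 11)
  # without pre-tilt the advance is 0
  m0 <- display_model(tau_rise_ms = 4, tau_fall_ms = 4)
  sim0 <- simulate_transition(m0, proto, 1, FS, RR, seed = 5)
  sig0 <- m0$max_luminance * sim0$truth$transparency
  expect_equal(
    detect_onset_advance(sig0, 10 / RR, lv$level_low, amp, FS, RR), 0)
  expect_error(
    detect_onset_advance(rep(lv$level_low, 1000), 0.05, lv$level_low,
                         amp, FS, RR), "no departure")
})

test_that("RT summaries aggregate the grid the way the report presents them", {
  # all equal -> sd 0, CoV 0
  eq <- data.frame(from_level = c(0, 255), to_level = c(255, 0),
                   rt_iso_ms = c(7, 7))
  s <- summarize_rts(eq)
  expect_equal(s$grand_mean, 7)
  expect_equal(s$grand_sd, 0)
  expect_equal(s$coefficient_of_variation, 0)
  # CoV equals sd/mean recomputed by brute force; rising count = n(n-1)/2
  set.seed(3)
  grid <- level_grid()
  pairs <- enumerate_transitions(grid)
  pairs$rt_iso_ms <- runif(nrow(pairs), 3, 25)
  s2 <- summarize_rts(pairs)
  expect_equal(s2$coefficient_of_variation,
               sd(pairs$rt_iso_ms) / mean(pairs$rt_iso_ms),
               tolerance = 1e-12)
  expect_equal(s2$n_rising, 10)
  expect_equal(s2$n_falling, 10)
  expect_equal(s2$rising_mean,
               mean(pairs$rt_iso_ms[pairs$to_level > pairs$from_level]))
  expect_equal(s2$black_to_white,
               pairs$rt_iso_ms[pairs$from_level == 0 & pairs$to_level == 255])
  # repetitions: per-transition sd over identical repetitions is 0
  reps <- pairs[rep(1:2, each = 3), ]
  s3 <- summarize_rts(reps)
  expect_equal(s3$per_transition$sd_ms, c(0, 0))
  expect_error(summarize_rts(pairs[0, ]), "empty")
})
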