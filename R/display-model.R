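#' Backlight configuration
#'
#' Describes the backlight modulation of a simulated LCD.  Real backlights
#' (CCFL or LED) are dimmed by pulse width modulation (PWM), producing a
#' periodic luminance ripple whose fundamental is typically between about
#' 89 and 207 Hz and, with few exceptions, not an integer multiple of the
#' refresh rate -- hence not phase locked to frame onsets.  Motion-picture
#' ("blinking backlight") modes instead switch the whole backlight on and
#' off once per frame, locking the modulation to the refresh rate.
#'
#' @param mode `"constant"`, `"pwm"` or `"blinking"`.
#' @param frequency PWM fundamental in Hz (ignored for `"constant"`; forced
#'   to the refresh rate for `"blinking"`).
#' @param duty_cycle Fraction of each PWM period the backlight is on, in
#'   (0, 1].
#' @param modulation_depth Peak-to-trough modulation as a fraction of the
#'   on-level, in \[0, 1\]; 0 gives a constant backlight whatever the mode.
#' @param phase Phase offset in radians of the PWM cycle at t = 0.  For
#'   `"blinking"` the default (`NULL`) places the flash in the last
#'   `duty_cycle` fraction of each frame, as motion-picture modes do so
#'   the liquid crystal has settled before the backlight illuminates it;
#'   for the other modes the default is 0.
#' @param phase_locked Logical bookkeeping flag: whether the configured
#'   frequency is an integer multiple of the refresh rate.
#' @param edge_smoothing_ms Raised-cosine smoothing of the pulse edges, in
#'   ms.  The default 0.2 ms avoids pathological single-sample duty cycles
#'   at a 10 kHz sampling rate.
#' @return An object of class `backlight_config`.
#' @export
backlight_config <- function(mode = c("constant", "pwm", "blinking"),
                             frequency = 120, duty_cycle = 0.5,
                             modulation_depth = 0, phase = NULL,
                             phase_locked = FALSE,
                             edge_smoothing_ms = 0.2) {
  mode <- match.arg(mode)
  if (is.null(phase))
    phase <- if (mode == "blinking") 2 * pi * duty_cycle else 0
  if (mode != "constant" && frequency <= 0)
    stop("backlight frequency must be > 0 for periodic modes", call. = FALSE)
  if (duty_cycle <= 0 || duty_cycle > 1)
    stop("duty_cycle must lie in (0, 1]", call. = FALSE)
  if (modulation_depth < 0 || modulation_depth > 1)
    stop("modulation_depth must lie in [0, 1]", call. = FALSE)
  structure(
    list(mode = mode, frequency = frequency, duty_cycle = duty_cycle,
         modulation_depth = modulation_depth, phase = phase,
         phase_locked = isTRUE(phase_locked),
         edge_smoothing_ms = edge_smoothing_ms),
    class = "backlight_config")
}

#' Overdrive (DCC) configuration
#'
#' Dynamic capacitance compensation shortens LC transitions by briefly
#' over-volting rising transitions (overdrive) and cutting the voltage on
#' falling ones (undershoot).  Improper tuning produces luminance
#' overshoot, framewise luminance stepping, or -- for the pre-tilt
#' variant (DCC II) -- a stimulus onset one frame before the commanded
#' frame.
#'
#' @param mode `"none"`, `"overdrive"` (overshoot on rising transitions),
#'   `"overdrive_undershoot"` (additionally undershoot on falling ones) or
#'   `"pre_tilt"` (DCC II onset advance).
#' @param overshoot_fraction Peak luminance excess above the target level
#'   as a fraction of the transition amplitude.
#' @param overshoot_decay_ms Time constant of the decay of the excess, in
#'   ms; the default spans about three frames at 60 Hz, matching the
#'   overshoot transients seen on badly tuned monitors.
#' @param pre_tilt_advance Onset advance in frames (0 or 1).
#' @param stepping Optional increasing vector of per-frame plateau
#'   fractions in (0, 1\] ending at 1; frame k of a transition saturates at
#'   `stepping[k]` of the amplitude (luminance stepping artifact).
#' @return An object of class `dcc_config`.
#' @export
dcc_config <- function(mode = c("none", "overdrive", "overdrive_undershoot",
                                "pre_tilt"),
                       overshoot_fraction = 0, overshoot_decay_ms = 50/3,
                       pre_tilt_advance = 0, stepping = NULL) {
  mode <- match.arg(mode)
  if (overshoot_fraction < 0)
    stop("overshoot_fraction must be >= 0", call. = FALSE)
  if (!pre_tilt_advance %in% c(0, 1))
    stop("pre_tilt_advance must be 0 or 1", call. = FALSE)
  if (!is.null(stepping)) {
    if (any(stepping <= 0) || any(stepping > 1) || any(diff(stepping) <= 0))
      stop("stepping fractions must be strictly increasing within (0, 1]",
           call. = FALSE)
  }
  structure(
    list(mode = mode, overshoot_fraction = overshoot_fraction,
         overshoot_decay_ms = overshoot_decay_ms,
         pre_tilt_advance = as.integer(pre_tilt_advance),
         stepping = stepping),
    class = "dcc_config")
}

#' Generative model of a synthetic LCD
#'
#' Bundles the parameters from which the simulator builds the photometric
#' output `L(t) = max_luminance * T(t) * B(t) * (1 + d * r(t)) + noise`:
#' first-order liquid-crystal transitions `T(t)` with separate rise and
#' fall time constants (normally white panels relax asymmetrically),
#' backlight modulation `B(t)`, a refresh-locked frame-response sawtooth
#' `r(t)` of relative depth `d`, and additive Gaussian sensor noise.
#'
#' @param tau_rise_ms,tau_fall_ms First-order LC time constants in ms for
#'   rising and falling transitions.
#' @param dcc A [dcc_config()].
#' @param backlight A [backlight_config()].
#' @param frame_response_depth Relative depth of the refresh-locked
#'   modulation, in \[0, 1); about 0.02 on the worst monitors measured.
#' @param noise_sd Standard deviation of additive Gaussian sensor noise in
#'   luminance units.
#' @param max_luminance Full-white luminance in cd/m^2.
#' @param gamma Exponent of the default gray-to-transparency map.
#' @param black_level Transparency at gray level 0 (LC panels leak; black
#'   is never zero luminance).
#' @param gamma_map Optional monotone function gray level (0..255) ->
#'   steady-state transparency in \[0, 1\]; overrides `gamma`/`black_level`.
#' @return An object of class `display_model`.
#' @export
display_model <- function(tau_rise_ms = 8, tau_fall_ms = 4,
                          dcc = dcc_config(),
                          backlight = backlight_config(),
                          frame_response_depth = 0, noise_sd = 0,
                          max_luminance = 300, gamma = 2.2,
                          black_level = 0.02, gamma_map = NULL) {
  if (tau_rise_ms <= 0 || tau_fall_ms <= 0)
    stop("LC time constants must be > 0", call. = FALSE)
  if (frame_response_depth < 0 || frame_response_depth >= 1)
    stop("frame_response_depth must lie in [0, 1)", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.null(gamma_map)) {
    b <- black_level
    g <- gamma
    gamma_map <- function(level) b + (1 - b) * (level / 255)^g
  }
  if (gamma_map(0) < 0 || gamma_map(255) > 1 ||
      gamma_map(255) <= gamma_map(0))
    stop("gamma_map must be nondecreasing within [0, 1]", call. = FALSE)
  structure(
    list(tau_rise_ms = tau_rise_ms, tau_fall_ms = tau_fall_ms,
         dcc = dcc, backlight = backlight,
         frame_response_depth = frame_response_depth,
         noise_sd = noise_sd, max_luminance = max_luminance,
         gamma_map = gamma_map),
    class = "display_model")
}

# Normalized overshoot pulse (1 - exp(-u/tau)) * exp(-u/decay), scaled so
# its maximum is exactly 1; the analytic argmax is tau*log((tau+decay)/tau).
overshoot_pulse <- function(u, tau, decay) {
  f <- function(v) (1 - exp(-v / tau)) * exp(-v / decay)
  peak <- f(tau * log((tau + decay) / tau))
  out <- numeric(length(u))
  pos <- u >= 0
  out[pos] <- f(u[pos]) / peak
  out
}

# Scale c of the excess pulse such that the waveform's realized peak
# exceeds the target by exactly os_frac * amp (the base exponential still
# sits below target while the pulse peaks, so c > os_frac * amp).
overshoot_excess_scale <- function(tau, decay, amp_abs, os_frac) {
  u <- seq(0, 6 * max(tau, decay), length.out = 4000)
  g <- overshoot_pulse(u, tau, decay)
  d <- amp_abs * exp(-u / tau)
  target <- os_frac * amp_abs
  stats::uniroot(function(c) max(c * g - d) - target,
                 lower = target, upper = target + amp_abs,
                 tol = 1e-10 * max(amp_abs, 1))$root
}

#' Liquid-crystal transition waveform
#'
#' Transparency time course of a single commanded transition: a
#' first-order exponential from `gamma_map(from_level)` toward
#' `gamma_map(to_level)`, optionally shaped by DCC artifacts (overshoot
#' excess, pre-tilt onset advance, per-frame stepping saturation).
#'
#' @param model A [display_model()].
#' @param from_level,to_level Commanded gray levels.
#' @param t Time grid in seconds.
#' @param onset Commanded transition onset in seconds (within `t`'s range).
#' @param refresh_rate Refresh rate in Hz (frame timing for pre-tilt and
#'   stepping).
#' @return Transparency sequence in \[0, 1\] on the grid `t`.
#' @export
lc_transition_waveform <- function(model, from_level, to_level, t,
                                   onset = 0, refresh_rate = 60) {
  start <- model$gamma_map(from_level)
  target <- model$gamma_map(to_level)
  if (from_level == to_level) {
    if (model$dcc$mode != "none")
      warning("identical levels with DCC enabled: constant output")
    return(rep(start, length(t)))
  }
  rising <- target > start
  tau <- (if (rising) model$tau_rise_ms else model$tau_fall_ms) / 1000
  eff_onset <- onset
  if (model$dcc$mode == "pre_tilt" && rising)
    eff_onset <- onset - model$dcc$pre_tilt_advance / refresh_rate
  u <- t - eff_onset
  y <- ifelse(u < 0, start, target + (start - target) * exp(-u / tau))
  dcc <- model$dcc
  amp <- target - start
  if (dcc$overshoot_fraction > 0 &&
      ((dcc$mode == "overdrive" && rising) ||
       (dcc$mode == "overdrive_undershoot"))) {
    decay <- dcc$overshoot_decay_ms / 1000
    cs <- overshoot_excess_scale(tau, decay, abs(amp),
                                 dcc$overshoot_fraction)
    y <- y + sign(amp) * cs * overshoot_pulse(u, tau, decay)
  }
  if (!is.null(dcc$stepping)) {
    frame <- 1 / refresh_rate
    k <- floor(u / frame) + 1          # frame index after onset, 1-based
    frac <- c(dcc$stepping, 1)[pmin(pmax(k, 1), length(dcc$stepping) + 1)]
    clamp <- start + frac * amp
    y <- ifelse(u >= 0,
                if (rising) pmin(y, clamp) else pmax(y, clamp),
                y)
  }
  pmin(pmax(y, 0), 1)
}

#' Backlight modulation waveform
#'
#' Generates the multiplicative backlight component `B(t)`, normalized to
#' mean 1 over the grid.  PWM mode produces a duty-cycled square wave with
#' raised-cosine edge smoothing; blinking mode is PWM locked to the
#' refresh rate (motion-picture mode); constant mode is all ones.
#'
#' @param config A [backlight_config()].
#' @param t Uniform time grid in seconds.
#' @param refresh_rate Refresh rate in Hz (blinking fundamental).
#' @return Numeric modulation sequence with mean 1.
#' @export
backlight_waveform <- function(config, t, refresh_rate = 60) {
  n <- length(t)
  if (config$mode == "constant" || config$modulation_depth == 0)
    return(rep(1, n))
  f <- if (config$mode == "blinking") refresh_rate else config$frequency
  dt <- t[2] - t[1]
  # area-sample the pulse train over each sample interval (a photometer
  # integrates over its sampling aperture; point-sampling would quantize
  # the pulse edges to whole samples)
  duty <- config$duty_cycle
  g <- function(phi) duty * floor(phi) + pmin(phi %% 1, duty)
  phase <- f * t + config$phase / (2 * pi)
  on <- (g(phase + f * dt) - g(phase)) / (f * dt)
  raw <- (1 - config$modulation_depth) + config$modulation_depth * on
  fs <- 1 / (t[2] - t[1])
  k <- round(config$edge_smoothing_ms / 1000 * fs)
  if (k >= 2) {
    w <- 0.5 * (1 - cos(2 * pi * seq_len(k) / (k + 1)))
    w <- w / sum(w)
    pad <- c(rep(raw[1], k), raw, rep(raw[n], k))
    sm <- stats::filter(pad, w, sides = 2)
    raw <- as.numeric(sm[(k + 1):(k + n)])
  }
  raw / mean(raw)
}

# Frame-response carrier: zero-mean sawtooth locked to the refresh rate.
frame_response_wave <- function(t, refresh_rate) {
  2 * ((t * refresh_rate) %% 1) - 1
}

# Commanded level per sample for the periodic blink protocol, plus the
# commanded transition onset times.  The recording starts at a frame
# boundary with a full block of from_level.
protocol_schedule <- function(protocol, duration, sampling_rate,
                              refresh_rate) {
  frame <- 1 / refresh_rate
  block <- protocol$frames_per_level * frame
  t <- seq(0, duration - 1 / sampling_rate, by = 1 / sampling_rate)
  half <- floor(t / block)                  # 0-based half-period index
  level <- ifelse(half %% 2 == 0, protocol$from_level, protocol$to_level)
  n_half <- floor(duration / block)
  starts <- (seq_len(n_half)) * block       # command-change times > 0
  list(t = t, level = level, block = block,
       onsets = starts[seq(1, length(starts), by = 2)],   # -> to_level
       offsets = if (length(starts) >= 2)
         starts[seq(2, length(starts), by = 2)] else numeric(0))
}

# Piecewise-analytic LC transparency for a commanded level schedule.
lc_schedule_waveform <- function(model, sched, refresh_rate) {
  t <- sched$t
  level <- sched$level
  y <- numeric(length(t))
  changes <- c(1L, which(diff(level) != 0) + 1L, length(t) + 1L)
  cur <- model$gamma_map(level[1])
  for (s in seq_len(length(changes) - 1L)) {
    i0 <- changes[s]; i1 <- changes[s + 1L] - 1L
    idx <- i0:i1
    tgt_level <- level[i0]
    target <- model$gamma_map(tgt_level)
    if (s == 1L || abs(target - cur) < 1e-12) {
      seg <- rep(cur, length(idx))
      # steady segment may still relax if cur != target (stepping clamp)
      if (abs(target - cur) >= 1e-12) {
        tau <- (if (target > cur) model$tau_rise_ms else
                  model$tau_fall_ms) / 1000
        u <- t[idx] - t[i0]
        seg <- target + (cur - target) * exp(-u / tau)
      }
      y[idx] <- seg
      cur <- seg[length(seg)]
      next
    }
    rising <- target > cur
    tau <- (if (rising) model$tau_rise_ms else model$tau_fall_ms) / 1000
    onset <- t[i0]
    dcc0 <- model$dcc
    if (dcc0$mode == "pre_tilt" && rising && dcc0$pre_tilt_advance > 0 &&
        i0 > 1L) {
      # DCC II: the voltage is applied during the preceding frame, so the
      # effective onset moves earlier; overwrite the tail of the previous
      # (settled) segment with the advanced exponential.
      adv <- dcc0$pre_tilt_advance / refresh_rate
      eff_onset <- onset - adv
      pre_idx <- which(t >= eff_onset & t < onset)
      if (length(pre_idx)) {
        start_val <- y[pre_idx[1]]
        all_idx <- c(pre_idx, idx)
        y[all_idx] <- target + (start_val - target) *
          exp(-(t[all_idx] - eff_onset) / tau)
        cur <- y[i1]
        next
      }
    }
    u <- t[idx] - onset
    seg <- target + (cur - target) * exp(-u / tau)
    dcc <- model$dcc
    amp <- target - cur
    if (dcc$overshoot_fraction > 0 &&
        ((dcc$mode == "overdrive" && rising) ||
         dcc$mode == "overdrive_undershoot")) {
      decay <- dcc$overshoot_decay_ms / 1000
      cs <- overshoot_excess_scale(tau, decay, abs(amp),
                                   dcc$overshoot_fraction)
      seg <- seg + sign(amp) * cs * overshoot_pulse(u, tau, decay)
    }
    if (!is.null(dcc$stepping)) {
      frame <- 1 / refresh_rate
      k <- pmin(pmax(floor(u / frame) + 1, 1), length(dcc$stepping) + 1)
      frac <- c(dcc$stepping, 1)[k]
      clamp <- cur + frac * amp
      seg <- if (rising) pmin(seg, clamp) else pmax(seg, clamp)
    }
    y[idx] <- seg
    cur <- seg[length(seg)]
  }
  pmin(pmax(y, 0), 1)
}

check_aliasing <- function(model, sampling_rate) {
  fmax <- max(model$backlight$frequency * (model$backlight$mode == "pwm"),
              0)
  if (sampling_rate <= 2 * fmax)
    stop("sampling_rate must exceed twice the backlight frequency",
         call. = FALSE)
}

#' Simulate a periodic transition recording
#'
#' Generates the photometric output of a synthetic LCD running the blink
#' protocol (from-level for `frames_per_level` frames, then to-level, and
#' so on), as the product of the LC transparency, the backlight modulation
#' and the frame-response factor, plus sensor noise.  Ground truth for all
#' generative components is returned alongside for estimator validation.
#'
#' @param model A [display_model()].
#' @param protocol A [transition_protocol()].
#' @param duration Recording duration in seconds (default 1).
#' @param sampling_rate Sampling rate in Hz (default 10000).
#' @param refresh_rate Refresh rate in Hz (default 60).
#' @param seed Integer seed; identical seeds give identical traces.
#' @return A list with elements `trace` (a [luminance_trace()]) and
#'   `truth` (list with the transparency `T`, backlight `B`, commanded
#'   onsets/offsets, steady levels, time constants and the analytic
#'   10--90% response times `tau * ln 9`).
#' @export
simulate_transition <- function(model, protocol, duration = 1,
                                sampling_rate = 10000, refresh_rate = 60,
                                seed = 1) {
  check_aliasing(model, sampling_rate)
  sched <- protocol_schedule(protocol, duration, sampling_rate,
                             refresh_rate)
  if (duration < 2 * sched$block)
    stop("duration must cover at least one full protocol period",
         call. = FALSE)
  Tsig <- lc_schedule_waveform(model, sched, refresh_rate)
  B <- backlight_waveform(model$backlight, sched$t, refresh_rate)
  fr <- 1 + model$frame_response_depth *
    frame_response_wave(sched$t, refresh_rate)
  set.seed(seed)
  noise <- if (model$noise_sd > 0)
    stats::rnorm(length(sched$t), 0, model$noise_sd) else 0
  samples <- model$max_luminance * Tsig * B * fr + noise
  rising <- model$gamma_map(protocol$to_level) >
    model$gamma_map(protocol$from_level)
  tau_on <- if (rising) model$tau_rise_ms else model$tau_fall_ms
  tau_off <- if (rising) model$tau_fall_ms else model$tau_rise_ms
  trace <- luminance_trace(
    samples, sampling_rate, refresh_rate,
    annotation = sprintf("synthetic transition %d->%d rgbU",
                         protocol$from_level, protocol$to_level))
  truth <- list(
    transparency = Tsig, backlight = B, time = sched$t,
    onsets = sched$onsets, offsets = sched$offsets,
    level_from = model$max_luminance * model$gamma_map(protocol$from_level),
    level_to = model$max_luminance * model$gamma_map(protocol$to_level),
    tau_on_ms = tau_on, tau_off_ms = tau_off,
    rt_on_ms = tau_on * log(9), rt_off_ms = tau_off * log(9),
    backlight_frequency = if (model$backlight$mode == "constant" ||
                              model$backlight$modulation_depth == 0)
      NA_real_
    else if (model$backlight$mode == "blinking") refresh_rate
    else model$backlight$frequency,
    backlight_phase = model$backlight$phase)
  list(trace = trace, truth = truth)
}

#' Simulate a static test-patch recording
#'
#' No commanded transition: the output contains only the steady LC
#' transparency, backlight modulation, frame response and noise.  Static
#' recordings are the input for backlight-template estimation and for the
#' spectral frame-response test.
#'
#' @inheritParams simulate_transition
#' @param level Commanded gray level held throughout.
#' @return A [luminance_trace()].
#' @export
simulate_static <- function(model, level, duration = 1,
                            sampling_rate = 10000, refresh_rate = 60,
                            seed = 1) {
  check_aliasing(model, sampling_rate)
  t <- seq(0, duration - 1 / sampling_rate, by = 1 / sampling_rate)
  B <- backlight_waveform(model$backlight, t, refresh_rate)
  fr <- 1 + model$frame_response_depth * frame_response_wave(t, refresh_rate)
  set.seed(seed)
  noise <- if (model$noise_sd > 0)
    stats::rnorm(length(t), 0, model$noise_sd) else 0
  samples <- model$max_luminance * model$gamma_map(level) * B * fr + noise
  luminance_trace(samples, sampling_rate, refresh_rate,
                  annotation = sprintf("synthetic static %d rgbU", level))
}
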