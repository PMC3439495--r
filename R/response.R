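#' Estimate steady luminance levels by oversmoothed KDE
#'
#' Backlight residue and frame response make plateau samples ripple, and
#' the ripple can be skewed (e.g. duty-cycled PWM dwells longer at the
#' high state), so a plain mean would be biased.  Each level is instead
#' the mode of a Gaussian kernel density estimate over the plateau portion
#' (last 50% of each half-period) of the transition signal, computed with
#' the deliberately oversmoothing Terrell bandwidth
#' `h = 1.144 * sd * n^(-1/5)`.
#'
#' @param transition_signal Numeric backlight-free transition signal (the
#'   `transition` element of a `decomposition_result`, or any numeric
#'   signal following the protocol).
#' @param protocol A [transition_protocol()]; the signal is assumed to
#'   start at a block boundary with a full `from_level` block.
#' @param sampling_rate,refresh_rate Hz.
#' @return List with `level_low` and `level_high`.
#' @export
estimate_levels <- function(transition_signal, protocol, sampling_rate,
                            refresh_rate = 60) {
  half <- protocol$frames_per_level / refresh_rate
  if (half < 2 / refresh_rate)
    stop("plateau shorter than 2 frames: insufficient data", call. = FALSE)
  n <- length(transition_signal)
  block_n <- half * sampling_rate
  if (n < 2 * block_n)
    stop("signal must contain at least one full protocol period",
         call. = FALSE)
  idx <- seq_len(n) - 1
  half_idx <- floor(idx / block_n)            # 0-based half-period counter
  pos <- idx / block_n - half_idx             # position within half-period
  plateau <- pos >= 0.5
  a_samples <- transition_signal[plateau & half_idx %% 2 == 0]
  b_samples <- transition_signal[plateau & half_idx %% 2 == 1]
  la <- kde_mode(a_samples)
  lb <- kde_mode(b_samples)
  list(level_low = min(la, lb), level_high = max(la, lb))
}

# Mode of an oversmoothed Gaussian KDE (Terrell's rule).
kde_mode <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < .Machine$double.eps^0.5 * max(1, abs(mean(x))))
    return(stats::median(x))
  h <- 1.144 * s * length(x)^(-1 / 5)
  d <- stats::density(x, bw = h, n = 2048)
  d$x[which.max(d$y)]
}

# First sustained threshold crossing of `x` above `thr`, with linear
# interpolation; sustained = stays above for >= n_sus samples.  Returns
# fractional sample index (1-based) or NA.
first_sustained_crossing <- function(x, thr, n_sus, from = 1L) {
  above <- x >= thr
  above[seq_len(from - 1L)] <- FALSE
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= n_sus)
  if (length(ok) == 0L) return(NA_real_)
  i <- starts[ok[1L]]
  if (i == 1L) return(1)
  i - 1 + (thr - x[i - 1L]) / (x[i] - x[i - 1L])
}

#' ISO-style 10%--90% response time
#'
#' Time between the last crossing of the 10% amplitude level before the
#' sustained rise (respectively fall) and the first sustained crossing of
#' the 90% level, with linear interpolation between samples.  "Sustained"
#' means the signal stays beyond the threshold for at least 0.5 ms,
#' protecting the crossing times against residual ripple.
#'
#' @param transition_signal Numeric backlight-free signal containing the
#'   transition.
#' @param level_low,level_high Steady luminance levels (from
#'   [estimate_levels()]).
#' @param direction `"rising"` or `"falling"`.
#' @param sampling_rate Hz.
#' @param sustain_ms Sustain requirement in ms (default 0.5).
#' @return Response time in ms.
#' @export
response_time <- function(transition_signal, level_low, level_high,
                          direction = c("rising", "falling"),
                          sampling_rate, sustain_ms = 0.5) {
  direction <- match.arg(direction)
  x <- as.numeric(transition_signal)
  if (direction == "falling") x <- level_low + level_high - x
  rt1 <- rt_crossings(x, level_low, level_high, sampling_rate, sustain_ms)
  # second pass: residual ripple/noise makes crossing times jitter where
  # the slope is shallow (slow transitions); re-measure on a signal
  # smoothed over 5% of the first-pass RT -- bias O((0.05 RT)^2), jitter
  # down by sqrt of the window length; degenerates to no smoothing for
  # fast transitions
  w <- round(0.05 * rt1 / 1000 * sampling_rate)
  if (w >= 2)
    rt1 <- rt_crossings(moving_average(x, w), level_low, level_high,
                        sampling_rate, sustain_ms)
  rt1
}

rt_crossings <- function(x, level_low, level_high, sampling_rate,
                         sustain_ms) {
  amp <- level_high - level_low
  if (amp <= 0) stop("level_high must exceed level_low", call. = FALSE)
  thr10 <- level_low + 0.1 * amp
  thr90 <- level_low + 0.9 * amp
  n_sus <- max(1L, round(sustain_ms / 1000 * sampling_rate))
  i90 <- first_sustained_crossing(x, thr90, n_sus)
  if (is.na(i90))
    stop("no transition: 90% threshold never sustainedly crossed",
         call. = FALSE)
  below10 <- which(x[seq_len(floor(i90))] <= thr10)
  if (length(below10) == 0L)
    stop("no transition: 10% threshold never crossed before the rise",
         call. = FALSE)
  j <- below10[length(below10)]
  i10 <- j + (thr10 - x[j]) / (x[j + 1L] - x[j])
  (i90 - i10) / sampling_rate * 1000
}

#' Overshoot-extended response time (10% to 110%)
#'
#' Improperly tuned overdrive can push a rising transition far above its
#' target before it decays back.  The ISO 10--90% figure ignores that
#' transient entirely, so the extended metric measures from the 10%
#' crossing to the *final* crossing of the 110% amplitude level during the
#' post-peak decay.  On a measured example this turned a 5 ms ISO figure
#' into 51 ms, an increase of 920%.
#'
#' @inheritParams response_time
#' @return List with `rt_extended_ms` (`NA` when the peak never exceeds
#'   110% of the amplitude) and `overshoot_peak_fraction` (peak excess
#'   above `level_high` as a fraction of the amplitude, >= 0).
#' @export
overshoot_response_time <- function(transition_signal, level_low,
                                    level_high, sampling_rate,
                                    sustain_ms = 0.5) {
  x <- as.numeric(transition_signal)
  amp <- level_high - level_low
  if (amp <= 0) stop("level_high must exceed level_low", call. = FALSE)
  peak <- max(x)
  pf <- max(0, (peak - level_high) / amp)
  thr10 <- level_low + 0.1 * amp
  thr110 <- level_low + 1.1 * amp
  if (peak < thr110)
    return(list(rt_extended_ms = NA_real_, overshoot_peak_fraction = pf))
  n_sus <- max(1L, round(sustain_ms / 1000 * sampling_rate))
  ipk <- which.max(x)
  above <- which(x >= thr110)
  m <- above[length(above)]                  # final sample at/above 110%
  if (m >= length(x))
    return(list(rt_extended_ms = NA_real_, overshoot_peak_fraction = pf))
  i110 <- m + (x[m] - thr110) / (x[m] - x[m + 1L])
  below10 <- which(x[seq_len(ipk)] <= thr10)
  if (length(below10) == 0L)
    stop("no transition: 10% threshold never crossed", call. = FALSE)
  j <- below10[length(below10)]
  i10 <- j + (thr10 - x[j]) / (x[j + 1L] - x[j])
  list(rt_extended_ms = (i110 - i10) / sampling_rate * 1000,
       overshoot_peak_fraction = pf)
}

#' Percentage increase of the extended over the ISO response time
#'
#' @param rt_iso_ms,rt_extended_ms Response times in ms.
#' @return Increase in percent; 5 ms vs 51 ms gives 920.
#' @export
rt_increase_percent <- function(rt_iso_ms, rt_extended_ms) {
  100 * (rt_extended_ms - rt_iso_ms) / rt_iso_ms
}

#' Detect luminance stepping
#'
#' Luminance stepping is a DCC artifact in which a transition saturates
#' framewise at intermediate plateaus: the signal jumps at every frame
#' start and holds below (rising) or above (falling) the target level.
#' The detector computes per-frame medians over the steady part of each
#' frame after the transition onset and flags the transition when at least
#' two frames form flat intermediate plateaus separated by a jump.
#'
#' @param transition_signal Numeric backlight-free signal starting with a
#'   full `from_level` block (as produced by the simulator/decomposition).
#' @param protocol A [transition_protocol()].
#' @param sampling_rate,refresh_rate Hz.
#' @return List with `stepping_detected`, `per_frame_plateaus` (fractions
#'   of the amplitude reached by each detected plateau frame) and
#'   `frame_medians` (all per-frame median fractions of the first
#'   transition).
#' @export
detect_stepping <- function(transition_signal, protocol, sampling_rate,
                            refresh_rate = 60) {
  if (protocol$frames_per_level < 2)
    stop("need >= 2 frames between commanded levels", call. = FALSE)
  lv <- estimate_levels(transition_signal, protocol, sampling_rate,
                        refresh_rate)
  amp <- lv$level_high - lv$level_low
  frame_n <- sampling_rate / refresh_rate
  onset_i <- round(protocol$frames_per_level * frame_n) + 1L
  rising <- protocol$to_level > protocol$from_level
  base <- if (rising) lv$level_low else lv$level_high
  sgn <- if (rising) 1 else -1
  fracs <- ranges <- numeric(0)
  for (k in seq_len(protocol$frames_per_level)) {
    i0 <- onset_i + round((k - 1) * frame_n)
    i1 <- onset_i + round(k * frame_n) - 1L
    if (i1 > length(transition_signal)) break
    steady <- transition_signal[(i0 + round(0.3 * frame_n)):
                                  (i0 + round(0.95 * frame_n))]
    fracs[k] <- sgn * (stats::median(steady) - base) / amp
    q <- stats::quantile(steady, c(0.1, 0.9), names = FALSE)
    ranges[k] <- (q[2] - q[1]) / amp
  }
  # a genuine plateau is flat, sits below target, and is left by a jump
  # at the next frame boundary; for a smooth exponential the within-frame
  # range is comparable to the between-frame change, so flatness is
  # judged relative to the jump as well as absolutely
  plateau <- logical(length(fracs))
  for (k in seq_along(fracs)) {
    nxt <- if (k < length(fracs)) fracs[k + 1L] else 1
    jump <- nxt - fracs[k]
    plateau[k] <- fracs[k] < 0.95 && jump > 0.05 &&
      ranges[k] < 0.05 && ranges[k] < 0.3 * jump
  }
  list(stepping_detected = any(plateau),
       per_frame_plateaus = fracs[plateau],
       frame_medians = fracs)
}

#' Detect a pre-tilt (DCC II) onset advance
#'
#' DCC II applies a pre-tilt voltage during the frame preceding a
#' commanded rising transition, so the luminance departs from baseline
#' one frame before the commanded onset.
#'
#' @param transition_signal Numeric backlight-free signal.
#' @param commanded_onset Commanded onset time in seconds (from the
#'   protocol phase).
#' @param baseline_level,amplitude Baseline luminance and transition
#'   amplitude.
#' @param sampling_rate,refresh_rate Hz.
#' @param sustain_ms Sustain requirement for the departure (default 0.5).
#' @return Onset advance in whole frames (>= 0).
#' @export
detect_onset_advance <- function(transition_signal, commanded_onset,
                                 baseline_level, amplitude, sampling_rate,
                                 refresh_rate = 60, sustain_ms = 0.5) {
  thr <- baseline_level + 0.05 * amplitude
  n_sus <- max(1L, round(sustain_ms / 1000 * sampling_rate))
  i_dep <- first_sustained_crossing(as.numeric(transition_signal), thr,
                                    n_sus)
  if (is.na(i_dep))
    stop("no departure from baseline found", call. = FALSE)
  t_dep <- (i_dep - 1) / sampling_rate
  max(0, round((commanded_onset - t_dep) * refresh_rate))
}

#' Duration above baseline of a pulse
#'
#' Stimulus duration defined as the time the signal stays above baseline
#' plus 5% of the amplitude.  With a pre-tilt onset advance and a slow
#' falling tail, a 10-frame commanded pulse can last more than eleven
#' frames by this definition.
#'
#' @inheritParams detect_onset_advance
#' @return Duration in seconds.
#' @export
duration_above_baseline <- function(transition_signal, baseline_level,
                                    amplitude, sampling_rate) {
  thr <- baseline_level + 0.05 * amplitude
  sum(transition_signal > thr) / sampling_rate
}

#' Summarize response times over a transition grid
#'
#' Aggregates per-transition response times the way a characterization
#' report presents them: per-transition mean and sd over repetitions, the
#' grand mean and sd over transitions, the coefficient of variation
#' (sd/mean, a scale-free homogeneity measure), means over rising and
#' falling transitions, and the black-to-white / white-to-black times.
#'
#' @param results Data frame with columns `from_level`, `to_level` and
#'   `rt_iso_ms` (one row per measurement; repetitions share the level
#'   pair).
#' @return An object of class `rt_summary`.
#' @export
summarize_rts <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("from_level", "to_level", "rt_iso_ms") %in%
                  names(results)))
  if (nrow(results) == 0L) stop("empty input", call. = FALSE)
  key <- interaction(results$from_level, results$to_level, drop = TRUE)
  per <- do.call(rbind, lapply(split(results, key), function(d) {
    data.frame(from_level = d$from_level[1], to_level = d$to_level[1],
               mean_ms = mean(d$rt_iso_ms),
               sd_ms = if (nrow(d) > 1) stats::sd(d$rt_iso_ms) else 0)
  }))
  rownames(per) <- NULL
  grand_mean <- mean(per$mean_ms)
  grand_sd <- if (nrow(per) > 1) stats::sd(per$mean_ms) else 0
  rising <- per$to_level > per$from_level
  pick <- function(from, to) {
    i <- which(per$from_level == from & per$to_level == to)
    if (length(i)) per$mean_ms[i] else NA_real_
  }
  lo <- min(per$from_level, per$to_level)
  hi <- max(per$from_level, per$to_level)
  structure(
    list(per_transition = per,
         grand_mean = grand_mean, grand_sd = grand_sd,
         coefficient_of_variation = grand_sd / grand_mean,
         rising_mean = mean(per$mean_ms[rising]),
         falling_mean = mean(per$mean_ms[!rising]),
         n_rising = sum(rising), n_falling = sum(!rising),
         black_to_white = pick(lo, hi),
         white_to_black = pick(hi, lo)),
    class = "rt_summary")
}
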