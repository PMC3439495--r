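#' Periodogram power spectral density with a Gaussian taper
#'
#' Estimates the one-sided PSD of the mean-normalized signal by the
#' periodogram method with a Gaussian window.  Mean normalization (division
#' by the signal mean, then removal of the DC component) makes modulation
#' depths comparable across displays of different absolute luminance.
#'
#' @param trace A [luminance_trace()] or a numeric vector (then
#'   `sampling_rate` must be given).
#' @param sampling_rate Sampling rate in Hz when `trace` is a bare vector.
#' @param taper_sd_fraction Standard deviation of the Gaussian taper as a
#'   fraction of the signal length (default 1/8).
#' @return An object of class `psd_estimate`: list with `frequency` (Hz),
#'   `power` (density, 1/Hz), `sampling_rate`, `n`, `variance` (variance of
#'   the mean-normalized signal, used by the smooth-signal cutoff) and
#'   `tapered_variance` (window-weighted variance; the density integrates
#'   to this value, a Parseval identity).
#' @export
psd <- function(trace, sampling_rate = NULL, taper_sd_fraction = 1 / 8) {
  if (inherits(trace, "luminance_trace")) {
    x <- trace$samples
    fs <- trace$sampling_rate
  } else {
    x <- as.numeric(trace)
    if (is.null(sampling_rate))
      stop("sampling_rate is required for a bare numeric signal",
           call. = FALSE)
    fs <- sampling_rate
  }
  n <- length(x)
  if (n < 64)
    stop("signal too short for spectral estimation (need >= 64 samples)",
         call. = FALSE)
  m <- mean(x)
  if (m <= 0) stop("cannot mean-normalize: non-positive mean", call. = FALSE)
  y <- x / m
  v <- stats::var(y)
  y <- y - mean(y)
  w <- exp(-0.5 * ((seq_len(n) - (n + 1) / 2) / (taper_sd_fraction * n))^2)
  yw <- y * w
  X <- stats::fft(yw)
  # density normalization: sum(power) * df == sum(yw^2) / sum(w^2)
  p <- Mod(X)^2 / (fs * sum(w^2))
  half <- seq_len(floor(n / 2) + 1L)
  power <- p[half]
  if (n %% 2 == 0) {
    power[2:(length(half) - 1L)] <- 2 * power[2:(length(half) - 1L)]
  } else {
    power[2:length(half)] <- 2 * power[2:length(half)]
  }
  structure(
    list(frequency = (half - 1) * fs / n, power = power,
         sampling_rate = fs, n = n, variance = v,
         tapered_variance = sum(yw^2) / sum(w^2)),
    class = "psd_estimate")
}

#' Dominant frequency of a PSD
#'
#' The dominant frequency is the frequency of maximal power within the
#' search band.  Very smooth signals (variance of the mean-normalized
#' signal below `smoothness_cutoff`) have no meaningful periodic component
#' and yield `NA` ("none").  Ties break toward the lower frequency.
#'
#' @param spectrum A `psd_estimate` from [psd()].
#' @param band Two-element numeric search band in Hz; the default
#'   \[20, 500\] excludes DC/drift and covers all backlight fundamentals
#'   observed in practice (89--207 Hz).
#' @param smoothness_cutoff Variance threshold below which no dominant
#'   frequency is reported (default `1e-6`, i.e. a modulation sd of 0.1%
#'   of the mean -- the instrument noise-floor scale).
#' @return Dominant frequency in Hz, or `NA_real_` when none.
#' @export
dominant_frequency <- function(spectrum, band = c(20, 500),
                               smoothness_cutoff = 1e-6) {
  stopifnot(inherits(spectrum, "psd_estimate"))
  if (length(band) != 2L || band[1] >= band[2])
    stop("band must be an increasing two-element interval", call. = FALSE)
  nyq <- spectrum$sampling_rate / 2
  band[2] <- min(band[2], nyq)
  sel <- which(spectrum$frequency >= band[1] &
                 spectrum$frequency <= band[2])
  if (length(sel) == 0L) stop("empty search band", call. = FALSE)
  if (spectrum$variance < smoothness_cutoff) return(NA_real_)
  # compare line power summed over a small neighborhood: a line falling
  # between two bins splits its power (scalloping), which could otherwise
  # let a lesser but better-centered harmonic win the single-bin argmax
  ps <- moving_average(spectrum$power, 5L)
  i <- sel[which.max(ps[sel])]               # which.max: first == lowest f
  cand <- intersect((i - 2L):(i + 2L), sel)
  i <- cand[which.max(spectrum$power[cand])]
  spectrum$frequency[i]
}

#' Frame-response test
#'
#' Frame response is a luminance modulation locked to the refresh rate
#' present even in static images.  The test checks whether the PSD bin
#' nearest the refresh rate is a local maximum over +/- 3 bins and exceeds
#' the surrounding median power by a dominance factor.
#'
#' @param spectrum A `psd_estimate` from [psd()].
#' @param refresh_rate Refresh rate in Hz (must be below Nyquist).
#' @param dominance_factor Required excess over the local median power
#'   (default 5).
#' @param neighborhood Half-width in bins of the local median window
#'   (default 20).
#' @param min_power Absolute detectability floor on the density at the
#'   refresh bin (default 1e-8, i.e. a modulation amplitude of a few
#'   hundredths of a percent of the mean).  Sampling beats of a strong
#'   PWM line can place genuine but minuscule spectral lines near the
#'   refresh rate; below this floor they are not reported as frame
#'   response.
#' @return List with `detected` (logical) and `power_at_refresh`.
#' @export
frame_response_test <- function(spectrum, refresh_rate,
                                dominance_factor = 5, neighborhood = 20,
                                min_power = 1e-8) {
  stopifnot(inherits(spectrum, "psd_estimate"))
  if (refresh_rate >= spectrum$sampling_rate / 2)
    stop("refresh_rate must lie below Nyquist", call. = FALSE)
  i <- which.min(abs(spectrum$frequency - refresh_rate))
  # 3-bin smoothing: the Gaussian taper spreads a true line over ~3 bins
  # anyway, while smoothing pulls in the exponential tail of single noisy
  # periodogram bins that would otherwise trip the dominance factor
  p <- moving_average(spectrum$power, 3L)
  lo <- max(1L, i - 3L); hi <- min(length(p), i + 3L)
  local_max <- p[i] >= max(p[lo:hi])
  nlo <- max(1L, i - neighborhood); nhi <- min(length(p), i + neighborhood)
  neigh <- setdiff(nlo:nhi, (i - 1L):(i + 1L))
  med <- stats::median(p[neigh])
  detected <- local_max && p[i] > dominance_factor * med &&
    p[i] > min_power
  list(detected = detected, power_at_refresh = p[i])
}

#' Phase-lock test for a backlight frequency
#'
#' A backlight is phase locked to the frames when its fundamental is an
#' integer multiple of the refresh rate.  Most PWM backlights are not
#' (e.g. the measured fundamentals of 89 Hz and 207 Hz against a 60 Hz
#' refresh), so transition signals differ from repetition to repetition
#' depending on the backlight phase at the transition onset.
#'
#' @param backlight_frequency Backlight fundamental in Hz.
#' @param refresh_rate Refresh rate in Hz.
#' @param tolerance Allowed deviation in Hz from an exact integer multiple
#'   (default 0.5, half a periodogram bin at the reference 1 s recording).
#' @return Logical.
#' @export
phase_lock_test <- function(backlight_frequency, refresh_rate,
                            tolerance = 0.5) {
  stopifnot(backlight_frequency > 0, refresh_rate > 0)
  k <- round(backlight_frequency / refresh_rate)
  k >= 1 && abs(backlight_frequency - k * refresh_rate) <= tolerance
}

#' Spectral summary of a static recording
#'
#' Convenience wrapper combining [psd()], [dominant_frequency()],
#' [frame_response_test()] and [phase_lock_test()].
#'
#' @param trace A [luminance_trace()].
#' @param band Dominant-frequency search band in Hz.
#' @return An object of class `spectral_summary`.
#' @export
spectral_summary <- function(trace, band = c(20, 500)) {
  stopifnot(inherits(trace, "luminance_trace"))
  sp <- psd(trace)
  dom <- dominant_frequency(sp, band = band)
  fr <- frame_response_test(sp, trace$refresh_rate)
  structure(
    list(frequency = sp$frequency, power = sp$power,
         dominant_frequency = dom,
         power_at_refresh = fr$power_at_refresh,
         frame_response_detected = fr$detected,
         phase_locked = if (is.na(dom)) NA else
           phase_lock_test(dom, trace$refresh_rate)),
    class = "spectral_summary")
}
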