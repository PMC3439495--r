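#' Estimate a backlight template from a static recording
#'
#' The division method measures the transition and its upper luminance
#' level independently: a static recording of a constant patch contains
#' the backlight modulation in isolation.  The template is obtained by
#' estimating the dominant backlight frequency from the periodogram,
#' refining it by maximizing the projection onto a complex exponential
#' (sub-bin accuracy, needed so that cyclic folding over ~100 periods does
#' not smear), folding all samples by phase into one period, and averaging
#' per phase bin.
#'
#' @param static_trace A [luminance_trace()] of a constant patch covering
#'   at least 5 backlight periods.
#' @param band Frequency search band in Hz.
#' @param smoothness_cutoff Variance cutoff below which the backlight is
#'   declared constant (see [dominant_frequency()]).
#' @return An object of class `backlight_template`: list with `values`
#'   (one period of the modulation, mean 1, phase bin centers at
#'   `(j - 0.5) / nbins`), `frequency` (Hz, `NA` when none) and `nbins`.
#' @export
estimate_backlight_template <- function(static_trace, band = c(20, 500),
                                        smoothness_cutoff = 1e-6) {
  stopifnot(inherits(static_trace, "luminance_trace"))
  x <- static_trace$samples / mean(static_trace$samples)
  fs <- static_trace$sampling_rate
  sp <- psd(static_trace)
  f0 <- dominant_frequency(sp, band = band,
                           smoothness_cutoff = smoothness_cutoff)
  flat <- structure(list(values = 1, frequency = NA_real_, nbins = 1L),
                    class = "backlight_template")
  if (is.na(f0)) return(flat)
  # dominance over the noise floor within the band
  sel <- which(sp$frequency >= band[1] &
                 sp$frequency <= min(band[2], fs / 2))
  if (max(sp$power[sel]) < 10 * stats::median(sp$power[sel])) return(flat)
  if (length(x) < 5 * fs / f0)
    stop("static trace must cover at least 5 backlight periods",
         call. = FALSE)
  f <- refine_frequency(x, fs, f0, halfwidth = fs / length(x))
  # fine phase bins (about 1/4 sample wide) resolve the PWM edges; the
  # non-locked sampling phase equidistributes samples over the bins
  nbins <- max(8L, min(4L * round(fs / f), floor(length(x) / 10)))
  t <- (seq_along(x) - 1) / fs
  phase <- (t * f) %% 1
  bin <- pmin(floor(phase * nbins) + 1L, nbins)
  template <- rep(NA_real_, nbins)
  agg <- tapply(x, bin, mean)
  template[as.integer(names(agg))] <- as.numeric(agg)
  if (anyNA(template)) {          # periodic interpolation of empty bins
    ok <- which(!is.na(template))
    idx <- c(ok - nbins, ok, ok + nbins)
    template <- stats::approx(idx, rep(template[ok], 3),
                              xout = seq_len(nbins))$y
  }
  template <- template / mean(template)
  structure(list(values = template, frequency = f, nbins = nbins),
            class = "backlight_template")
}

# Sub-bin frequency refinement: maximize the Gaussian-tapered projection
# |sum w x exp(-2 pi i f t)| (the taper suppresses leakage bias from
# other spectral lines).
refine_frequency <- function(x, fs, f0, halfwidth) {
  n <- length(x)
  t <- (seq_len(n) - 1) / fs
  w <- exp(-0.5 * ((seq_len(n) - (n + 1) / 2) / (n / 8))^2)
  x0 <- (x - mean(x)) * w
  amp <- function(f) Mod(sum(x0 * exp(-2i * pi * f * t)))
  stats::optimize(amp, interval = c(f0 - halfwidth, f0 + halfwidth),
                  maximum = TRUE, tol = 1e-5)$maximum
}

# Evaluate the template at arbitrary phases in [0, 1) by periodic linear
# interpolation; bin j's center sits at phase (j - 0.5) / nbins.
template_at <- function(template, phase) {
  v <- template$values
  nb <- template$nbins
  if (nb == 1L) return(rep(v, length(phase)))
  pos <- (phase * nb - 0.5) %% nb          # fractional bin position
  j0 <- floor(pos)
  frac <- pos - j0
  i0 <- (j0 %% nb) + 1L
  i1 <- ((j0 + 1L) %% nb) + 1L
  v[i0] * (1 - frac) + v[i1] * frac
}

# Replace runs of masked samples by cubic Hermite segments anchored just
# outside the run, with endpoint slopes fit to the 5 flanking samples on
# each side.  Runs touching the signal ends are left for the caller.
hermite_bridge <- function(x, masked, context = 5L) {
  n <- length(x)
  r <- rle(masked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  side_slope <- function(idx) {
    if (length(idx) < 2L) return(0)
    stats::coef(stats::lm.fit(cbind(1, idx), x[idx]))[2]
  }
  for (j in which(r$values)) {
    a <- starts[j]; b <- ends[j]
    if (a == 1L || b == n) next
    li <- seq.int(max(1L, a - context), a - 1L)
    ri <- seq.int(b + 1L, min(n, b + context))
    li <- li[!masked[li]]; ri <- ri[!masked[ri]]
    if (length(li) == 0L || length(ri) == 0L) next
    x0 <- a - 1L; x1 <- b + 1L
    y0 <- x[x0]; y1 <- x[x1]
    s0 <- side_slope(li); s1 <- side_slope(ri)
    h <- x1 - x0
    t <- ((a:b) - x0) / h
    h00 <- (1 + 2 * t) * (1 - t)^2
    h10 <- t * (1 - t)^2
    h01 <- t^2 * (3 - 2 * t)
    h11 <- t^2 * (t - 1)
    x[a:b] <- h00 * y0 + h10 * h * s0 + h01 * y1 + h11 * h * s1
  }
  x
}

# Centered moving average with edge replication.
moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w == 1L) return(x)
  n <- length(x)
  pad <- c(rep(x[1], w), x, rep(x[n], w))
  cs <- cumsum(pad)
  half_lo <- floor((w - 1) / 2)
  half_hi <- w - 1 - half_lo
  i <- seq_len(n) + w
  (cs[i + half_hi] - cs[i - half_lo - 1L]) / w
}

#' Align the backlight phase of a transition recording
#'
#' Finds the lag (in samples, possibly fractional) at which the tiled
#' template best matches the residual backlight ripple of the transition
#' recording.  The ripple is isolated by dividing out a one-period moving
#' average (which removes the transition trend), then scored against the
#' template ripple by cross-correlation over all integer lags within one
#' period, with parabolic sub-sample refinement.  Alignment is invariant
#' to slow trends in the trace.
#'
#' @param transition_trace A [luminance_trace()].
#' @param template A `backlight_template` from
#'   [estimate_backlight_template()].
#' @return Alignment lag in samples, in `[0, period)`.  0 for a flat
#'   template.
#' @export
align_phase <- function(transition_trace, template) {
  stopifnot(inherits(transition_trace, "luminance_trace"),
            inherits(template, "backlight_template"))
  if (is.na(template$frequency) ||
      max(template$values) - min(template$values) < 1e-9)
    return(0)
  x <- transition_trace$samples
  fs <- transition_trace$sampling_rate
  f <- template$frequency
  period <- fs / f
  w <- max(2L, round(period))
  base <- moving_average(x, w)
  base[base <= 0] <- max(base) * 1e-6
  ripple <- x / base - 1
  n <- length(x)
  t <- (seq_len(n) - 1) / fs
  # phase of the backlight fundamental: the template's fundamental has
  # phase psi, the trace ripple's fundamental psi - 2 pi f lag / fs, so
  # the lag follows from the argument difference (exact for the
  # fundamental; PWM harmonics are phase-locked to it)
  v <- template$values
  nb <- template$nbins
  zt <- sum((v - 1) * exp(-2i * pi * (seq_len(nb) - 0.5) / nb))
  zr <- sum(ripple * exp(-2i * pi * f * t))
  lag <- (Arg(zt) - Arg(zr)) / (2 * pi * f) * fs
  lag %% period
}

#' Divide out the backlight: the division method with dynamical filtering
#'
#' Divides the transition recording by the phase-aligned, tiled backlight
#' template, then suppresses residual ripple at the backlight frequency by
#' dynamical filtering: a one-period moving average (which nulls the
#' fundamental and all its harmonics) is blended with the raw quotient
#' according to the local slope, so plateaus are fully smoothed while fast
#' transitions pass unfiltered and unbiased.  Samples where the template
#' is nearly off (deep-PWM phases below 5% of the template mean) are
#' masked before division and linearly interpolated.
#'
#' @param transition_trace A [luminance_trace()].
#' @param template A `backlight_template`.
#' @param lag Alignment lag in samples from [align_phase()].
#' @return An object of class `decomposition_result`: list with
#'   `transition` (backlight-free luminance signal, same length as the
#'   input), `backlight_template`, `alignment_lag`, `backlight_frequency`,
#'   `residual_rms` (relative rms of the reconstruction residual) and
#'   `masked_fraction`.
#' @export
divide_out_backlight <- function(transition_trace, template, lag = 0) {
  stopifnot(inherits(transition_trace, "luminance_trace"),
            inherits(template, "backlight_template"))
  x <- transition_trace$samples
  fs <- transition_trace$sampling_rate
  n <- length(x)
  if (is.na(template$frequency)) {
    res <- structure(
      list(transition = x, backlight_template = template,
           alignment_lag = 0, backlight_frequency = NA_real_,
           residual_rms = 0, masked_fraction = 0),
      class = "decomposition_result")
    return(res)
  }
  f <- template$frequency
  ph <- ((seq_len(n) - 1 - lag) * f / fs) %% 1
  B <- template_at(template, ph)
  eps <- 0.05 * mean(template$values)
  v <- template$values
  nb <- template$nbins
  # samples straddling a steep PWM edge carry an O(bin-width) phase
  # quantization error of the full step height; mask them (with the
  # deep-off-phase samples) and bridge the quotient by interpolation
  grad <- abs(v[c(2:nb, 1L)] - v)
  steep <- grad > 0.04 * max(diff(range(v)), .Machine$double.eps)
  for (shift in 1:2)
    steep <- steep | c(steep[-seq_len(shift)], steep[seq_len(shift)]) |
      c(steep[nb - seq_len(shift) + 1L], steep[seq_len(nb - shift)])
  bin <- pmin(floor(ph * nb) + 1L, nb)
  masked <- B < eps | steep[bin]
  if (all(masked)) masked[] <- FALSE
  Bsafe <- ifelse(masked, NA_real_, B)
  Traw <- x / Bsafe
  if (any(masked)) {
    ok <- which(!masked)
    # bridge each masked run with a cubic Hermite whose endpoint slopes
    # come from the flanking unmasked samples only: a straight line (or a
    # gap-secant-weighted spline) across a gap containing a transition
    # corner would leave the plateau early
    Traw <- hermite_bridge(Traw, masked)
    # interpolation cannot bridge masked runs touching the trace ends;
    # extrapolate linearly from the nearest unmasked samples instead
    lead <- which(masked & seq_len(n) < ok[1])
    if (length(lead)) {
      ref <- ok[seq_len(min(12L, length(ok)))]
      fit <- stats::lm.fit(cbind(1, ref), Traw[ref])
      Traw[lead] <- fit$coefficients[1] + fit$coefficients[2] * lead
    }
    trail <- which(masked & seq_len(n) > ok[length(ok)])
    if (length(trail)) {
      ref <- ok[seq(max(1L, length(ok) - 11L), length(ok))]
      fit <- stats::lm.fit(cbind(1, ref), Traw[ref])
      Traw[trail] <- fit$coefficients[1] + fit$coefficients[2] * trail
    }
  }
  # dynamical filtering: slope-adaptive one-period smoothing
  period <- fs / f
  w <- max(2L, round(period))
  sm <- moving_average(Traw, w)
  rng <- diff(range(sm))
  if (rng <= 0) rng <- max(abs(sm), 1)
  slope <- c(diff(sm), 0) + c(0, diff(sm))   # centered, per sample
  change_per_window <- abs(slope) / 2 * w
  weight <- 1 / (1 + (change_per_window / (0.02 * rng))^2)
  Thats <- weight * sm + (1 - weight) * Traw
  recon <- Thats * B
  residual_rms <- sqrt(mean((x[!masked] - recon[!masked])^2)) / mean(x)
  structure(
    list(transition = Thats, backlight_template = template,
         alignment_lag = lag, backlight_frequency = f,
         residual_rms = residual_rms,
         masked_fraction = mean(masked)),
    class = "decomposition_result")
}

#' Decompose a transition recording into transition and backlight
#'
#' End-to-end division method: estimate the backlight template (from a
#' static recording when available, otherwise from the transition
#' recording itself), align its phase to the transition recording, and
#' divide it out with dynamical filtering.
#'
#' @param transition_trace A [luminance_trace()] of a transition protocol.
#' @param static_trace Optional [luminance_trace()] of a static patch on
#'   the same display (preferred source for the template).
#' @param band Backlight frequency search band in Hz.
#' @return A `decomposition_result`, see [divide_out_backlight()].
#' @export
decompose_trace <- function(transition_trace, static_trace = NULL,
                            band = c(20, 500)) {
  src <- if (is.null(static_trace))
    upper_plateau_segment(transition_trace) else static_trace
  template <- estimate_backlight_template(src, band = band)
  lag <- align_phase(transition_trace, template)
  divide_out_backlight(transition_trace, template, lag)
}

# Longest contiguous stretch of the upper plateau, used as a pseudo-static
# recording when no separate static trace is available (the division
# method measures the upper luminance level independently).
upper_plateau_segment <- function(trace) {
  x <- trace$samples
  fs <- trace$sampling_rate
  sm <- moving_average(x, round(fs / trace$refresh_rate))
  hi <- sm >= max(sm) - 0.1 * diff(range(sm))
  r <- rle(hi)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  if (length(cand) == 0L) return(trace)
  best <- cand[which.max(r$lengths[cand])]
  idx <- starts[best]:ends[best]
  # trim the transition tails at both ends of the run
  margin <- min(round(0.1 * length(idx)), round(0.01 * fs))
  if (length(idx) > 2 * margin + 2)
    idx <- idx[(margin + 1L):(length(idx) - margin)]
  luminance_trace(x[idx], fs, trace$refresh_rate, trace$primary,
                  paste(trace$annotation, "(upper plateau)"))
}
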