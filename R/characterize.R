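#' Extract one transition window from a periodic recording
#'
#' Slices a window around the first commanded onset of the given kind:
#' from 40% of a block before the onset to 95% of a block after it, so
#' the window holds the pre-transition plateau, the transition and the
#' post-transition plateau but not the next commanded change.
#'
#' @param signal Numeric signal following the blink protocol (starting
#'   with a full `from_level` block).
#' @param protocol A [transition_protocol()].
#' @param sampling_rate,refresh_rate Hz.
#' @param which `"onset"` (from-to transition) or `"offset"` (back).
#' @return List with `signal` (the window), `onset_s` (commanded onset
#'   time within the window) and `start_index`.
#' @export
extract_transition_window <- function(signal, protocol, sampling_rate,
                                      refresh_rate = 60,
                                      which = c("onset", "offset")) {
  which <- match.arg(which)
  block_n <- protocol$frames_per_level * sampling_rate / refresh_rate
  k <- if (which == "onset") 1 else 2
  onset_i <- round(k * block_n) + 1L
  i0 <- max(1L, onset_i - round(0.4 * block_n))
  i1 <- min(length(signal), onset_i + round(0.95 * block_n))
  list(signal = signal[i0:i1],
       onset_s = (onset_i - i0) / sampling_rate,
       start_index = i0)
}

#' Flag response-time instability over repeated measurements
#'
#' Some monitors show unsystematic doubling of response times over
#' repetitions of the very same transition (e.g. alternating 10 ms and
#' 20 ms).  The detector flags a transition when the max/min ratio over
#' its repetitions exceeds a threshold; 1.5 sits midway between stable
#' repetitions and a doubling.
#'
#' @param rts_ms Numeric vector of response times (>= 3 repetitions).
#' @param ratio_threshold Flagging threshold on max/min (default 1.5).
#' @return List with `flagged` (logical) and `spread_ratio`.
#' @export
detect_rt_instability <- function(rts_ms, ratio_threshold = 1.5) {
  if (length(rts_ms) < 3)
    stop("need >= 3 repetitions", call. = FALSE)
  ratio <- max(rts_ms) / min(rts_ms)
  list(flagged = ratio > ratio_threshold, spread_ratio = ratio)
}

#' Run a full display characterization on a simulated display
#'
#' Sequences the complete analysis a practitioner would run before using
#' a display in an experiment: for every ordered transition of the level
#' grid, simulate the recording, decompose out the backlight, estimate
#' levels, ISO and extended response times, overshoot, stepping and onset
#' advance, and the visible motion blur; for every static level, estimate
#' the PSD, dominant backlight frequency and frame response.  Detected
#' artifacts are collected with severities.  Deterministic given the
#' seed.
#'
#' @param model A [display_model()].
#' @param grid A [level_grid()].
#' @param frames_per_level Frames per level of the blink protocol.
#' @param duration,sampling_rate,refresh_rate Acquisition parameters.
#' @param blur A [blur_params()] or `NULL` to skip the blur stage.
#' @param seed Integer seed.
#' @return An object of class `characterization_report`.
#' @export
run_characterization <- function(model, grid = level_grid(),
                                 frames_per_level = 10, duration = 1,
                                 sampling_rate = 10000, refresh_rate = 60,
                                 blur = blur_params(), seed = 1) {
  pairs <- enumerate_transitions(grid)
  static_trace <- simulate_static(model, max(grid$levels), duration,
                                  sampling_rate, refresh_rate, seed = seed)
  template <- estimate_backlight_template(static_trace)
  transitions <- vector("list", nrow(pairs))
  artifacts <- list()
  for (i in seq_len(nrow(pairs))) {
    proto <- transition_protocol(pairs$from_level[i], pairs$to_level[i],
                                 frames_per_level)
    sim <- simulate_transition(model, proto, duration, sampling_rate,
                               refresh_rate, seed = seed + i)
    lag <- align_phase(sim$trace, template)
    dec <- divide_out_backlight(sim$trace, template, lag)
    lv <- estimate_levels(dec$transition, proto, sampling_rate,
                          refresh_rate)
    rising <- pairs$to_level[i] > pairs$from_level[i]
    win <- extract_transition_window(dec$transition, proto, sampling_rate,
                                     refresh_rate)
    rt <- response_time(win$signal, lv$level_low, lv$level_high,
                        if (rising) "rising" else "falling",
                        sampling_rate)
    ov <- if (rising)
      overshoot_response_time(win$signal, lv$level_low, lv$level_high,
                              sampling_rate)
    else list(rt_extended_ms = NA_real_, overshoot_peak_fraction = 0)
    st <- detect_stepping(dec$transition, proto, sampling_rate,
                          refresh_rate)
    adv <- if (rising)
      tryCatch(detect_onset_advance(
        dec$transition, frames_per_level / refresh_rate,
        lv$level_low, lv$level_high - lv$level_low,
        sampling_rate, refresh_rate), error = function(e) NA_integer_)
    else NA_integer_
    jnd <- if (!is.null(blur))
      vmb_jnd(win$signal, blur, refresh_rate, sampling_rate)$jnd
    else NA_real_
    transitions[[i]] <- data.frame(
      from_level = pairs$from_level[i], to_level = pairs$to_level[i],
      direction = if (rising) "rising" else "falling",
      level_low = lv$level_low, level_high = lv$level_high,
      rt_iso_ms = rt, rt_extended_ms = ov$rt_extended_ms,
      overshoot_peak_fraction = ov$overshoot_peak_fraction,
      stepping_detected = st$stepping_detected,
      onset_advance_frames = adv, jnd = jnd,
      residual_rms = dec$residual_rms)
    if (isTRUE(ov$overshoot_peak_fraction > 0.1))
      artifacts <- c(artifacts, list(list(
        type = "overshoot", from = pairs$from_level[i],
        to = pairs$to_level[i],
        severity = ov$overshoot_peak_fraction)))
    if (isTRUE(st$stepping_detected))
      artifacts <- c(artifacts, list(list(
        type = "stepping", from = pairs$from_level[i],
        to = pairs$to_level[i],
        severity = 1 - min(st$per_frame_plateaus))))
    if (isTRUE(adv >= 1))
      artifacts <- c(artifacts, list(list(
        type = "pre_tilt_advance", from = pairs$from_level[i],
        to = pairs$to_level[i], severity = adv)))
  }
  transitions <- do.call(rbind, transitions)
  statics <- lapply(grid$levels, function(lv) {
    tr <- simulate_static(model, lv, duration, sampling_rate,
                          refresh_rate, seed = seed + 1000 + lv)
    ss <- spectral_summary(tr)
    list(level = lv, dominant_frequency = ss$dominant_frequency,
         frame_response_detected = ss$frame_response_detected,
         power_at_refresh = ss$power_at_refresh,
         phase_locked = ss$phase_locked)
  })
  rt_sum <- summarize_rts(transitions[, c("from_level", "to_level",
                                          "rt_iso_ms")])
  structure(
    list(transitions = transitions, rt_summary = rt_sum,
         statics = statics, artifacts = artifacts,
         backlight = list(frequency = template$frequency,
                          template = template$values),
         provenance = list(seed = seed, sampling_rate = sampling_rate,
                           refresh_rate = refresh_rate,
                           duration = duration,
                           package_version =
                             as.character(utils::packageVersion("lcdtempo")))),
    class = "characterization_report")
}

#' Serialize a characterization report to JSON
#'
#' @param report A `characterization_report`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "characterization_report"))
  strip <- function(x) {
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  js <- jsonlite::toJSON(strip(report), auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE,
                         na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
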