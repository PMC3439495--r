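# Shared builders for synthetic scenarios used across test files.

FS <- 10000   # reference sampling rate, Hz
RR <- 60      # reference refresh rate, Hz

pwm_model <- function(frequency = 120, depth = 0.5, duty = 0.6,
                      phase = 0, tau_rise = 8, tau_fall = 4,
                      noise_sd = 0, ...) {
  display_model(
    tau_rise_ms = tau_rise, tau_fall_ms = tau_fall,
    backlight = backlight_config("pwm", frequency = frequency,
                                 duty_cycle = duty,
                                 modulation_depth = depth, phase = phase),
    noise_sd = noise_sd, ...)
}

# Simulate a transition plus matching static recording and decompose.
sim_and_decompose <- function(model, from = 127, to = 255, seed = 1,
                              duration = 1, fs = FS) {
  proto <- transition_protocol(from, to, 10)
  sim <- simulate_transition(model, proto, duration, fs, RR, seed = seed)
  static <- simulate_static(model, 255, duration, fs, RR, seed = seed + 5000)
  dec <- decompose_trace(sim$trace, static)
  list(sim = sim, dec = dec, proto = proto, model = model)
}

# Clean (noise- and backlight-free) transition window for blur tests.
clean_transition_window <- function(tau, from = 0, to = 255, fs = FS,
                                    seed = 3, model = NULL) {
  if (is.null(model))
    model <- display_model(tau_rise_ms = tau, tau_fall_ms = tau)
  proto <- transition_protocol(from, to, 10)
  sim <- simulate_transition(model, proto, 0.5, fs, RR, seed = seed)
  sig <- model$max_luminance * sim$truth$transparency
  extract_transition_window(sig, proto, fs, RR)$signal
}
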