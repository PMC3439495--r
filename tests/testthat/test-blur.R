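test_that("kernel normalization solves the erf constraints exactly", {
  p <- blur_params()
  expect_true(all(abs(p$norm_residuals) < 1e-10))
  # doubling a width doubles the factor and halves the peak
  p2 <- blur_params(sigma_center = 2 * p$sigma_center)
  expect_equal(p2$norm_center, 2 * p$norm_center, tolerance = 1e-12)
  peak <- function(pp) pp$scale_center / pp$norm_center
  expect_equal(peak(p2), peak(p) / 2, tolerance = 1e-12)
  # raw quadrature vs analytic erf constraint at 0.001 degree sampling
  u <- seq(-p$support_sigmas * p$sigma_center,
           p$support_sigmas * p$sigma_center, by = 0.001)
  raw <- (p$scale_center / p$norm_center) *
    exp(-u^2 / (2 * p$sigma_center^2)) * 0.001
  expect_lt(abs(sum(raw) - p$scale_center), 1e-4)
  # the discrete kernel is exactly renormalized to the constraint
  k <- lcdtempo:::discrete_kernel(p$sigma_center, p$scale_center,
                                  p$norm_center, p$support_sigmas, 0.001)
  expect_equal(sum(k), p$scale_center, tolerance = 1e-14)
  expect_error(blur_params(sigma_center = -1), "> 0")
})

test_that("parameter file round-trips through the JSON loader", {
  def <- blur_params_from_json(
    system.file("extdata", "blur-model-default.json", package = "lcdtempo"))
  expect_equal(def$sigma_center, blur_params()$sigma_center)
  p <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(speed_px_per_frame = 8, sigma_mask = 0.2), p,
                       auto_unbox = TRUE)
  custom <- blur_params_from_json(p)
  expect_equal(custom$speed_px_per_frame, 8)
  expect_equal(custom$sigma_mask, 0.2)
})

test_that("METP preserves plateaus and turns a step into a one-frame ramp", {
  fs <- FS
  frame_ms <- 1000 / RR
  expect_equal(metp(rep(3.5, 2000), frame_ms, fs), rep(3.5, 2000))
  stp <- c(rep(1, 1000), rep(2, 1000))
  mp <- metp(stp, frame_ms, fs)
  # closed-form convolution: linear ramp exactly one frame wide
  w <- frame_ms / 1000 * fs
  ramp_region <- which(mp > 1 + 1e-9 & mp < 2 - 1e-9)
  expect_equal(length(ramp_region), floor(w), tolerance = 2)
  interior <- ramp_region[10:(length(ramp_region) - 10)]
  slopes <- diff(mp[interior])
  expect_equal(max(slopes), min(slopes), tolerance = 1e-9)  # linear
  # tau << frame: METP approximately the hold ramp (numerical oracle)
  t <- seq(0, 0.1 - 1 / fs, by = 1 / fs)
  expon <- c(rep(1, 1000), 1 + (1 - exp(-t / 5e-4)))
  mpe <- metp(expon, frame_ms, fs)
  expect_lt(max(abs(mpe - mp)), 0.05)
  expect_error(metp(1:10, 0.1, 1000), "2 samples")
})

test_that("time-to-space conversion follows dx = speed*refresh/(res*fs)", {
  p <- blur_params()  # 16 px/frame, 40 px/deg
  prof <- rep(1, 100)
  sp <- time_to_space(prof, p, 60, 10000)
  expect_equal(sp$dx, 16 * 60 / (40 * 10000))
  # one frame maps to 0.4 degrees
  expect_equal(sp$dx * 10000 / 60, 0.4)
  expect_length(sp$x, length(prof))
  p2 <- blur_params(speed_px_per_frame = 32)
  expect_equal(time_to_space(prof, p2, 60, 10000)$dx, 2 * sp$dx)
})

test_that("centering finds the cumulative-Gaussian midpoint", {
  dx <- 0.002
  x <- seq(-2, 2, by = dx)
  y <- 10 + 90 * pnorm((x - 0.3) / 0.1)
  ctr <- center_profile(list(x = x - x[1], y = y, dx = dx))
  expect_equal(ctr$midpoint, 0.3 - x[1], tolerance = 2 * dx)
  expect_false(ctr$fallback)
  # translation equivariance
  ctr2 <- center_profile(list(x = x - x[1], y = 10 + 90 * pnorm((x - 0.8) / 0.1),
                              dx = dx))
  expect_equal(ctr2$midpoint - ctr$midpoint, 0.5, tolerance = 2 * dx)
  # asymmetric overshoot profile: midpoint matches a brute-force
  # least-squares scan over candidate midpoints and widths
  yo <- 10 + 90 * pnorm((x - 0.1) / 0.15) +
    15 * exp(-pmax(x - 0.1, 0) / 0.2) * (x > 0.1)
  ctr3 <- center_profile(list(x = x - x[1], y = yo, dx = dx))
  mids <- seq(-0.2, 0.4, by = 0.01)
  widths <- seq(0.05, 0.4, by = 0.01)
  sse <- outer(mids, widths, Vectorize(function(mu, s)
    sum((yo - (min(yo) + diff(range(yo)) * pnorm((x - mu) / s)))^2)))
  best_mu <- mids[which(sse == min(sse), arr.ind = TRUE)[1]]
  expect_equal(ctr3$midpoint, best_mu - x[1], tolerance = 0.05)
})

test_that("masked contrast is a ratio: zero on constants, scale invariant", {
  p <- blur_params()
  dx <- 0.002
  xg <- seq(0, 3, by = dx)
  const <- list(x = xg, y = rep(2, length(xg)), dx = dx)
  mc <- masked_contrast(const, p)
  expect_lt(max(abs(mc$contrast)), 1e-10)
  expect_lt(max(abs(mc$masked)), 1e-10)
  edge <- list(x = xg, y = 0.1 + 0.9 * pnorm((xg - 1.5) / 0.2), dx = dx)
  m1 <- masked_contrast(edge, p)
  edge5 <- edge; edge5$y <- 5 * edge$y
  m5 <- masked_contrast(edge5, p)
  expect_equal(m5$masked, m1$masked, tolerance = 1e-9)
  bad <- edge; bad$y[3] <- 0
  expect_error(masked_contrast(bad, p), "positive")
})

test_that("masked contrast agrees with a direct-quadrature implementation", {
  # independent oracle: brute-force O(n^2) convolution sums
  p <- blur_params()
  dx <- 0.005
  xg <- seq(0, 2.4, by = dx)
  y <- 0.2 + 0.8 * pnorm((xg - 1.2) / 0.15)
  mc <- masked_contrast(list(x = xg, y = y, dx = dx), p)
  # quadrature weights rebuilt independently, convolved by direct sums
  kw <- function(sigma, s, nu) {
    m <- floor(p$support_sigmas * sigma / dx)
    u <- (-m:m) * dx
    w <- (s / nu) * exp(-u^2 / (2 * sigma^2)) * dx
    w * (s / sum(w))
  }
  kc <- kw(p$sigma_center, p$scale_center, p$norm_center)
  ks <- kw(p$sigma_surround, p$scale_surround, p$norm_surround)
  km <- kw(p$sigma_mask, p$scale_mask, p$norm_mask)
  ypad <- c(rep(y[1], 600), y, rep(y[length(y)], 600))
  probe <- seq(200, length(xg) - 200, by = 40)
  direct_conv <- function(w, sig) {
    m <- (length(w) - 1) / 2
    vapply(probe, function(i) sum(sig[600 + ((i - m):(i + m))] * w),
           numeric(1))
  }
  rc <- direct_conv(kc, ypad)
  rs <- direct_conv(ks, ypad)
  C_or <- (rc - rs) / rs
  expect_equal(mc$contrast[probe], C_or, tolerance = 1e-6)
  # full masked stage on the probe points
  Cfull_pad <- c(rep(mc$contrast[1], 600), mc$contrast,
                 rep(mc$contrast[length(mc$contrast)], 600))
  E_or <- direct_conv(km, Cfull_pad^2)
  M_or <- C_or / sqrt(p$masking_threshold^2 + E_or)
  expect_equal(mc$masked[probe], M_or, tolerance = 1e-6)
})

test_that("JND vanishes for an ideal edge profile and is nonnegative", {
  p <- blur_params()
  dx <- p$speed_px_per_frame * 60 / (p$resolution_px_per_deg * FS)
  n <- 1200
  y <- c(rep(0.1, n / 2), rep(1, n / 2))
  ctr <- list(x = (seq_len(n) - n / 2 - 0.5) * dx, y = y, dx = dx)
  r <- vmb_profile_jnd(ctr, p)
  expect_equal(r$jnd, 0, tolerance = 1e-9)
  expect_gte(min(r$per_location), 0)
})

test_that("JND is monotone in LC time constant and in edge speed", {
  p <- blur_params()
  jnds <- vapply(c(1, 4, 8, 16), function(tau)
    vmb_jnd(clean_transition_window(tau), p, RR, FS)$jnd, numeric(1))
  expect_true(all(diff(jnds) > 0))
  sig <- clean_transition_window(8)
  jspeed <- vapply(c(8, 16, 32), function(v)
    vmb_jnd(sig, blur_params(speed_px_per_frame = v), RR, FS)$jnd,
    numeric(1))
  expect_true(all(diff(jspeed) > 0))
  # hold-blur floor: an (almost) instantaneous transition still blurs
  expect_gt(vmb_jnd(clean_transition_window(0.05), p, RR, FS)$jnd, 1)
})

test_that("a blinking (motion-picture) backlight reduces the predicted blur", {
  p <- blur_params()
  const_jnd <- vmb_jnd(clean_transition_window(4), p, RR, FS)$jnd
  blink <- backlight_config("blinking", duty_cycle = 0.3,
                            modulation_depth = 1)
  mb <- display_model(tau_rise_ms = 4, tau_fall_ms = 4, backlight = blink)
  proto <- transition_protocol(0, 255, 10)
  simb <- simulate_transition(mb, proto, 0.5, FS, RR, seed = 3)
  sigb <- extract_transition_window(simb$trace$samples, proto, FS, RR)$signal
  blink_jnd <- vmb_jnd(sigb, p, RR, FS)$jnd
  expect_lt(blink_jnd, const_jnd)
})

test_that("production minimizer equals an exhaustive from-scratch location scan", {
  p <- blur_params()
  set.seed(21)
  for (rep in 1:10) {
    n <- 400
    dx <- 0.004
    lo <- runif(1, 0.05, 0.4)
    mid <- runif(1, -0.3, 0.3)
    width <- runif(1, 0.02, 0.25)
    y <- lo + (1 - lo) * pnorm((((seq_len(n) - n / 2) * dx) - mid) / width)
    ctr <- list(x = (seq_len(n) - n / 2 - 0.5) * dx, y = y, dx = dx)
    r <- vmb_profile_jnd(ctr, p)
    # oracle: rebuild the ideal-edge profile at every location and push it
    # through masked_contrast directly
    yn <- pmax(y / max(y), 1e-3)
    lo_n <- max(min(y) / max(y), 1e-3)
    ms <- masked_contrast(list(x = ctr$x, y = yn, dx = dx), p)
    per <- vapply(0:n, function(j) {
      ideal <- c(rep(lo_n, j), rep(1, n - j))
      mi <- masked_contrast(list(x = ctr$x, y = ideal, dx = dx), p)
      p$jnd_scale *
        (sum(abs(ms$masked - mi$masked)^p$jnd_exponent) * dx)^(1 / p$jnd_exponent)
    }, numeric(1))
    expect_equal(r$jnd, min(per), tolerance = 1e-6)
  }
})

test_that("degenerate zero-amplitude input warns and returns zero blur", {
  expect_warning(r <- vmb_jnd(rep(5, 4000), blur_params(), RR, FS),
                 "degenerate")
  expect_equal(r$jnd, 0)
})
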