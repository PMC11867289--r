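# Signal <-> concentration conversion and the tracer-kinetic forward model.

test_that("signal_to_concentration implements the log-ratio relaxation model", {
  acq <- acquisition_config(te = 0.054, dt = 1, n_frames = 12, n_baseline = 3,
                            r2star = 87)
  times <- 0:11

  # constant signal: concentration identically zero
  s <- signal_ts(times, rep(100, 12), baseline_count = 3)
  expect_equal(signal_to_concentration(s, acq)$values, rep(0, 12))

  # S = S0 * exp(-1) with te * r2star = 1 gives concentration exactly 1
  acq1 <- acquisition_config(te = 1, dt = 1, n_frames = 12, n_baseline = 3,
                             r2star = 1)
  s1 <- signal_ts(times, c(rep(100, 3), rep(100 * exp(-1), 9)),
                  baseline_count = 3)
  expect_equal(signal_to_concentration(s1, acq1)$values[4:12], rep(1, 9))

  # hand-computed value: -ln(0.70)/(0.054*87) = 0.0759155...
  s2 <- signal_ts(times, c(rep(100, 3), 70, rep(100, 8)), baseline_count = 3)
  conc <- signal_to_concentration(s2, acq)
  expect_equal(conc$values[4], -log(0.70) / (0.054 * 87), tolerance = 1e-12)
  expect_equal(conc$times, s2$times)
})

test_that("signal validation names the offending frame", {
  expect_error(signal_ts(0:3, c(1, 2, -1, 2), 2), "frame 3")
  expect_error(signal_ts(0:3, c(1, 2, 3, 4), 0), "baseline_count")
})

test_that("conversion round-trips with its synthetic inverse to machine precision", {
  acq <- acquisition_config()
  times <- default_times(acq)
  aif <- gamma_variate_aif(times)
  conc <- forward_model(linear_residue(3.8), 0.012, 0.5, aif, acq)
  sig <- concentration_to_signal(conc, acq, s0 = 120)
  back <- signal_to_concentration(sig, acq)
  expect_equal(back$values, conc$values, tolerance = 1e-12)
})

test_that("shift_aif interpolates sub-grid delays and zero-pads the onset", {
  times <- 0:9
  aif <- conc_ts(times, c(0, 0, 1, 2, 3, 2, 1, 0, 0, 0), role = "arterial")

  expect_identical(shift_aif(aif, 0), aif)

  # whole-frame shift moves values by one index
  s1 <- shift_aif(aif, 1)
  expect_equal(s1$values, c(0, aif$values[1:9]))

  # half-frame shift on a piecewise-linear curve averages neighbours
  s05 <- shift_aif(aif, 0.5)
  expect_equal(s05$values[2:10],
               (aif$values[2:10] + aif$values[1:9]) / 2)

  # dense-grid interpolation oracle for an arbitrary sub-grid delay
  dense_t <- seq(0, 9, by = 0.001)
  dense <- stats::approx(times, aif$values, xout = dense_t)$y
  oracle <- stats::approx(dense_t, dense, xout = times - 0.731, yleft = 0,
                          rule = 2)$y
  expect_equal(shift_aif(aif, 0.731)$values, oracle, tolerance = 1e-9)

  expect_error(shift_aif(aif, -0.1), "non-negative")
})

test_that("forward model reduces correctly for impulse AIF and zero flow", {
  acq <- acquisition_config(dt = 1, n_frames = 20, n_baseline = 2)
  times <- 0:19
  res <- linear_residue(3)

  impulse <- conc_ts(times, c(1 / 1, rep(0, 19)), role = "arterial")
  out <- forward_model(res, 2.5, 0, impulse, acq)
  expect_equal(out$values, 2.5 * evaluate_residue(res, times), tolerance = 1e-12)

  aif <- gamma_variate_aif(times, t0 = 3, alpha = 2, beta = 1, amplitude = 1)
  expect_equal(forward_model(res, 0, 0.4, aif, acq)$values, rep(0, 20))
})

test_that("forward model is linear in CBF and in the AIF values", {
  acq <- acquisition_config()
  times <- default_times(acq)
  aif <- gamma_variate_aif(times)
  res <- exp_like_residue(3.8)
  base <- forward_model(res, 0.01, 0.6, aif, acq)$values
  expect_equal(forward_model(res, 0.03, 0.6, aif, acq)$values, 3 * base,
               tolerance = 1e-12)
  aif2 <- conc_ts(aif$times, 2 * aif$values, role = "arterial")
  expect_equal(forward_model(res, 0.01, 0.6, aif2, acq)$values, 2 * base,
               tolerance = 1e-12)
})

test_that("boxcar residue convolved with an exponential AIF matches the closed form", {
  # R = 1 on [0, T); AIF = exp(-t/b). Continuous convolution:
  # integral_0^min(t,T) exp(-(t-u)/b) du, i.e. b*(1 - exp(-t/b)) for t < T
  # and b*(exp(-(t-T)/b) - exp(-t/b)) after. Rectangle-rule output must
  # converge to it at first order in dt.
  T_box <- 3
  b <- 2
  closed <- function(t) {
    ifelse(t < T_box, b * (1 - exp(-t / b)),
           b * (exp(-(t - T_box) / b) - exp(-t / b)))
  }
  err <- sapply(c(0.1, 0.05, 0.025), function(dt) {
    n <- round(20 / dt)
    times <- (0:(n - 1)) * dt
    acq <- acquisition_config(dt = dt, n_frames = n, n_baseline = 2)
    aif <- conc_ts(times, exp(-times / b), role = "arterial")
    rv <- as.numeric(times < T_box)
    out <- forward_model(rv, 1, 0, aif, acq)$values
    max(abs(out - closed(times)))
  })
  expect_lt(err[1], 0.15)
  # first-order convergence: halving dt about halves the error
  expect_lt(err[2] / err[1], 0.65)
  expect_lt(err[3] / err[2], 0.65)
})

test_that("time series CSV and acquisition YAML round-trip", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  aif <- gamma_variate_aif(default_times())
  write_timeseries_csv(aif, tmp)
  back <- read_timeseries_csv(tmp, role = "arterial")
  expect_equal(back$values, aif$values, tolerance = 1e-8)

  ytmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("te_s: 0.054", "dt_s: 1.65", "n_frames: 46",
               "n_baseline: 11", "r2star: 87", "k_h: 0.705"), ytmp)
  acq <- read_acquisition_config(ytmp)
  expect_equal(acq$k_h, 0.705)
  expect_equal(acq$n_frames, 46L)
})
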