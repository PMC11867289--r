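# Capillary oxygen transport model and the AOEF transit-time integral.

normal_p <- condition_presets("normal_breathing")
hyper_p <- condition_presets("hyperventilation")

q_asymptote <- function(p) {
  1 - dscbezier:::.equilibrium_concentration(p) /
    dscbezier:::.inlet_concentration(p)
}

test_that("condition presets carry the assumed blood-gas values", {
  expect_equal(normal_p$p50, 26)
  expect_equal(normal_p$hill, 2.8)
  expect_equal(normal_p$pt_o2, 32)
  expect_equal(hyper_p$p50, 24)
  expect_equal(hyper_p$hill, 2.6)
  expect_equal(hyper_p$pt_o2, 28)
  expect_equal(normal_p$k, 118)
  expect_equal(hyper_p$k, 118)
  expect_equal(normal_p$alpha_h, 3.1e-5)
  expect_equal(normal_p$b_max, 0.1943)
  expect_error(condition_presets("apnoea"))
})

test_that("zero transit time gives a flat profile and zero extraction", {
  prof <- capillary_profile(normal_p, 0)
  expect_equal(stats::sd(prof$concentration), 0)
  expect_equal(extraction_fraction(normal_p, 0), 0)
})

test_that("the profile decreases monotonically and never crosses equilibrium", {
  for (p in list(normal_p, hyper_p)) {
    s_eq <- p$pt_o2^p$hill / (p$pt_o2^p$hill + p$p50^p$hill)
    c_eq <- p$b_max * s_eq + p$alpha_h * p$pt_o2
    for (tau in c(0.5, 3.8, 20)) {
      prof <- capillary_profile(p, tau)
      expect_true(all(diff(prof$concentration) <= 1e-12))
      expect_true(all(prof$concentration >= c_eq - 1e-9))
    }
  }
})

test_that("the solution depends on tau only through k * tau", {
  p_half_k <- oxygen_params(k = 59, p50 = 26, hill = 2.8, pt_o2 = 32)
  a <- capillary_profile(normal_p, 1.7)$concentration
  b <- capillary_profile(p_half_k, 3.4)$concentration
  expect_equal(a, b, tolerance = 1e-8)
})

test_that("Q is non-decreasing in tau and bounded by the algebraic asymptote", {
  taus <- c(0, 0.02, 0.05, 0.1, 0.3, 0.8, 2, 3.8, 6, 10, 20)
  for (p in list(normal_p, hyper_p)) {
    q <- extraction_fraction(p, taus)
    expect_true(all(diff(q) >= -1e-10))
    expect_true(all(q < q_asymptote(p)))
    # large k*tau approaches the asymptote
    expect_equal(extraction_fraction(p, 60), q_asymptote(p), tolerance = 1e-4)
  }
})

test_that("standard-tolerance ODE solutions match a refined-tolerance oracle", {
  taus <- c(0.05, 0.5, 3.8, 12)
  q_std <- extraction_fraction(normal_p, taus, rtol = 1e-8)
  q_ref <- extraction_fraction(normal_p, taus, rtol = 1e-10)
  expect_equal(q_std, q_ref, tolerance = 1e-6)
})

test_that("parameters without an extraction gradient are rejected", {
  expect_error(oxygen_params(p_a0 = 1, s_a0 = 1e-6), "gradient")
})

test_that("AOEF converges to Q(MTT) as the transit-time distribution concentrates", {
  # A cubic Bezier residue pinned at (0, 1) cannot carry a point mass at
  # tau0 > 0 (its support always reaches back to 0), so the delta-
  # distribution identity AOEF -> Q(tau0) is checked in the shrinking-
  # support limit: for h uniform on [0, 2m] the Jensen gap between
  # E[Q(tau)] and Q(E[tau]) must vanish as m -> 0.
  # Q varies on the k*tau scale (k = 118 /s), so linearity requires
  # supports well below 10 ms
  rel_gap <- sapply(c(0.01, 0.002, 0.0005), function(m) {
    a <- aoef(linear_residue(m), normal_p, as_percent = FALSE)
    q0 <- extraction_fraction(normal_p, m)
    abs(a - q0) / q0
  })
  expect_true(all(diff(rel_gap) < 0))
  expect_lt(rel_gap[3], 0.02)
})

test_that("AOEF of a uniform distribution equals the grid average of Q", {
  r <- linear_residue(4)  # uniform h on [0, 8]
  tau <- seq(0, 8, length.out = 4001)
  qc <- extraction_curve(normal_p, tau_max = 8)
  qv <- qc$fun(tau)
  oracle <- (sum(qv) - (qv[1] + qv[4001]) / 2) / 4000  # trapezoid mean
  expect_equal(aoef(r, normal_p, as_percent = FALSE), oracle,
               tolerance = 1e-4)
})

test_that("longer transit times increase AOEF", {
  p <- normal_p
  a_short <- aoef(bezier_residue(0.4, 0.7, 1.2, 0.3, 3), p)
  a_long <- aoef(bezier_residue(0.4, 0.7, 1.2, 0.3, 9), p)
  expect_gt(a_long, a_short)
})

test_that("a precomputed extraction curve reproduces the direct AOEF", {
  r <- exp_like_residue(3.8)
  qc <- extraction_curve(normal_p, tau_max = r$t_end + 1)
  expect_equal(aoef(r, qcurve = qc), aoef(r, normal_p), tolerance = 1e-4)
  short <- extraction_curve(normal_p, tau_max = 1)
  expect_error(aoef(r, qcurve = short), "cover")
})

test_that("oxygen YAML configuration selects presets with overrides", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("oxygen:", "  condition: hyperventilation", "  p_a0: 180"), tmp)
  p <- read_oxygen_params(tmp)
  expect_equal(p$p50, 24)
  expect_equal(p$p_a0, 180)
})
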