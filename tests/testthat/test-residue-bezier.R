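# Constrained Bezier residue functions: evaluation, transit-time density,
# MTT and CTH quadratures.

test_that("evaluation honours the pinned endpoints and known exact curves", {
  r <- random_residue()
  expect_equal(evaluate_residue(r, 0), 1)
  expect_equal(evaluate_residue(r, r$t_end), 0)
  expect_equal(evaluate_residue(r, r$t_end + 5), 0)

  # collinear control points degenerate to the straight line 1 - t/T
  T <- 6
  lin <- bezier_residue(T / 3, 2 / 3, 2 * T / 3, 1 / 3, T)
  tt <- seq(0, T, by = 0.25)
  expect_equal(evaluate_residue(lin, tt), 1 - tt / T, tolerance = 1e-9)

  # point-symmetric curve: R(1) = 0.5 by symmetry about (1, 0.5)
  sym <- bezier_residue(1, 1, 1, 0, 2)
  expect_equal(evaluate_residue(sym, 1), 0.5, tolerance = 1e-9)
})

test_that("residue functions are non-increasing for random valid tuples", {
  set.seed(11)
  for (i in 1:40) {
    r <- random_residue()
    t1 <- sort(stats::runif(2, 0, 1.2 * r$t_end))
    expect_gte(evaluate_residue(r, t1[1]), evaluate_residue(r, t1[2]) - 1e-9)
  }
})

test_that("constructor rejects out-of-order control points", {
  expect_error(bezier_residue(3, 0.8, 2, 0.4, 5), "abscissae")
  expect_error(bezier_residue(1, 0.4, 2, 0.8, 5), "ordinates")
  expect_error(bezier_residue(1, 0.8, 2, 0.4, -1), "t_end")
})

test_that("transit-time density is non-negative, integrates to 1, and matches finite differences", {
  # linear residue: h is constant 1/T
  lin <- linear_residue(3)  # T = 6
  h <- transit_time_density(lin, n = 64)
  expect_equal(h$density[-64], rep(1 / 6, 63), tolerance = 1e-8)

  set.seed(7)
  for (i in 1:50) {
    r <- random_residue()
    h <- transit_time_density(r, n = 2048)
    expect_true(all(h$density >= 0))
    # h can have integrable inverse-square-root endpoint singularities, so
    # the unit-mass check uses adaptive quadrature rather than a fixed grid
    area <- stats::integrate(function(t) transit_time_density(r, tau = t)$density,
                             0, r$t_end, subdivisions = 500,
                             stop.on.error = FALSE)$value
    expect_equal(area, 1, tolerance = 5e-3)
  }

  # central finite differences of R on a dense grid as the density oracle
  r <- bezier_residue(1, 1, 1, 0, 2)
  tau <- seq(0.05, 1.95, by = 0.01)
  dd <- 1e-5
  fd <- -(evaluate_residue(r, tau + dd) - evaluate_residue(r, tau - dd)) / (2 * dd)
  expect_equal(transit_time_density(r, tau = tau)$density, fd,
               tolerance = 1e-5)
})

test_that("MTT quadrature is exact against dense trapezoid integration", {
  expect_equal(mtt(linear_residue(3.8)), 3.8)          # triangle area
  expect_equal(mtt(bezier_residue(1, 1, 1, 0, 2)), 1)  # symmetric curve

  set.seed(23)
  for (i in 1:20) {
    r <- random_residue()
    tt <- seq(0, r$t_end, length.out = 20001)
    trap <- sum(diff(tt) * (utils::head(evaluate_residue(r, tt), -1) +
                              utils::tail(evaluate_residue(r, tt), -1)) / 2)
    expect_equal(mtt(r), trap, tolerance = 1e-6)
    expect_gt(mtt(r), 0)
    expect_lt(mtt(r), r$t_end)
  }
})

test_that("CTH is the central second moment of the transit-time density", {
  # uniform h on [0, T]: variance T^2 / 12
  expect_equal(cth(linear_residue(3)), 36 / 12)
  expect_equal(cth(linear_residue(3), as_sd = TRUE), sqrt(3))

  # near-degenerate residue: point-mass h, vanishing second moment
  narrow <- bezier_residue(0.005 / 3, 2 / 3, 0.01 / 3, 1 / 3, 0.01)
  expect_lt(cth(narrow), 1e-4)

  # dense-grid oracle via integration by parts: the density h has
  # inverse-square-root endpoint behaviour, but
  # CTH = MTT^2 + integral 2 (t - MTT) R(t) dt uses only the smooth R
  set.seed(31)
  for (i in 1:10) {
    r <- random_residue()
    m <- mtt(r)
    tt <- seq(0, r$t_end, length.out = 200001)
    f <- 2 * (tt - m) * evaluate_residue(r, tt)
    oracle <- m^2 + sum(diff(tt) * (utils::head(f, -1) + utils::tail(f, -1)) / 2)
    expect_equal(cth(r), oracle, tolerance = 1e-6)
  }
})

test_that("MTT equals the first raw moment of the density", {
  set.seed(41)
  for (i in 1:15) {
    r <- random_residue()
    h <- transit_time_density(r, n = 40001)
    w <- diff(h$tau)
    mids <- (utils::head(h$tau, -1) + utils::tail(h$tau, -1)) / 2
    dens <- (utils::head(h$density, -1) + utils::tail(h$density, -1)) / 2
    expect_equal(sum(w * mids * dens), mtt(r), tolerance = 2e-3)
  }
})

test_that("fixed-order quadratures agree with adaptive quadrature", {
  set.seed(53)
  for (i in 1:10) {
    r <- random_residue()
    m_ad <- stats::integrate(function(t) evaluate_residue(r, t), 0, r$t_end,
                             rel.tol = 1e-12)$value
    expect_equal(mtt(r), m_ad, tolerance = 1e-9)
  }
})

test_that("residues serialise to JSON and back", {
  r <- random_residue()
  r2 <- residue_from_json(residue_to_json(r))
  expect_equal(unclass(r2), unclass(r), tolerance = 1e-12)
})

test_that("the optimiser reparameterisation always yields valid residues", {
  set.seed(61)
  for (i in 1:50) {
    th <- stats::runif(4)
    r <- dscbezier:::.theta_to_residue(th[1], th[2], th[3], th[4],
                                       stats::runif(1, 0.5, 40))
    expect_s3_class(r, "bezier_residue")
  }
})
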