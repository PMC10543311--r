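test_that("scattering vector matches hand evaluations and scalings", {
  # unit construction: theta = 180, n0 = 1, lambda0 = 4 pi -> q = 1
  expect_equal(scatteringVector(scatteringConfig(n0 = 1, lambda0 = 4 * pi,
                                                 theta_deg = 180)), 1)
  # backscattering optics: 4 pi 1.330 / 632.8 nm * sin(86.5 deg)
  q_hand <- 4 * pi * 1.330 / 632.8e-9 * sin(86.5 * pi / 180)
  expect_equal(scatteringVector(scatteringConfig()), q_hand)
  expect_equal(q_hand, 2.64e7, tolerance = 0.005)
  # doubling the wavelength halves q
  expect_equal(scatteringVector(scatteringConfig(lambda0 = 2 * 632.8e-9)),
               scatteringVector(scatteringConfig()) / 2)
})

test_that("Stokes-Einstein maps 1 nm radius to 2.46e-10 m^2/s and inverts", {
  # hand evaluation with explicit constants
  D_hand <- 1.380649e-23 * 298.15 / (6 * pi * 8.872e-4 * 1e-9)
  expect_equal(diffusionCoefficient(2), D_hand, tolerance = 1e-12)
  expect_equal(D_hand, 2.461e-10, tolerance = 5e-4)  # 4 significant figures
  # size -> D -> size round trip is the identity to machine precision
  d <- c(1, 20, 100, 950)
  expect_equal(hydrodynamicDiameter(diffusionCoefficient(d)), d,
               tolerance = 1e-12)
})

test_that("single-exponential fit is self-consistent on a noiseless curve", {
  fit <- fitSingleExponential(dls_curve(1e-11, 0.8), scatteringConfig())
  expect_equal(fit@D, 1e-11, tolerance = 1e-4)
  expect_equal(fit@b, 0.8, tolerance = 1e-4)
  expect_equal(fit@d_h, 2 * fit@R_h)
})

test_that("fit is equivariant under joint lag/D rescaling", {
  opt <- scatteringConfig()
  lag <- 10^seq(-6, -2, length.out = 60)
  f1 <- fitSingleExponential(dls_curve(1e-11, 0.6, opt, lag), opt)
  f2 <- fitSingleExponential(dls_curve(1e-11 / 8, 0.6, opt, lag * 8), opt)
  expect_equal(f2@D * 8, f1@D, tolerance = 1e-6)
  expect_equal(f2@residual, f1@residual, tolerance = 1e-8)
})

test_that("non-decaying curves produce a fit failure, not silent defaults", {
  lag <- 10^seq(-6, -3, length.out = 20)
  flat <- CorrelationCurve(lag, rep(1, 20))
  expect_error(fitSingleExponential(flat, scatteringConfig()), "fail")
  expect_error(fitSingleExponential(
    CorrelationCurve(lag[1:5], rep(1.5, 5)), scatteringConfig()), ">= 10")
})

test_that("simulated monodisperse suspension round-trips to its diameter", {
  opt <- scatteringConfig()
  traj <- simulateBrownianSuspension(150, 100, dt = 2e-5, n_steps = 3e4,
                                     seed = 11)
  tr <- renderScatteredIntensity(traj, opt)
  cv <- correlateDirect(tr, max_lag = 1.5e-3)
  fit <- fitSingleExponential(cv, opt)
  expect_equal(fit@d_h * 1e9, 100, tolerance = 0.15)
})

test_that("slow-mode detection flags mixtures and not single components", {
  opt <- scatteringConfig()
  Df <- 1e-11
  lag <- 10^seq(-6, -2, length.out = 60)
  mix <- dls_curve(c(Df, Df / 100), c(0.5, 0.5), opt, lag)
  sm <- detectSlowMode(mix, opt)
  expect_true(sm@slow_mode_flag)
  expect_equal(sm@slow_mode_fraction, 0.5, tolerance = 0.05)
  # 95/5 mixture stays below the default 0.1 fraction threshold
  weak <- dls_curve(c(Df, Df / 100), c(0.95, 0.05), opt, lag)
  expect_false(detectSlowMode(weak, opt)@slow_mode_flag)
  # single component: fraction ~ 0, no flag
  single <- detectSlowMode(dls_curve(Df, 0.9, opt, lag), opt)
  expect_false(single@slow_mode_flag)
  expect_lt(single@slow_mode_fraction, 0.05)
})

test_that("size-distribution inversion concentrates mass at the true size", {
  opt <- scatteringConfig()
  lag <- 10^seq(-6, -2, length.out = 60)
  q <- scatteringVector(opt)
  one <- CorrelationCurve(lag, 1 + exp(-2 * diffusionCoefficient(100) *
                                         q^2 * lag))
  sd1 <- sizeDistribution(one, opt)
  expect_true(all(sd1@weight >= 0))
  expect_equal(sum(sd1@weight), 1)
  in_band <- sd1@diameter_nm >= 80 & sd1@diameter_nm <= 120
  expect_gt(sum(sd1@weight[in_band]), 0.8)
})

test_that("well-separated sizes are recovered as a bimodal distribution", {
  opt <- scatteringConfig()
  lag <- 10^seq(-6, -2, length.out = 60)
  q <- scatteringVector(opt)
  g1 <- 0.5 * exp(-diffusionCoefficient(50) * q^2 * lag) +
    0.5 * exp(-diffusionCoefficient(1000) * q^2 * lag)
  two <- CorrelationCurve(lag, 1 + g1^2)
  sd2 <- sizeDistribution(two, opt)
  d <- sd2@diameter_nm
  m_small <- sum(sd2@weight[d >= 35 & d <= 70])
  m_large <- sum(sd2@weight[d >= 700 & d <= 1400])
  expect_gt(m_small, 0.3)
  expect_gt(m_large, 0.3)
  expect_lt(sum(sd2@weight[d > 120 & d < 500]), 0.2)
})

test_that("intensity weighting biases the mean size above the number mean", {
  # equal particle numbers at 50 and 500 nm; field amplitudes scale as d^3
  opt <- scatteringConfig()
  lag <- 10^seq(-6, -1, length.out = 80)
  q <- scatteringVector(opt)
  a <- c(1, 1) * c(50, 500)^3
  w <- a^2 / sum(a^2)  # intensity weights
  g1 <- w[1] * exp(-diffusionCoefficient(50) * q^2 * lag) +
    w[2] * exp(-diffusionCoefficient(500) * q^2 * lag)
  cv <- CorrelationCurve(lag, 1 + g1^2)
  sdist <- sizeDistribution(cv, opt)
  mean_intensity <- sum(sdist@diameter_nm * sdist@weight)
  expect_gt(mean_intensity, mean(c(50, 500)))
})

test_that("derived count rate rescales by the transmitted fraction", {
  expect_equal(derivedCountRate(100, 1), 100)
  expect_equal(derivedCountRate(50, 0.25), 200)
  expect_gt(derivedCountRate(50, 0.1), derivedCountRate(50, 0.5))
  expect_error(derivedCountRate(50, 0), "attenuation")
})
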