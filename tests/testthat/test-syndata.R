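test_that("zero-diffusion hook freezes all particles", {
  traj <- simulateBrownianSuspension(5, 100, n_steps = 50, seed = 1,
                                     zero_diffusion = TRUE)
  expect_equal(max(abs(apply(traj@positions, c(2, 3), stats::sd))), 0)
})

test_that("ensemble MSD slope recovers the configured D within 10%", {
  traj <- simulateBrownianSuspension(20, 100, dt = 1e-5, n_steps = 1e4,
                                     seed = 4)
  m <- ensembleMsd(traj, 10)
  D_hat <- stats::coef(stats::lm(msd_m2 ~ lag_s, m))[2] / 6
  expect_equal(unname(D_hat), diffusionCoefficient(100), tolerance = 0.1)
})

test_that("Brownian increments are Gaussian with variance 2 D dt", {
  traj <- simulateBrownianSuspension(10, 200, dt = 1e-5, n_steps = 1e4,
                                     seed = 6)
  # 3 x 10^5 per-axis increments in total
  inc <- apply(traj@positions, c(2, 3), diff)
  v <- stats::var(as.vector(inc))
  expect_equal(v, 2 * diffusionCoefficient(200) * 1e-5, tolerance = 0.05)
  expect_gt(stats::shapiro.test(sample(as.vector(inc), 5000))$p.value, 1e-3)
})

test_that("per-particle D separates a two-size mixture into two modes", {
  traj <- simulateBrownianSuspension(40, rep(c(50, 500), each = 20),
                                     dt = 1e-5, n_steps = 3000, seed = 5)
  Dp <- perParticleD(traj)
  ratio <- stats::median(Dp[1:20]) / stats::median(Dp[21:40])
  expect_gt(ratio, 5)   # true ratio 10
  expect_lt(ratio, 20)
  expect_true(max(Dp[21:40]) < min(Dp[1:20]))  # modes do not overlap
})

test_that("heavy-tailed diameter sampler respects its bounds and tail", {
  set.seed(9)
  d <- sampleClusterDiameters(2e4, 10, monomer_fraction = 0.5, alpha = 3,
                              d_max_nm = 1000)
  expect_true(all(d >= 10 & d <= 1000))
  expect_equal(mean(d == 10), 0.5, tolerance = 0.05)
  tail_d <- d[d > 10]
  # truncated power law: survival beyond 100 nm ~ (100/10)^(1-3) = 1%
  expect_equal(mean(tail_d > 100), 0.01, tolerance = 0.5)
})

test_that("scattered intensity is constant for a static particle and scales", {
  traj <- simulateBrownianSuspension(1, 100, n_steps = 20, seed = 2,
                                     zero_diffusion = TRUE)
  tr <- renderScatteredIntensity(traj, scatteringConfig())
  expect_equal(stats::sd(tr@values), 0)
  traj2 <- simulateBrownianSuspension(30, 100, n_steps = 500, seed = 3)
  t1 <- renderScatteredIntensity(traj2, scatteringConfig())
  t2 <- renderScatteredIntensity(traj2, scatteringConfig(),
                                 amplitude_scale = 2)
  expect_equal(t2@values, 4 * t1@values, tolerance = 1e-12)
})

test_that("configuration errors are raised for invalid suspensions", {
  expect_error(simulateBrownianSuspension(3, -5), "positive")
  expect_error(simulateBrownianSuspension(3, 100, viscosity = 0), "positive")
  expect_error(
    renderScatteredIntensity(
      simulateBrownianSuspension(0, numeric(0), n_steps = 5),
      scatteringConfig()),
    "empty")
})

test_that("background-only photon streams are Poisson with the right mean", {
  st <- simulatePhotonStream(10, background_khz = 1.25, seed = 1)
  expect_equal(nRecords(st), 5e4, tolerance = 4 * sqrt(5e4) / 5e4)
  per_chan <- table(st@channel)
  expect_true(all(abs(per_chan - 1.25e4) < 4 * sqrt(1.25e4)))
})

test_that("photon streams are bit-reproducible given a seed", {
  sp <- emitterSpecies(2, 1, 50, 4)
  a <- simulatePhotonStream(0.5, sp, background_khz = 0.1, seed = 42)
  b <- simulatePhotonStream(0.5, sp, background_khz = 0.1, seed = 42)
  expect_identical(a@macrotime, b@macrotime)
  expect_identical(a@channel, b@channel)
  expect_identical(a@microtime, b@microtime)
})

test_that("a static source has exponential inter-photon intervals", {
  sp <- emitterSpecies(1, Inf, brightness_khz = 20, lifetime_ns = 4)
  st <- simulatePhotonStream(1, sp, seed = 2, p_parallel = 1)
  iv <- diff(st@macrotime[st@channel == "Gp"])
  iv <- iv[seq_len(min(length(iv), 1e4))]
  expect_gt(stats::ks.test(iv, "pexp", 1 / mean(iv))$p.value, 0.01)
})

test_that("microtimes of an immobile emitter fit the configured lifetime", {
  sp <- emitterSpecies(1, Inf, brightness_khz = 60, lifetime_ns = 4)
  st <- simulatePhotonStream(2, sp, seed = 12)   # ~1.2e5 photons
  f <- fitBurstLifetime(st@microtime, st@period_ns / 2)
  expect_lt(abs(f$tau_ns - 4), 3 * f$se_ns)
})

test_that("unit FRET efficiency sends every emitter photon to red channels", {
  sp <- emitterSpecies(3, 0.5, brightness_khz = 50, lifetime_ns = 4,
                       fret = 1, acc_brightness_khz = 25)
  st <- simulatePhotonStream(2, sp, background_khz = 0, crosstalk = 0,
                             seed = 3)
  expect_true(all(st@channel %in% c("Rp", "Rs")))
})

test_that("photon stream rejects non-positive durations", {
  expect_error(simulatePhotonStream(0), "positive")
})

test_that("scan traces: no concentration, no peaks; linear in concentration", {
  s0 <- simulateScanTraces(0, seed = 1)
  expect_lt(meanClusterCount(s0), 0.1)  # nothing beyond baseline statistics
  s1 <- simulateScanTraces(1e-13, seed = 2)
  s2 <- simulateScanTraces(2e-13, seed = 3)
  n1 <- meanClusterCount(s1); n2 <- meanClusterCount(s2)
  expect_equal(n2 / n1, 2, tolerance = 0.25)
})

test_that("solvation box validates weights and keeps counts constant", {
  expect_error(
    simulateSolvationBox(n_frames = 1, w_anion = function(r) rep(0.5, length(r))),
    "bulk")
  bx <- simulateSolvationBox(n_frames = 4, n_water = 500, seed = 2)
  counts <- sapply(bx@frames, function(f) sapply(f, nrow))
  expect_true(all(counts == counts[, 1]))
  expect_equal(bx@meta$n_anion, round(0.5 * 6.02214076e23 * (7e-7)^3 * 1e-3))
})

test_that("cation enhancement raises gamma at the modulation radius", {
  wc <- function(r) ifelse(r < 1, 2, 1)
  bx <- simulateSolvationBox(n_frames = 10, w_cation = wc, seed = 11)
  g <- gammaIon(bx, "K")
  expect_gt(g$gamma[which.min(abs(g$r_nm - 1))], 0)
})

test_that("spin-down series reproduces the breakpoint identity", {
  s <- simulateSpindownSeries(3, 1:5)
  expect_equal(s$supernatant_uM, c(1, 2, 3, 3, 3))
  s2 <- simulateSpindownSeries(10, 1:5)
  expect_equal(s2$supernatant_uM, s2$total_uM)
})
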