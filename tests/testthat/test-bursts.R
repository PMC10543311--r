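test_that("a photon spike is selected as exactly one burst", {
  st <- spike_stream()
  b <- selectBursts(st)
  # the spike sits in one burst carrying most of its photons
  spike_t <- attr(st, "spike_times")
  hits <- which(b$start_s <= min(spike_t) & b$end_s >= max(spike_t))
  expect_length(hits, 1)
  in_burst <- sum(spike_t >= b$start_s[hits] & spike_t <= b$end_s[hits])
  expect_gte(in_burst, 45)
  expect_gte(b$n_photons[hits], 45)
  # threshold monotonicity: a 100-photon floor removes the 50-photon spike
  expect_equal(nrow(selectBursts(st, min_photons = 100)), 0)
})

test_that("burst selection is deterministic and partitions the photons", {
  sp <- emitterSpecies(3, 0.5, brightness_khz = 100, lifetime_ns = 4)
  st <- simulatePhotonStream(5, sp, background_khz = 0.025, seed = 8)
  b1 <- selectBursts(st)
  b2 <- selectBursts(st)
  expect_identical(b1, b2)
  idx <- attr(b1, "photon_idx")
  all_idx <- unlist(idx)
  expect_equal(anyDuplicated(all_idx), 0)   # no photon in two bursts
  expect_equal(sum(b1$n_photons) + (nRecords(st) - length(all_idx)),
               nRecords(st))
})

test_that("two spikes separated by a wide gap give two bursts", {
  st1 <- spike_stream(spike_t0 = 1.0, seed = 4)
  sp2 <- 3.0 + sort(stats::runif(50, 0, 2e-3))
  mt <- c(st1@macrotime, sp2); ord <- order(mt)
  st <- PhotonStream(mt[ord],
                     c(as.character(st1@channel), rep("Gp", 50))[ord],
                     c(st1@microtime, stats::runif(50, 0, 32))[ord], 32, 5)
  expect_equal(nrow(selectBursts(st)), 2)
})

test_that("the photon maximum discards oversized bursts", {
  # a uniform high-rate stream: supra-threshold runs carry thousands of
  # photons and are removed by the 3000-photon cap
  st <- simulatePhotonStream(5, background_khz = 15, seed = 1)
  capped <- selectBursts(st, bin_ms = 50)
  uncapped <- selectBursts(st, bin_ms = 50, max_photons = Inf)
  expect_equal(nrow(capped), 0)
  expect_gt(nrow(uncapped), 0)
  expect_true(all(uncapped$n_photons > 3000))
})

test_that("lifetime MLE is unbiased within 3 SE across the Nile-Red window", {
  set.seed(1)
  for (tau in c(0.6, 2, 4, 4.66)) {
    mts <- stats::rexp(1e4, 1 / tau) %% 16
    f <- fitBurstLifetime(mts, 16)
    expect_lt(abs(f$tau_ns - tau), 3 * f$se_ns)
    expect_gt(f$tau_ns, 0.5)
    expect_lt(f$tau_ns, 5)
  }
})

test_that("supplying the background fraction removes the lifetime bias", {
  set.seed(2)
  mts <- c(stats::rexp(5e3, 1 / 2) %% 16, stats::runif(5e3, 0, 16))
  with_bg <- fitBurstLifetime(mts, 16, background_fraction = 0.5)
  without <- fitBurstLifetime(mts, 16)
  expect_lt(abs(with_bg$tau_ns - 2), 3 * with_bg$se_ns * 2)
  expect_gt(without$tau_ns, 2 + 3 * with_bg$se_ns)  # biased when ignored
})

test_that("lifetime estimator RMSE scales as 1/sqrt(n)", {
  set.seed(3)
  rmse <- vapply(c(1e2, 1e3, 1e4), function(n) {
    reps <- max(20, round(2e4 / n))
    sqrt(mean(vapply(seq_len(reps), function(i) {
      (fitBurstLifetime(stats::rexp(n, 1 / 2) %% 16, 16)$tau_ns - 2)^2
    }, numeric(1))))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
  expect_equal(rmse[1] / rmse[3], 10, tolerance = 0.6)
})

test_that("degenerate microtimes are rejected", {
  expect_error(fitBurstLifetime(rep(2, 50), 16), "degenerate")
})

test_that("burst intensity histogram: mass conserved, tail discriminates", {
  b <- data.frame(start_s = 0, end_s = 1, duration_ms = 1,
                  n_photons = 100, rate_khz = c(100, 100, 100))
  h <- burstIntensityHistogram(b)
  expect_equal(sum(h$counts), 3)
  expect_equal(sum(h$counts > 0), 1)     # identical rates: one occupied bin
  # monomers only vs monomers + bright clusters (paired simulation)
  mono <- emitterSpecies(6, 0.5, brightness_khz = 100, lifetime_ns = 4)
  clus <- rbind(mono, emitterSpecies(2, 2, brightness_khz = 1500,
                                     lifetime_ns = 4))
  st_m <- simulatePhotonStream(5, mono, background_khz = 0.025, seed = 21)
  st_c <- simulatePhotonStream(5, clus, background_khz = 0.025, seed = 21)
  tm <- burstIntensityHistogram(selectBursts(st_m))$tail_mass
  tc <- burstIntensityHistogram(selectBursts(st_c))$tail_mass
  expect_gt(tc, tm)
})

test_that("FRET observables: donor-only, half-transfer, competitor shift", {
  # donor-only bursts: E ~ 0, S ~ 1
  spd <- emitterSpecies(8, 1, brightness_khz = 80, lifetime_ns = 3.8)
  std <- simulatePhotonStream(6, spd, background_khz = 0.025, seed = 6)
  frd <- computeFret(std, selectBursts(std))
  expect_lt(mean(frd$E, na.rm = TRUE), 0.05)
  expect_gt(mean(frd$S, na.rm = TRUE), 0.9)
  # E_true = 0.5 with ideal corrections: mean E in [0.45, 0.55]
  spf <- emitterSpecies(15, 1, brightness_khz = 80, lifetime_ns = 3.8,
                        fret = 0.5, acc_brightness_khz = 40,
                        acc_lifetime_ns = 1.5)
  stf <- simulatePhotonStream(18, spf, background_khz = 0.025, seed = 5)
  bf <- selectBursts(stf)
  expect_gt(nrow(bf), 400)
  frf <- computeFret(stf, bf)
  expect_gt(mean(frf$E, na.rm = TRUE), 0.45)
  expect_lt(mean(frf$E, na.rm = TRUE), 0.55)
  # unlabeled competitor: mostly donor-only bursts shift the E histogram low
  comp <- rbind(spf[, ], spd)
  comp$n <- c(3, 20)
  stc <- simulatePhotonStream(8, comp, background_khz = 0.025, seed = 7)
  frc <- computeFret(stc, selectBursts(stc))
  expect_lt(mean(frc$E, na.rm = TRUE), mean(frf$E, na.rm = TRUE))
})

test_that("FRET lines: endpoints, limits, and the two-state inequality", {
  fl <- fretLines(4)
  expect_equal(fl$static(4), 0)
  expect_equal(fl$static(0), 1)
  dyn <- fretLines(4, states = c(0.8, 3.2))$dynamic
  # x -> 0, 1 limits coincide with the states' static-line points
  expect_equal(dyn$E[dyn$x == 0], 1 - 3.2 / 4)
  expect_equal(dyn$tau_f_ns[dyn$x == 0], 3.2)
  expect_equal(dyn$E[dyn$x == 1], 1 - 0.8 / 4)
  expect_equal(dyn$tau_f_ns[dyn$x == 1], 0.8)
  # dynamic-line E at a given tau_f is >= static-line E (brute force on grid)
  static_E <- 1 - dyn$tau_f_ns / 4
  expect_true(all(dyn$E >= static_E - 1e-12))
  expect_warning(fretLines(4, states = c(2, 2)), "degenerate")
})

test_that("g-factor combination weights the perpendicular channel", {
  expect_equal(totalSignal(10, 5), 20)
  expect_equal(totalSignal(10, 5, g_factor = 1.2), 22)
})
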