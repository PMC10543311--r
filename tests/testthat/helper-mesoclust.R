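# shared fixture builders (all fixtures are generated in code)

# lognormal Ornstein-Uhlenbeck intensity trace: positive, smoothly correlated
ou_trace <- function(n = 4096, tau_corr = 50, dt = 1e-3) {
  x <- numeric(n)
  x[1] <- stats::rnorm(1)
  a <- exp(-1 / tau_corr)
  s <- sqrt(1 - a^2)
  for (i in 2:n) x[i] <- a * x[i - 1] + s * stats::rnorm(1)
  IntensityTrace(exp(x / 2), dt = dt)
}

# noiseless single- or multi-exponential DLS curve on a log-spaced lag grid
dls_curve <- function(D, b, optics = scatteringConfig(),
                      lag = 10^seq(-6, -2, length.out = 60)) {
  q <- scatteringVector(optics)
  g <- 1 + colSums(b * exp(-2 * outer(D, lag) * q^2))
  CorrelationCurve(lag, g)
}

# photon stream with a deterministic photon spike inserted into background
spike_stream <- function(duration_s = 5, bg_per_channel_khz = 0.025,
                         spike_t0 = 2.5, spike_n = 50, spike_width_s = 2e-3,
                         seed = 3) {
  st <- simulatePhotonStream(duration_s, background_khz = bg_per_channel_khz,
                             seed = seed)
  sp_t <- spike_t0 + sort(stats::runif(spike_n, 0, spike_width_s))
  mt <- c(st@macrotime, sp_t)
  ch <- c(as.character(st@channel), rep("Gp", spike_n))
  mc <- c(st@microtime, stats::runif(spike_n, 0, st@period_ns))
  ord <- order(mt)
  out <- PhotonStream(mt[ord], ch[ord], mc[ord], st@period_ns, duration_s)
  attr(out, "spike_times") <- sp_t
  out
}

# 2D Brownian localization table with ground-truth particle ids
brownian_locs <- function(n_particles = 50, n_frames = 300, fps = 30,
                          d_nm = 100, field_um = 200,
                          temperature = 298.15, viscosity = 8.872e-4) {
  D <- diffusionCoefficient(d_nm, temperature, viscosity)
  sd_um <- sqrt(2 * D / fps) * 1e6
  do.call(rbind, lapply(seq_len(n_particles), function(i) {
    data.frame(
      frame = 0:(n_frames - 1),
      x_um = cumsum(c(stats::runif(1, 0, field_um),
                      stats::rnorm(n_frames - 1, 0, sd_um))),
      y_um = cumsum(c(stats::runif(1, 0, field_um),
                      stats::rnorm(n_frames - 1, 0, sd_um))),
      particle = i)
  }))
}

# hand-built solvation frames: explicit coordinates, cubic box (nm)
manual_frames <- function(frames, box = 7) SolvationFrames(frames, box)
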