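#' @include AllClasses.R constants.R
NULL

#' Diffusion coefficient and hydrodynamic diameter (Stokes-Einstein)
#'
#' \code{diffusionCoefficient} maps a hydrodynamic diameter to the
#' translational diffusion coefficient D = kB T / (3 pi eta d);
#' \code{hydrodynamicDiameter} is its exact inverse. Defaults are water at
#' 298.15 K (eta = 0.8872 mPa s).
#'
#' @param d_nm hydrodynamic diameter (nm).
#' @param D diffusion coefficient (m^2/s).
#' @param temperature temperature (K).
#' @param viscosity dynamic viscosity (Pa s).
#' @return \code{diffusionCoefficient}: D in m^2/s;
#'   \code{hydrodynamicDiameter}: d in nm.
#' @examples
#' diffusionCoefficient(2)     # R_h = 1 nm -> ~2.46e-10 m^2/s
#' @export
diffusionCoefficient <- function(d_nm, temperature = 298.15,
                                 viscosity = 8.872e-4) {
  if (any(d_nm <= 0)) stop("diameters must be positive")
  if (viscosity <= 0) stop("viscosity must be positive")
  .kB * temperature / (3 * pi * viscosity * d_nm * 1e-9)
}

#' @rdname diffusionCoefficient
#' @export
hydrodynamicDiameter <- function(D, temperature = 298.15,
                                 viscosity = 8.872e-4) {
  if (any(D <= 0)) stop("D must be positive")
  .kB * temperature / (3 * pi * viscosity * D) * 1e9
}

#' Sample particle diameters from a monomer + heavy-tailed cluster mixture
#'
#' Cluster-size distributions in sub-saturated solutions are heavy-tailed;
#' this sampler emulates them as a mixture of a monomer delta at
#' \code{d_monomer_nm} and a truncated power law p(d) ~ d^-alpha on
#' [d_monomer_nm, d_max_nm], drawn by inverse-CDF sampling.
#'
#' @param n number of particles.
#' @param d_monomer_nm monomer diameter (nm).
#' @param monomer_fraction fraction of particles that are monomers.
#' @param alpha power-law exponent (> 1).
#' @param d_max_nm upper truncation of the cluster tail (nm).
#' @return numeric vector of diameters (nm).
#' @export
sampleClusterDiameters <- function(n, d_monomer_nm = 10,
                                   monomer_fraction = 0.9,
                                   alpha = 3, d_max_nm = 1000) {
  stopifnot(alpha > 1, d_max_nm > d_monomer_nm, d_monomer_nm > 0)
  is_mono <- stats::runif(n) < monomer_fraction
  d <- rep(d_monomer_nm, n)
  k <- sum(!is_mono)
  if (k) {
    u <- stats::runif(k)
    a <- 1 - alpha
    lo <- d_monomer_nm^a; hi <- d_max_nm^a
    d[!is_mono] <- (lo + u * (hi - lo))^(1 / a)
  }
  d
}

#' Simulate a Brownian particle suspension
#'
#' Free Brownian dynamics of a polydisperse suspension: each particle gets
#' its diffusion coefficient from the Stokes-Einstein relation and Gaussian
#' displacement increments with per-axis variance 2 D dt. Unwrapped positions
#' are stored (so the MSD is computable directly); wrapped coordinates follow
#' from the recorded box edge.
#'
#' @param n_particles number of particles.
#' @param diameter_nm particle diameters (nm); scalar recycled, or a vector of
#'   length \code{n_particles} (e.g. from
#'   \code{\link{sampleClusterDiameters}}).
#' @param temperature temperature (K).
#' @param viscosity dynamic viscosity (Pa s).
#' @param dt time step (s).
#' @param n_steps number of steps.
#' @param box_edge box edge (m); must exceed 10x the largest diameter.
#'   Default 100x the largest diameter.
#' @param seed RNG seed.
#' @param zero_diffusion test hook: freeze all particles (zero-variance
#'   increments) regardless of diameter.
#' @return A \linkS4class{ParticleTrajectorySet}.
#' @export
simulateBrownianSuspension <- function(n_particles, diameter_nm,
                                       temperature = 298.15,
                                       viscosity = 8.872e-4,
                                       dt = 1e-5, n_steps = 1000,
                                       box_edge = NULL, seed = NULL,
                                       zero_diffusion = FALSE) {
  if (any(diameter_nm <= 0)) stop("diameters must be positive")
  if (viscosity <= 0) stop("viscosity must be positive")
  if (dt <= 0) stop("dt must be positive")
  d <- rep_len(diameter_nm, n_particles)
  if (n_particles > 0L) {
    if (is.null(box_edge)) box_edge <- 100 * max(d) * 1e-9
    if (box_edge <= 10 * max(d) * 1e-9)
      stop("box_edge must exceed 10x the largest diameter")
  } else if (is.null(box_edge)) box_edge <- 1e-5
  if (!is.null(seed)) set.seed(seed)
  D <- diffusionCoefficient(d, temperature, viscosity)
  sd_step <- if (zero_diffusion) rep(0, n_particles) else sqrt(2 * D * dt)
  pos <- array(0, dim = c(n_steps + 1L, n_particles, 3L))
  start <- matrix(stats::runif(n_particles * 3L, 0, box_edge),
                  ncol = 3L)
  for (i in seq_len(n_particles)) {
    inc <- matrix(stats::rnorm(n_steps * 3L, sd = sd_step[i]), ncol = 3L)
    pos[, i, ] <- rbind(start[i, ],
                        sweep(apply(inc, 2, cumsum), 2, start[i, ], `+`))
  }
  new("ParticleTrajectorySet", positions = pos, box_edge = box_edge,
      dt = dt, diameter_nm = d, temperature = temperature,
      viscosity = viscosity,
      meta = list(D = D, seed = seed, zero_diffusion = zero_diffusion))
}

#' Ensemble and per-particle mean-squared displacement
#'
#' \code{ensembleMsd} averages the 3D MSD over all particles;
#' \code{perParticleD} estimates each particle's diffusion coefficient from
#' the slope of its MSD over the first \code{n_lags} lags (slope/6 in 3D).
#'
#' @param traj a \linkS4class{ParticleTrajectorySet}.
#' @param n_lags number of lags used.
#' @return \code{ensembleMsd}: data.frame with \code{lag_s} and \code{msd_m2};
#'   \code{perParticleD}: numeric vector of D (m^2/s).
#' @export
ensembleMsd <- function(traj, n_lags = 10) {
  pos <- traj@positions
  n <- dim(pos)[1]
  lags <- seq_len(min(n_lags, n - 1L))
  msd <- vapply(lags, function(k) {
    d2 <- (pos[seq_len(n - k) + k, , , drop = FALSE] -
             pos[seq_len(n - k), , , drop = FALSE])^2
    mean(apply(d2, c(1, 2), sum))
  }, numeric(1))
  data.frame(lag_s = lags * traj@dt, msd_m2 = msd)
}

#' @rdname ensembleMsd
#' @export
perParticleD <- function(traj, n_lags = 5) {
  pos <- traj@positions
  n <- dim(pos)[1]
  lags <- seq_len(min(n_lags, n - 1L))
  vapply(seq_len(dim(pos)[2]), function(i) {
    msd <- vapply(lags, function(k) {
      d <- pos[seq_len(n - k) + k, i, ] - pos[seq_len(n - k), i, ]
      mean(rowSums(d^2))
    }, numeric(1))
    stats::coef(stats::lm(msd ~ I(lags * traj@dt)))[2] / 6
  }, numeric(1))
}

#' Render the scattered light intensity of a suspension
#'
#' Coherent sum of per-particle fields: I(t) = |sum_i a_i exp(i q . r_i(t))|^2
#' with scattering amplitude a_i proportional to d_i^3 (Rayleigh volume
#' scaling). The scattering vector magnitude comes from the optics
#' configuration; its direction is \code{q_dir}.
#'
#' @param traj a \linkS4class{ParticleTrajectorySet}.
#' @param optics a \code{ScatteringConfig} (see \code{\link{scatteringConfig}}).
#' @param q_dir unit direction of the scattering vector.
#' @param amplitude_scale overall intensity scale factor.
#' @return An \linkS4class{IntensityTrace} sampled at the trajectory dt.
#' @export
renderScatteredIntensity <- function(traj, optics, q_dir = c(0, 0, 1),
                                     amplitude_scale = 1) {
  stopifnot(is(traj, "ParticleTrajectorySet"))
  if (dim(traj@positions)[2] == 0L) stop("empty trajectory set")
  q <- scatteringVector(optics)
  qv <- q * q_dir / sqrt(sum(q_dir^2))
  a <- amplitude_scale * (traj@diameter_nm / max(traj@diameter_nm))^3
  pos <- traj@positions
  n_t <- dim(pos)[1]
  field <- complex(real = numeric(n_t), imaginary = numeric(n_t))
  for (i in seq_along(a)) {
    phase <- pos[, i, 1] * qv[1] + pos[, i, 2] * qv[2] + pos[, i, 3] * qv[3]
    field <- field + a[i] * exp(1i * phase)
  }
  IntensityTrace(Mod(field)^2, dt = traj@dt, unit = "counts",
                 origin = "renderScatteredIntensity")
}
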