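#' @include AllClasses.R constants.R
NULL

#' ScatteringConfig: DLS optics and solvent conditions
#'
#' @slot n0 solvent refractive index.
#' @slot lambda0 laser vacuum wavelength (m).
#' @slot theta_deg scattering angle (degrees).
#' @slot temperature temperature (K).
#' @slot viscosity dynamic viscosity (Pa s).
#' @export
setClass("ScatteringConfig",
  representation(n0 = "numeric", lambda0 = "numeric", theta_deg = "numeric",
                 temperature = "numeric", viscosity = "numeric"))

setValidity("ScatteringConfig", function(object) {
  msg <- character()
  if (object@theta_deg <= 0 || object@theta_deg > 180)
    msg <- c(msg, "theta must be in (0, 180]")
  if (any(c(object@n0, object@lambda0, object@temperature,
            object@viscosity) <= 0))
    msg <- c(msg, "n0, lambda0, temperature, viscosity must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a ScatteringConfig
#'
#' Defaults are a 632.8 nm laser observed at 173 degrees (backscattering) in
#' water at 298.15 K with refractive index 1.330 and viscosity
#' 0.8872 mPa s.
#'
#' @param n0 refractive index.
#' @param lambda0 vacuum wavelength (m).
#' @param theta_deg scattering angle (degrees).
#' @param temperature temperature (K).
#' @param viscosity dynamic viscosity (Pa s).
#' @return A \linkS4class{ScatteringConfig}.
#' @export
scatteringConfig <- function(n0 = 1.330, lambda0 = 632.8e-9,
                             theta_deg = 173, temperature = 298.15,
                             viscosity = 8.872e-4) {
  new("ScatteringConfig", n0 = n0, lambda0 = lambda0, theta_deg = theta_deg,
      temperature = temperature, viscosity = viscosity)
}

#' Scattering vector magnitude
#'
#' q = (4 pi n0 / lambda0) sin(theta / 2).
#'
#' @param optics a \linkS4class{ScatteringConfig}.
#' @return q in 1/m.
#' @examples
#' scatteringVector(scatteringConfig())  # ~2.64e7 1/m
#' @export
scatteringVector <- function(optics) {
  stopifnot(is(optics, "ScatteringConfig"))
  4 * pi * optics@n0 / optics@lambda0 * sin(optics@theta_deg * pi / 360)
}

.curve_g2 <- function(curve) {
  if (curve@normalization == "g2") curve@g else curve@g + 1
}

#' Single-exponential fit of a DLS correlation curve
#'
#' Least-squares fit of G(tau) = 1 + b exp(-2 D q^2 tau); the hydrodynamic
#' radius follows from the Stokes-Einstein relation
#' D = kB T / (6 pi eta R_h) and the reported size is the hydrodynamic
#' diameter d_h = 2 R_h. The amplitude b absorbs the instrument coherence
#' factor.
#'
#' @param curve a \linkS4class{CorrelationCurve} spanning the decay
#'   (>= 10 lags).
#' @param optics a \linkS4class{ScatteringConfig}.
#' @return A \linkS4class{DlsFit}. A non-decaying curve yields an error
#'   rather than silent defaults.
#' @export
fitSingleExponential <- function(curve, optics) {
  stopifnot(is(curve, "CorrelationCurve"))
  if (length(curve@lag) < 10) stop("need >= 10 lags spanning the decay")
  q <- scatteringVector(optics)
  tau <- curve@lag
  y <- .curve_g2(curve) - 1
  b0 <- max(y)
  if (b0 <= 0 || y[1] <= utils::tail(y, 1) + 1e-12 * abs(b0))
    stop("fit failure: correlation curve does not decay")
  # initialize decay rate from the lag where the curve falls to b/e
  idx <- which(y < b0 / exp(1))[1]
  gamma0 <- if (is.na(idx)) 1 / max(tau) else 1 / tau[idx]
  fit <- minpack.lm::nls.lm(
    par = c(lb = log(b0), lg = log(gamma0)),
    fn = function(p) y - exp(p["lb"]) * exp(-exp(p["lg"]) * tau),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  b <- exp(fit$par[["lb"]]); gamma <- exp(fit$par[["lg"]])
  if (!is.finite(gamma) || !is.finite(b))
    stop("fit failure: non-physical parameters (non-decaying curve)")
  D <- gamma / (2 * q^2)
  R_h <- .kB * optics@temperature / (6 * pi * optics@viscosity * D)
  new("DlsFit", b = b, D = D, R_h = R_h, d_h = 2 * R_h,
      residual = sqrt(mean(fit$fvec^2)),
      slow_mode_fraction = NA_real_, slow_mode_flag = FALSE,
      converged = fit$info %in% 1:4)
}

#' Two-component fit and slow-mode detection
#'
#' Fits G(tau) = 1 + b1 exp(-2 D1 q^2 tau) + b2 exp(-2 D2 q^2 tau) and
#' reports the amplitude share of the slower component. The slow-mode flag is
#' raised when that share exceeds \code{fraction_threshold} and the
#' diffusion coefficients are separated by more than \code{ratio_threshold}.
#' Degenerate fits (components within a factor 2) collapse to the
#' single-component result, flagged by \code{slow_mode_fraction = 0}.
#'
#' @param curve a \linkS4class{CorrelationCurve}.
#' @param optics a \linkS4class{ScatteringConfig}.
#' @param fraction_threshold minimum slow amplitude share (default 0.1).
#' @param ratio_threshold minimum D_fast / D_slow separation (default 10).
#' @return A \linkS4class{DlsFit} with two components (fast first) or the
#'   collapsed single-component fit.
#' @export
detectSlowMode <- function(curve, optics, fraction_threshold = 0.1,
                           ratio_threshold = 10) {
  stopifnot(is(curve, "CorrelationCurve"))
  q <- scatteringVector(optics)
  tau <- curve@lag
  y <- .curve_g2(curve) - 1
  single <- fitSingleExponential(curve, optics)
  g1 <- 2 * single@D * q^2
  model <- function(p) {
    # p = (log b1, log g1, log b2, log g2)
    exp(p[1]) * exp(-exp(p[2]) * tau) + exp(p[3]) * exp(-exp(p[4]) * tau)
  }
  start <- c(log(single@b / 2), log(g1 * 3), log(single@b / 2), log(g1 / 30))
  fit <- minpack.lm::nls.lm(par = start, fn = function(p) y - model(p),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- fit$par
  b <- exp(p[c(1, 3)]); gam <- exp(p[c(2, 4)])
  ord <- order(gam, decreasing = TRUE)  # fast first
  b <- b[ord]; gam <- gam[ord]
  if (gam[1] / gam[2] < 2) {
    out <- single
    out@slow_mode_fraction <- 0
    out@slow_mode_flag <- FALSE
    return(out)
  }
  D <- gam / (2 * q^2)
  R_h <- .kB * optics@temperature / (6 * pi * optics@viscosity * D)
  frac <- b[2] / sum(b)
  new("DlsFit", b = b, D = D, R_h = R_h, d_h = 2 * R_h,
      residual = sqrt(mean(fit$fvec^2)),
      slow_mode_fraction = frac,
      slow_mode_flag = frac > fraction_threshold &&
        D[1] / D[2] > ratio_threshold,
      converged = fit$info %in% 1:4)
}

# second-difference matrix for Tikhonov smoothing
.second_diff <- function(n) {
  if (n < 3) return(matrix(0, 0, n))
  L <- matrix(0, n - 2, n)
  for (i in seq_len(n - 2)) L[i, i:(i + 2)] <- c(1, -2, 1)
  L
}

#' Regularized inversion of a correlation curve into a size distribution
#'
#' First-order model: sqrt(G(tau) - 1) = sum_i w_i exp(-D_i q^2 tau) over a
#' diameter grid, solved by nonnegative least squares with second-difference
#' smoothing. The smoothing weight is chosen by an L-curve corner search
#' over a log-spaced lambda grid (override with \code{lambda}). Weights are
#' normalized to sum to 1.
#'
#' @param curve a \linkS4class{CorrelationCurve}.
#' @param optics a \linkS4class{ScatteringConfig}.
#' @param grid_nm diameter grid (nm); default 40 log-spaced bins spanning
#'   10-2000 nm.
#' @param lambda optional fixed smoothing weight.
#' @return A \linkS4class{SizeDistribution} with intensity weighting.
#' @export
sizeDistribution <- function(curve, optics,
                             grid_nm = exp(seq(log(10), log(2000),
                                               length.out = 40)),
                             lambda = NULL) {
  stopifnot(is(curve, "CorrelationCurve"))
  q <- scatteringVector(optics)
  tau <- curve@lag
  y <- sqrt(pmax(.curve_g2(curve) - 1, 0))
  D <- diffusionCoefficient(grid_nm, optics@temperature, optics@viscosity)
  A <- exp(-outer(tau, D * q^2))
  L <- .second_diff(length(grid_nm))
  solve_one <- function(lam) {
    Aa <- rbind(A, lam * L)
    ya <- c(y, rep(0, nrow(L)))
    w <- pracma::lsqnonneg(Aa, ya)$x
    list(w = w, res = sqrt(sum((A %*% w - y)^2)),
         pen = sqrt(sum((L %*% w)^2)))
  }
  if (is.null(lambda)) {
    lams <- 10^seq(-4, 1, length.out = 12)
    sols <- lapply(lams, solve_one)
    lr <- log10(pmax(vapply(sols, `[[`, numeric(1), "res"), 1e-12))
    lp <- log10(pmax(vapply(sols, `[[`, numeric(1), "pen"), 1e-12))
    # L-curve corner: maximum curvature of (lr, lp)
    k <- length(lams)
    curv <- rep(-Inf, k)
    for (i in 2:(k - 1)) {
      v1 <- c(lr[i] - lr[i - 1], lp[i] - lp[i - 1])
      v2 <- c(lr[i + 1] - lr[i], lp[i + 1] - lp[i])
      ang <- atan2(v2[2], v2[1]) - atan2(v1[2], v1[1])
      curv[i] <- abs(ang)
    }
    sol <- sols[[which.max(curv)]]
  } else sol <- solve_one(lambda)
  w <- sol$w
  if (sum(w) <= 0) stop("all-zero solution: curve carries no decay")
  SizeDistribution(diameter_nm = grid_nm, weight = w / sum(w),
                   weighting = "intensity")
}

#' Derived count rate
#'
#' Rescales a measured scattering count rate to 100% laser power and zero
#' attenuation: measured rate divided by the transmitted fraction.
#'
#' @param measured_khz measured count rate (kHz).
#' @param attenuation fraction of laser power transmitted, in (0, 1].
#' @return derived count rate (kHz).
#' @examples
#' derivedCountRate(50, 0.25)  # 200 kHz
#' @export
derivedCountRate <- function(measured_khz, attenuation) {
  if (any(attenuation <= 0) || any(attenuation > 1))
    stop("attenuation must be in (0, 1]")
  measured_khz / attenuation
}
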