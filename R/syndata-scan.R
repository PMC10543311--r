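#' @include AllClasses.R constants.R
NULL

#' Simulate microfluidic confocal scan traces
#'
#' Emulates an MCS survey: one intensity trace per scan location, locations
#' split evenly over the device's channel groups. Each trace is a Poisson
#' baseline; cluster transits add localized peaks. The per-trace transit
#' count is Poisson with the mean implied by the true cluster concentration,
#' inverted through the flux and concentration relations (see
#' \code{\link{clusterFlux}} and \code{\link{clusterConcentration}}).
#'
#' @param concentration_M true cluster concentration (mol/L), >= 0.
#' @param geometry an \code{McsGeometry} from \code{\link{mcsGeometry}}.
#' @param baseline_khz baseline count rate (kHz).
#' @param peak_meanlog,peak_sdlog lognormal parameters of the peak amplitude
#'   (kHz above baseline).
#' @param peak_width_bins Gaussian 1-sigma transit width in bins.
#' @param bin_s trace bin width (s).
#' @param seed RNG seed.
#' @return A \linkS4class{ScanSet}; \code{meta} echoes the configuration and
#'   the implied mean transit count per trace.
#' @export
simulateScanTraces <- function(concentration_M, geometry = mcsGeometry(),
                               baseline_khz = 10, peak_meanlog = log(500),
                               peak_sdlog = 0.5, peak_width_bins = 1.5,
                               bin_s = 1e-3, seed = NULL) {
  if (concentration_M < 0) stop("concentration must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  g <- geometry
  # mean transits per trace implied by c: c -> F -> nbar
  F_total <- concentration_M * .NA * g$Q_sample_uLh * 1e-6 / 3600
  lambda <- F_total * g$t_s * (pi / 4) * g$z_um * g$w_um /
    (g$h_um * g$d_step_um)
  n_bins <- round(g$t_s / bin_s)
  groups <- rep(seq_len(g$n_groups), each = g$n_locations / g$n_groups)
  base_mean <- baseline_khz * 1e3 * bin_s
  traces <- lapply(seq_len(g$n_locations), function(i) {
    vals <- stats::rpois(n_bins, base_mean)
    k <- stats::rpois(1, lambda)
    if (k > 0) {
      centers <- stats::runif(k, 1, n_bins)
      amps <- stats::rlnorm(k, peak_meanlog, peak_sdlog)  # kHz
      for (j in seq_len(k)) {
        span <- max(1L, ceiling(4 * peak_width_bins))
        bins <- max(1L, floor(centers[j]) - span):min(n_bins, floor(centers[j]) + span)
        shape <- exp(-(bins - centers[j])^2 / (2 * peak_width_bins^2))
        vals[bins] <- vals[bins] +
          stats::rpois(length(bins), amps[j] * 1e3 * bin_s * shape)
      }
    }
    IntensityTrace(vals, dt = bin_s, unit = "counts", origin = "simulateScanTraces")
  })
  ScanSet(traces = traces, group = groups,
          meta = list(concentration_M = concentration_M, lambda = lambda,
                      geometry = g, baseline_khz = baseline_khz,
                      bin_s = bin_s, seed = seed))
}

#' Simulate a spin-down dilution series
#'
#' Supernatant concentration after pelleting the dense phase:
#' min(total, csat) plus Gaussian noise, floored at zero.
#'
#' @param csat_true true saturation concentration (same unit as totals).
#' @param totals vector of total concentrations, positive.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed RNG seed.
#' @param buffer free-text buffer label.
#' @return data.frame with columns \code{total_uM}, \code{supernatant_uM};
#'   attributes \code{csat_true} and \code{buffer}.
#' @export
simulateSpindownSeries <- function(csat_true, totals, noise_sd = 0,
                                   seed = NULL, buffer = "") {
  if (any(totals <= 0)) stop("totals must be positive")
  if (!is.null(seed)) set.seed(seed)
  sup <- pmax(0, pmin(totals, csat_true) +
                stats::rnorm(length(totals), sd = noise_sd))
  out <- data.frame(total_uM = totals, supernatant_uM = sup)
  attr(out, "csat_true") <- csat_true
  attr(out, "buffer") <- buffer
  out
}
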