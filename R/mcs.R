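#' @include AllClasses.R constants.R
NULL

#' Microfluidic confocal spectroscopy geometry
#'
#' Defaults are the measurement settings of the scanning assay: 4 s traces,
#' 28 um channel height, 5.64 um step width, a confocal spot of 3 um height
#' and 0.4 um width, 15 uL/h sample flow, and 200 evenly spaced locations
#' over the four central channels.
#'
#' @param t_s collection time per trace (s).
#' @param h_um channel height (um).
#' @param d_step_um scan step width (um).
#' @param z_um confocal spot height (um).
#' @param w_um confocal spot width (um).
#' @param Q_sample_uLh sample flow rate (uL/h).
#' @param n_locations number of scan locations.
#' @param n_groups number of channel groups (must divide n_locations).
#' @return list of class \code{McsGeometry}.
#' @export
mcsGeometry <- function(t_s = 4, h_um = 28, d_step_um = 5.64, z_um = 3,
                        w_um = 0.4, Q_sample_uLh = 15, n_locations = 200L,
                        n_groups = 4L) {
  vals <- c(t_s, h_um, d_step_um, z_um, w_um, Q_sample_uLh, n_locations,
            n_groups)
  if (any(vals <= 0)) stop("all geometry parameters must be positive")
  if (n_locations %% n_groups != 0)
    stop("n_locations must be divisible by n_groups")
  structure(list(t_s = t_s, h_um = h_um, d_step_um = d_step_um, z_um = z_um,
                 w_um = w_um, Q_sample_uLh = Q_sample_uLh,
                 n_locations = as.integer(n_locations),
                 n_groups = as.integer(n_groups)),
            class = "McsGeometry")
}

#' Count cluster transit peaks in a scan trace
#'
#' Peaks are maximal runs of samples exceeding \code{k_sigma} standard
#' deviations above the mean trace intensity, each run counted once.
#' Baseline mean and sigma come from iterative sigma-clipping (3 rounds at
#' 3 sigma) so the peaks themselves do not inflate the threshold.
#'
#' @param trace an \linkS4class{IntensityTrace}.
#' @param k_sigma threshold in baseline sigmas (default 5).
#' @return integer peak count. A zero-variance trace yields 0 with a
#'   warning.
#' @export
detectClusterPeaks <- function(trace, k_sigma = 5) {
  stopifnot(is(trace, "IntensityTrace"))
  v <- trace@values
  if (!length(v)) stop("empty trace")
  if (stats::sd(v) == 0) {
    warning("zero-variance trace: no peaks detectable")
    return(0L)
  }
  bg <- .clipped_background(v)
  thr <- bg$mean + k_sigma * bg$sd
  supra <- v > thr
  r <- rle(supra)
  sum(r$values)
}

#' Average cluster count over channel groups
#'
#' Per-trace peak counts are averaged within each channel group, then the
#' group means are averaged with equal weight (independent of group sizes).
#'
#' @param scan a \linkS4class{ScanSet}.
#' @param k_sigma peak threshold passed to \code{\link{detectClusterPeaks}}.
#' @return mean cluster count n-bar.
#' @export
meanClusterCount <- function(scan, k_sigma = 5) {
  stopifnot(is(scan, "ScanSet"))
  counts <- vapply(scan@traces, detectClusterPeaks, integer(1),
                   k_sigma = k_sigma)
  gm <- tapply(counts, scan@group, mean)
  if (any(is.na(gm)) || !length(gm)) stop("empty trace group")
  mean(gm)
}

#' Cluster flux from the mean transit count
#'
#' F_total = n-bar h d_step / (t (pi/4) z w): the confocal spot
#' cross-section (pi/4) z w samples a fraction of the per-step channel
#' cross-section h d_step, so the mean transit count per trace scales up to
#' the flux of clusters through the channel.
#'
#' @param nbar mean cluster count per trace.
#' @param geometry an \code{McsGeometry}.
#' @return flux in clusters/s.
#' @examples
#' clusterFlux(2, mcsGeometry())  # ~83.8 1/s
#' @export
clusterFlux <- function(nbar, geometry = mcsGeometry()) {
  stopifnot(inherits(geometry, "McsGeometry"))
  g <- geometry
  nbar * (g$h_um * g$d_step_um) / (g$t_s * (pi / 4) * g$z_um * g$w_um)
}

#' Cluster concentration from the flux
#'
#' c_cluster = F_total / (N_A Q_sample), with the flow rate converted to
#' L/s.
#'
#' @param F_total cluster flux (1/s).
#' @param geometry an \code{McsGeometry}.
#' @return concentration in mol/L.
#' @examples
#' clusterConcentration(clusterFlux(2), mcsGeometry())  # ~3.3e-14 M
#' @export
clusterConcentration <- function(F_total, geometry = mcsGeometry()) {
  stopifnot(inherits(geometry, "McsGeometry"))
  Q_Ls <- geometry$Q_sample_uLh * 1e-6 / 3600
  F_total / (.NA * Q_Ls)
}

#' End-to-end cluster concentration estimate from a scan set
#'
#' Convenience wrapper: peak counting, group averaging, flux and
#' concentration in one call.
#'
#' @param scan a \linkS4class{ScanSet}.
#' @param geometry an \code{McsGeometry}; defaults to the geometry stored in
#'   the scan metadata when present.
#' @param k_sigma peak threshold.
#' @return list with \code{nbar}, \code{F_total}, \code{c_cluster_M}.
#' @export
estimateClusterConcentration <- function(scan, geometry = NULL, k_sigma = 5) {
  if (is.null(geometry))
    geometry <- if (!is.null(scan@meta$geometry)) scan@meta$geometry else
      mcsGeometry()
  nbar <- meanClusterCount(scan, k_sigma = k_sigma)
  F_total <- clusterFlux(nbar, geometry)
  list(nbar = nbar, F_total = F_total,
       c_cluster_M = clusterConcentration(F_total, geometry))
}

#' Dilute-phase concentration from the trace intensity mode
#'
#' The dilute-phase (baseline) intensity dominates the intensity histogram
#' because the dilute-phase volume fraction far exceeds that of the dense
#' phase; the baseline mode of the kernel-smoothed intensity histogram,
#' divided by a calibration factor, gives the dilute-phase (saturation)
#' concentration. Sparse bright transits are ignored by construction.
#'
#' @param trace an \linkS4class{IntensityTrace}.
#' @param calibration_khz_per_uM detector calibration (kHz per uM), > 0.
#' @param min_baseline_fraction minimum fraction of samples at or below
#'   twice the located mode for it to count as a stable baseline
#'   (default 0.8).
#' @return concentration estimate in uM, with the located mode (kHz) in
#'   \code{attr(, "mode_khz")}.
#' @export
dilutePhaseConcentration <- function(trace, calibration_khz_per_uM,
                                     min_baseline_fraction = 0.8) {
  stopifnot(is(trace, "IntensityTrace"))
  if (calibration_khz_per_uM <= 0) stop("calibration must be positive")
  khz <- if (trace@unit == "kHz") trace@values else
    trace@values / trace@dt / 1e3
  if (stats::sd(khz) == 0) {
    mode_khz <- khz[1]
  } else {
    d <- stats::density(khz, n = 1024)
    mode_khz <- d$x[which.max(d$y)]
  }
  frac <- mean(khz <= 2 * mode_khz + 1e-12)
  if (frac < min_baseline_fraction)
    stop("no stable baseline: intensity histogram is tail-dominated")
  out <- mode_khz / calibration_khz_per_uM
  attr(out, "mode_khz") <- mode_khz
  out
}
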