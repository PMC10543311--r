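#' @include AllClasses.R
NULL

# sigma-clipped mean/sd of binned counts: 3 rounds of 3-sigma clipping
.clipped_background <- function(counts, n_rounds = 3, clip_sigma = 3) {
  keep <- rep(TRUE, length(counts))
  for (i in seq_len(n_rounds)) {
    m <- mean(counts[keep]); s <- stats::sd(counts[keep])
    if (!is.finite(s) || s == 0) break
    keep <- counts <= m + clip_sigma * s
    if (all(!keep)) break
  }
  list(mean = mean(counts[keep]), sd = max(stats::sd(counts[keep]), 0),
       keep = keep)
}

#' Select single-molecule bursts from a photon stream
#'
#' The macrotime trace is binned; background mean and sigma are estimated by
#' iterative sigma-clipping of the binned counts; bursts are maximal runs of
#' contiguous bins whose counts exceed mean + \code{threshold_sigma} sigma.
#' Adjacent supra-threshold runs separated by at most \code{gap_bins}
#' sub-threshold bins are merged. Bursts with fewer than \code{min_photons}
#' photons are discarded, as are bursts above \code{max_photons} when set.
#'
#' @param stream a \linkS4class{PhotonStream}.
#' @param bin_ms bin width (ms).
#' @param threshold_sigma threshold in background sigmas above the mean
#'   (default 2).
#' @param min_photons minimum photons per burst (default 10).
#' @param max_photons maximum photons per burst (default 3000; \code{Inf}
#'   disables).
#' @param gap_bins merge runs separated by at most this many sub-threshold
#'   bins (default 1).
#' @return data.frame with one row per burst: \code{start_s, end_s,
#'   duration_ms, n_photons, rate_khz}; \code{attr(, "photon_idx")} holds the
#'   photon index vectors and \code{attr(, "background")} the background
#'   estimate (mean and sd in counts per bin).
#' @export
selectBursts <- function(stream, bin_ms = 1, threshold_sigma = 2,
                         min_photons = 10, max_photons = 3000,
                         gap_bins = 1L) {
  stopifnot(is(stream, "PhotonStream"))
  if (is.finite(max_photons) && min_photons >= max_photons)
    stop("min_photons must be below max_photons")
  bin_s <- bin_ms * 1e-3
  if (stream@duration_s < 10 * bin_s)
    stop("stream duration must greatly exceed the bin width")
  nb <- ceiling(stream@duration_s / bin_s)
  bin_of <- pmin(floor(stream@macrotime / bin_s) + 1L, nb)
  counts <- tabulate(bin_of, nbins = nb)
  bg <- .clipped_background(counts)
  thr <- bg$mean + threshold_sigma * bg$sd
  supra <- counts > thr
  if (all(supra)) stop("no background separable: all bins above threshold")
  # merge supra runs separated by <= gap_bins sub-threshold bins
  rr <- rle(supra)
  if (gap_bins > 0L && length(rr$lengths) > 2L) {
    inner <- seq_along(rr$values)[-c(1, length(rr$values))]
    fill <- inner[!rr$values[inner] & rr$lengths[inner] <= gap_bins]
    rr$values[fill] <- TRUE
  }
  rr <- rle(rep(rr$values, rr$lengths))
  ends <- cumsum(rr$lengths)
  starts <- ends - rr$lengths + 1L
  bursts <- which(rr$values)
  rows <- list(); idx_list <- list()
  for (bi in bursts) {
    b0 <- starts[bi]; b1 <- ends[bi]
    ph <- which(bin_of >= b0 & bin_of <= b1)
    np <- length(ph)
    if (np < min_photons || np > max_photons) next
    dur_s <- (b1 - b0 + 1L) * bin_s
    rows[[length(rows) + 1L]] <- data.frame(
      start_s = (b0 - 1L) * bin_s, end_s = b1 * bin_s,
      duration_ms = dur_s * 1e3, n_photons = np,
      rate_khz = np / dur_s / 1e3)
    idx_list[[length(idx_list) + 1L]] <- ph
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start_s = numeric(0), end_s = numeric(0),
               duration_ms = numeric(0), n_photons = integer(0),
               rate_khz = numeric(0))
  attr(out, "photon_idx") <- idx_list
  attr(out, "background") <- list(mean = bg$mean, sd = bg$sd,
                                  bin_ms = bin_ms)
  out
}

#' Maximum-likelihood mono-exponential fluorescence lifetime
#'
#' Fits microtimes with a mono-exponential decay wrapped into the
#' observation window (equivalently, a truncated renormalized exponential)
#' plus a uniform background fraction. Returns the MLE of the lifetime and
#' its Fisher standard error. For a mono-exponential decay this MLE is the
#' fluorescence-weighted average lifetime.
#'
#' @param microtimes_ns photon microtimes (ns) within the window.
#' @param window_ns observation window width (ns), e.g. the excitation
#'   period or the donor half of a PIE period.
#' @param background_fraction known fraction of uniform background photons
#'   in [0, 1).
#' @param offset_ns instrument-response offset subtracted from microtimes.
#' @param tau_range_ns search interval for the lifetime (ns).
#' @return list with \code{tau_ns} and \code{se_ns}.
#' @export
fitBurstLifetime <- function(microtimes_ns, window_ns,
                             background_fraction = 0, offset_ns = 0,
                             tau_range_ns = c(0.05, 100)) {
  t <- (microtimes_ns - offset_ns) %% window_ns
  if (length(t) < 2 || stats::sd(t) == 0)
    stop("degenerate microtimes: lifetime not identifiable")
  if (background_fraction < 0 || background_fraction >= 1)
    stop("background_fraction must be in [0, 1)")
  W <- window_ns
  b <- background_fraction
  nll <- function(tau) {
    f <- (1 - b) * exp(-t / tau) / (tau * (1 - exp(-W / tau))) + b / W
    -sum(log(pmax(f, 1e-300)))
  }
  opt <- stats::optimize(nll, interval = tau_range_ns)
  tau <- opt$minimum
  # Fisher standard error from the numeric curvature of the log-likelihood
  h <- max(1e-4, tau * 1e-3)
  d2 <- (nll(tau + h) - 2 * nll(tau) + nll(tau - h)) / h^2
  se <- if (is.finite(d2) && d2 > 0) 1 / sqrt(d2) else NA_real_
  list(tau_ns = tau, se_ns = se)
}

#' Combined polarization-corrected signal
#'
#' Total signal from parallel and perpendicular detection channels,
#' S = S_par + 2 g S_perp.
#'
#' @param n_parallel,n_perpendicular photon counts (or rates).
#' @param g_factor polarization detection-efficiency correction.
#' @return combined signal.
#' @export
totalSignal <- function(n_parallel, n_perpendicular, g_factor = 1) {
  n_parallel + 2 * g_factor * n_perpendicular
}

#' Histogram of per-burst count rates
#'
#' Log-spaced histogram of burst count rates with a tail-mass statistic:
#' the fraction of bursts above \code{cutoff_khz} (bright clusters populate
#' this tail; monomer-only samples do not).
#'
#' @param bursts burst table from \code{\link{selectBursts}}.
#' @param n_bins number of log-spaced bins.
#' @param cutoff_khz count-rate cutoff for the tail mass (default 400 kHz).
#' @return list with \code{breaks_khz}, \code{counts}, \code{tail_mass}.
#' @export
burstIntensityHistogram <- function(bursts, n_bins = 30, cutoff_khz = 400) {
  if (!nrow(bursts)) stop("no bursts")
  r <- bursts$rate_khz
  lo <- min(r) * 0.999; hi <- max(r) * 1.001
  if (lo <= 0) lo <- min(r[r > 0], 1e-3) * 0.999
  breaks <- exp(seq(log(lo), log(hi), length.out = max(n_bins + 1, 2)))
  h <- graphics::hist(r, breaks = unique(c(breaks, hi)), plot = FALSE)
  list(breaks_khz = h$breaks, counts = h$counts,
       tail_mass = mean(r > cutoff_khz))
}

#' Per-burst FRET efficiency and stoichiometry
#'
#' Pulsed-interleaved-excitation bookkeeping: photons with microtime in the
#' first half of the excitation period are donor-excited, the second half
#' acceptor-excited. Per burst, E is the corrected
#' acceptor-after-donor-excitation signal over the total donor-excited
#' signal, and S the donor-excited signal over all signal. Corrections are
#' applied in order background (per-channel rates) -> crosstalk (linear
#' subtraction, coefficient \code{alpha}) -> detection-efficiency factor
#' \code{gamma_det}; defaults are ideal. Polarization channels are combined
#' with the g-factor.
#'
#' @param stream a \linkS4class{PhotonStream}.
#' @param bursts burst table from \code{\link{selectBursts}} on the same
#'   stream.
#' @param alpha crosstalk coefficient (green leakage into red).
#' @param gamma_det detection-efficiency correction factor.
#' @param bg_khz background rate per channel (kHz), scalar or length 4
#'   (Gp, Gs, Rp, Rs).
#' @param g_factor polarization g-factor.
#' @return data.frame with per-burst \code{E}, \code{S}, \code{F_D},
#'   \code{F_A}, \code{F_AA} and a \code{flagged} column marking bursts with
#'   no usable signal or E/S clipped into [0, 1].
#' @export
computeFret <- function(stream, bursts, alpha = 0, gamma_det = 1,
                        bg_khz = 0, g_factor = 1) {
  stopifnot(is(stream, "PhotonStream"))
  idx_list <- attr(bursts, "photon_idx")
  if (is.null(idx_list)) stop("bursts must carry photon indices")
  half <- stream@period_ns / 2
  bg <- rep_len(bg_khz, 4L); names(bg) <- .CHANNEL_LEVELS
  out <- lapply(seq_len(nrow(bursts)), function(i) {
    ph <- idx_list[[i]]
    chan <- stream@channel[ph]
    donor_win <- stream@microtime[ph] < half
    dur_s <- bursts$duration_ms[i] * 1e-3
    cnt <- function(sel_chan, sel_win) {
      np <- sum(chan == sel_chan[1] & sel_win)
      ns <- sum(chan == sel_chan[2] & sel_win)
      # background: uniform microtimes, half the rate falls in each window
      np_b <- bg[sel_chan[1]] * 1e3 * dur_s / 2
      ns_b <- bg[sel_chan[2]] * 1e3 * dur_s / 2
      totalSignal(np - np_b, ns - ns_b, g_factor)
    }
    F_D <- cnt(c("Gp", "Gs"), donor_win)
    F_A <- cnt(c("Rp", "Rs"), donor_win)
    F_AA <- cnt(c("Rp", "Rs"), !donor_win)
    F_A_corr <- F_A - alpha * F_D
    denom_E <- gamma_det * F_D + F_A_corr
    denom_S <- denom_E + F_AA
    if (denom_E <= 0 || denom_S <= 0)
      return(data.frame(E = NA_real_, S = NA_real_, F_D = F_D, F_A = F_A,
                        F_AA = F_AA, flagged = TRUE))
    E <- F_A_corr / denom_E
    S <- denom_E / denom_S
    clipped <- E < 0 || E > 1 || S < 0 || S > 1
    data.frame(E = min(max(E, 0), 1), S = min(max(S, 0), 1),
               F_D = F_D, F_A = F_A, F_AA = F_AA, flagged = clipped)
  })
  do.call(rbind, out)
}

#' Static and dynamic FRET lines
#'
#' Static line: E = 1 - tau_f / tau0 (single species of lifetime tau_f,
#' donor-only reference lifetime tau0). Dynamic line for two interconverting
#' states with lifetimes tau1, tau2: a parametric curve over the species
#' fraction x, with the burst-averaged fluorescence-weighted lifetime
#' tau_f = (x tau1^2 + (1-x) tau2^2) / (x tau1 + (1-x) tau2) and the
#' species-averaged efficiency E = 1 - (x tau1 + (1-x) tau2) / tau0. Since
#' tau_f exceeds the species-averaged lifetime, the dynamic line lies at or
#' above the static line.
#'
#' @param tau0_ns donor-only lifetime (ns), > 0.
#' @param states optional two state lifetimes c(tau1, tau2) in ns.
#' @param n_points points along the dynamic line.
#' @return list with \code{static} (function of tau_f), and when two states
#'   are given \code{dynamic} (data.frame x, tau_f_ns, E) plus
#'   \code{degenerate} (TRUE when tau1 == tau2, line collapses to a point).
#' @export
fretLines <- function(tau0_ns, states = NULL, n_points = 101) {
  if (tau0_ns <= 0) stop("tau0 must be positive")
  out <- list(static = function(tau_f_ns) 1 - tau_f_ns / tau0_ns)
  if (!is.null(states)) {
    stopifnot(length(states) == 2, all(states > 0))
    t1 <- states[1]; t2 <- states[2]
    x <- seq(0, 1, length.out = n_points)
    tau_f <- (x * t1^2 + (1 - x) * t2^2) / (x * t1 + (1 - x) * t2)
    E <- 1 - (x * t1 + (1 - x) * t2) / tau0_ns
    out$dynamic <- data.frame(x = x, tau_f_ns = tau_f, E = E)
    out$degenerate <- isTRUE(all.equal(t1, t2))
    if (out$degenerate)
      warning("equal state lifetimes: dynamic line degenerates to a point")
  }
  out
}
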