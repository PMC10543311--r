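#' @include AllClasses.R
NULL

# g2 at a single integer lag; symmetric normalization divides by the means of
# the head and tail segments actually entering the product (reduces tail bias),
# plain normalization divides by the squared global mean.
.g2_at_lag <- function(x, k, symmetric = TRUE) {
  n <- length(x)
  h <- x[seq_len(n - k)]
  t <- x[seq.int(k + 1L, n)]
  num <- mean(h * t)
  den <- if (symmetric) mean(h) * mean(t) else mean(x)^2
  if (den == 0) return(NA_real_)
  num / den
}

#' Direct (exact) intensity autocorrelation
#'
#' Computes the normalized second-order autocorrelation
#' g2(tau) = <I(t) I(t+tau)> / <I>^2 at every integer lag up to
#' \code{max_lag}, using the exact (non-approximate) estimator.
#'
#' @param trace an \linkS4class{IntensityTrace}.
#' @param max_lag largest lag in seconds; must be below half the trace length.
#' @param symmetric use symmetric normalization (default TRUE); set FALSE for
#'   plain normalization by the global mean squared.
#' @return A \linkS4class{CorrelationCurve} with normalization \code{"g2"}.
#' @examples
#' tr <- IntensityTrace(rep(5, 100), dt = 1e-3)
#' correlateDirect(tr, max_lag = 1e-2)  # constant trace: g2 == 1
#' @export
correlateDirect <- function(trace, max_lag, symmetric = TRUE) {
  stopifnot(is(trace, "IntensityTrace"))
  dt <- trace@dt
  n <- length(trace@values)
  kmax <- floor(max_lag / dt + 1e-9)
  if (kmax < 1) stop("max_lag below one sample interval")
  if (n <= 2L * kmax)
    stop("trace too short: need length > 2 * max_lag / interval")
  g <- vapply(seq_len(kmax), function(k)
    .g2_at_lag(trace@values, k, symmetric), numeric(1))
  CorrelationCurve(lag = dt * seq_len(kmax), g = g, normalization = "g2")
}

.multitau_on_values <- function(x, dt, m, levels, max_lag, symmetric) {
  lags_s <- numeric(0); g <- numeric(0)
  lev <- 0L
  cur <- x; cur_dt <- dt
  repeat {
    ks <- if (lev == 0L) seq_len(m) else seq.int(m / 2L + 1L, m)
    ks <- ks[ks * cur_dt <= max_lag & ks < length(cur) / 2]
    if (!length(ks)) break
    g <- c(g, vapply(ks, function(k) .g2_at_lag(cur, k, symmetric), numeric(1)))
    lags_s <- c(lags_s, ks * cur_dt)
    lev <- lev + 1L
    if (lev >= levels) break
    nhalf <- floor(length(cur) / 2L)
    if (nhalf < 2L * m) break
    cur <- (cur[2L * seq_len(nhalf) - 1L] + cur[2L * seq_len(nhalf)]) / 2
    cur_dt <- cur_dt * 2
  }
  list(lag = lags_s, g = g)
}

#' Multi-tau autocorrelation on a quasi-logarithmic lag grid
#'
#' Standard multi-tau estimator: \code{m} linear lags per level, trace
#' coarse-grained by pairwise averaging (factor 2) between levels. Photon
#' streams are binned at \code{bin_s} before correlation. Agrees with
#' \code{\link{correlateDirect}} on overlapping lags within binning error.
#'
#' @param x an \linkS4class{IntensityTrace} or \linkS4class{PhotonStream}.
#' @param m points per level, even, >= 8 (default 16).
#' @param levels maximum number of levels (default 30, i.e. effectively
#'   limited by trace length).
#' @param bin_s bin width (s) used to bin photon streams (default 1e-6).
#' @param max_lag largest lag (s); defaults to a quarter of the record.
#' @param symmetric symmetric normalization flag (default TRUE).
#' @param n_blocks when > 0, the record is split into this many contiguous
#'   blocks and per-lag standard errors are estimated from the block-to-block
#'   scatter of the correlation.
#' @param channels for photon streams, an optional subset of channels
#'   (e.g. \code{c("Gp", "Gs")} for the donor autocorrelation).
#' @return A \linkS4class{CorrelationCurve}.
#' @export
correlateMultiTau <- function(x, m = 16L, levels = 30L, bin_s = 1e-6,
                              max_lag = NULL, symmetric = TRUE,
                              n_blocks = 0L, channels = NULL) {
  if (m %% 2L != 0L || m < 8L) stop("m must be even and >= 8")
  if (is(x, "PhotonStream")) {
    if (length(x@macrotime) == 0L) stop("empty photon stream")
    tt <- x@macrotime
    if (!is.null(channels)) tt <- tt[x@channel %in% channels]
    if (length(tt) == 0L) stop("no photons in requested channels")
    nb <- ceiling(x@duration_s / bin_s)
    vals <- tabulate(pmin(floor(tt / bin_s) + 1L, nb), nbins = nb)
    dt <- bin_s
  } else if (is(x, "IntensityTrace")) {
    if (length(x@values) == 0L) stop("empty trace")
    vals <- x@values
    dt <- x@dt
  } else stop("x must be an IntensityTrace or PhotonStream")
  if (is.null(max_lag)) max_lag <- length(vals) * dt / 4
  res <- .multitau_on_values(vals, dt, as.integer(m), as.integer(levels),
                             max_lag, symmetric)
  sigma <- NULL
  if (n_blocks > 1L) {
    nb <- as.integer(n_blocks)
    splits <- split(vals, cut(seq_along(vals), nb, labels = FALSE))
    per <- lapply(splits, function(v)
      .multitau_on_values(v, dt, as.integer(m), as.integer(levels),
                          max_lag, symmetric))
    sigma <- vapply(seq_along(res$lag), function(i) {
      vv <- vapply(per, function(p) {
        j <- match(res$lag[i], p$lag)
        if (is.na(j)) NA_real_ else p$g[j]
      }, numeric(1))
      vv <- vv[is.finite(vv)]
      if (length(vv) >= 3) stats::sd(vv) / sqrt(length(vv)) else NA_real_
    }, numeric(1))
    # lags too long for a block: reuse the largest available block error
    if (any(is.na(sigma)) && any(!is.na(sigma)))
      sigma[is.na(sigma)] <- max(sigma, na.rm = TRUE)
  }
  CorrelationCurve(lag = res$lag, g = res$g, sigma = sigma,
                   normalization = "g2")
}
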