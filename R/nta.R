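#' @include AllClasses.R constants.R
NULL

#' Link particle localizations into trajectories
#'
#' Greedy nearest-neighbour frame-to-frame assignment: candidate links are
#' taken in order of increasing displacement (ties broken by lowest track
#' id), so no two tracks ever share a localization; gaps of up to
#' \code{memory} missed frames are bridged. Input row order is irrelevant
#' (rows are sorted internally).
#'
#' @param locs data.frame with columns \code{frame} (0-based), \code{x_um},
#'   \code{y_um}.
#' @param max_disp_um maximum frame-to-frame displacement (um), > 0.
#' @param memory number of consecutive missed frames a track may survive.
#' @param fps frame rate (1/s), stored on each track.
#' @param min_track_length tracks shorter than this are dropped.
#' @return list of track data.frames (\code{frame, x_um, y_um, row}) where
#'   \code{row} indexes the localization in the sorted input; each carries
#'   \code{attr(, "fps")}. Empty input gives an empty list.
#' @export
linkTrajectories <- function(locs, max_disp_um, memory = 0L, fps = 30,
                             min_track_length = 10L) {
  if (max_disp_um <= 0) stop("max_disp_um must be positive")
  if (!nrow(locs)) return(list())
  ord <- order(locs$frame, locs$x_um, locs$y_um)
  locs <- locs[ord, , drop = FALSE]
  locs$.row <- seq_len(nrow(locs))
  frames <- sort(unique(locs$frame))
  tracks <- list()           # each: list(rows, last_xy, last_frame)
  active <- integer(0)
  for (f in frames) {
    det <- locs[locs$frame == f, , drop = FALSE]
    nd <- nrow(det)
    assigned_det <- rep(FALSE, nd)
    if (length(active) && nd) {
      keep <- vapply(active, function(ti)
        f - tracks[[ti]]$last_frame <= memory + 1L, logical(1))
      cand <- active[keep]
      if (length(cand)) {
        dx <- outer(vapply(cand, function(ti) tracks[[ti]]$last_xy[1],
                           numeric(1)), det$x_um, `-`)
        dy <- outer(vapply(cand, function(ti) tracks[[ti]]$last_xy[2],
                           numeric(1)), det$y_um, `-`)
        dist <- sqrt(dx^2 + dy^2)
        free_t <- rep(TRUE, length(cand))
        repeat {
          dist_ok <- dist
          dist_ok[!free_t, ] <- Inf
          dist_ok[, assigned_det] <- Inf
          mn <- min(dist_ok)
          if (!is.finite(mn) || mn > max_disp_um) break
          # ties: smallest displacement, then lowest track id (row order)
          hit <- which(dist_ok == mn, arr.ind = TRUE)[1, ]
          ti <- cand[hit[1]]; di <- hit[2]
          tracks[[ti]]$rows <- c(tracks[[ti]]$rows, det$.row[di])
          tracks[[ti]]$last_xy <- c(det$x_um[di], det$y_um[di])
          tracks[[ti]]$last_frame <- f
          free_t[hit[1]] <- FALSE
          assigned_det[di] <- TRUE
        }
      }
    }
    # unmatched detections start new tracks
    for (di in which(!assigned_det)) {
      tracks[[length(tracks) + 1L]] <-
        list(rows = det$.row[di], last_xy = c(det$x_um[di], det$y_um[di]),
             last_frame = f)
    }
    active <- which(vapply(tracks, function(t)
      f - t$last_frame <= memory, logical(1)))
    active <- union(active, which(vapply(tracks, function(t)
      t$last_frame == f, logical(1))))
  }
  out <- lapply(tracks, function(t) {
    tr <- locs[match(t$rows, locs$.row), c("frame", "x_um", "y_um"), drop = FALSE]
    tr$row <- t$rows
    rownames(tr) <- NULL
    attr(tr, "fps") <- fps
    tr
  })
  out[vapply(out, nrow, integer(1)) >= min_track_length]
}

#' Per-track diffusion coefficient from the mean-squared displacement
#'
#' 2D camera tracking: D = slope/4 of the MSD over the first \code{n_lags}
#' lags, intercept left free to absorb localization noise. Tracks whose MSD
#' is dominated by curvature (deterministic drift) or that give a negative
#' slope are flagged and should be excluded from size distributions.
#'
#' @param track a track data.frame from \code{\link{linkTrajectories}} with
#'   \code{attr(, "fps")} (or pass \code{fps}).
#' @param n_lags number of MSD lags fitted (default 5).
#' @param fps frame rate (1/s); defaults to the track attribute.
#' @param temperature,viscosity Stokes-Einstein conditions for d_h.
#' @return list with \code{D} (m^2/s), \code{d_h_nm}, \code{flagged},
#'   \code{reason}.
#' @export
estimateDiffusion <- function(track, n_lags = 5, fps = attr(track, "fps"),
                              temperature = 298.15, viscosity = 8.872e-4) {
  if (nrow(track) <= n_lags + 1) stop("track too short for n_lags")
  if (is.null(fps)) stop("frame rate unknown")
  lags <- seq_len(n_lags)
  x <- track$x_um * 1e-6; y <- track$y_um * 1e-6
  n <- length(x)
  msd <- vapply(lags, function(k)
    mean((x[seq_len(n - k) + k] - x[seq_len(n - k)])^2 +
           (y[seq_len(n - k) + k] - y[seq_len(n - k)])^2), numeric(1))
  tt <- lags / fps
  lin <- stats::lm(msd ~ tt)
  slope <- stats::coef(lin)[2]
  quad <- stats::lm(msd ~ tt + I(tt^2))
  c2 <- stats::coef(quad)[3]
  curved <- is.finite(c2) &&
    abs(c2) * max(tt)^2 > 0.5 * abs(stats::coef(quad)[2]) * max(tt)
  if (!is.finite(slope) || slope <= 0)
    return(list(D = NA_real_, d_h_nm = NA_real_, flagged = TRUE,
                reason = "negative MSD slope"))
  D <- unname(slope) / 4
  list(D = D,
       d_h_nm = hydrodynamicDiameter(D, temperature, viscosity),
       flagged = curved,
       reason = if (curved) "MSD curvature (drift)" else "")
}

#' Size distribution and particle concentration from tracks
#'
#' Number-weighted hydrodynamic-diameter histogram over linked tracks plus a
#' concentration estimate: mean simultaneous particle count divided by the
#' observation volume, times the dilution factor. Sizes outside the gate
#' (default 20 nm - 1 um, the instrument's measurement range) and flagged
#' tracks are excluded.
#'
#' @param tracks list of tracks from \code{\link{linkTrajectories}}.
#' @param volume_mL observation volume (mL), > 0.
#' @param dilution dilution factor multiplied onto the concentration.
#' @param n_lags,fps,temperature,viscosity passed to
#'   \code{\link{estimateDiffusion}}.
#' @param breaks_nm histogram bin edges (nm).
#' @param size_gate_nm keep sizes within this window (nm).
#' @return A \linkS4class{SizeDistribution} with per-bin concentrations
#'   (particles/mL). Empty input yields an empty distribution with zero
#'   concentration.
#' @export
sizeAndConcentration <- function(tracks, volume_mL, dilution = 1,
                                 n_lags = 5, fps = 30,
                                 temperature = 298.15, viscosity = 8.872e-4,
                                 breaks_nm = exp(seq(log(20), log(1000),
                                                     length.out = 31)),
                                 size_gate_nm = c(20, 1000)) {
  if (volume_mL <= 0) stop("volume must be positive")
  if (!length(tracks))
    return(SizeDistribution(numeric(0), numeric(0), concentration = NULL))
  est <- lapply(tracks, function(tr)
    estimateDiffusion(tr, n_lags = n_lags,
                      fps = if (is.null(attr(tr, "fps"))) fps else attr(tr, "fps"),
                      temperature = temperature, viscosity = viscosity))
  d_h <- vapply(est, function(e)
    if (e$flagged) NA_real_ else e$d_h_nm, numeric(1))
  d_h <- d_h[is.finite(d_h) & d_h >= size_gate_nm[1] & d_h <= size_gate_nm[2]]
  # mean simultaneous count over the observed frame span
  all_frames <- unlist(lapply(tracks, function(t) t$frame))
  span <- max(all_frames) - min(all_frames) + 1L
  mean_count <- length(all_frames) / span
  conc_total <- mean_count / volume_mL * dilution
  h <- graphics::hist(d_h, breaks = breaks_nm, plot = FALSE)
  w <- h$counts
  conc <- if (sum(w)) conc_total * w / sum(w) else rep(0, length(w))
  SizeDistribution(diameter_nm = h$mids, weight = w,
                   concentration = conc, weighting = "number")
}

#' Total particle volume fraction of a size distribution
#'
#' phi = sum over bins of c_i (pi/6) d_i^3 with concentrations in
#' particles/mL and diameters in nm (converted to cm internally), giving a
#' dimensionless volume fraction.
#'
#' @param dist a \linkS4class{SizeDistribution} carrying concentrations.
#' @return volume fraction (dimensionless).
#' @examples
#' d <- SizeDistribution(100, 1, concentration = 1e12)
#' volumeFraction(d)  # ~5.24e-4
#' @export
volumeFraction <- function(dist) {
  stopifnot(is(dist, "SizeDistribution"))
  if (is.null(dist@concentration))
    stop("distribution carries no concentrations")
  if (!length(dist@diameter_nm)) return(0)
  d_cm <- dist@diameter_nm * 1e-7
  sum(dist@concentration * (pi / 6) * d_cm^3)
}
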