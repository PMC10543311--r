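#' @include AllClasses.R
NULL

#' Describe one emitter species for the photon-stream generator
#'
#' @param n number of emitters of this species.
#' @param t_d_ms focal diffusion time (ms), t_d = w0^2 / (4 D); \code{Inf}
#'   pins the emitters at the focus centre (immobile source).
#' @param brightness_khz donor-excited count rate (kHz) at the focus centre.
#' @param lifetime_ns donor fluorescence lifetime (ns).
#' @param fret FRET efficiency in [0, 1]; \code{NA} for donor-only species
#'   (no acceptor, hence no acceptor-excited signal).
#' @param acc_brightness_khz direct acceptor-excitation count rate (kHz) at
#'   the focus centre (0 for donor-only species).
#' @param acc_lifetime_ns acceptor lifetime (ns).
#' @return one-row data.frame, rows of which are stacked into the
#'   \code{species} table of \code{\link{simulatePhotonStream}}.
#' @export
emitterSpecies <- function(n, t_d_ms = Inf, brightness_khz = 50,
                           lifetime_ns = 4, fret = NA_real_,
                           acc_brightness_khz = 0, acc_lifetime_ns = 1.5) {
  if (!is.na(fret) && (fret < 0 || fret > 1))
    stop("fret must be in [0, 1]")
  if (brightness_khz < 0 || acc_brightness_khz < 0)
    stop("rates must be nonnegative")
  data.frame(n = n, t_d_ms = t_d_ms, brightness_khz = brightness_khz,
             lifetime_ns = lifetime_ns, fret = fret,
             acc_brightness_khz = acc_brightness_khz,
             acc_lifetime_ns = acc_lifetime_ns)
}

# draw microtimes: exponential decay wrapped into a window of width win_ns
# starting at offset_ns (wrapping reproduces the truncated-renormalized
# exponential that TCSPC observes within one excitation period)
.draw_microtimes <- function(n, tau_ns, offset_ns, win_ns) {
  offset_ns + stats::rexp(n, rate = 1 / tau_ns) %% win_ns
}

#' Simulate a time-tagged photon stream from diffusing emitters
#'
#' Emitters diffuse through a 3D-Gaussian detection focus (waist
#' \code{w0_um}, axial elongation \code{axial_ratio}); emission in each
#' integration step is Poisson with the focus-modulated rate, photon
#' macrotimes are drawn uniformly within the step. Detection channels are
#' green/red x parallel/perpendicular. With pulsed interleaved excitation
#' (default) the first half of the excitation period is the donor-excitation
#' window and the second half the acceptor-excitation window; donor-excited
#' photons of a FRET species land in the red channels with probability equal
#' to the FRET efficiency. Microtimes are exponential with the species
#' lifetime (wrapped into the excitation window); background photons have
#' uniform microtimes.
#'
#' @param duration_s acquisition duration (s), > 0.
#' @param species data.frame of emitter species (rows from
#'   \code{\link{emitterSpecies}}); may be empty for background-only streams.
#' @param background_khz background rate per channel (kHz); scalar recycled
#'   to the four channels.
#' @param crosstalk fraction of green photons detected in the red channels.
#' @param period_ns excitation period (ns).
#' @param w0_um lateral focus waist (um).
#' @param axial_ratio z0 / w0 of the detection volume.
#' @param box_um periodic box around the focus (length 3, um).
#' @param dt_s diffusion integration step (s).
#' @param p_parallel probability of detection in the parallel channel.
#' @param seed RNG seed.
#' @return A \linkS4class{PhotonStream}.
#' @export
simulatePhotonStream <- function(duration_s, species = NULL,
                                 background_khz = 0, crosstalk = 0,
                                 period_ns = 32, w0_um = 0.35,
                                 axial_ratio = 5,
                                 box_um = c(2, 2, 4) * w0_um / 0.35,
                                 dt_s = 1e-5, p_parallel = 0.5,
                                 seed = NULL) {
  if (duration_s <= 0) stop("duration must be positive")
  if (!is.null(seed)) set.seed(seed)
  bg <- rep_len(background_khz, 4L)
  if (any(bg < 0)) stop("rates must be nonnegative")
  names(bg) <- .CHANNEL_LEVELS
  z0_um <- axial_ratio * w0_um
  n_steps <- ceiling(duration_s / dt_s)
  half <- period_ns / 2

  mt <- list(); ch <- list(); mc <- list()
  add <- function(macro, channel, micro) {
    k <- length(mt) + 1L
    mt[[k]] <<- macro; ch[[k]] <<- channel; mc[[k]] <<- micro
  }

  emit_one <- function(sp) {
    for (e in seq_len(sp$n)) {
      if (is.finite(sp$t_d_ms)) {
        D_um2s <- w0_um^2 / (4 * sp$t_d_ms * 1e-3)
        sd_step <- sqrt(2 * D_um2s * dt_s)
        xyz <- matrix(stats::rnorm(n_steps * 3L, sd = sd_step), ncol = 3L)
        xyz <- apply(xyz, 2, cumsum)
        start <- stats::runif(3, -box_um / 2, box_um / 2)
        xyz <- sweep(xyz, 2, start, `+`)
        # periodic wrap into the box centred on the focus
        xyz <- sweep(sweep(xyz, 2, box_um / 2, `+`) %% rep(box_um, each = n_steps),
                     2, box_um / 2, `-`)
        focus <- exp(-2 * (xyz[, 1]^2 + xyz[, 2]^2) / w0_um^2 -
                       2 * xyz[, 3]^2 / z0_um^2)
      } else {
        focus <- rep(1, n_steps)
      }
      for (mode in c("donor", "acceptor")) {
        rate_khz <- if (mode == "donor") sp$brightness_khz else
          if (is.na(sp$fret)) 0 else sp$acc_brightness_khz
        if (rate_khz <= 0) next
        counts <- stats::rpois(n_steps, rate_khz * 1e3 * focus * dt_s)
        tot <- sum(counts)
        if (!tot) next
        step_idx <- rep.int(which(counts > 0L), counts[counts > 0L])
        macro <- (step_idx - 1L + stats::runif(tot)) * dt_s
        if (mode == "donor") {
          is_red <- if (is.na(sp$fret)) rep(FALSE, tot) else
            stats::runif(tot) < sp$fret
          # crosstalk: green photons leaking into red detection
          leak <- !is_red & (stats::runif(tot) < crosstalk)
          color <- ifelse(is_red | leak, "R", "G")
          tau <- ifelse(is_red, sp$acc_lifetime_ns, sp$lifetime_ns)
          micro <- .draw_microtimes(tot, tau, 0, half)
        } else {
          color <- rep("R", tot)
          micro <- .draw_microtimes(tot, sp$acc_lifetime_ns, half, half)
        }
        pol <- ifelse(stats::runif(tot) < p_parallel, "p", "s")
        add(macro, paste0(color, pol), micro)
      }
    }
  }

  if (!is.null(species) && nrow(species))
    for (r in seq_len(nrow(species))) emit_one(species[r, ])

  for (chan in .CHANNEL_LEVELS) {
    if (bg[chan] <= 0) next
    nb <- stats::rpois(1, bg[chan] * 1e3 * duration_s)
    if (!nb) next
    add(stats::runif(nb, 0, duration_s), rep(chan, nb),
        stats::runif(nb, 0, period_ns))
  }

  macro <- unlist(mt, use.names = FALSE)
  if (is.null(macro)) macro <- numeric(0)
  chans <- unlist(ch, use.names = FALSE)
  micro <- unlist(mc, use.names = FALSE)
  ord <- order(macro)
  PhotonStream(macrotime = macro[ord],
               channel = if (length(ord)) chans[ord] else character(0),
               microtime = if (length(ord)) micro[ord] else numeric(0),
               period_ns = period_ns, duration_s = duration_s,
               meta = list(species = species, background_khz = bg,
                           crosstalk = crosstalk, w0_um = w0_um,
                           axial_ratio = axial_ratio, dt_s = dt_s,
                           seed = seed))
}
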