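#' @include AllClasses.R
NULL

# minimum-image distances (orthorhombic box) from coords to a reference point
.min_image_dist <- function(coords, ref, box) {
  d <- sweep(coords, 2, ref, `-`)
  d <- d - sweep(round(sweep(d, 2, box, `/`)), 2, box, `*`)
  sqrt(rowSums(d^2))
}

.solute_com <- function(frame, masses) {
  s <- frame$solute
  if (length(masses) == nrow(s)) {
    colSums(s * masses) / sum(masses)
  } else colMeans(s)
}

.default_shell <- function(frames) {
  box_min <- min(frames@box)
  shell <- c(2.5, 3.38)
  if (abs(box_min - 7) > 1e-9) {
    shell <- shell * box_min / 7
    warning(sprintf(
      "box edge %.3g nm differs from 7 nm; bulk shell scaled to %.3g-%.3g nm",
      box_min, shell[1], shell[2]))
  }
  shell
}

#' Cumulative radial counts around the solute centre of mass
#'
#' Minimum-image distances from the (mass-weighted) solute centre of mass,
#' accumulated into 0.02 nm distance bins; monotone nondecreasing in r.
#'
#' @param frames a \linkS4class{SolvationFrames}.
#' @param species species name present in the frames (e.g. \code{"CL"},
#'   \code{"OW"}).
#' @param bin_nm distance bin width (nm), default 0.02 (0.2 Angstrom).
#' @param r_max_nm largest radius; must not exceed half the smallest box
#'   edge (minimum image is invalid beyond), which is also the default.
#' @return matrix [n_frames x n_bins] of cumulative counts N(r), with the
#'   bin radii in \code{attr(, "r_nm")}.
#' @export
cumulativeCounts <- function(frames, species, bin_nm = 0.02,
                             r_max_nm = NULL) {
  stopifnot(is(frames, "SolvationFrames"))
  half <- min(frames@box) / 2
  if (is.null(r_max_nm)) r_max_nm <- floor(half / bin_nm) * bin_nm
  if (r_max_nm > half + 1e-9)
    stop("r_max beyond box_edge/2: minimum-image convention invalid")
  if (!species %in% names(frames@frames[[1]]))
    stop("species not present: ", species)
  edges <- seq(0, r_max_nm, by = bin_nm)
  r_grid <- edges[-1]
  out <- t(vapply(frames@frames, function(fr) {
    ref <- .solute_com(fr, frames@solute_mass)
    d <- .min_image_dist(fr[[species]], ref, frames@box)
    cumsum(graphics::hist(d[d <= r_max_nm], breaks = edges,
                          plot = FALSE)$counts)
  }, numeric(length(r_grid))))
  attr(out, "r_nm") <- r_grid
  out
}

#' Bulk ion-to-water count ratio
#'
#' Frame-averaged counts of the ion species and of water in the bulk shell
#' (default 2.5-3.38 nm from the solute centre of mass, scaled
#' proportionally for non-7 nm boxes), then their ratio:
#' N_ion,bulk / N_H2O,bulk.
#'
#' @param frames a \linkS4class{SolvationFrames}.
#' @param species ion species name.
#' @param water water species name (default \code{"OW"}).
#' @param shell_nm bulk shell bounds (nm).
#' @return the bulk ratio (dimensionless).
#' @export
bulkRatio <- function(frames, species, water = "OW", shell_nm = NULL) {
  stopifnot(is(frames, "SolvationFrames"))
  if (is.null(shell_nm)) shell_nm <- .default_shell(frames)
  count_in_shell <- function(sp) {
    vapply(frames@frames, function(fr) {
      ref <- .solute_com(fr, frames@solute_mass)
      d <- .min_image_dist(fr[[sp]], ref, frames@box)
      sum(d >= shell_nm[1] & d <= shell_nm[2])
    }, numeric(1))
  }
  nw <- count_in_shell(water)
  if (mean(nw) == 0) stop("empty water shell: cannot normalize")
  mean(count_in_shell(species)) / mean(nw)
}

#' Preferential interaction coefficient profile
#'
#' Local-bulk partitioning: Gamma_ion(r) = N_ion(r) - N_H2O(r) *
#' (N_ion,bulk / N_H2O,bulk), evaluated per frame on a 0.02 nm grid and
#' averaged. With a list of frame sets (replicates) the SEM is taken across
#' replicate means, matching a multi-replicate trajectory layout; a single
#' frame set uses the frame-to-frame scatter (frames must then be
#' statistically independent, as the synthetic generator's are). A single
#' frame yields no SEM and is flagged.
#'
#' @param x a \linkS4class{SolvationFrames} or a list of them (replicates).
#' @param species ion species name.
#' @param water water species name.
#' @param shell_nm bulk shell bounds (nm); default 2.5-3.38 nm scaled to
#'   the box.
#' @param bin_nm distance bin width (nm).
#' @param r_max_nm largest radius (nm).
#' @return data.frame with \code{r_nm}, \code{gamma}, \code{sem};
#'   \code{attr(, "bulk_ratio")} holds the ratio used;
#'   \code{attr(, "flagged")} is TRUE when no SEM could be formed.
#' @export
gammaIon <- function(x, species, water = "OW", shell_nm = NULL,
                     bin_nm = 0.02, r_max_nm = NULL) {
  reps <- if (is(x, "SolvationFrames")) list(x) else x
  stopifnot(length(reps) >= 1, all(vapply(reps, is, logical(1),
                                          class2 = "SolvationFrames")))
  if (is.null(shell_nm)) shell_nm <- .default_shell(reps[[1]])
  per_rep <- lapply(reps, function(fr) {
    ni <- cumulativeCounts(fr, species, bin_nm, r_max_nm)
    nw <- cumulativeCounts(fr, water, bin_nm, r_max_nm)
    r <- attr(ni, "r_nm")
    # per-frame bulk normalization: shell-count ratio of each configuration,
    # so normalization noise enters the frame-to-frame scatter and the SEM
    # shell = (lo, hi] on the binned grid; for continuous coordinates this
    # equals the closed shell [lo, hi] almost surely
    lo <- max(which(r <= shell_nm[1] + 1e-9), 1L)
    hi <- max(which(r <= shell_nm[2] + 1e-9))
    shell_ion <- ni[, hi] - ni[, lo]
    shell_wat <- nw[, hi] - nw[, lo]
    if (any(shell_wat == 0)) stop("empty water shell: cannot normalize")
    ratio_f <- shell_ion / shell_wat
    g <- ni - nw * ratio_f
    list(gamma = g, r = r, ratio = mean(shell_ion) / mean(shell_wat))
  })
  r <- per_rep[[1]]$r
  if (length(reps) > 1L) {
    means <- t(vapply(per_rep, function(p) colMeans(p$gamma),
                      numeric(length(r))))
    gamma <- colMeans(means)
    sem <- apply(means, 2, stats::sd) / sqrt(nrow(means))
    flagged <- FALSE
  } else {
    g <- per_rep[[1]]$gamma
    gamma <- colMeans(g)
    if (nrow(g) > 1L) {
      sem <- apply(g, 2, stats::sd) / sqrt(nrow(g))
      flagged <- FALSE
    } else {
      sem <- rep(NA_real_, length(r))
      flagged <- TRUE
    }
  }
  out <- data.frame(r_nm = r, gamma = gamma, sem = sem)
  attr(out, "bulk_ratio") <- mean(vapply(per_rep, `[[`, numeric(1), "ratio"))
  attr(out, "flagged") <- flagged
  out
}

#' Whole-salt preferential interaction coefficient
#'
#' Gamma_salt(r) = 0.5 (Gamma_anion(r) + Gamma_cation(r) - |Z|), with Z the
#' solute net charge. SEMs combine in quadrature.
#'
#' @param gamma_anion,gamma_cation profiles from \code{\link{gammaIon}} on
#'   the same grid.
#' @param Z solute net charge (e).
#' @return data.frame \code{r_nm}, \code{gamma}, \code{sem}.
#' @export
gammaSalt <- function(gamma_anion, gamma_cation, Z) {
  if (length(gamma_anion$r_nm) != length(gamma_cation$r_nm) ||
      any(abs(gamma_anion$r_nm - gamma_cation$r_nm) > 1e-9))
    stop("profiles are on different r grids")
  data.frame(
    r_nm = gamma_anion$r_nm,
    gamma = 0.5 * (gamma_anion$gamma + gamma_cation$gamma - abs(Z)),
    sem = 0.5 * sqrt(gamma_anion$sem^2 + gamma_cation$sem^2))
}

#' Difference of two interaction profiles at a radius
#'
#' Gamma_A(r_eval) - Gamma_B(r_eval) with SEM propagated in quadrature;
#' used to compare salts (e.g. glutamate vs chloride) at r ~ 3 nm.
#'
#' @param profile_A,profile_B profiles on the same grid.
#' @param r_eval_nm evaluation radius (nm); must lie inside the grid.
#' @return list with \code{delta}, \code{sem}, \code{r_nm} (grid point
#'   used).
#' @export
deltaGamma <- function(profile_A, profile_B, r_eval_nm = 3.0) {
  if (length(profile_A$r_nm) != length(profile_B$r_nm) ||
      any(abs(profile_A$r_nm - profile_B$r_nm) > 1e-9))
    stop("profiles are on different r grids")
  if (r_eval_nm < min(profile_A$r_nm) - 1e-9 ||
      r_eval_nm > max(profile_A$r_nm) + 1e-9)
    stop("r_eval outside profile grid")
  i <- which.min(abs(profile_A$r_nm - r_eval_nm))
  list(delta = profile_A$gamma[i] - profile_B$gamma[i],
       sem = sqrt(profile_A$sem[i]^2 + profile_B$sem[i]^2),
       r_nm = profile_A$r_nm[i])
}

# resolve a site selector into per-frame coordinate matrices
.site_coords <- function(frames, selector) {
  if (is.function(selector)) return(lapply(frames@frames, selector))
  if (is.character(selector)) {
    if (!selector %in% names(frames@frames[[1]]))
      stop("no atoms match selector '", selector, "'")
    return(lapply(frames@frames, `[[`, selector))
  }
  stop("selector must be a species name or a function(frame)")
}

#' Site-site radial distribution function
#'
#' g(r): histogram of minimum-image pair distances between two atom
#' selections, normalized by the ideal-gas shell expectation
#' N_A N_B (4 pi r^2 dr) / V per frame (quantifying the relative
#' probability with respect to an ideal-gas prior).
#'
#' @param frames a \linkS4class{SolvationFrames}.
#' @param site_a,site_b selectors: a species name, \code{"solute"}, or a
#'   function(frame) returning a coordinate matrix.
#' @param bin_nm bin width (nm), default 0.02.
#' @param r_max_nm largest radius; default half the smallest box edge.
#' @return data.frame \code{r_nm}, \code{g}.
#' @export
siteRdf <- function(frames, site_a, site_b, bin_nm = 0.02,
                    r_max_nm = NULL) {
  stopifnot(is(frames, "SolvationFrames"))
  half <- min(frames@box) / 2
  if (is.null(r_max_nm)) r_max_nm <- floor(half / bin_nm) * bin_nm
  if (r_max_nm > half + 1e-9)
    stop("r_max beyond box_edge/2: minimum-image convention invalid")
  A <- .site_coords(frames, site_a)
  B <- .site_coords(frames, site_b)
  edges <- seq(0, r_max_nm, by = bin_nm)
  r <- edges[-1] - bin_nm / 2
  V <- prod(frames@box)
  box <- frames@box
  acc <- numeric(length(r))
  norm <- 0
  same <- is.character(site_a) && is.character(site_b) &&
    identical(site_a, site_b)
  for (f in seq_along(A)) {
    a <- A[[f]]; b <- B[[f]]
    counts <- numeric(length(r))
    for (i in seq_len(nrow(a))) {
      d <- .min_image_dist(b, a[i, ], box)
      if (same) d <- d[-i]
      d <- d[d <= r_max_nm & d > 0]
      if (length(d))
        counts <- counts + graphics::hist(d, breaks = edges,
                                          plot = FALSE)$counts
    }
    npairs <- if (same) nrow(a) * (nrow(a) - 1L) else nrow(a) * nrow(b)
    acc <- acc + counts
    norm <- norm + npairs
  }
  shell_vol <- 4 * pi * r^2 * bin_nm
  expected <- norm * shell_vol / V
  data.frame(r_nm = r, g = ifelse(expected > 0, acc / expected, NA_real_))
}
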