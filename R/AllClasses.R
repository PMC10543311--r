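#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' IntensityTrace: uniformly sampled intensity time series
#'
#' Container for detector count traces (DLS scattering intensity, confocal
#' fluorescence, MCS scan traces). Values are nonnegative counts per sample
#' interval unless \code{unit} says otherwise.
#'
#' @slot dt sample interval in seconds.
#' @slot values numeric vector of nonnegative intensities.
#' @slot unit character, \code{"counts"} (per interval) or \code{"kHz"}.
#' @slot origin character label describing provenance.
#' @export
setClass("IntensityTrace",
  representation(dt = "numeric", values = "numeric",
                 unit = "character", origin = "character"),
  prototype(unit = "counts", origin = "")
)

setValidity("IntensityTrace", function(object) {
  msg <- character()
  if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
    msg <- c(msg, "dt must be a single positive number")
  if (any(!is.finite(object@values)) || any(object@values < 0))
    msg <- c(msg, "values must be finite and nonnegative")
  if (!object@unit %in% c("counts", "kHz"))
    msg <- c(msg, "unit must be 'counts' or 'kHz'")
  if (length(msg)) msg else TRUE
})

#' Construct an IntensityTrace
#'
#' @param values nonnegative intensities sampled on a uniform grid.
#' @param dt sample interval (s).
#' @param unit "counts" per interval or "kHz".
#' @param origin free-text provenance label.
#' @return An \linkS4class{IntensityTrace}.
#' @export
IntensityTrace <- function(values, dt, unit = "counts", origin = "") {
  new("IntensityTrace", values = as.numeric(values), dt = dt,
      unit = unit, origin = origin)
}

#' CorrelationCurve: lag grid plus correlation amplitudes
#'
#' Shared by DLS and FCS. \code{normalization} records whether \code{g} holds
#' the normalized second-order correlation g2 (baseline 1) or g2 - 1.
#'
#' @slot lag lag times in seconds, strictly increasing, positive.
#' @slot g correlation amplitudes.
#' @slot sigma optional per-lag standard errors.
#' @slot normalization "g2" or "g2m1".
#' @export
setClass("CorrelationCurve",
  representation(lag = "numeric", g = "numeric",
                 sigma = "numericOrNULL", normalization = "character"),
  prototype(sigma = NULL, normalization = "g2")
)

setValidity("CorrelationCurve", function(object) {
  msg <- character()
  if (length(object@lag) != length(object@g))
    msg <- c(msg, "lag and g must have equal length")
  if (length(object@lag) && (any(object@lag <= 0) || any(diff(object@lag) <= 0)))
    msg <- c(msg, "lags must be strictly increasing and positive")
  if (!is.null(object@sigma) && length(object@sigma) != length(object@lag))
    msg <- c(msg, "sigma must match lag length")
  if (!object@normalization %in% c("g2", "g2m1"))
    msg <- c(msg, "normalization must be 'g2' or 'g2m1'")
  if (length(msg)) msg else TRUE
})

#' Construct a CorrelationCurve
#'
#' @param lag lag times (s), strictly increasing.
#' @param g correlation amplitudes.
#' @param sigma optional per-lag standard errors.
#' @param normalization "g2" (baseline 1) or "g2m1" (baseline 0).
#' @return A \linkS4class{CorrelationCurve}.
#' @export
CorrelationCurve <- function(lag, g, sigma = NULL, normalization = "g2") {
  new("CorrelationCurve", lag = as.numeric(lag), g = as.numeric(g),
      sigma = if (is.null(sigma)) NULL else as.numeric(sigma),
      normalization = normalization)
}

#' PhotonStream: time-tagged photon records
#'
#' Photons carry a macrotime (s, ascending), a detection channel (green/red
#' times parallel/perpendicular) and a microtime (ns within the excitation
#' period, i.e. TCSPC time). For pulsed interleaved excitation the first half
#' of the period is the donor-excitation window and the second half the
#' acceptor-excitation window.
#'
#' @slot macrotime photon arrival times in seconds, sorted ascending.
#' @slot channel factor with levels \code{Gp, Gs, Rp, Rs} (G/R = green/red,
#'   p/s = parallel/perpendicular).
#' @slot microtime TCSPC times in ns, in [0, excitation period).
#' @slot period_ns excitation period (ns).
#' @slot duration_s acquisition duration (s).
#' @slot meta list of generator metadata (configuration echo, seed, truth).
#' @export
setClass("PhotonStream",
  representation(macrotime = "numeric", channel = "factor",
                 microtime = "numeric", period_ns = "numeric",
                 duration_s = "numeric", meta = "list"),
  prototype(meta = list())
)

.CHANNEL_LEVELS <- c("Gp", "Gs", "Rp", "Rs")

setValidity("PhotonStream", function(object) {
  msg <- character()
  n <- length(object@macrotime)
  if (length(object@channel) != n || length(object@microtime) != n)
    msg <- c(msg, "macrotime, channel, microtime must have equal length")
  if (n > 1 && any(diff(object@macrotime) < 0))
    msg <- c(msg, "macrotimes must be sorted ascending")
  if (!identical(levels(object@channel), .CHANNEL_LEVELS))
    msg <- c(msg, "channel levels must be Gp, Gs, Rp, Rs")
  if (length(object@period_ns) != 1L || object@period_ns <= 0)
    msg <- c(msg, "period_ns must be a single positive number")
  if (n && any(object@microtime < 0 | object@microtime >= object@period_ns))
    msg <- c(msg, "microtimes must lie in [0, period_ns)")
  if (object@duration_s <= 0)
    msg <- c(msg, "duration_s must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a PhotonStream
#'
#' @param macrotime arrival times (s), ascending.
#' @param channel character or factor of channels among \code{Gp,Gs,Rp,Rs}.
#' @param microtime TCSPC times (ns) in [0, period_ns).
#' @param period_ns excitation period (ns).
#' @param duration_s total acquisition time (s).
#' @param meta metadata list.
#' @return A \linkS4class{PhotonStream}.
#' @export
PhotonStream <- function(macrotime, channel, microtime, period_ns,
                         duration_s, meta = list()) {
  new("PhotonStream",
      macrotime = as.numeric(macrotime),
      channel = factor(as.character(channel), levels = .CHANNEL_LEVELS),
      microtime = as.numeric(microtime),
      period_ns = period_ns, duration_s = duration_s, meta = meta)
}

#' ScanSet: raster of per-location intensity traces
#'
#' Microfluidic confocal spectroscopy records one intensity trace per scan
#' location; locations fall into channel groups (the four central channels of
#' the device).
#'
#' @slot traces list of \linkS4class{IntensityTrace}.
#' @slot group integer group id per trace.
#' @slot meta list of generator metadata.
#' @export
setClass("ScanSet",
  representation(traces = "list", group = "integer", meta = "list"),
  prototype(meta = list())
)

setValidity("ScanSet", function(object) {
  msg <- character()
  if (length(object@traces) != length(object@group))
    msg <- c(msg, "one group id per trace required")
  if (!all(vapply(object@traces, is, logical(1), class2 = "IntensityTrace")))
    msg <- c(msg, "traces must be IntensityTrace objects")
  if (length(msg)) msg else TRUE
})

#' Construct a ScanSet
#' @param traces list of \linkS4class{IntensityTrace}.
#' @param group integer vector of group ids, one per trace.
#' @param meta metadata list.
#' @return A \linkS4class{ScanSet}.
#' @export
ScanSet <- function(traces, group, meta = list()) {
  new("ScanSet", traces = traces, group = as.integer(group), meta = meta)
}

#' SolvationFrames: periodic-box solvation configurations
#'
#' Frames of an orthorhombic periodic box holding a central solute plus ion
#' and water coordinates, the input to preferential-interaction and RDF
#' analysis. Coordinates are in nm. Each frame is a named list of coordinate
#' matrices (columns x, y, z); the solute entry is named \code{"solute"},
#' other entries are species labels (e.g. \code{"CL"}, \code{"K"},
#' \code{"OW"}). Species counts must be constant across frames.
#'
#' @slot box box edge lengths (nm), length 3.
#' @slot frames list of frames; each frame a named list of coordinate
#'   matrices in nm.
#' @slot solute_mass numeric vector of per-atom masses used for the solute
#'   centre of mass (uniform weights if empty).
#' @slot replicate integer replicate id.
#' @slot meta list of generator metadata.
#' @export
setClass("SolvationFrames",
  representation(box = "numeric", frames = "list", solute_mass = "numeric",
                 replicate = "integer", meta = "list"),
  prototype(solute_mass = numeric(), replicate = 1L, meta = list())
)

setValidity("SolvationFrames", function(object) {
  msg <- character()
  if (length(object@box) != 3L || any(object@box <= 0))
    msg <- c(msg, "box must be three positive edge lengths (nm)")
  if (length(object@frames)) {
    nm <- lapply(object@frames, names)
    if (!all(vapply(nm, identical, logical(1), y = nm[[1]])))
      msg <- c(msg, "all frames must carry the same species")
    if (!"solute" %in% nm[[1]])
      msg <- c(msg, "each frame needs a 'solute' entry")
    cnt <- vapply(object@frames, function(f) vapply(f, nrow, integer(1)),
                  integer(length(nm[[1]])))
    if (is.matrix(cnt) && any(apply(cnt, 1, function(x) length(unique(x))) != 1))
      msg <- c(msg, "species counts must be constant across frames")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SolvationFrames object
#' @param frames list of frames, each a named list of nm coordinate matrices
#'   including a \code{"solute"} entry.
#' @param box box edge lengths in nm (length 1 or 3).
#' @param solute_mass optional per-atom solute masses for the centre of mass.
#' @param replicate replicate id.
#' @param meta metadata list.
#' @return A \linkS4class{SolvationFrames}.
#' @export
SolvationFrames <- function(frames, box, solute_mass = numeric(),
                            replicate = 1L, meta = list()) {
  if (length(box) == 1L) box <- rep(box, 3)
  new("SolvationFrames", frames = frames, box = as.numeric(box),
      solute_mass = as.numeric(solute_mass),
      replicate = as.integer(replicate), meta = meta)
}

#' SizeDistribution: hydrodynamic-diameter distribution
#'
#' Diameter bins with number or intensity weights, optionally carrying
#' particle concentrations per bin.
#'
#' @slot diameter_nm bin centres in nm, increasing.
#' @slot weight nonnegative weights.
#' @slot concentration optional particles/mL per bin.
#' @slot weighting "number" or "intensity".
#' @export
setClass("SizeDistribution",
  representation(diameter_nm = "numeric", weight = "numeric",
                 concentration = "numericOrNULL", weighting = "character"),
  prototype(concentration = NULL, weighting = "number")
)

setValidity("SizeDistribution", function(object) {
  msg <- character()
  if (length(object@diameter_nm) != length(object@weight))
    msg <- c(msg, "diameter_nm and weight must have equal length")
  if (length(object@diameter_nm) > 1 && any(diff(object@diameter_nm) <= 0))
    msg <- c(msg, "diameter bins must be increasing")
  if (any(object@weight < 0))
    msg <- c(msg, "weights must be nonnegative")
  if (!is.null(object@concentration) &&
      (length(object@concentration) != length(object@diameter_nm) ||
       any(object@concentration < 0)))
    msg <- c(msg, "concentration must be nonnegative, one value per bin")
  if (!object@weighting %in% c("number", "intensity"))
    msg <- c(msg, "weighting must be 'number' or 'intensity'")
  if (length(msg)) msg else TRUE
})

#' Construct a SizeDistribution
#' @param diameter_nm bin centres (nm), increasing.
#' @param weight nonnegative weights.
#' @param concentration optional particles/mL per bin.
#' @param weighting "number" or "intensity".
#' @return A \linkS4class{SizeDistribution}.
#' @export
SizeDistribution <- function(diameter_nm, weight, concentration = NULL,
                             weighting = "number") {
  new("SizeDistribution", diameter_nm = as.numeric(diameter_nm),
      weight = as.numeric(weight),
      concentration = if (is.null(concentration)) NULL else as.numeric(concentration),
      weighting = weighting)
}

#' ParticleTrajectorySet: Brownian suspension trajectories
#'
#' Unwrapped 3D positions of a polydisperse particle suspension; wrapped
#' coordinates are recovered with the box edge, unwrapped ones feed MSD
#' estimation.
#'
#' @slot positions array [n_steps + 1, n_particles, 3] of unwrapped positions
#'   (m).
#' @slot box_edge box edge (m) for periodic wrapping.
#' @slot dt time step (s).
#' @slot diameter_nm particle diameters (nm).
#' @slot temperature temperature (K).
#' @slot viscosity dynamic viscosity (Pa s).
#' @slot meta list of generator metadata.
#' @export
setClass("ParticleTrajectorySet",
  representation(positions = "array", box_edge = "numeric", dt = "numeric",
                 diameter_nm = "numeric", temperature = "numeric",
                 viscosity = "numeric", meta = "list"),
  prototype(meta = list())
)

setValidity("ParticleTrajectorySet", function(object) {
  msg <- character()
  d <- dim(object@positions)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "positions must be [steps, particles, 3]")
  if (!is.null(d) && d[2] != length(object@diameter_nm))
    msg <- c(msg, "one diameter per particle required")
  if (any(object@diameter_nm <= 0))
    msg <- c(msg, "diameters must be positive")
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (length(msg)) msg else TRUE
})

#' DlsFit: result of exponential fits to a DLS correlation curve
#'
#' @slot b amplitude(s) of the fitted exponential component(s).
#' @slot D translational diffusion coefficient(s) (m^2/s), fast first.
#' @slot R_h hydrodynamic radius(es) (m) from the Stokes-Einstein relation.
#' @slot d_h hydrodynamic diameter(s) (m), 2 R_h.
#' @slot residual root-mean-square fit residual.
#' @slot slow_mode_fraction amplitude share of the slower component (two-
#'   component fits; NA for single fits).
#' @slot slow_mode_flag TRUE when a slow mode is detected.
#' @slot converged logical fit status.
#' @export
setClass("DlsFit",
  representation(b = "numeric", D = "numeric", R_h = "numeric", d_h = "numeric",
                 residual = "numeric", slow_mode_fraction = "numeric",
                 slow_mode_flag = "logical", converged = "logical"),
  prototype(slow_mode_fraction = NA_real_, slow_mode_flag = FALSE,
            converged = TRUE)
)

setValidity("DlsFit", function(object) {
  msg <- character()
  if (any(object@D <= 0, na.rm = TRUE))
    msg <- c(msg, "diffusion coefficients must be positive")
  if (!isTRUE(all.equal(object@d_h, 2 * object@R_h)))
    msg <- c(msg, "d_h must equal 2 R_h")
  if (length(msg)) msg else TRUE
})

#' FcsFit: parameters of the two-component 3D-Gaussian FCS model
#'
#' Holds the fitted offset G0, mean occupancy N, fraction R of the first
#' (fast, dye/monomer) component, diffusion times (ms), axial ratios, kinetic
#' relaxation amplitude A and time tA (ms), per-parameter standard errors and
#' the weighted residual vector.
#'
#' @slot par named numeric of fitted parameters (G0, N, R, td1_ms, td2_ms,
#'   ar1, ar2, A, tA_ms).
#' @slot se named numeric of standard errors (NA where fixed).
#' @slot fixed character vector of parameter names held fixed.
#' @slot residuals weighted residuals (data - model)/sigma.
#' @slot lag_ms lag grid of the fitted curve in ms.
#' @slot converged logical.
#' @slot at_bounds character vector of parameters that ended at bounds.
#' @export
setClass("FcsFit",
  representation(par = "numeric", se = "numeric", fixed = "character",
                 residuals = "numeric", lag_ms = "numeric",
                 converged = "logical", at_bounds = "character"),
  prototype(converged = TRUE, at_bounds = character())
)

setValidity("FcsFit", function(object) {
  need <- c("G0", "N", "R", "td1_ms", "td2_ms", "ar1", "ar2", "A", "tA_ms")
  if (!all(need %in% names(object@par)))
    return(paste("par must contain", paste(need, collapse = ", ")))
  if (object@par["N"] <= 0) return("N must be positive")
  if (object@par["td2_ms"] < object@par["td1_ms"])
    return("td2 must be >= td1 (component ordering)")
  TRUE
})
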