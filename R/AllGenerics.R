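#' @include AllClasses.R
NULL

#' Sample interval of a trace
#' @param x an object with a time base.
#' @return interval in seconds.
#' @export
setGeneric("sampleInterval", function(x) standardGeneric("sampleInterval"))

#' Intensity values of a trace
#' @param x an object holding intensities.
#' @return numeric vector.
#' @export
setGeneric("intensityValues", function(x) standardGeneric("intensityValues"))

#' Lag times of a correlation curve
#' @param x a \linkS4class{CorrelationCurve}.
#' @return numeric vector of lags (s).
#' @export
setGeneric("lagTimes", function(x) standardGeneric("lagTimes"))

#' Correlation amplitudes
#' @param x a \linkS4class{CorrelationCurve}.
#' @return numeric vector.
#' @export
setGeneric("corrValues", function(x) standardGeneric("corrValues"))

#' Number of frames / steps / photons in a container
#' @param x a package data object.
#' @return integer count.
#' @export
setGeneric("nRecords", function(x) standardGeneric("nRecords"))

#' @rdname sampleInterval
setMethod("sampleInterval", "IntensityTrace", function(x) x@dt)

#' @rdname intensityValues
setMethod("intensityValues", "IntensityTrace", function(x) x@values)

#' @rdname lagTimes
setMethod("lagTimes", "CorrelationCurve", function(x) x@lag)

#' @rdname corrValues
setMethod("corrValues", "CorrelationCurve", function(x) x@g)

#' @rdname nRecords
setMethod("nRecords", "IntensityTrace", function(x) length(x@values))
#' @rdname nRecords
setMethod("nRecords", "CorrelationCurve", function(x) length(x@lag))
#' @rdname nRecords
setMethod("nRecords", "PhotonStream", function(x) length(x@macrotime))
#' @rdname nRecords
setMethod("nRecords", "ScanSet", function(x) length(x@traces))
#' @rdname nRecords
setMethod("nRecords", "SolvationFrames", function(x) length(x@frames))

setMethod("show", "IntensityTrace", function(object) {
  cat(sprintf("IntensityTrace: %d samples at dt = %.3g s (%s)\n",
              length(object@values), object@dt, object@unit))
  if (nzchar(object@origin)) cat("  origin:", object@origin, "\n")
})

setMethod("show", "CorrelationCurve", function(object) {
  cat(sprintf("CorrelationCurve: %d lags, %.3g - %.3g s [%s]%s\n",
              length(object@lag),
              if (length(object@lag)) min(object@lag) else NA,
              if (length(object@lag)) max(object@lag) else NA,
              object@normalization,
              if (is.null(object@sigma)) "" else ", with sigma"))
})

setMethod("show", "PhotonStream", function(object) {
  cat(sprintf("PhotonStream: %d photons over %.3g s, period %.3g ns\n",
              length(object@macrotime), object@duration_s, object@period_ns))
  print(table(object@channel))
})

setMethod("show", "ScanSet", function(object) {
  cat(sprintf("ScanSet: %d traces in %d groups\n",
              length(object@traces), length(unique(object@group))))
})

setMethod("show", "SolvationFrames", function(object) {
  sp <- if (length(object@frames)) names(object@frames[[1]]) else character()
  cat(sprintf("SolvationFrames: %d frames, box %s nm, species: %s\n",
              length(object@frames),
              paste(signif(object@box, 3), collapse = " x "),
              paste(sp, collapse = ", ")))
})

setMethod("show", "SizeDistribution", function(object) {
  cat(sprintf("SizeDistribution (%s-weighted): %d bins, %.3g - %.3g nm%s\n",
              object@weighting, length(object@diameter_nm),
              if (length(object@diameter_nm)) min(object@diameter_nm) else NA,
              if (length(object@diameter_nm)) max(object@diameter_nm) else NA,
              if (is.null(object@concentration)) "" else ", with concentrations"))
})

setMethod("show", "ParticleTrajectorySet", function(object) {
  d <- dim(object@positions)
  cat(sprintf("ParticleTrajectorySet: %d particles, %d steps, dt = %.3g s\n",
              d[2], d[1] - 1L, object@dt))
})

setMethod("show", "DlsFit", function(object) {
  k <- length(object@D)
  cat(sprintf("DlsFit (%d component%s):\n", k, if (k > 1) "s" else ""))
  for (i in seq_len(k))
    cat(sprintf("  D = %.4g m^2/s, d_h = %.4g nm, b = %.3g\n",
                object@D[i], object@d_h[i] * 1e9, object@b[i]))
  if (!is.na(object@slow_mode_fraction))
    cat(sprintf("  slow-mode fraction = %.3f (flag: %s)\n",
                object@slow_mode_fraction, object@slow_mode_flag))
})

setMethod("show", "FcsFit", function(object) {
  cat("FcsFit:\n")
  p <- object@par
  cat(sprintf("  N = %.3g, R = %.3f, td1 = %.4g ms, td2 = %.4g ms\n",
              p["N"], p["R"], p["td1_ms"], p["td2_ms"]))
  cat(sprintf("  A = %.3f, tA = %.4g ms, G0 = %.3g\n",
              p["A"], p["tA_ms"], p["G0"]))
  if (length(object@fixed))
    cat("  fixed:", paste(object@fixed, collapse = ", "), "\n")
  if (length(object@at_bounds))
    cat("  at bounds:", paste(object@at_bounds, collapse = ", "), "\n")
})
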