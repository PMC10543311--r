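#' @include AllClasses.R
NULL

.read_table_checked <- function(path, required, sep) {
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "#"))
  if (!length(body_idx)) stop("no data rows in ", path)
  header <- strsplit(lines[body_idx[1]], sep, fixed = TRUE)[[1]]
  missing_cols <- setdiff(required, header)
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  rows <- lines[body_idx[-1]]
  rows <- rows[nzchar(rows)]
  parts <- strsplit(rows, sep, fixed = TRUE)
  bad <- which(lengths(parts) != length(header))
  if (length(bad))
    stop("malformed row at line ", body_idx[1] + bad[1], " of ", path)
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- header
  for (cc in required) {
    num <- suppressWarnings(as.numeric(out[[cc]]))
    if (cc != "channel" && anyNA(num) && !all(is.na(out[[cc]]))) {
      bad <- which(is.na(num) & out[[cc]] != "NA")
      if (length(bad))
        stop("non-numeric value in column '", cc, "' at line ",
             body_idx[1] + bad[1], " of ", path)
    }
  }
  out
}

.meta_lines <- function(path, key) {
  lines <- grep(paste0("^# ", key, "="), readLines(path), value = TRUE)
  if (!length(lines)) return(NA_character_)
  sub(paste0("^# ", key, "="), "", lines[1])
}

#' Write / read an intensity trace as TSV
#'
#' One \code{value} column plus \code{#}-prefixed metadata lines carrying the
#' sample interval, unit and origin. Round trips losslessly.
#'
#' @param trace an \linkS4class{IntensityTrace}.
#' @param path file path.
#' @return \code{readIntensityTrace} returns an \linkS4class{IntensityTrace};
#'   \code{writeIntensityTrace} returns \code{path} invisibly.
#' @export
writeIntensityTrace <- function(trace, path) {
  stopifnot(is(trace, "IntensityTrace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# dt_s=%.17g", trace@dt),
               sprintf("# unit=%s", trace@unit),
               sprintf("# origin=%s", trace@origin),
               "value",
               sprintf("%.17g", trace@values)), con)
  invisible(path)
}

#' @rdname writeIntensityTrace
#' @export
readIntensityTrace <- function(path) {
  tab <- .read_table_checked(path, "value", "\t")
  dt <- as.numeric(.meta_lines(path, "dt_s"))
  if (is.na(dt)) stop("missing '# dt_s=' metadata in ", path)
  unit <- .meta_lines(path, "unit")
  origin <- .meta_lines(path, "origin")
  IntensityTrace(as.numeric(tab$value), dt = dt,
                 unit = if (is.na(unit)) "counts" else unit,
                 origin = if (is.na(origin)) "" else origin)
}

#' Write / read a photon stream as a columnar text table
#'
#' Columns \code{macrotime_ns}, \code{channel}, \code{microtime_ps}; metadata
#' lines carry the excitation period and duration.
#'
#' @param stream a \linkS4class{PhotonStream}.
#' @param path file path.
#' @return \code{readPhotonStream} returns a \linkS4class{PhotonStream}.
#' @export
writePhotonStream <- function(stream, path) {
  stopifnot(is(stream, "PhotonStream"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# period_ns=%.17g", stream@period_ns),
               sprintf("# duration_s=%.17g", stream@duration_s),
               "macrotime_ns\tchannel\tmicrotime_ps",
               sprintf("%.17g\t%s\t%.17g",
                       stream@macrotime * 1e9,
                       as.character(stream@channel),
                       stream@microtime * 1e3)), con)
  invisible(path)
}

#' @rdname writePhotonStream
#' @export
readPhotonStream <- function(path) {
  tab <- .read_table_checked(
    path, c("macrotime_ns", "channel", "microtime_ps"), "\t")
  period <- as.numeric(.meta_lines(path, "period_ns"))
  duration <- as.numeric(.meta_lines(path, "duration_s"))
  if (is.na(period) || is.na(duration))
    stop("missing period/duration metadata in ", path)
  PhotonStream(macrotime = as.numeric(tab$macrotime_ns) * 1e-9,
               channel = tab$channel,
               microtime = as.numeric(tab$microtime_ps) * 1e-3,
               period_ns = period, duration_s = duration)
}

#' Write / read a correlation curve as CSV
#'
#' Columns \code{lag_s,G,sigma} (sigma written as NA when absent).
#'
#' @param curve a \linkS4class{CorrelationCurve}.
#' @param path file path.
#' @return \code{readCorrelationCurve} returns a
#'   \linkS4class{CorrelationCurve}.
#' @export
writeCorrelationCurve <- function(curve, path) {
  stopifnot(is(curve, "CorrelationCurve"))
  sig <- if (is.null(curve@sigma)) rep(NA_real_, length(curve@lag)) else curve@sigma
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# normalization=%s", curve@normalization),
               "lag_s,G,sigma",
               sprintf("%.17g,%.17g,%.17g", curve@lag, curve@g, sig)), con)
  invisible(path)
}

#' @rdname writeCorrelationCurve
#' @export
readCorrelationCurve <- function(path) {
  tab <- .read_table_checked(path, c("lag_s", "G", "sigma"), ",")
  norm <- .meta_lines(path, "normalization")
  sig <- suppressWarnings(as.numeric(tab$sigma))
  if (all(is.na(sig))) sig <- NULL
  CorrelationCurve(lag = as.numeric(tab$lag_s), g = as.numeric(tab$G),
                   sigma = sig,
                   normalization = if (is.na(norm)) "g2" else norm)
}

#' Write / read particle localizations as TSV
#'
#' Columns \code{frame,x_um,y_um} with a frame-rate metadata line; the input
#' format of the tracking stage.
#'
#' @param locs data.frame with columns \code{frame} (0-based), \code{x_um},
#'   \code{y_um}; may carry a ground-truth \code{particle} column, preserved.
#' @param fps frame rate (1/s).
#' @param path file path.
#' @return \code{readLocalizations} returns the data.frame with the frame
#'   rate in \code{attr(, "fps")}.
#' @export
writeLocalizations <- function(locs, fps, path) {
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(locs)))
  con <- file(path, "w")
  on.exit(close(con))
  has_id <- "particle" %in% names(locs)
  hdr <- if (has_id) "frame\tx_um\ty_um\tparticle" else "frame\tx_um\ty_um"
  body <- if (has_id)
    sprintf("%d\t%.17g\t%.17g\t%d", locs$frame, locs$x_um, locs$y_um,
            locs$particle)
  else sprintf("%d\t%.17g\t%.17g", locs$frame, locs$x_um, locs$y_um)
  writeLines(c(sprintf("# fps=%.17g", fps), hdr, body), con)
  invisible(path)
}

#' @rdname writeLocalizations
#' @export
readLocalizations <- function(path) {
  tab <- .read_table_checked(path, c("frame", "x_um", "y_um"), "\t")
  out <- data.frame(frame = as.integer(tab$frame),
                    x_um = as.numeric(tab$x_um),
                    y_um = as.numeric(tab$y_um))
  if ("particle" %in% names(tab)) out$particle <- as.integer(tab$particle)
  attr(out, "fps") <- as.numeric(.meta_lines(path, "fps"))
  out
}

#' Write / read solvation frames as multi-frame extended XYZ
#'
#' Each frame is written as an atom count, a comment line carrying
#' \code{Lattice="Lx 0 0 0 Ly 0 0 0 Lz"} (nm), then one
#' \code{species x y z} row per atom. Solute atoms are labelled
#' \code{SOLUTE} on write and collected back into the \code{solute} entry on
#' read (configurable via \code{solute_label}).
#'
#' @param frames a \linkS4class{SolvationFrames} object.
#' @param path file path.
#' @param solute_label species label marking solute atoms.
#' @return \code{readXyzFrames} returns a \linkS4class{SolvationFrames}.
#' @export
writeXyzFrames <- function(frames, path, solute_label = "SOLUTE") {
  stopifnot(is(frames, "SolvationFrames"))
  con <- file(path, "w")
  on.exit(close(con))
  box <- frames@box
  lattice <- sprintf('Lattice="%.10g 0 0 0 %.10g 0 0 0 %.10g" Properties=species:S:1:pos:R:3',
                     box[1], box[2], box[3])
  for (fr in frames@frames) {
    nat <- sum(vapply(fr, nrow, integer(1)))
    writeLines(c(as.character(nat), lattice), con)
    for (sp in names(fr)) {
      lab <- if (sp == "solute") solute_label else sp
      m <- fr[[sp]]
      writeLines(sprintf("%s %.10g %.10g %.10g", lab, m[, 1], m[, 2], m[, 3]),
                 con)
    }
  }
  invisible(path)
}

#' @rdname writeXyzFrames
#' @export
readXyzFrames <- function(path, solute_label = "SOLUTE") {
  lines <- readLines(path)
  i <- 1L
  frames <- list()
  box <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop("expected atom count at line ", i, " of ", path)
    comment <- lines[i + 1L]
    lat <- regmatches(comment, regexpr('Lattice="[^"]*"', comment))
    if (!length(lat)) stop("missing Lattice box line at line ", i + 1L)
    nums <- as.numeric(strsplit(gsub('Lattice="|"', "", lat), "\\s+")[[1]])
    box <- nums[c(1, 5, 9)]
    rows <- lines[i + 1L + seq_len(nat)]
    parts <- strsplit(trimws(rows), "\\s+")
    if (any(lengths(parts) < 4))
      stop("malformed atom row at line ",
           i + 1L + which(lengths(parts) < 4)[1], " of ", path)
    sp <- vapply(parts, `[`, character(1), 1L)
    xyz <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))),
                  ncol = 3, byrow = TRUE)
    if (anyNA(xyz)) stop("non-numeric coordinate in frame starting line ", i)
    fr <- lapply(split(seq_len(nat), sp), function(ix) xyz[ix, , drop = FALSE])
    names(fr)[names(fr) == solute_label] <- "solute"
    frames[[length(frames) + 1L]] <- fr
    i <- i + 2L + nat
  }
  # order species consistently so frames validate
  if (length(frames) > 1L) {
    ord <- names(frames[[1]])
    frames <- lapply(frames, function(f) f[ord])
  }
  SolvationFrames(frames = frames, box = box)
}

#' Read solvation frames from a (multi-MODEL) PDB file
#'
#' Uses \code{bio3d} to parse single- or multi-MODEL PDB files. Coordinates
#' are converted from Angstrom to nm. The solute is selected by residue-name
#' pattern; each ion/water species by an atom- or residue-name pattern
#' matched against \code{"RESID:ATOM"} strings.
#'
#' @param path PDB file.
#' @param solute_pattern regular expression matched against residue names to
#'   pick solute atoms.
#' @param species named list of regular expressions matched against
#'   \code{"RESID:ATOM"} to pick each species (e.g.
#'   \code{list(CL = "^CLA?:", OW = ":OW?$")}).
#' @param box box edges in nm; taken from the CRYST1 record when NULL.
#' @return A \linkS4class{SolvationFrames}.
#' @export
readPdbFrames <- function(path, solute_pattern, species, box = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  atom <- pdb$atom
  key <- paste0(atom$resid, ":", atom$elety)
  sol_idx <- grep(solute_pattern, atom$resid)
  if (!length(sol_idx)) stop("no solute atoms match ", solute_pattern)
  sp_idx <- lapply(species, function(p) {
    ix <- grep(p, key)
    if (!length(ix)) stop("no atoms match species selector ", p)
    ix
  })
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)
  get_coords <- function(model, ix) {
    cols <- as.vector(rbind(3 * ix - 2, 3 * ix - 1, 3 * ix))
    matrix(xyz[model, cols], ncol = 3, byrow = TRUE) / 10  # A -> nm
  }
  frames <- lapply(seq_len(n_models), function(mdl) {
    fr <- c(list(solute = get_coords(mdl, sol_idx)),
            lapply(sp_idx, function(ix) get_coords(mdl, ix)))
    fr
  })
  if (is.null(box)) {
    cr <- grep("^CRYST1", readLines(path, n = 200), value = TRUE)
    if (length(cr)) {
      abc <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                          substr(cr[1], 25, 33)))
      box <- abc / 10
    } else stop("no CRYST1 record; supply box explicitly")
  }
  SolvationFrames(frames = frames, box = box)
}
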