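#' @include AllClasses.R constants.R
NULL

# default solute: a compact 5-site cluster at the box centre (nm offsets)
.default_solute <- function(center) {
  offs <- rbind(c(0, 0, 0),
                c(0.15, 0.15, 0.15), c(-0.15, -0.15, 0.15),
                c(0.15, -0.15, -0.15), c(-0.15, 0.15, -0.15))
  sweep(offs, 2, center, `+`)
}

# rejection-sample n points in the box with acceptance probability w(r)/max_w,
# r = minimum-image distance to the box centre
.sample_modulated <- function(n, box, w, max_w) {
  out <- matrix(numeric(0), ncol = 3)
  half <- box / 2
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 64L)
    cand <- cbind(stats::runif(m, 0, box[1]), stats::runif(m, 0, box[2]),
                  stats::runif(m, 0, box[3]))
    d <- sweep(cand, 2, half, `-`)
    r <- sqrt(rowSums(d^2))
    keep <- stats::runif(m) < w(r) / max_w
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Simulate equilibrium solvation configurations around a central solute
#'
#' Builds independent frames of an orthorhombic periodic box: a fixed solute
#' at the centre, waters uniform, and each ion species placed with position
#' density proportional to a radial weight function w(r) (w = 1 reproduces a
#' uniform solution). Ion counts follow from the salt concentration and box
#' volume, with extra counter-ions neutralizing the solute net charge Z.
#' Frames are independent equilibrium draws, not dynamics: preferential-
#' interaction estimation only needs equilibrium configurations.
#'
#' The weight functions must equal 1 inside the bulk-normalization shell
#' (and beyond), otherwise the local-bulk normalization would be biased; this
#' is validated and violations are an error.
#'
#' @param box_nm cubic box edge (nm).
#' @param n_water number of water (oxygen) sites.
#' @param salt_M salt concentration (mol/L).
#' @param anion,cation species labels.
#' @param w_anion,w_cation vectorized radial weight functions w(r), r in nm.
#' @param max_w upper bound of the weight functions (rejection envelope).
#' @param Z solute net charge (e); positive Z adds anions, negative adds
#'   cations.
#' @param n_frames number of independent frames.
#' @param bulk_shell_nm bulk shell bounds (nm) inside which w must be 1;
#'   defaults to 2.5-3.38 nm scaled proportionally when the box is not 7 nm.
#' @param solute_xyz optional solute coordinates (nm, matrix), default a
#'   compact 5-site cluster at the centre.
#' @param replicate replicate id stored on the object.
#' @param seed RNG seed.
#' @return A \linkS4class{SolvationFrames} with species \code{anion},
#'   \code{cation} and \code{OW}.
#' @export
simulateSolvationBox <- function(box_nm = 7, n_water = 3000, salt_M = 0.5,
                                 anion = "CL", cation = "K",
                                 w_anion = function(r) rep(1, length(r)),
                                 w_cation = function(r) rep(1, length(r)),
                                 max_w = 2, Z = 0L, n_frames = 20,
                                 bulk_shell_nm = NULL, solute_xyz = NULL,
                                 replicate = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  box <- rep(box_nm, 3)
  if (is.null(bulk_shell_nm)) bulk_shell_nm <- c(2.5, 3.38) * box_nm / 7
  rr <- seq(bulk_shell_nm[1], min(box_nm / 2, box_nm), length.out = 64)
  for (w in list(anion = w_anion, cation = w_cation)) {
    if (max(abs(w(rr) - 1)) > 1e-9)
      stop("weight function must equal 1 in and beyond the bulk shell ",
           "(would bias bulk normalization)")
    if (any(w(seq(0.01, box_nm / 2, length.out = 200)) < 0))
      stop("weight functions must be nonnegative")
  }
  n_salt <- round(salt_M * .NA * (box_nm * 1e-7)^3 * 1e-3)  # nm^3 -> L
  n_anion <- n_salt + max(Z, 0L)
  n_cation <- n_salt + max(-Z, 0L)
  solute <- if (is.null(solute_xyz)) .default_solute(box / 2) else solute_xyz
  frames <- lapply(seq_len(n_frames), function(f) {
    fr <- list(solute = solute)
    fr[[anion]] <- .sample_modulated(n_anion, box, w_anion, max_w)
    fr[[cation]] <- .sample_modulated(n_cation, box, w_cation, max_w)
    fr[["OW"]] <- cbind(stats::runif(n_water, 0, box[1]),
                        stats::runif(n_water, 0, box[2]),
                        stats::runif(n_water, 0, box[3]))
    fr
  })
  SolvationFrames(frames = frames, box = box, replicate = replicate,
                  meta = list(salt_M = salt_M, n_anion = n_anion,
                              n_cation = n_cation, n_water = n_water,
                              Z = Z, anion = anion, cation = cation,
                              bulk_shell_nm = bulk_shell_nm, seed = seed))
}
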