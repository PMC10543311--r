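#' Physical constants
#'
#' CODATA values used throughout the package: Boltzmann constant \code{kB}
#' (J/K), Avogadro constant \code{NA} (1/mol) and the molar gas constant
#' \code{R_kcal} in kcal/(mol K).
#'
#' @return Named list with elements \code{kB}, \code{NA_const} and
#'   \code{R_kcal}.
#' @examples
#' physicalConstants()$kB
#' @export
physicalConstants <- function() {
  list(
    kB       = 1.380649e-23,   # J/K
    NA_const = 6.02214076e23,  # 1/mol
    R_kcal   = 1.987204e-3     # kcal/(mol K)
  )
}

.kB <- 1.380649e-23
.NA <- 6.02214076e23
.R_KCAL <- 1.987204e-3
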