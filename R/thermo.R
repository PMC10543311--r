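#' @include AllClasses.R constants.R
NULL

#' Saturation concentration from a spin-down dilution series
#'
#' Above the saturation concentration the supernatant plateaus: the series
#' follows supernatant = min(total, csat). The breakpoint is estimated by a
#' 1D grid search over candidate csat values followed by local refinement
#' (robust and derivative-free), with a bootstrap confidence interval over
#' the points.
#'
#' @param series data.frame with columns \code{total_uM},
#'   \code{supernatant_uM} (e.g. from \code{\link{simulateSpindownSeries}}
#'   or \code{\link{readSpindownSeries}}).
#' @param n_grid grid resolution of the search.
#' @param n_boot bootstrap replicates for the confidence interval.
#' @param conf confidence level.
#' @param seed RNG seed for the bootstrap.
#' @return list with \code{csat}, \code{ci} (length 2), \code{rss}. An
#'   error is raised when no plateau is observed (all points below the
#'   candidate breakpoint range).
#' @export
estimateCsat <- function(series, n_grid = 512L, n_boot = 200L,
                         conf = 0.95, seed = NULL) {
  tot <- series$total_uM; sup <- series$supernatant_uM
  if (length(tot) < 4) stop("need >= 4 points spanning the breakpoint")
  fit_one <- function(tot, sup) {
    rng <- range(tot)
    grid <- seq(rng[1], rng[2], length.out = n_grid)
    rss <- vapply(grid, function(cc) sum((sup - pmin(tot, cc))^2),
                  numeric(1))
    i <- which.min(rss)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(n_grid, i + 1L)]
    if (lo < hi) {
      o <- stats::optimize(function(cc) sum((sup - pmin(tot, cc))^2),
                           c(lo, hi))
      c(o$minimum, o$objective)
    } else c(grid[i], rss[i])
  }
  est <- fit_one(tot, sup)
  # identity fit (csat at or beyond the largest total) means no plateau seen
  if (est[1] >= max(tot) * 0.999 &&
      sum((sup - tot)^2) <= est[2] * 1.0001)
    stop("no saturation observed: supernatant tracks total over the series")
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    bs <- vapply(seq_len(n_boot), function(b) {
      ix <- sample(length(tot), replace = TRUE)
      fit_one(tot[ix], sup[ix])[1]
    }, numeric(1))
    a <- (1 - conf) / 2
    ci <- unname(stats::quantile(bs, c(a, 1 - a), na.rm = TRUE))
  }
  list(csat = est[1], ci = ci, rss = est[2])
}

#' Read / write a spin-down series as CSV
#'
#' Columns \code{total_uM,supernatant_uM}.
#'
#' @param series data.frame with the two columns.
#' @param path file path.
#' @return \code{readSpindownSeries} returns the data.frame.
#' @export
writeSpindownSeries <- function(series, path) {
  stopifnot(all(c("total_uM", "supernatant_uM") %in% names(series)))
  utils::write.csv(series[c("total_uM", "supernatant_uM")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSpindownSeries
#' @export
readSpindownSeries <- function(path) {
  tab <- .read_table_checked(path, c("total_uM", "supernatant_uM"), ",")
  data.frame(total_uM = as.numeric(tab$total_uM),
             supernatant_uM = as.numeric(tab$supernatant_uM))
}

#' Cluster abundance ratio
#'
#' Fold change c_A / c_B with uncertainty propagated in quadrature when
#' standard errors are supplied.
#'
#' @param c_A,c_B abundances (concentrations); \code{c_B} > 0.
#' @param sem_A,sem_B optional standard errors.
#' @return list with \code{ratio} and \code{sem} (NA without input SEMs).
#' @export
abundanceRatio <- function(c_A, c_B, sem_A = NULL, sem_B = NULL) {
  if (c_B == 0) stop("division by zero abundance")
  r <- c_A / c_B
  sem <- if (!is.null(sem_A) && !is.null(sem_B))
    abs(r) * sqrt((sem_A / c_A)^2 + (sem_B / c_B)^2) else NA_real_
  list(ratio = r, sem = sem)
}

#' Transfer free energy from an abundance ratio
#'
#' Free energy of transfer of molecules from the dispersed phase into
#' mesoscale clusters implied by a fold change in cluster abundance:
#' delta-delta-G = R T ln(ratio), in kcal/mol.
#'
#' @param ratio abundance fold change, > 0.
#' @param temperature temperature (K), default 293.15 (20 C).
#' @return free energy difference in kcal/mol.
#' @examples
#' transferFreeEnergy(4)  # ~0.81 kcal/mol at 293.15 K
#' @export
transferFreeEnergy <- function(ratio, temperature = 293.15) {
  if (any(ratio <= 0)) stop("ratio must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  .R_KCAL * temperature * log(ratio)
}
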