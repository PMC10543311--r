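#' @include AllClasses.R
NULL

#' Two-component 3D-Gaussian FCS model with a kinetic relaxation term
#'
#' G(tc) = G0 + 1/N [ |R| g_d(tc; td1, ar1) + |1 - |R|| g_d(tc; td2, ar2) ]
#' (1 - |A| + |A| exp(-tc / tA)), where
#' g_d(tc; td, ar) = 1 / ((1 + tc/td) sqrt(1 + tc/(ar^2 td))) is the
#' 3D-Gaussian diffusion factor with axial ratio ar = z0/w0. The first
#' component is the fast dye/monomer term, the second the multimer term.
#'
#' @param tc_ms correlation times (ms).
#' @param par named vector or list with \code{G0, N, R, td1_ms, td2_ms,
#'   ar1, ar2, A, tA_ms}.
#' @return model values (same normalization as g2 - 1 plus offset G0).
#' @export
fcsModel <- function(tc_ms, par) {
  p <- as.list(par)
  gd <- function(td, ar)
    1 / ((1 + tc_ms / abs(td)) * sqrt(1 + tc_ms / (ar^2 * abs(td))))
  diff_part <- abs(p$R) * gd(p$td1_ms, p$ar1) +
    abs(1 - abs(p$R)) * gd(p$td2_ms, p$ar2)
  kin <- 1 - abs(p$A) + abs(p$A) * exp(-tc_ms / abs(p$tA_ms))
  p$G0 + (1 / p$N) * diff_part * kin
}

.fcs_par_names <- c("G0", "N", "R", "td1_ms", "td2_ms", "ar1", "ar2",
                    "A", "tA_ms")

# transform to/from unconstrained optimizer space: positive scale parameters
# via log; R and A handled downstream through absolute value (as the model
# is written); G0 free.
.fcs_to_opt <- function(p) {
  c(G0 = unname(p["G0"]), lN = log(p[["N"]]), R = unname(p["R"]),
    ltd1 = log(p[["td1_ms"]]), ltd2 = log(p[["td2_ms"]]),
    lar1 = log(p[["ar1"]]), lar2 = log(p[["ar2"]]),
    A = unname(p["A"]), ltA = log(p[["tA_ms"]]))
}
.fcs_from_opt <- function(q) {
  c(G0 = unname(q[["G0"]]), N = exp(q[["lN"]]), R = unname(q[["R"]]),
    td1_ms = exp(q[["ltd1"]]), td2_ms = exp(q[["ltd2"]]),
    ar1 = exp(q[["lar1"]]), ar2 = exp(q[["lar2"]]),
    A = unname(q[["A"]]), tA_ms = exp(q[["ltA"]]))
}

#' Fit the two-component FCS model to a correlation curve
#'
#' Damped least-squares (Levenberg-Marquardt) fit of \code{\link{fcsModel}}
#' to g2 - 1 over the requested lag range, weighted by the curve's per-lag
#' sigma when available. Parameters named in \code{fixed} are held at their
#' initial values (e.g. a dye/monomer diffusion time fitted globally across
#' a titration); axial ratios default to 5 and are fixed unless listed in
#' \code{free}. Component ordering td2 >= td1 is enforced by swapping after
#' the fit. Magnitudes of R and A are reported.
#'
#' @param curve a \linkS4class{CorrelationCurve}.
#' @param fixed named numeric of parameters to fix (e.g.
#'   \code{c(td1_ms = 0.3)}).
#' @param init optional named numeric of initial values; defaults: td1 from
#'   the curve half-decay, td2 = 10 td1, R = 0.5, A = 0.1, tA = 10 td2,
#'   N from the zero-lag amplitude, G0 = 0 (the fit surface is multimodal,
#'   so initialization is documented and overridable).
#' @param range_ms lag range fitted (ms), default 1e-4 to 1e2.
#' @param free parameters to free in addition to the defaults (e.g.
#'   \code{"ar1"}).
#' @return An \linkS4class{FcsFit}. Non-convergence is reported on the
#'   object (last iterate, \code{converged = FALSE}); diffusion times at the
#'   lag-range bounds are flagged in \code{at_bounds}.
#' @export
fitFcs <- function(curve, fixed = NULL, init = NULL,
                   range_ms = c(1e-4, 1e2), free = character()) {
  stopifnot(is(curve, "CorrelationCurve"))
  tc_all <- curve@lag * 1e3
  sel <- tc_all >= range_ms[1] & tc_all <= range_ms[2]
  if (sum(sel) < 8) stop("too few lags in the requested range")
  tc <- tc_all[sel]
  y <- (if (curve@normalization == "g2") curve@g - 1 else curve@g)[sel]
  sig <- if (!is.null(curve@sigma)) pmax(curve@sigma[sel], 1e-12,
                                         na.rm = TRUE) else rep(1, length(tc))
  sig[!is.finite(sig)] <- stats::median(sig[is.finite(sig)])

  # default initialization
  amp <- max(stats::quantile(y, 0.98), 1e-6)
  half_idx <- which(y < amp / 2)[1]
  td1_0 <- if (is.na(half_idx)) stats::median(tc) else tc[half_idx] / 2
  td1_0 <- min(max(td1_0, range_ms[1] * 10), range_ms[2] / 100)
  p0 <- c(G0 = 0, N = 1 / amp, R = 0.5, td1_ms = td1_0,
          td2_ms = 10 * td1_0, ar1 = 5, ar2 = 5, A = 0.1,
          tA_ms = 100 * td1_0)
  if (!is.null(init)) p0[names(init)] <- init
  if (!is.null(fixed)) p0[names(fixed)] <- fixed
  fixed_names <- union(names(fixed), setdiff(c("ar1", "ar2"), free))
  fit_names <- setdiff(.fcs_par_names, fixed_names)

  q0 <- .fcs_to_opt(p0)
  opt_name <- c(G0 = "G0", N = "lN", R = "R", td1_ms = "ltd1",
                td2_ms = "ltd2", ar1 = "lar1", ar2 = "lar2", A = "A",
                tA_ms = "ltA")
  resid_fn <- function(qfree) {
    q <- q0
    q[opt_name[fit_names]] <- qfree
    (y - fcsModel(tc, .fcs_from_opt(q))) / sig
  }
  fit <- minpack.lm::nls.lm(
    par = q0[opt_name[fit_names]], fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 300))
  q <- q0
  q[opt_name[fit_names]] <- fit$par
  p <- .fcs_from_opt(q)
  p["R"] <- abs(p["R"]); p["A"] <- abs(p["A"])
  if (p["R"] > 1) p["R"] <- 1  # |1-|R|| form caps the useful range

  # standard errors from the LM Jacobian, mapped through the log transforms
  se <- stats::setNames(rep(NA_real_, length(.fcs_par_names)),
                        .fcs_par_names)
  cv <- try({
    s2 <- fit$deviance / max(1, length(tc) - length(fit$par))
    diag(solve(fit$hessian) * s2)
  }, silent = TRUE)
  if (!inherits(cv, "try-error") && all(is.finite(cv)) && all(cv >= 0)) {
    se_opt <- sqrt(cv)
    for (nm in fit_names) {
      v <- se_opt[[opt_name[nm]]]
      # log-scale parameters: delta method
      se[nm] <- if (opt_name[nm] %in% c("lN", "ltd1", "ltd2", "lar1",
                                        "lar2", "ltA")) v * p[[nm]] else v
    }
  }

  # enforce component ordering (fast dye/monomer first)
  if (p["td2_ms"] < p["td1_ms"]) {
    p[c("td1_ms", "td2_ms")] <- p[c("td2_ms", "td1_ms")]
    p[c("ar1", "ar2")] <- p[c("ar2", "ar1")]
    se[c("td1_ms", "td2_ms")] <- se[c("td2_ms", "td1_ms")]
    p["R"] <- 1 - p["R"]
  }
  at_bounds <- character()
  for (nm in c("td1_ms", "td2_ms"))
    if (p[nm] <= range_ms[1] * 1.05 || p[nm] >= range_ms[2] / 1.05)
      at_bounds <- c(at_bounds, nm)
  res <- (y - fcsModel(tc, p)) / sig
  new("FcsFit", par = p, se = se, fixed = fixed_names,
      residuals = res, lag_ms = tc,
      converged = fit$info %in% 1:4, at_bounds = at_bounds)
}

#' Runs-test statistic on late-lag weighted residuals
#'
#' Wald-Wolfowitz runs test on the signs of the weighted residuals at lags
#' beyond the slow diffusion time td2. Unmodelled slower components produce
#' long same-sign stretches, pushing the statistic outside the null band
#' (|z| > 1.96 at 5%). Invariant to residual scaling.
#'
#' @param fit an \linkS4class{FcsFit}.
#' @param beyond lags beyond this multiple of td2 enter the test
#'   (default 1).
#' @return list with \code{z}, \code{n_runs}, \code{n} and
#'   \code{outside_band} (logical at the 95% level).
#' @export
residualStructure <- function(fit, beyond = 1) {
  stopifnot(is(fit, "FcsFit"))
  sel <- fit@lag_ms > beyond * fit@par["td2_ms"]
  r <- fit@residuals[sel]
  r <- r[r != 0]
  n <- length(r)
  if (n < 8) stop("too few residuals beyond td2 for a runs test")
  s <- r > 0
  n1 <- sum(s); n2 <- n - n1
  runs <- 1 + sum(s[-1] != s[-n])
  if (n1 == 0 || n2 == 0)
    return(list(z = -Inf, n_runs = runs, n = n, outside_band = TRUE))
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  z <- (runs - mu) / sqrt(v)
  list(z = z, n_runs = runs, n = n, outside_band = abs(z) > 1.96)
}
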