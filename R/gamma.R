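#' Gamma-analysis acceptance criteria for DVH comparison
#'
#' @param delta_D Dose-to-agreement criterion as a fraction of the
#'   reference DVH's maximum dose (default 0.01 = 1 percent).
#' @param delta_V Volume-difference criterion as a fraction of the total
#'   structure volume (default 0.01).
#' @param pass_threshold Fraction of reference points required to have
#'   gamma <= 1 for the comparison to pass (default 0.95).
#' @return An object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(delta_D = 0.01, delta_V = 0.01,
                           pass_threshold = 0.95) {
  if (delta_D <= 0 || delta_V <= 0)
    abort_isodvh("delta_D and delta_V must be > 0", "invalid_parameter")
  if (pass_threshold <= 0 || pass_threshold > 1)
    abort_isodvh("pass_threshold must be in (0, 1]", "invalid_parameter")
  structure(list(delta_D = delta_D, delta_V = delta_V,
                 pass_threshold = pass_threshold), class = "gamma_criteria")
}

# Sampled cumulative curve of a DVH: points at the occupied-bin edges.
gamma_curve_points <- function(x) {
  occ <- x$volume > 0
  if (!any(occ)) abort_isodvh("DVH has no occupied bins", "empty_structure")
  d <- sort(unique(c(x$bin_lower[occ], x$bin_upper[occ])))
  list(dose = d, volume = dvh_cum_at_dose(x, d))
}

densify_curve <- function(pts, oversample) {
  if (oversample <= 1L || length(pts$dose) < 2L) return(pts)
  d <- pts$dose; v <- pts$volume
  dd <- c(); vv <- c()
  for (i in seq_len(length(d) - 1L)) {
    t <- seq(0, 1, length.out = oversample + 1L)[-(oversample + 1L)]
    dd <- c(dd, d[i] + t * (d[i + 1] - d[i]))
    vv <- c(vv, v[i] + t * (v[i + 1] - v[i]))
  }
  list(dose = c(dd, d[length(d)]), volume = c(vv, v[length(v)]))
}

#' 1-D gamma analysis between two cumulative DVHs
#'
#' For each point \eqn{(D_r, V_r)} of the reference cumulative curve (one
#' per occupied reference bin edge), the gamma index is the minimum over
#' evaluated-curve points \eqn{(D_e, V_e)} of
#' \deqn{\gamma = \sqrt{\left(\frac{D_e - D_r}{\Delta D \cdot D_{max}}\right)^2
#'              + \left(\frac{V_e - V_r}{\Delta V \cdot V_{tot}}\right)^2},}
#' where \eqn{D_{max}} is the reference DVH's maximum dose and
#' \eqn{V_{tot}} its total volume.  The evaluated curve's sample points are
#' densified by `oversample`-fold linear interpolation before the minimum
#' search; reference points beyond the evaluated dose range are compared
#' against the nearest evaluated endpoint (which the minimum picks up
#' automatically).  A point passes when \eqn{\gamma \le 1}; the comparison
#' passes when the pass rate reaches the criteria's threshold.
#'
#' @param reference,evaluated [dvh()]s on the same dose scale.
#' @param criteria A [gamma_criteria()].
#' @param oversample Linear oversampling factor for the evaluated curve
#'   (1 = compare against the evaluated sample points only).
#' @return An object of class `gamma_result`: list with `dose`, `gamma`
#'   (per reference point), `pass_rate`, `pass`, and the `criteria`.
#' @export
gamma_dvh <- function(reference, evaluated, criteria = gamma_criteria(),
                      oversample = 10L) {
  stopifnot(inherits(reference, "dvh"), inherits(evaluated, "dvh"),
            inherits(criteria, "gamma_criteria"))
  if (reference$scale != evaluated$scale)
    abort_isodvh(sprintf("scale mismatch: reference is %s, evaluated is %s",
                         reference$scale, evaluated$scale), "unit")
  ref <- gamma_curve_points(reference)
  ev <- densify_curve(gamma_curve_points(evaluated), as.integer(oversample))
  dmax <- max(ref$dose)
  if (dmax <= 0)
    abort_isodvh("reference maximum dose must be > 0", "invalid_parameter")
  vtot <- sum(reference$volume)
  dD <- criteria$delta_D * dmax
  dV <- criteria$delta_V * vtot
  g <- vapply(seq_along(ref$dose), function(i)
    sqrt(min(((ev$dose - ref$dose[i]) / dD)^2 +
             ((ev$volume - ref$volume[i]) / dV)^2)),
    numeric(1))
  pass_rate <- mean(g <= 1 + 1e-9)   # numeric tolerance at the boundary
  structure(list(dose = ref$dose, gamma = g, pass_rate = pass_rate,
                 pass = pass_rate >= criteria$pass_threshold,
                 criteria = criteria),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %d reference points, pass rate %.1f%% (threshold %.0f%%): %s\n",
              length(x$gamma), 100 * x$pass_rate,
              100 * x$criteria$pass_threshold,
              if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  gamma: median %.3g, max %.3g\n", stats::median(x$gamma),
              max(x$gamma)))
  invisible(x)
}
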