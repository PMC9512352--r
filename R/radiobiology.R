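#' Schedule summary for a block of fractions
#'
#' Scalar description of a fractionation schedule (or a contiguous segment of
#' one): number of fractions `N`, dose per fraction `d` (Gy), overall
#' treatment time `T` in calendar days (counted inclusively from first to
#' last session, weekends and gap days included), the number of treatment
#' days `TD` on which two fractions were given, and the interfraction
#' interval `m` (hours) for same-day fractions.
#'
#' @param N Number of fractions (>= 0).
#' @param d Dose per fraction in Gy.
#' @param T Overall treatment time in calendar days (>= 1 when N >= 1).
#'   For a segment of a longer course this is the cumulative overall time at
#'   the end of the segment, counted from the first day of the whole course.
#' @param TD Number of twice-daily treatment days (0 <= TD <= floor(N/2)).
#' @param m Interfraction interval in hours for same-day fractions.
#' @return An object of class `schedule_summary`.
#' @export
schedule_summary <- function(N, d, T, TD = 0, m = 6) {
  if (!is.numeric(N) || length(N) != 1L || N < 0 || N != round(N))
    abort_isodvh("N must be a single non-negative integer", "invalid_parameter")
  if (!is.numeric(d) || length(d) != 1L || d < 0)
    abort_isodvh("d must be a single non-negative dose", "invalid_parameter")
  if (N >= 1 && (!is.numeric(T) || T < 1))
    abort_isodvh("T must be >= 1 calendar day when N >= 1", "invalid_parameter")
  if (TD < 0 || TD > floor(N / 2) || TD != round(TD))
    abort_isodvh("TD must satisfy 0 <= TD <= floor(N/2)", "invalid_parameter")
  if (TD > 0 && (!is.numeric(m) || m <= 0))
    abort_isodvh("m must be > 0 hours when TD > 0", "invalid_parameter")
  structure(list(N = as.integer(N), d = d, T = T, TD = as.integer(TD), m = m),
            class = "schedule_summary")
}

#' Biologically effective dose value
#'
#' A BED carries the \eqn{\alpha/\beta} of the tissue it was computed for in
#' its unit subscript (Gy\out{<sub>}10\out{</sub>}, Gy\out{<sub>}3\out{</sub>},
#' ...).  Addition and subtraction are only defined between values with the
#' same subscript; mixing subscripts raises a unit error.  Negative values
#' are legal: a short post-gap segment can lose more dose to repopulation
#' than it delivers.
#'
#' @param value BED in Gy (may be negative).
#' @param alpha_beta_tag The \eqn{\alpha/\beta} (Gy) identifying the unit.
#' @return An object of class `bed_value`.
#' @export
bed_value <- function(value, alpha_beta_tag) {
  if (!is.numeric(value) || !is.numeric(alpha_beta_tag) || alpha_beta_tag <= 0)
    abort_isodvh("bed_value needs a numeric value and a positive alpha/beta tag",
                 "invalid_parameter")
  structure(list(value = as.numeric(value),
                 alpha_beta_tag = as.numeric(alpha_beta_tag)),
            class = "bed_value")
}

#' @export
print.bed_value <- function(x, ...) {
  cat(sprintf("%.1f Gy[%g]\n", x$value, x$alpha_beta_tag))
  invisible(x)
}

#' @export
Ops.bed_value <- function(e1, e2) {
  if (!.Generic %in% c("+", "-"))
    abort_isodvh(paste("operation", .Generic, "not defined for bed_value"),
                 "unit")
  if (missing(e2)) {  # unary
    return(bed_value(get(.Generic)(e1$value), e1$alpha_beta_tag))
  }
  v1 <- if (inherits(e1, "bed_value")) e1 else bed_value(e1, e2$alpha_beta_tag)
  v2 <- if (inherits(e2, "bed_value")) e2 else bed_value(e2, e1$alpha_beta_tag)
  if (v1$alpha_beta_tag != v2$alpha_beta_tag)
    abort_isodvh(sprintf("cannot combine BED values with different subscripts (Gy[%g] vs Gy[%g])",
                         v1$alpha_beta_tag, v2$alpha_beta_tag), "unit")
  bed_value(get(.Generic)(v1$value, v2$value), v1$alpha_beta_tag)
}

#' Incomplete-repair factor for twice-daily fractionation
#'
#' When two fractions are delivered on the same day, sublethal damage from
#' the first fraction is only partially repaired before the second, which
#' appears as an increase in the biologically effective dose.  With a
#' mono-exponential repair model of half-time \eqn{T_{1/2}} and interfraction
#' interval \eqn{m}, the factor is \eqn{h = 2^{-m/T_{1/2}}}.  Repair is
#' considered complete for intervals longer than 8 hours, where `h` is
#' exactly 0.
#'
#' @param repair_half_time Repair half-time in hours (> 0).
#' @param interval Interfraction interval in hours (> 0).
#' @return The dimensionless factor `h` in [0, 1).
#' @examples
#' incomplete_repair_factor(2, 6)   # 0.125
#' incomplete_repair_factor(2, 9)   # 0: interval beyond 8 h
#' @export
incomplete_repair_factor <- function(repair_half_time, interval) {
  if (!is.numeric(repair_half_time) || any(repair_half_time <= 0))
    abort_isodvh("repair_half_time must be > 0", "invalid_parameter")
  if (!is.numeric(interval) || any(interval <= 0))
    abort_isodvh("interval must be > 0", "invalid_parameter")
  ifelse(interval > 8, 0, 2^(-interval / repair_half_time))
}

#' Dose lost to tumor repopulation
#'
#' Once the overall treatment time `T` exceeds the onset lag
#' \eqn{T_{delay}}, rapid cell repopulation removes `K` Gy of biologically
#' effective dose per calendar day: the loss is
#' \eqn{\max(0, K (T - T_{delay}))}.  Before onset the loss is exactly zero.
#' OAR parameter sets have `K = 0` and therefore no loss.
#'
#' @param params [tissue_params()].
#' @param T Overall treatment time in calendar days (vectorized).
#' @return Dose lost, in Gy on the BED scale (>= 0).
#' @export
repopulation_loss <- function(params, T) {
  stopifnot(inherits(params, "tissue_params"))
  if (any(T < 0))
    abort_isodvh("T must be >= 0", "invalid_parameter")
  pmax(0, params$K * (T - params$T_delay))
}

#' Scalar biologically effective dose with repopulation correction
#'
#' Evaluates the linear-quadratic BED of a uniform schedule,
#' \deqn{BED = N d \left(1 + \frac{d (1 + h)}{\alpha/\beta}\right) - K (T - T_{delay})_+,}
#' where the repopulation term applies to tumor tissue only.  `h` is the
#' incomplete-repair factor applying to the whole schedule; for mixed
#' schedules where only some fractions are closely spaced use
#' [session_groups_for()] together with [convert_dvh()] or sum per-segment
#' values from [segment_bed()].
#'
#' @param total_dose Total physical dose in Gy; must equal `N * d` within
#'   rounding tolerance.
#' @param schedule [schedule_summary()].
#' @param params [tissue_params()].
#' @param h Incomplete-repair factor (default 0; tumors use 0 since repair
#'   is essentially complete after the minimum 6 h interval).
#' @return A [bed_value()] tagged with the tissue's \eqn{\alpha/\beta}.
#' @examples
#' c1 <- tissue_params("PTV", 10, "tumor", K = 0.9, T_delay = 28)
#' bed_scalar(70, schedule_summary(35, 2, 50), c1)  # 64.2 Gy[10]
#' @export
bed_scalar <- function(total_dose, schedule, params, h = 0) {
  stopifnot(inherits(schedule, "schedule_summary"),
            inherits(params, "tissue_params"))
  if (schedule$N < 1)
    abort_isodvh("schedule must have N >= 1", "invalid_parameter")
  if (abs(total_dose - schedule$N * schedule$d) >
      1e-6 * max(1, abs(total_dose)))
    abort_isodvh(sprintf("total_dose (%g) inconsistent with N*d (%g)",
                         total_dose, schedule$N * schedule$d), "consistency")
  lq <- total_dose * (1 + schedule$d * (1 + h) / params$alpha_beta)
  loss <- if (params$tissue_class == "tumor")
    repopulation_loss(params, schedule$T) else 0
  bed_value(lq - loss, params$alpha_beta)
}

#' Convert BED to EQD2
#'
#' EQD2 is the total dose in conventional 2-Gy fractions producing the same
#' biological effect: \eqn{EQD_2 = BED / (1 + 2 / (\alpha/\beta))}.  The
#' conversion is sign-preserving; negative BED maps to negative EQD2.
#'
#' @param bed A [bed_value()] whose tag matches `params$alpha_beta`.
#' @param params [tissue_params()].
#' @return EQD2 in Gy (plain numeric).
#' @export
eqd2_from_bed <- function(bed, params) {
  stopifnot(inherits(params, "tissue_params"))
  if (inherits(bed, "bed_value")) {
    if (bed$alpha_beta_tag != params$alpha_beta)
      abort_isodvh(sprintf("BED tag Gy[%g] does not match tissue alpha/beta %g",
                           bed$alpha_beta_tag, params$alpha_beta), "unit")
    bed <- bed$value
  }
  bed / (1 + 2 / params$alpha_beta)
}

#' Repopulation-corrected BED of one plan segment
#'
#' A treatment course interrupted by a gap is accounted as contiguous
#' segments (pre-gap, post-gap, compensation).  Repopulation loss is
#' attributed cumulatively: the loss carried by a segment ending at overall
#' time `T` is the cumulative loss at `T` minus the loss already attributed
#' to earlier segments (`prior_loss`).  A segment ending before
#' \eqn{T_{delay}} therefore carries zero loss, and a short post-gap segment
#' can come out negative when the gap pushed the course deep into the
#' repopulation regime.
#'
#' @param segment_dose Physical dose of the segment in Gy (`N * d`).
#' @param segment [schedule_summary()] whose `T` is the cumulative overall
#'   time (days from the start of the whole course) at the segment's end.
#' @param params [tissue_params()].
#' @param prior_loss Loss (Gy, BED scale) already attributed to earlier
#'   segments; must not exceed the cumulative loss at this segment's end.
#' @param h Incomplete-repair factor for this segment's fractions.
#' @return A [bed_value()]; may be negative.
#' @examples
#' c1 <- tissue_params("PTV", 10, "tumor", K = 0.9, T_delay = 28)
#' # 4 x 2 Gy ending on day 59 after a pre-gap block ending day 46:
#' segment_bed(8, schedule_summary(4, 2, 59), c1,
#'             prior_loss = repopulation_loss(c1, 46))  # -2.1 Gy[10]
#' @export
segment_bed <- function(segment_dose, segment, params, prior_loss = 0, h = 0) {
  stopifnot(inherits(segment, "schedule_summary"),
            inherits(params, "tissue_params"))
  if (prior_loss < 0)
    abort_isodvh("prior_loss must be >= 0", "invalid_parameter")
  if (abs(segment_dose - segment$N * segment$d) >
      1e-6 * max(1, abs(segment_dose)))
    abort_isodvh(sprintf("segment_dose (%g) inconsistent with N*d (%g)",
                         segment_dose, segment$N * segment$d), "consistency")
  loss_end <- if (params$tissue_class == "tumor")
    repopulation_loss(params, segment$T) else 0
  if (prior_loss > loss_end + 1e-9)
    abort_isodvh(sprintf("prior_loss (%g) exceeds cumulative loss (%g) at segment end",
                         prior_loss, loss_end), "consistency")
  lq <- segment_dose * (1 + segment$d * (1 + h) / params$alpha_beta)
  bed_value(lq - (loss_end - prior_loss), params$alpha_beta)
}

#' Session groups for a mixed once-/twice-daily schedule
#'
#' The per-bin converter applies the incomplete-repair factor per group of
#' fractions: fractions on once-daily days are separated by ~24 h (h = 0)
#' while the `2 * TD` fractions on twice-daily days are separated by
#' `schedule$m` hours.  For tumor tissue repair is taken as complete after
#' the minimum recommended 6 h interval, so h = 0 for all groups.
#'
#' @param schedule [schedule_summary()].
#' @param params [tissue_params()].
#' @return A data.frame with columns `n` (fraction count) and `h`, with
#'   `sum(n) == schedule$N`.
#' @export
session_groups_for <- function(schedule, params) {
  stopifnot(inherits(schedule, "schedule_summary"),
            inherits(params, "tissue_params"))
  n_bid <- 2L * schedule$TD
  h_bid <- if (params$tissue_class == "tumor") 0
           else incomplete_repair_factor(params$repair_half_time, schedule$m)
  g <- data.frame(n = c(schedule$N - n_bid, n_bid), h = c(0, h_bid))
  g[g$n > 0L, , drop = FALSE]
}

#' Scalar dose map underlying the per-bin converter
#'
#' Maps a physical structure dose `D` (the dose a DVH bin reports for the
#' whole course) to its repopulation-corrected EQD2 under a schedule of `N`
#' fractions: the variable dose per fraction is `D / N`, each session group
#' `g` (with `n_g` fractions and incomplete-repair factor `h_g`) contributes
#' \deqn{D \frac{n_g}{N}\left(1 + \frac{(D/N)(1+h_g)}{\alpha/\beta}\right),}
#' the tumor repopulation loss is subtracted from the summed BED, and the
#' result is scaled by \eqn{1/(1 + 2/(\alpha/\beta))}.  With a single group
#' this reduces to the uniform-schedule formula of [bed_scalar()].
#'
#' @param D Physical dose(s) in Gy (vectorized).
#' @param schedule [schedule_summary()].
#' @param params [tissue_params()].
#' @param session_groups Optional data.frame with columns `n`, `h`;
#'   defaults to [session_groups_for()].  `sum(n)` must equal `schedule$N`.
#' @return EQD2 value(s) in Gy; strictly increasing in `D`.
#' @export
eqd2_convert_dose <- function(D, schedule, params, session_groups = NULL) {
  stopifnot(inherits(schedule, "schedule_summary"),
            inherits(params, "tissue_params"))
  if (schedule$N < 1)
    abort_isodvh("schedule must have N >= 1", "invalid_parameter")
  g <- session_groups %||% session_groups_for(schedule, params)
  if (sum(g$n) != schedule$N)
    abort_isodvh(sprintf("session group fractions (%d) do not sum to N (%d)",
                         sum(g$n), schedule$N), "session_group")
  N <- schedule$N
  ab <- params$alpha_beta
  bed <- rep(0, length(D))
  for (k in seq_len(nrow(g)))
    bed <- bed + D * (g$n[k] / N) * (1 + (D / N) * (1 + g$h[k]) / ab)
  if (params$tissue_class == "tumor")
    bed <- bed - repopulation_loss(params, schedule$T)
  bed / (1 + 2 / ab)
}

#' Convert a physical DVH to a repopulation-corrected EQD2 DVH
#'
#' Applies [eqd2_convert_dose()] to the dose axis of a physical-dose DVH:
#' every bin edge is mapped through the (monotone) conversion, bin volumes
#' are unchanged, and the result is tagged `EQD2` with the tissue's
#' \eqn{\alpha/\beta}.  The repopulation loss (tumor only) shifts every
#' bin's BED uniformly, so low-dose bins may map to negative EQD2; negative
#' values are preserved.
#'
#' @inheritParams eqd2_convert_dose
#' @param dvh A [dvh()] on the physical-dose scale.
#' @return A [dvh()] on the EQD2 scale.
#' @export
convert_dvh <- function(dvh, schedule, params, session_groups = NULL) {
  stopifnot(inherits(dvh, "dvh"))
  if (dvh$scale != "physical")
    abort_isodvh("convert_dvh expects a physical-dose DVH", "unit")
  if (length(dvh$volume) == 0L)
    return(dvh_new(numeric(0), numeric(0), numeric(0), dvh$structure,
                   scale = "EQD2", alpha_beta_tag = params$alpha_beta,
                   volume_unit = dvh$volume_unit))
  lo <- eqd2_convert_dose(dvh$bin_lower, schedule, params, session_groups)
  hi <- eqd2_convert_dose(dvh$bin_upper, schedule, params, session_groups)
  dvh_new(dvh$volume, lo, hi, dvh$structure, scale = "EQD2",
          alpha_beta_tag = params$alpha_beta, volume_unit = dvh$volume_unit)
}
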