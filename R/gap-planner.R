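#' Plan segment
#'
#' A contiguous block of fractions within a treatment course (pre-gap,
#' post-gap, or a compensation block) with its own dose per fraction, a
#' cumulative overall time at the block's end, and optionally its own
#' twice-daily day count.
#'
#' @param label Segment label (e.g. `"pre-gap"`).
#' @param n Number of fractions in the segment.
#' @param d Dose per fraction (Gy).
#' @param t_end Cumulative overall treatment time (days from the first day
#'   of the whole course) at the end of this segment.
#' @param TD Twice-daily treatment days within the segment.
#' @param m Same-day interfraction interval (hours).
#' @return An object of class `plan_segment`.
#' @export
plan_segment <- function(label, n, d, t_end, TD = 0, m = 6) {
  s <- schedule_summary(n, d, t_end, TD = TD, m = m)
  structure(list(label = as.character(label), schedule = s),
            class = "plan_segment")
}

segment_groups <- function(seg, params) {
  session_groups_for(seg$schedule, params)
}

#' Evaluate a (possibly interrupted or revised) plan
#'
#' Produces the per-segment and whole-plan accounting used for plan
#' comparison: for each segment the physical dose, `d`, `N`, cumulative `T`,
#' repopulation-corrected BED and EQD2 (loss attributed cumulatively:
#' each segment carries the loss accrued between the previous segment's end
#' and its own), the cumulative dose lost, and -- when a reference plan is
#' given -- the BED/EQD2 difference (reference minus this plan).
#'
#' In DVH mode (a physical-dose DVH supplied), each segment's share of the
#' distribution is the plan DVH scaled by its fraction of the plan's
#' physical dose, converted per-bin with the segment's session groups, and
#' the per-segment EQD2 histograms are summed bin-wise; the summary then
#' also reports EQD2 DVH statistics (default `D98%`).
#'
#' @param segments List of [plan_segment()]s, contiguous and in time order
#'   (strictly increasing `t_end`).
#' @param params [tissue_params()] of the structure being scored.
#' @param reference Optional reference plan for the difference row: either
#'   another list of [plan_segment()]s or the result of a previous
#'   `evaluate_plan()` call.
#' @param dvh Optional physical-dose [dvh()] of this plan's full course
#'   (dose axis = total physical dose of all segments).
#' @param headline DVH statistic reported per plan in DVH mode.
#' @return An object of class `plan_evaluation`: a list with `table` (the
#'   per-segment + total rows), `bed`, `eqd2`, `dose_lost`, and in DVH mode
#'   `eqd2_dvh` and `headline` (named value).
#' @export
evaluate_plan <- function(segments, params, reference = NULL, dvh = NULL,
                          headline = "D98%") {
  stopifnot(inherits(params, "tissue_params"))
  if (length(segments) == 0L)
    abort_isodvh("at least one segment is required", "calendar")
  t_ends <- vapply(segments, function(s) s$schedule$T, numeric(1))
  if (any(diff(t_ends) <= 0))
    abort_isodvh("segments must be contiguous with strictly increasing end times",
                 "calendar")
  rows <- list(); prior_loss <- 0
  beds <- numeric(length(segments))
  for (i in seq_along(segments)) {
    seg <- segments[[i]]; sch <- seg$schedule
    g <- segment_groups(seg, params)
    h_seg <- sum(g$n * g$h) / sum(g$n)   # fraction-weighted factor
    b <- segment_bed(sch$N * sch$d, sch, params, prior_loss = prior_loss,
                     h = h_seg)
    loss_end <- if (params$tissue_class == "tumor")
      repopulation_loss(params, sch$T) else 0
    beds[i] <- b$value
    rows[[i]] <- data.frame(row = seg$label, physical_dose = sch$N * sch$d,
                            d = sch$d, N = sch$N, T = sch$T,
                            BED = b$value,
                            EQD2 = eqd2_from_bed(b, params),
                            dose_lost = loss_end - prior_loss)
    prior_loss <- loss_end
  }
  total_bed <- sum(beds)
  last <- segments[[length(segments)]]$schedule
  total_loss <- if (params$tissue_class == "tumor")
    repopulation_loss(params, last$T) else 0
  rows[[length(rows) + 1L]] <-
    data.frame(row = "plan",
               physical_dose = sum(vapply(segments, function(s)
                 s$schedule$N * s$schedule$d, numeric(1))),
               d = NA_real_,
               N = sum(vapply(segments, function(s) s$schedule$N,
                              integer(1))),
               T = last$T, BED = total_bed,
               EQD2 = total_bed / (1 + 2 / params$alpha_beta),
               dose_lost = total_loss)
  tab <- do.call(rbind, rows)
  out <- list(table = tab, bed = total_bed,
              eqd2 = total_bed / (1 + 2 / params$alpha_beta),
              dose_lost = total_loss, params = params)
  if (!is.null(reference)) {
    ref <- if (inherits(reference, "plan_evaluation")) reference
           else evaluate_plan(reference, params)
    out$diff_bed <- ref$bed - out$bed
    out$diff_eqd2 <- ref$eqd2 - out$eqd2
  }
  if (!is.null(dvh)) {
    stopifnot(inherits(dvh, "dvh"))
    plan_dose <- sum(vapply(segments, function(s)
      s$schedule$N * s$schedule$d, numeric(1)))
    prior_loss <- 0
    seg_dvhs <- list()
    for (i in seq_along(segments)) {
      seg <- segments[[i]]; sch <- seg$schedule
      seg_dose <- sch$N * sch$d
      seg_phys <- scale_dvh(dvh, seg_dose / plan_dose)
      # per-segment conversion: loss share = loss(t_end) - prior_loss
      loss_end <- if (params$tissue_class == "tumor")
        repopulation_loss(params, sch$T) else 0
      noloss <- if (params$tissue_class == "tumor") {
        p <- params; p$K <- 0; p
      } else params
      conv <- convert_dvh(seg_phys, sch, noloss,
                          session_groups = segment_groups(seg, params))
      share <- (loss_end - prior_loss) / (1 + 2 / params$alpha_beta)
      conv$bin_lower <- conv$bin_lower - share
      conv$bin_upper <- conv$bin_upper - share
      seg_dvhs[[i]] <- conv
      prior_loss <- loss_end
    }
    out$eqd2_dvh <- sum_dvh_dose(seg_dvhs)
    out$headline <- stats::setNames(dvh_statistic(out$eqd2_dvh, headline),
                                    headline)
  }
  class(out) <- "plan_evaluation"
  out
}

#' @export
print.plan_evaluation <- function(x, ...) {
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round_report)  # 1 d.p., half away from zero
  print.data.frame(tab, row.names = FALSE)
  if (!is.null(x$diff_bed))
    cat(sprintf("difference (reference - plan): BED %.1f Gy[%g], EQD2 %.1f Gy[%g]\n",
                x$diff_bed, x$params$alpha_beta,
                x$diff_eqd2, x$params$alpha_beta))
  if (!is.null(x$headline))
    cat(sprintf("%s (EQD2): %.1f Gy[%g]\n", names(x$headline), x$headline,
                x$params$alpha_beta))
  invisible(x)
}

#' Point-dose gap calculation (current standard method)
#'
#' Represents a whole structure by a single dose per fraction, as in the
#' standard gap-compensation methodology: the scalar BED/EQD2 of the
#' schedule evaluated at that point dose.  Exposed side by side with the
#' DVH-based converter; for OARs the point dose is typically chosen at or
#' above the near-maximum dose, which overestimates the dose to most of the
#' organ.
#'
#' @param dose_per_fraction Point dose per fraction (Gy).
#' @param schedule [schedule_summary()].
#' @param params [tissue_params()].
#' @param h Incomplete-repair factor (default from the schedule's
#'   twice-daily fraction share via [session_groups_for()]).
#' @return A list with `bed` ([bed_value()]) and `eqd2` (numeric).
#' @export
point_dose_rcr <- function(dose_per_fraction, schedule, params, h = NULL) {
  if (is.null(h)) {
    g <- session_groups_for(schedule, params)
    h <- sum(g$n * g$h) / sum(g$n)
  }
  sch <- schedule_summary(schedule$N, dose_per_fraction, schedule$T,
                          TD = schedule$TD, m = schedule$m)
  b <- bed_scalar(sch$N * sch$d, sch, params, h = h)
  list(bed = b, eqd2 = eqd2_from_bed(b, params))
}
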