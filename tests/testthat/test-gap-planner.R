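test_that("overall time counts calendar days inclusively", {
  expect_equal(overall_time(treatment_calendar("2021-05-03")), 1)
  expect_equal(overall_time(treatment_calendar(c("2021-05-03", "2021-05-16"))),
               14)
  expect_error(overall_time(treatment_calendar(as.Date(character()))),
               class = "isodvh_error_calendar")
  # 35 weekday fractions from Mon 2021-04-26 with a 13-day interruption:
  # 6 delivered pre-gap, the rest resume on 2021-05-17 and end 2021-06-24
  gap_days <- seq(as.Date("2021-05-04"), by = 1, length.out = 13)
  cal <- make_calendar("2021-04-26", 35, 2, gap = gap_days)
  expect_equal(overall_time(cal), 60)
  expect_equal(calendar_summary(cal)$N, 35)
  expect_false(any(cal$date %in% gap_days))
  expect_equal(sum(cal$date < min(gap_days)), 6)
})

test_that("schedule validation flags weekly limit, consecutive BID and short intervals", {
  # 6 fx/week with alternating BID days: compliant
  ok <- make_calendar("2021-06-07", 8, 2, weekdays = c(1, 3, 5),
                      bid_dates = as.Date(c("2021-06-07", "2021-06-09")))
  expect_equal(nrow(validate_schedule(ok)), 0)
  # 7 fractions Monday-Sunday
  seven <- treatment_calendar(seq(as.Date("2021-06-07"), by = 1,
                                  length.out = 7))
  v <- validate_schedule(seven)
  expect_equal(v$rule, "weekly_limit")
  # twice daily on consecutive days
  bid2 <- treatment_calendar(rep(as.Date(c("2021-06-08", "2021-06-09")),
                                 each = 2),
                             time = c(9, 15, 9, 15))
  expect_true("consecutive_bid" %in% validate_schedule(bid2)$rule)
  # same-day interval below 6 h
  close2 <- treatment_calendar(rep(as.Date("2021-06-08"), 2), time = c(9, 13))
  expect_true("min_interval" %in% validate_schedule(close2)$rule)
  expect_error(treatment_calendar(rep(as.Date("2021-06-08"), 3),
                                  time = c(8, 12, 16)),
               class = "isodvh_error_calendar")
})

test_that("calendar summaries report N, T, TD and the minimum interval", {
  cal <- make_calendar("2021-06-07", 10, 2.2,
                       bid_dates = as.Date(c("2021-06-08", "2021-06-10")),
                       bid_interval = 7)
  s <- calendar_summary(cal)
  expect_equal(s$N, 10); expect_equal(s$d, 2.2)
  expect_equal(s$TD, 2); expect_equal(s$m, 7)
})

test_that("evaluate_plan reproduces the interrupted-course comparison rows", {
  cs <- build_case_study("C")
  intended <- evaluate_plan(list(
    plan_segment("intended", cs$intended$N, cs$intended$d, cs$intended$T)),
    cs$params)
  uncomp <- evaluate_plan(list(
    plan_segment("pre-gap", cs$pre_gap$N, cs$pre_gap$d, cs$pre_gap$T),
    plan_segment("post-gap", cs$post_gap$N, cs$post_gap$d, cs$post_gap$T)),
    cs$params, reference = intended)
  expect_equal(intended$bed, 64.2, tolerance = 1e-9)
  expect_equal(intended$eqd2, 53.5, tolerance = 1e-9)
  expect_equal(uncomp$bed, 52.5, tolerance = 1e-9)
  expect_equal(uncomp$eqd2, 43.75, tolerance = 1e-9)
  expect_equal(uncomp$diff_bed, 11.7, tolerance = 1e-9)
  expect_equal(uncomp$diff_eqd2, 9.75, tolerance = 1e-9)
  expect_equal(uncomp$dose_lost, 31.5, tolerance = 1e-9)
  tab <- uncomp$table
  expect_equal(tab$BED[tab$row == "pre-gap"], 14.4, tolerance = 1e-9)
  expect_equal(tab$dose_lost[tab$row == "pre-gap"], 0)
  # a plan compared with itself differs by exactly zero
  self <- evaluate_plan(list(
    plan_segment("intended", 35, 2, 50)), cs$params, reference = intended)
  expect_identical(self$diff_bed, 0)
  expect_identical(self$diff_eqd2, 0)
  expect_error(evaluate_plan(list(plan_segment("a", 5, 2, 10),
                                  plan_segment("b", 5, 2, 8)), cs$params),
               class = "isodvh_error_calendar")
})

test_that("DVH-mode evaluation agrees with scalar mode on uniform DVHs", {
  cs <- build_case_study("E")
  segs <- list(
    plan_segment("pre-gap", cs$pre_gap$N, cs$pre_gap$d, cs$pre_gap$T),
    plan_segment("post-gap", cs$post_gap$N, cs$post_gap$d, cs$post_gap$T))
  plan_dose <- (cs$pre_gap$N + cs$post_gap$N) * 2
  uniform <- point_dvh(plan_dose, 120, structure = "PTV")
  ev <- evaluate_plan(segs, cs$params, dvh = uniform, headline = "D50%")
  expect_equal(unname(ev$headline), ev$eqd2, tolerance = 1e-9)
  expect_equal(ev$eqd2_dvh$bin_lower, ev$eqd2, tolerance = 1e-9)
})

test_that("point-dose method matches bed_scalar and bounds the DVH near-max", {
  p <- c1_params()
  sch <- schedule_summary(35, 2, 50)
  pd <- point_dose_rcr(2, sch, p)
  expect_equal(pd$bed$value, bed_scalar(70, sch, p)$value)
  expect_equal(pd$eqd2, 53.5, tolerance = 1e-9)
  # gradient OAR: point dose at/above Dmax overestimates the D2% EQD2
  oar <- oar_params()
  osch <- schedule_summary(30, 2, 40)
  grad <- dvh(rep(1, 50), bin_lower = seq(20, 69, 1), bin_width = 1,
              structure = "oar")
  conv <- convert_dvh(grad, osch, oar)
  d2 <- dvh_statistic(conv, "D2%")
  worst <- point_dose_rcr(dvh_statistic(grad, "Dmax") / osch$N, osch, oar)
  expect_gte(worst$eqd2, d2)
})

test_that("shorter overall time never decreases PTV EQD2; dose and TD raise OAR EQD2", {
  p <- c1_params()
  # monotone in T beyond T_delay (fixed N, d)
  eq <- vapply(seq(63, 35, by = -1), function(T)
    eqd2_from_bed(bed_scalar(58, schedule_summary(29, 2, T), p), p),
    numeric(1))
  expect_true(all(diff(eq) >= -1e-12))
  # OAR EQD2 strictly increasing in d at fixed N
  oar <- oar_params()
  eq_d <- vapply(seq(1.8, 2.6, by = 0.1), function(d)
    eqd2_from_bed(bed_scalar(29 * d, schedule_summary(29, d, 40), oar), oar),
    numeric(1))
  expect_true(all(diff(eq_d) > 0))
  # OAR D2% strictly increasing in TD (direction of the stepwise mechanism)
  grad <- dvh(rep(2, 40), bin_lower = seq(30, 69.25, length.out = 40),
              bin_width = 0.5)
  d2 <- vapply(0:4, function(td) {
    sch <- schedule_summary(29, 2, 40, TD = td, m = 6)
    dvh_statistic(convert_dvh(grad, sch, oar), "D2%")
  }, numeric(1))
  expect_true(all(diff(d2) > 0))
})
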