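test_that("incomplete repair factor follows mono-exponential repair with 8 h cutoff", {
  expect_equal(incomplete_repair_factor(2, 6), 0.125)
  expect_equal(incomplete_repair_factor(2, 2), 0.5)    # one half-time
  expect_equal(incomplete_repair_factor(2, 9), 0)      # > 8 h: repair complete
  expect_equal(incomplete_repair_factor(3, 3), 0.5)
  # limits: h -> 0 as the interval grows, 0.125 at three half-times
  expect_equal(incomplete_repair_factor(1, 3), 0.125)
  expect_lt(incomplete_repair_factor(2, 7.9), incomplete_repair_factor(2, 6))
  expect_error(incomplete_repair_factor(0, 6),
               class = "isodvh_error_invalid_parameter")
  expect_error(incomplete_repair_factor(2, -1),
               class = "isodvh_error_invalid_parameter")
})

test_that("repopulation loss is clamped at zero before onset", {
  p <- c1_params()
  expect_equal(repopulation_loss(p, 26), 0)
  expect_equal(repopulation_loss(p, 28), 0)
  expect_equal(repopulation_loss(p, 47), 17.1)
  expect_equal(repopulation_loss(p, 55), 24.3)
  # property: non-negative and zero for all T <= T_delay
  for (T in seq(0, 60, by = 2.5)) {
    l <- repopulation_loss(p, T)
    expect_gte(l, 0)
    if (T <= p$T_delay) expect_identical(l, 0)
  }
  expect_identical(repopulation_loss(oar_params(), 100), 0)  # K = 0
})

test_that("scalar BED reproduces the case-study plan values", {
  p <- c1_params()
  cases <- list(  # total dose, N, d, T, printed BED
    list(70, 35, 2, 50, 64.2),   # vocal cord / larynx intended
    list(60, 30, 2, 43, 58.5),   # parotid intended
    list(60, 30, 2, 44, 57.6),   # right lung intended
    list(62, 31, 2, 46, 58.2)    # larynx pre-gap block
  )
  for (cs in cases) {
    b <- bed_scalar(cs[[1]], schedule_summary(cs[[2]], cs[[3]], cs[[4]]), p)
    expect_equal(b$value, cs[[5]], tolerance = 1e-9)
    expect_equal(b$alpha_beta_tag, 10)
  }
  expect_error(bed_scalar(71, schedule_summary(35, 2, 50), p),
               class = "isodvh_error_consistency")
})

test_that("EQD2 conversion is the BED scaled by 1/(1 + 2/(alpha/beta)), sign-preserving", {
  p <- c1_params()
  expect_equal(eqd2_from_bed(bed_value(64.2, 10), p), 53.5)
  expect_equal(eqd2_from_bed(bed_value(52.5, 10), p), 43.75)
  expect_equal(eqd2_from_bed(bed_value(-2.1, 10), p), -1.75)
  expect_equal(eqd2_from_bed(bed_value(0, 10), p), 0)
  expect_error(eqd2_from_bed(bed_value(10, 3), p), class = "isodvh_error_unit")
})

test_that("BED arithmetic enforces matching unit subscripts", {
  a <- bed_value(10, 10); b <- bed_value(5, 10); c3 <- bed_value(5, 3)
  expect_equal((a + b)$value, 15)
  expect_equal((a - b)$value, 5)
  expect_error(a + c3, class = "isodvh_error_unit")
})

test_that("segment BED uses cumulative loss attribution and may be negative", {
  p <- c1_params()
  # post-gap 8 Gy in 4 fx ending day 59, pre-gap block ended day 46
  b <- segment_bed(8, schedule_summary(4, 2, 59), p,
                   prior_loss = repopulation_loss(p, 46))
  expect_equal(b$value, -2.1, tolerance = 1e-9)
  # pre-gap 12 Gy in 6 fx ending day 9 (< T_delay): pure LQ term
  b2 <- segment_bed(12, schedule_summary(6, 2, 9), p)
  expect_equal(b2$value, 14.4, tolerance = 1e-9)
  expect_error(segment_bed(12, schedule_summary(6, 2, 9), p, prior_loss = 5),
               class = "isodvh_error_consistency")
})

test_that("segment additivity: pre-gap + post-gap equals the whole delivered course", {
  p <- c1_params()
  for (label in c("C", "E")) {
    cs <- build_case_study(label)
    pre <- segment_bed(cs$pre_gap$N * cs$pre_gap$d, cs$pre_gap, p)
    post <- segment_bed(cs$post_gap$N * cs$post_gap$d, cs$post_gap, p,
                        prior_loss = repopulation_loss(p, cs$pre_gap$T))
    whole <- bed_scalar(
      (cs$pre_gap$N + cs$post_gap$N) * cs$pre_gap$d,
      schedule_summary(cs$pre_gap$N + cs$post_gap$N, cs$pre_gap$d,
                       cs$post_gap$T), p)
    expect_equal((pre + post)$value, whole$value, tolerance = 1e-12)
  }
})

test_that("2-Gy schedules with no repair penalty and no repopulation are EQD2 fixed points", {
  set.seed(42)
  p0 <- function(ab) tissue_params("S", ab, "tumor", K = 0, T_delay = 0)
  for (i in 1:200) {
    N <- sample(1:45, 1)
    ab <- runif(1, 1.5, 15)
    sch <- schedule_summary(N, 2, sample(1:80, 1))
    b <- bed_scalar(2 * N, sch, p0(ab))
    expect_lt(abs(eqd2_from_bed(b, p0(ab)) - 2 * N), 1e-10)
  }
})

test_that("per-bin conversion matches the fraction-by-fraction oracle", {
  # 3-bin toy DVH, mixed session groups: 2 of 10 fractions twice daily
  ab <- 3
  p <- tissue_params("OAR", ab, "oar")
  sch <- schedule_summary(10, 2, 12, TD = 1, m = 6)
  groups <- session_groups_for(sch, p)
  expect_equal(sum(groups$n), 10)
  expect_equal(groups$h[groups$n == 2], 0.125)
  for (D in c(10, 20, 30)) {
    expect_lt(abs(eqd2_convert_dose(D, sch, p, groups) -
                    oracle_eqd2(D, 10, ab, groups)), 1e-9)
  }
  # tumor with repopulation loss
  pt <- c1_params()
  scht <- schedule_summary(10, 2, 40)
  gt <- session_groups_for(scht, pt)
  loss <- repopulation_loss(pt, 40)
  for (D in c(5, 18, 33.3))
    expect_lt(abs(eqd2_convert_dose(D, scht, pt, gt) -
                    oracle_eqd2(D, 10, 10, gt, loss)), 1e-9)
})

test_that("convert_dvh on a single-bin DVH reproduces the scalar pipeline", {
  p <- c1_params()
  sch <- schedule_summary(35, 2, 50)
  d <- point_dvh(70, 100)
  out <- convert_dvh(d, sch, p)
  b <- bed_scalar(70, sch, p)
  expect_equal(out$bin_lower, eqd2_from_bed(b, p))
  expect_equal(out$bin_upper, out$bin_lower)
  expect_identical(out$volume, d$volume)
  expect_identical(out$scale, "EQD2")
  expect_equal(out$alpha_beta_tag, 10)
})

test_that("convert_dvh conserves volume, preserves negatives and is monotone in dose", {
  p <- c1_params()
  sch <- schedule_summary(30, 2, 50)
  phys <- dvh(c(5, 10, 30, 40, 15), bin_lower = c(0, 15, 30, 45, 58),
              bin_width = 1)
  out <- convert_dvh(phys, sch, p)
  expect_equal(sum(out$volume), sum(phys$volume))
  expect_true(all(diff(out$bin_lower) > 0))   # monotone map keeps order
  expect_lt(out$bin_lower[1], 0)              # loss pushes 0 Gy bin negative
  # session-group bookkeeping errors
  expect_error(convert_dvh(phys, sch, p,
                           session_groups = data.frame(n = 10, h = 0)),
               class = "isodvh_error_session_group")
  expect_error(convert_dvh(out, sch, p), class = "isodvh_error_unit")
})

test_that("tissue parameter invariants are enforced", {
  expect_error(tissue_params("x", 0, "tumor"),
               class = "isodvh_error_invalid_parameter")
  expect_error(tissue_params("x", 3, "oar", K = 0.5),
               class = "isodvh_error_invalid_parameter")
  expect_error(schedule_summary(10, 2, 5, TD = 6),
               class = "isodvh_error_invalid_parameter")
  presets <- tissue_presets()
  expect_setequal(names(presets), c("C1_tumor", "generic_oar", "spinal_cord"))
  expect_equal(presets$C1_tumor$K, 0.9)
  expect_equal(presets$C1_tumor$T_delay, 28)
  expect_equal(presets$spinal_cord$alpha_beta, 2)
})
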