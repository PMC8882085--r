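# PTT decomposition, cleavage efficiency, induction ratios, comparison table.

est <- function(P1, P3) ptt_estimate(list(P1 = P1, P3 = P3))

test_that("ptt_estimate decomposes P1 into FL and T", {
  e <- est(100, 25)
  expect_equal(e$T, 75)
  expect_equal(e$FL, 25)
  expect_equal(e$termination_fraction, 0.75)
  expect_equal(e$fl_to_t_ratio, 1 / 3)
  # boundary cases
  expect_equal(est(100, 100)$termination_fraction, 0)
  expect_equal(est(100, 0)$termination_fraction, 1)
  expect_true(is.na(est(100, 100)$fl_to_t_ratio))
  expect_error(est(0, 10), class = "pttq_data_error")
})

test_that("FL + T = P1 exactly over randomized inputs (conservation)", {
  set.seed(11)
  for (i in 1:200) {
    P1 <- stats::runif(1, 1e-3, 1e4)
    P3 <- stats::runif(1, 0, P1 * 1.2) # allow noisy P3 > P1
    e <- est(P1, P3)
    # exact up to one float rounding in P3 + (P1 - P3)
    expect_equal(e$FL + e$T, P1, tolerance = 1e-14)
    expect_identical(e$negative_T_flag, P3 > P1)
  }
})

test_that("negative T propagates flagged and is refused downstream", {
  e <- est(100, 120)
  expect_equal(e$T, -20) # reported as computed, not clamped
  expect_true(e$negative_T_flag)
  good <- est(100, 20)
  expect_error(induction_ratio(e, good), "negative", class = "pttq_data_error")
  expect_error(induction_ratio_star(good, e), "negative", class = "pttq_data_error")
})

test_that("cleavage efficiency is 1 - P2_with / P2_without, clamped", {
  expect_equal(as.numeric(cleavage_efficiency(0, 500)), 1)
  expect_equal(as.numeric(cleavage_efficiency(500, 500)), 0)
  expect_equal(as.numeric(cleavage_efficiency(15, 500)), 0.97)
  over <- cleavage_efficiency(600, 500)
  expect_equal(as.numeric(over), 0)
  expect_true(attr(over, "out_of_range"))
  expect_error(cleavage_efficiency(10, 0), class = "pttq_data_error")
})

test_that("induction ratios match the arithmetic oracles", {
  mm <- est(100, 80) # Met-: mostly full-length
  mp <- est(100, 20) # Met+: mostly terminated
  expect_equal(induction_ratio(mm, mp), 16)      # (80/20)/(20/80)
  expect_equal(induction_ratio_star(mm, mp), 4)  # 0.8/0.2
  # identical conditions give exactly 1
  expect_equal(induction_ratio(mm, mm), 1)
  expect_equal(induction_ratio_star(mp, mp), 1)
  # degenerate inputs are refused with a diagnostic naming the condition
  expect_error(induction_ratio(est(100, 100), mp), "T_Met-", class = "pttq_data_error")
  expect_error(induction_ratio(mm, est(100, 100)), "T_Met\\+", class = "pttq_data_error")
  expect_error(induction_ratio(est(100, 0), mp), "FL_Met-", class = "pttq_data_error")
  expect_warning(z <- induction_ratio_star(est(100, 0), mp), "IR\\* = 0")
  expect_equal(z, 0)
})

test_that("IR and IR* are scale invariant and ordered (IR >= IR*)", {
  set.seed(23)
  for (i in 1:200) {
    f_minus <- stats::runif(1, 0.02, 0.98)
    f_plus <- stats::runif(1, 0.02, 0.98)
    scale_m <- stats::runif(1, 0.1, 50)
    P1m <- stats::runif(1, 10, 1000)
    P1p <- stats::runif(1, 10, 1000)
    mm <- est(P1m, P1m * (1 - f_minus))
    mp <- est(P1p, P1p * (1 - f_plus))
    mm_s <- est(P1m * scale_m, P1m * scale_m * (1 - f_minus))
    ir <- induction_ratio(mm, mp)
    irs <- induction_ratio_star(mm, mp)
    # scaling all concentrations of one condition changes nothing
    expect_equal(induction_ratio(mm_s, mp), ir, tolerance = 1e-10)
    expect_equal(induction_ratio_star(mm_s, mp), irs, tolerance = 1e-10)
    # ordering: IR >= IR* iff termination is at least as high under Met+
    if (f_plus >= f_minus) {
      expect_gte(ir + 1e-12, irs)
    } else {
      expect_lte(ir - 1e-12, irs)
    }
    if (abs(f_plus - f_minus) < 1e-12) expect_equal(ir, irs)
  }
})

test_that("percent differences follow the printed-table rounding convention", {
  expect_equal(ir_percent_difference(17.38, 25.91)$rounded, 49)
  expect_equal(ir_percent_difference(18.79, 30.02)$rounded, 60)
  expect_equal(ir_percent_difference(3.3, 3.3)$rounded, 0)
  # round-half-away-from-zero, both signs
  expect_equal(round_half_away(c(0.5, 1.5, -0.5, -16.5, 2.4)), c(1, 2, -1, -17, 2))
  expect_error(ir_percent_difference(0, 5), class = "pttq_data_error")
})

test_that("summarize_cleavage_effect aggregates pairs and excludes controls", {
  single <- data.frame(gene = "metE", timepoint_h = 2,
                       ir_no_cleavage = 10, ir_cleavage = 12)
  s1 <- summarize_cleavage_effect(single)
  expect_equal(s1$mean_percent, 20)
  expect_equal(s1$max_percent, 20)

  sym <- data.frame(gene = c("a", "b"), timepoint_h = c(0, 0),
                    ir_no_cleavage = c(10, 10), ir_cleavage = c(11, 9))
  s2 <- summarize_cleavage_effect(sym, control_genes = character(0))
  expect_equal(s2$mean_percent, 0)
  expect_equal(s2$max_percent, 10)

  ctrl <- rbind(single, data.frame(gene = "gyrA", timepoint_h = 2,
                                   ir_no_cleavage = 1, ir_cleavage = 2))
  s3 <- summarize_cleavage_effect(ctrl)
  expect_equal(s3$mean_percent, 20) # gyrA excluded from the mean
  expect_true(s3$table$is_control[s3$table$gene == "gyrA"])

  expect_error(summarize_cleavage_effect(
    data.frame(gene = "a", timepoint_h = 0, ir_no_cleavage = NA, ir_cleavage = 2)),
    "unmatched", class = "pttq_data_error")
  expect_error(summarize_cleavage_effect(single, control_genes = "metE"),
               class = "pttq_data_error")
})
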