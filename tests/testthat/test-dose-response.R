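# The printed FAC ladder: 11 rows x (5-FU, doxorubicin, 4-HC) in uM.
reference_dilution_table <- rbind(
  c(460, 10, 220), c(230, 5, 110), c(115, 2.5, 55), c(46, 1, 22),
  c(23, 0.5, 11), c(11.5, 0.25, 5.5), c(4.6, 0.1, 2.2), c(2.3, 0.05, 1.1),
  c(1.15, 0.025, 0.55), c(0.46, 0.01, 0.22), c(0, 0, 0))

test_that("the dilution table reproduces all 33 printed concentrations", {
  dt <- build_dilution_table()
  expect_identical(nrow(dt), 11L)
  expect_equal(as.matrix(dt[, c("c_5fu_um", "c_dox_um", "c_4hc_um")]),
               reference_dilution_table, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(dt[11, -1] == 0))
  # strictly decreasing over the treated rows
  expect_true(all(diff(dt$c_dox_um[1:10]) < 0))
})

test_that("the ladder keeps the 46:1:22 ratio and decade spacing", {
  dt <- build_dilution_table()
  treated <- dt[1:10, ]
  expect_equal(treated$c_5fu_um / treated$c_dox_um, rep(46, 10))
  expect_equal(treated$c_4hc_um / treated$c_dox_um, rep(22, 10))
  for (d in 1:7)
    expect_equal(dt$c_dox_um[d] / dt$c_dox_um[d + 3], 10)
  expect_error(build_dilution_table(top_c_dox = 0), "> 0")
})

test_that("EdU flags compare slice medians against half the control median", {
  s <- readout_series("edu", 2:7, rep(10, 6), control_median = 10)
  expect_false(any(edu_effect_flags(s)))

  s0 <- readout_series("edu", 2:7, rep(0, 6), control_median = 10)
  expect_true(all(edu_effect_flags(s0)))

  s2 <- readout_series("edu", 2:7, c(1, 2, 8, 9, 10, 10),
                       control_median = 10)
  fl <- edu_effect_flags(s2)
  expect_identical(unname(fl), c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))

  expect_error(readout_series("edu", 2:7, rep(1, 6)), "missing control")
})

test_that("TUNEL flags use the control median + 1.5 IQR criterion", {
  # control median 2%, IQR 1%: cut at 3.5; a 40% burst at dilution 2 flags
  s <- readout_series("tunel", 2:7, c(40, 3.4, 2, 2, 2, 2),
                      control_median = 2, control_iqr = 1)
  fl <- tunel_effect_flags(s)
  expect_true(fl[["2"]])
  expect_false(any(fl[as.character(3:7)]))

  same <- readout_series("tunel", 2:7, rep(2, 6), control_median = 2,
                         control_iqr = 1)
  expect_false(any(tunel_effect_flags(same)))
})

test_that("threshold calling finds the weakest dilution of the unbroken run", {
  fl <- c(`2` = TRUE, `3` = TRUE, `4` = FALSE, `5` = FALSE, `6` = FALSE,
          `7` = FALSE)
  expect_identical(call_threshold(fl), 3L)

  none <- setNames(rep(FALSE, 6), 2:7)
  expect_identical(call_threshold(none), NA_integer_)

  broken <- c(`2` = TRUE, `3` = TRUE, `4` = FALSE, `5` = TRUE, `6` = FALSE,
              `7` = FALSE)
  expect_warning(thr <- call_threshold(broken), "non-monotone")
  expect_identical(thr, 3L)

  expect_error(call_threshold(logical(0)), "empty flag set")
})

test_that("turning on a weaker-dilution flag never lowers the threshold", {
  set.seed(19)
  for (rep in 1:25) {
    fl <- setNames(sample(c(TRUE, FALSE), 6, replace = TRUE), 2:7)
    base <- suppressWarnings(call_threshold(fl))
    cand <- which(!fl)
    if (!length(cand)) next
    i <- cand[sample.int(length(cand), 1)]
    fl2 <- fl
    fl2[i] <- TRUE
    new <- suppressWarnings(call_threshold(fl2))
    if (!is.na(base)) expect_gte(new, base)
  }
})

test_that("classification boundaries follow the assay's definitions", {
  expect_identical(unname(classify_tumor(7L)), "sensitive")
  expect_identical(unname(classify_tumor(8L)), "sensitive")
  expect_identical(unname(classify_tumor(2L)), "resistant")
  expect_identical(unname(classify_tumor(NA_integer_)), "resistant")
  expect_identical(unname(classify_tumor(3L)), "intermediate")
  expect_identical(unname(classify_tumor(5L)), "intermediate")
  expect_identical(classify_tumor(c(edu = 7L, tunel = 2L)),
                   c(edu = "sensitive", tunel = "resistant"))
})

test_that("cohort_counts reproduces the published 5/7/3 morphology split", {
  ref <- fac_reference_cohort()
  cc <- cohort_counts(ref, "morphology")
  expect_identical(cc$counts, c(`2` = 3L, `3` = 7L, `5` = 5L))
  expect_identical(cc$n_missing, 0L)
  expect_identical(cc$n_total, 15L)
  expect_identical(sum(cc$counts) + cc$n_missing, cc$n_total)

  # the EdU column has one unavailable threshold
  ce <- cohort_counts(ref, "edu")
  expect_identical(ce$n_missing, 1L)
  expect_identical(sum(ce$counts), 14L)
})

test_that("cohort_counts accepts response-profile objects", {
  profs <- list(tumor_response_profile("a", c(morphology = 5L)),
                tumor_response_profile("b", c(morphology = 5L)),
                tumor_response_profile("c", c(morphology = NA_integer_)))
  cc <- cohort_counts(profs, "morphology")
  expect_identical(cc$counts, c(`5` = 2L))
  expect_identical(cc$n_missing, 1L)
})
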