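# Questionnaire-derived analysis variables and complete-case assembly.

test_that("pack-years follow the definition, cap at 140, and handle never-smokers", {
  expect_equal(as.numeric(compute_pack_years(20, 60, 1.0, 73)), 40.0)
  capped <- compute_pack_years(15, NA, 2.0, 90)
  expect_equal(as.numeric(capped), 140.0)
  expect_true(attr(capped, "truncated"))
  never <- compute_pack_years(NA, NA, NA, 73)
  expect_equal(as.numeric(never), 0.0)
  expect_false(attr(never, "truncated"))
  expect_error(compute_pack_years(50, 40, 1, 73), "quit age")
  expect_error(compute_pack_years(20, 60, -1, 73), "non-negative")
})

test_that("pack-years are monotone in intensity and duration, bounded by 140", {
  for (ppd in c(0.25, 0.5, 1, 2, 4)) {
    vals <- vapply(seq(25, 85, by = 10), function(quit)
      as.numeric(compute_pack_years(20, quit, ppd, 90)), numeric(1))
    expect_true(all(diff(vals) >= 0))
    expect_true(all(vals <= 140))
  }
  for (quit in c(30, 50, 70)) {
    vals <- vapply(c(0.5, 1, 1.5, 2, 3), function(ppd)
      as.numeric(compute_pack_years(20, quit, ppd, 90)), numeric(1))
    expect_true(all(diff(vals) >= 0))
  }
})

test_that("alcohol decades count decades with any drinking", {
  expect_identical(compute_alcohol_decades(c(TRUE, TRUE, TRUE, FALSE, FALSE)), 3L)
  expect_identical(compute_alcohol_decades(rep(FALSE, 5)), 0L)
  expect_identical(compute_alcohol_decades(rep(TRUE, 7)), 7L)
  expect_error(compute_alcohol_decades(logical(0)), "empty")
  # complement identity over random sequences
  set.seed(11)
  for (i in 1:20) {
    s <- runif(sample(1:8, 1)) < 0.5
    expect_identical(compute_alcohol_decades(s), length(s) - sum(!s))
  }
})

test_that("weekly ethanol grams use the standard drink equivalences", {
  expect_equal(alcohol_grams_per_week(1, 0, 0), 12.8)
  expect_equal(alcohol_grams_per_week(0, 1, 1), 25.0)
  expect_equal(alcohol_grams_per_week(0, 0, 0), 0.0)
  expect_error(alcohol_grams_per_week(-1, 0, 0), "non-negative")
})

test_that("BMI uses height at 25 and is capped at 40", {
  expect_equal(as.numeric(compute_bmi(80, 1.75)), 80 / 1.75^2)
  capped <- compute_bmi(130, 1.6)
  expect_equal(as.numeric(capped), 40.0)
  expect_true(attr(capped, "truncated"))
  expect_equal(as.numeric(compute_bmi(61.25, 1.75)), 20.0)
  expect_false(attr(compute_bmi(61.25, 1.75), "truncated"))
  expect_error(compute_bmi(-1, 1.7), "positive")
})

make_raw <- function(n = 6) {
  data.frame(
    patient_id = sprintf("R%02d", seq_len(n)),
    age_years = rep(75, n),
    sex = rep(c("male", "female"), length.out = n),
    smoke_start_age = rep(20, n),
    smoke_quit_age = rep(60, n),
    packs_per_day = rep(1, n),
    alcohol_decades = rep(3L, n),
    bmi_raw = rep(26, n),
    htn_history = rep(1L, n),
    chol_history = rep(0L, n),
    cfh_rs1061170 = rep("CT", n),
    arms2_rs1049331 = rep("TC", n),
    stringsAsFactors = FALSE
  )
}

test_that("complete input passes through build_cohort unchanged in size", {
  raw <- make_raw(8)
  cohort <- build_cohort(raw)
  expect_equal(nrow(cohort$records), 8L)
  expect_equal(nrow(cohort$exclusions), 0L)
  expect_equal(cohort$records$pack_years, rep(40, 8))
  expect_false(anyNA(cohort$records))
})

test_that("records missing an analysis variable are excluded and logged by field", {
  raw <- make_raw(5)
  raw$cfh_rs1061170[2] <- NA
  raw$bmi_raw[4] <- NA
  raw$htn_history[4] <- NA
  cohort <- build_cohort(raw)
  expect_equal(nrow(cohort$records), 3L)
  expect_equal(cohort$exclusions$patient_id, c("R02", "R04"))
  expect_equal(cohort$exclusions$missing_fields[1], "cfh_genotype")
  expect_equal(cohort$exclusions$missing_fields[2], "bmi;htn_history")
  # partition identity: kept + excluded = input
  expect_equal(nrow(cohort$records) + nrow(cohort$exclusions), nrow(raw))
})

test_that("duplicate patient ids are rejected", {
  raw <- make_raw(3)
  raw$patient_id[2] <- raw$patient_id[1]
  expect_error(build_cohort(raw), "duplicate")
})

test_that("the raw questionnaire dialect derives the same analysis variables", {
  raw <- data.frame(
    patient_id = c("Q1", "Q2"),
    age_years = c(75, 62),
    sex = c("female", "male"),
    smoke_start_age = c(NA, 18),
    smoke_quit_age = c(NA, 48),
    packs_per_day = c(NA, 1.5),
    drank_decade_1 = c(1, 0), drank_decade_2 = c(1, 1),
    drank_decade_3 = c(0, 1), drank_decade_4 = c(1, 1),
    weight_lb_decade_1 = c(120, 150), weight_lb_decade_2 = c(130, 170),
    weight_lb_decade_3 = c(140, 180), weight_lb_decade_4 = c(150, NA),
    height_m_at_25 = c(1.60, 1.80),
    htn_treated_6mo = c(1, 0),
    chol_treated_6mo = c(0, 1),
    cfh_rs1061170 = c("CC", "TT"),
    arms2_rs1049331 = c("TT", "CC"),
    stringsAsFactors = FALSE
  )
  cohort <- build_cohort(raw)
  expect_equal(nrow(cohort$records), 2L)
  expect_equal(cohort$records$pack_years, c(0, 45))
  expect_equal(cohort$records$alcohol_decades, c(3L, 3L))
  # BMI from the most recent reported decade weight, pounds -> kg
  expect_equal(cohort$records$bmi,
               c(150 * 0.45359237 / 1.60^2, 180 * 0.45359237 / 1.80^2))
  expect_equal(as.character(cohort$records$cfh_genotype), c("CC", "TT"))
})

test_that("cohort CSV round-trips through write and read", {
  raw <- make_raw(4)
  cohort <- build_cohort(raw)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(cohort, path)
  re <- build_cohort(read_cohort_csv(path))
  expect_equal(re$records$pack_years, cohort$records$pack_years)
  expect_equal(as.character(re$records$sex), as.character(cohort$records$sex))
  expect_equal(re$records$bmi, cohort$records$bmi)
})
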