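test_that("BMI follows the kg / m^2 formula", {
  expect_equal(compute_bmi(81, 1.80), 25)
  h <- c(1.6, 1.75, 1.9); cc <- c(20, 25, 31)
  expect_equal(compute_bmi(h^2 * cc, h), cc)
  expect_error(compute_bmi(70, 0), "> 0")
  expect_error(compute_bmi(-1, 1.7), "> 0")
})

clin_row <- function(glucose = 100, sys = 120, dia = 75, chol = 180,
                     bmi = 24, waist = 80, gender = "Female",
                     diabetes_med = FALSE, bp_med = FALSE) {
  tibble::tibble(glucose = glucose, sys_bp = sys, dia_bp = dia,
                 cholesterol = chol, bmi = bmi, waist = waist,
                 gender = gender, diabetes_med = diabetes_med,
                 bp_med = bp_med)
}

test_that("condition rules honour their boundary conventions", {
  # glucose bound is inclusive
  expect_true(classify_conditions(clin_row(glucose = 126))$hyperglycemia)
  expect_false(classify_conditions(clin_row(glucose = 125.9))$hyperglycemia)
  expect_true(classify_conditions(
    clin_row(glucose = 90, diabetes_med = TRUE))$hyperglycemia)

  # diabetic persons face the stricter 135/85 bounds
  nondiab <- classify_conditions(clin_row(sys = 136, dia = 80))
  expect_false(nondiab$hypertension)
  diab <- classify_conditions(clin_row(sys = 136, dia = 80, glucose = 130))
  expect_true(diab$hypertension)
  expect_true(classify_conditions(clin_row(bp_med = TRUE))$hypertension)
  # strict inequalities at the general bounds
  expect_false(classify_conditions(clin_row(sys = 140, dia = 90))$hypertension)

  # BMI exactly 25 is not obese (strictly greater than)
  expect_false(classify_conditions(clin_row(bmi = 25))$obesity)
  expect_true(classify_conditions(clin_row(bmi = 25.01))$obesity)
  expect_false(classify_conditions(clin_row(chol = 250))$cholesterolemia)
  # waist bounds differ by gender
  expect_true(classify_conditions(
    clin_row(waist = 103, gender = "Male"))$abdominal_obesity)
  expect_false(classify_conditions(
    clin_row(waist = 102, gender = "Male"))$abdominal_obesity)
  expect_true(classify_conditions(
    clin_row(waist = 89, gender = "Female"))$abdominal_obesity)
  expect_false(classify_conditions(
    clin_row(waist = 89, gender = "Male"))$abdominal_obesity)
  expect_error(classify_conditions(clin_row(gender = "other")),
               "unknown gender")
})

test_that("condition flags are monotone in each clinical measurement", {
  base <- clin_row()
  worse <- list(glucose = 200, sys = 190, dia = 120, chol = 400, bmi = 40,
                waist = 130)
  flags <- c("hyperglycemia", "hypertension", "cholesterolemia", "obesity",
             "abdominal_obesity")
  for (grid in seq(0, 1, by = 0.25)) {
    row <- clin_row(glucose = 100 + grid * 100, sys = 120 + grid * 70,
                    dia = 75 + grid * 45, chol = 180 + grid * 220,
                    bmi = 24 + grid * 16, waist = 80 + grid * 50)
    f1 <- classify_conditions(row)[flags]
    row2 <- clin_row(glucose = 100 + (grid + 0.25) * 100,
                     sys = 120 + (grid + 0.25) * 70,
                     dia = 75 + (grid + 0.25) * 45,
                     chol = 180 + (grid + 0.25) * 220,
                     bmi = 24 + (grid + 0.25) * 16,
                     waist = 80 + (grid + 0.25) * 50)
    f2 <- classify_conditions(row2)[flags]
    expect_true(all(unlist(f2) >= unlist(f1)))
  }
})

test_that("alcohol categories follow the gender-specific weekly bounds", {
  expect_equal(classify_alcohol(0, "Male"), "Non drinker")
  expect_equal(classify_alcohol(0, "Female"), "Non drinker")
  expect_equal(classify_alcohol(279.9, "Male"), "Moderate drinker")
  expect_equal(classify_alcohol(280, "Male"), "Risk drinker")
  expect_equal(classify_alcohol(170, "Female"), "Risk drinker")
  expect_equal(classify_alcohol(169.9, "Female"), "Moderate drinker")
  expect_error(classify_alcohol(-5, "Male"), ">= 0")
})

test_that("threshold objects validate their invariants", {
  expect_error(condition_thresholds(bp_sys_diab = 150), "must not exceed")
  expect_error(condition_thresholds(chol_high = -1), "> 0")
})

test_that("the clinical chain has the documented shape", {
  ch <- clinical_chain()
  outcomes <- vapply(ch, function(s) s$outcome, character(1))
  expect_equal(outcomes, c("clin_height", "clin_weight", "bmi", "waist",
                           "sys_bp", "dia_bp", "cholesterol", "glucose",
                           "cvd", "diabetes"))
  expect_false(is.null(ch[[3]]$derive))         # BMI is derived, not fitted
  expect_equal(sum(vapply(ch, function(s) is.null(s$derive), logical(1))), 9)
  # fitting it yields 7 linear submodels + 1 derived + 2 logistic
  sc <- tiny_scenario(n = 700, donor_n = 320, seed = 73)
  model <- fit_sequential_regression(sc$donor, sc$spec, sc$schema, chain = ch)
  types <- vapply(model$submodels, function(s) s$type, character(1))
  expect_equal(sum(types == "gaussian"), 7)
  expect_equal(sum(types == "derived"), 1)
  expect_equal(sum(types == "binomial"), 2)
})

test_that("prevalence pooling behaves at its fixed points", {
  sc <- tiny_scenario(n = 700, donor_n = 280, seed = 74)
  mi <- multiply_impute(sc$donor, sc$recipient, sc$spec, sc$schema,
                        method = "sqreg", m = 3, seed = 2,
                        chain = clinical_chain())
  # all-positive flags in donor and imputations -> rates 1 and B = 0
  donor1 <- dplyr::mutate(sc$donor, cvd = "Yes")
  mi1 <- mi
  mi1$tables <- lapply(mi$tables, function(t) dplyr::mutate(t, cvd = "Yes"))
  pt <- estimate_prevalence(donor1, mi1, conditions = "cvd")
  expect_equal(pt$donor_rate, 1)
  expect_equal(pt$fused_rate, 1)
  expect_equal(pt$fused_between, 0)

  # with an empty recipient set the fused estimate equals the donor-only one
  mi0 <- mi
  mi0$tables <- lapply(mi$tables, function(t) t[0, ])
  pt0 <- estimate_prevalence(sc$donor, mi0, conditions = c("cvd", "diabetes"))
  expect_equal(pt0$fused_rate, pt0$donor_rate)
  expect_equal(pt0$sd_ratio, c(1, 1), tolerance = 1e-9)
})

test_that("prevalence tables break down by subgroups consistently", {
  sc <- tiny_scenario(n = 800, donor_n = 300, seed = 75)
  mi <- multiply_impute(sc$donor, sc$recipient, sc$spec, sc$schema,
                        method = "sqreg", m = 3, seed = 3,
                        chain = clinical_chain())
  pt <- estimate_prevalence(sc$donor, mi, conditions = "cvd",
                            subgroup_vars = c("gender"))
  glob <- pt[pt$group_var == "global", ]
  by_g <- pt[pt$group_var == "gender", ]
  expect_equal(sum(by_g$donor_n), glob$donor_n)
  expect_equal(sum(by_g$fused_n), glob$fused_n)
  expect_true(all(pt$fused_rate >= 0 & pt$fused_rate <= 1))
  expect_true(all(pt$sd_ratio > 0))
})
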