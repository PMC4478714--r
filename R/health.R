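#' Clinical thresholds for condition classification
#'
#' Defaults follow the standard clinical definitions: hyperglycemia at
#' fasting glucose >= 126 mg/dL (or diabetes medication), hypertension at
#' systolic > 140 or diastolic > 90 mmHg (135/85 for diabetic persons, or
#' blood-pressure medication), cholesterolemia above 250 mg/dL, obesity at
#' BMI > 25 kg/m2, abdominal obesity at waist > 102 cm (men) / 88 cm
#' (women), and risk drinking at or above 280 g (men) / 170 g (women) of
#' pure alcohol per week.
#'
#' @param glucose_hyper Inclusive glucose bound (mg/dL).
#' @param bp_sys,bp_dia Exclusive blood-pressure bounds (mmHg).
#' @param bp_sys_diab,bp_dia_diab Exclusive bounds for diabetic persons.
#' @param chol_high Exclusive cholesterol bound (mg/dL).
#' @param bmi_obese Exclusive BMI bound (kg/m2).
#' @param waist_male,waist_female Exclusive waist bounds (cm).
#' @param alcohol_male,alcohol_female Weekly pure-alcohol bounds (g); intake
#'   at or above the bound is risk drinking.
#' @return A list of class `condition_thresholds`.
#' @export
condition_thresholds <- function(glucose_hyper = 126, bp_sys = 140,
                                 bp_dia = 90, bp_sys_diab = 135,
                                 bp_dia_diab = 85, chol_high = 250,
                                 bmi_obese = 25, waist_male = 102,
                                 waist_female = 88, alcohol_male = 280,
                                 alcohol_female = 170) {
  th <- list(glucose_hyper = glucose_hyper, bp_sys = bp_sys, bp_dia = bp_dia,
             bp_sys_diab = bp_sys_diab, bp_dia_diab = bp_dia_diab,
             chol_high = chol_high, bmi_obese = bmi_obese,
             waist_male = waist_male, waist_female = waist_female,
             alcohol_male = alcohol_male, alcohol_female = alcohol_female)
  if (any(unlist(th) <= 0)) abort("all thresholds must be > 0")
  if (bp_sys_diab > bp_sys || bp_dia_diab > bp_dia) {
    abort("diabetic blood-pressure thresholds must not exceed the general ones")
  }
  structure(th, class = "condition_thresholds")
}

#' Body mass index
#'
#' @param weight Weight in kg (> 0).
#' @param height Height in metres (> 0).
#' @return `weight / height^2` in kg/m2.
#' @export
#' @examples compute_bmi(81, 1.80)  # 25
compute_bmi <- function(weight, height) {
  if (any(weight <= 0) || any(height <= 0)) {
    abort("weight and height must be > 0")
  }
  weight / height^2
}

#' Classify clinical risk-factor conditions
#'
#' Applies the threshold rules to a table of clinical measurements:
#' hyperglycemia iff glucose >= 126 mg/dL or diabetes medication;
#' hypertension iff systolic > 140 or diastolic > 90 mmHg (135/85 for
#' diabetic persons) or blood-pressure medication; cholesterolemia iff
#' cholesterol > 250 mg/dL; obesity iff BMI > 25; abdominal obesity iff
#' waist > 102 cm for men, > 88 cm for women. A "diabetic person" for the
#' blood-pressure rule is one who meets the hyperglycemia definition.
#'
#' @param data Tibble with columns `glucose`, `sys_bp`, `dia_bp`,
#'   `cholesterol`, `bmi`, `waist`, `gender` (`"Male"`/`"Female"`), and
#'   logical `diabetes_med`, `bp_med` medication flags (self-declared
#'   treatment status).
#' @param thresholds A [condition_thresholds()].
#' @return `data` with added logical columns `hyperglycemia`,
#'   `hypertension`, `cholesterolemia`, `obesity`, `abdominal_obesity`.
#' @export
classify_conditions <- function(data, thresholds = condition_thresholds()) {
  assert_columns(data, c("glucose", "sys_bp", "dia_bp", "cholesterol", "bmi",
                         "waist", "gender", "diabetes_med", "bp_med"),
                 "clinical data")
  if (!all(data$gender %in% c("Male", "Female"))) {
    abort("unknown gender level in clinical data")
  }
  th <- thresholds
  data |>
    dplyr::mutate(
      hyperglycemia = .data$glucose >= th$glucose_hyper | .data$diabetes_med,
      hypertension = ifelse(
        .data$hyperglycemia,
        .data$sys_bp > th$bp_sys_diab | .data$dia_bp > th$bp_dia_diab,
        .data$sys_bp > th$bp_sys | .data$dia_bp > th$bp_dia) | .data$bp_med,
      cholesterolemia = .data$cholesterol > th$chol_high,
      obesity = .data$bmi > th$bmi_obese,
      abdominal_obesity = ifelse(.data$gender == "Male",
                                 .data$waist > th$waist_male,
                                 .data$waist > th$waist_female)
    )
}

#' Classify weekly alcohol intake
#'
#' Zero intake is a non-drinker; positive intake strictly below the
#' gender-specific bound is moderate; intake at or above the bound is risk
#' drinking (the moderate category is defined as strictly below the bound).
#'
#' @param weekly_grams Grams of pure alcohol per week (>= 0).
#' @param gender `"Male"` or `"Female"`.
#' @param thresholds A [condition_thresholds()].
#' @return Character vector in `{"Non drinker", "Moderate drinker",
#'   "Risk drinker"}`.
#' @export
classify_alcohol <- function(weekly_grams, gender,
                             thresholds = condition_thresholds()) {
  if (any(weekly_grams < 0)) abort("weekly alcohol intake must be >= 0")
  bound <- ifelse(gender == "Male", thresholds$alcohol_male,
                  thresholds$alcohol_female)
  dplyr::case_when(
    weekly_grams == 0 ~ "Non drinker",
    weekly_grams < bound ~ "Moderate drinker",
    .default = "Risk drinker"
  )
}

#' The clinical sequential-regression imputation scheme
#'
#' Builds the ordered chain used to impute the clinical block into the
#' recipient survey: clinical height from self-reported height/weight and
#' gender-by-age interactions; clinical weight from imputed height and
#' self-reported weight; BMI derived by formula; then abdominal perimeter,
#' systolic and diastolic blood pressure, cholesterol and glucose, each from
#' demographics, BMI and the matching declared-status variable; finally
#' logistic submodels for cardiovascular disease and diabetes on the
#' standard risk factors. Every submodel is subject to the
#' significance-pruning rule of [fit_sequential_regression()].
#'
#' @param use_age_groups If `TRUE`, the height model uses gender-by-age-group
#'   interactions (the survey presentation); if `FALSE`, continuous age is
#'   used throughout.
#' @return A list of [chain_step()]s.
#' @export
clinical_chain <- function(use_age_groups = TRUE) {
  height_terms <- if (use_age_groups) {
    c("self_height", "self_weight", "gender", "age_group", "gender:age_group")
  } else {
    c("self_height", "self_weight", "gender", "age_cont")
  }
  list(
    chain_step("clin_height", candidates = height_terms),
    chain_step("clin_weight", candidates = c("clin_height", "self_weight")),
    chain_step("bmi", derive = ~ clin_weight / (clin_height / 100)^2),
    chain_step("waist", candidates = c("bmi", "age_cont", "gender",
                                       "age_cont:gender")),
    chain_step("sys_bp", candidates = c("age_cont", "gender", "bmi",
                                        "bp_decl", "age_cont:gender")),
    chain_step("dia_bp", candidates = c("sys_bp", "bmi", "bp_decl")),
    chain_step("cholesterol", candidates = c("age_cont", "gender", "bmi",
                                             "chol_decl")),
    chain_step("glucose", candidates = c("age_cont", "bmi", "diab_decl")),
    chain_step("cvd", candidates = c("age_cont", "gender", "bmi", "sys_bp",
                                     "cholesterol", "activity", "smoking",
                                     "waist", "education"),
               draw_parameters = FALSE),
    chain_step("diabetes", candidates = c("age_cont", "gender", "bmi",
                                          "glucose", "activity", "education"),
               draw_parameters = FALSE)
  )
}

#' Estimate condition prevalences from donor-only and fused data
#'
#' For each condition and subgroup the donor-only entry is the observed
#' donor proportion with its binomial standard deviation; the fused entry
#' pools, over the `m` completed tables, the proportion across donor plus
#' recipient rows with binomial within-variance, via [pool_estimates()]. The
#' SD ratio (donor SD / fused SD) measures the precision gained by fusing:
#' values above 1 mean the fused file estimates the prevalence more
#' precisely than the clinical subsample alone.
#'
#' @param donor Donor tibble with the observed condition flags.
#' @param fused A `multi_imputation` over the recipient rows carrying
#'   imputed condition flags.
#' @param conditions Character vector of condition flag columns (values
#'   `"Yes"`/`"No"`).
#' @param subgroup_vars Common variables to break the estimates down by
#'   (besides the global row).
#' @return A tibble of class `prevalence_table`: one row per condition x
#'   subgroup with `donor_n`, `donor_rate`, `donor_sd`, `fused_n`,
#'   `fused_rate`, `fused_sd`, `fused_within`, `fused_between`, `sd_ratio`.
#' @export
estimate_prevalence <- function(donor, fused, conditions = c("cvd", "diabetes"),
                                subgroup_vars = character()) {
  if (!inherits(fused, "multi_imputation")) {
    abort("fused must be a multi_imputation object")
  }
  assert_columns(donor, conditions, "donor")
  for (tab in fused$tables) assert_columns(tab, conditions, "completed table")
  groups <- c("global", subgroup_vars)
  one_cell <- function(cond, gv, level) {
    din <- if (gv == "global") donor else donor[donor[[gv]] == level, ]
    n0 <- nrow(din)
    p0 <- mean(din[[cond]] == "Yes")
    sd0 <- sqrt(p0 * (1 - p0) / n0)
    per_imp <- purrr::map(fused$tables, function(tab) {
      tin <- if (gv == "global") tab else tab[tab[[gv]] == level, ]
      pos <- sum(tin[[cond]] == "Yes") + sum(din[[cond]] == "Yes")
      n <- nrow(tin) + n0
      p <- pos / n
      c(p = p, v = p * (1 - p) / n, n = n)
    })
    ests <- vapply(per_imp, `[[`, numeric(1), "p")
    vars <- vapply(per_imp, `[[`, numeric(1), "v")
    if (n0 == 0 || per_imp[[1]][["n"]] == 0) {
      return(tibble::tibble(condition = cond, group_var = gv, group = level,
                            donor_n = n0, donor_rate = NA_real_,
                            donor_sd = NA_real_, fused_n = NA_real_,
                            fused_rate = NA_real_, fused_sd = NA_real_,
                            fused_within = NA_real_, fused_between = NA_real_,
                            sd_ratio = NA_real_))
    }
    pooled <- pool_estimates(ests, vars)
    tibble::tibble(
      condition = cond, group_var = gv, group = level, donor_n = n0,
      donor_rate = p0, donor_sd = sd0, fused_n = per_imp[[1]][["n"]],
      fused_rate = pooled$qbar, fused_sd = pooled$sd,
      fused_within = pooled$within, fused_between = pooled$between,
      sd_ratio = sd0 / pooled$sd)
  }
  out <- purrr::map_dfr(conditions, function(cond) {
    purrr::map_dfr(groups, function(gv) {
      levels <- if (gv == "global") "global" else {
        sort(unique(c(donor[[gv]],
                      unlist(purrr::map(fused$tables, ~ unique(.x[[gv]]))))))
      }
      purrr::map_dfr(levels, function(lv) one_cell(cond, gv, lv))
    })
  })
  class(out) <- c("prevalence_table", class(out))
  out
}

#' Bar display of donor vs fused prevalence estimates
#' @param object A `prevalence_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.prevalence_table <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(c("donor_rate", "fused_rate"), names_to = "source",
                        values_to = "rate") |>
    dplyr::mutate(sd = ifelse(.data$source == "donor_rate", .data$donor_sd,
                              .data$fused_sd),
                  source = ifelse(.data$source == "donor_rate", "donor only",
                                  "fused"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$rate,
                                     fill = .data$source)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$rate - 1.96 * .data$sd,
                   ymax = .data$rate + 1.96 * .data$sd),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3) +
    ggplot2::facet_grid(condition ~ group_var, scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(y = "prevalence", x = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
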