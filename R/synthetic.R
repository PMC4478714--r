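#' Default parameters for the synthetic health-survey population
#'
#' The generator emulates the structure of a large interview survey enriched
#' with a clinical-examination subsample: self-reported demographics and
#' behaviour for everyone, and a clinical block (height, weight, abdominal
#' perimeter, blood pressure, cholesterol, glucose, plus cardiovascular and
#' diabetes status) available only for donors. The clinical block is generated
#' by a chain of linear-Gaussian submodels on demographics and earlier
#' clinical variables, self-reported height/weight are the clinical values
#' plus reporting error, and the two conditions are Bernoulli draws from
#' logistic models on the standard risk factors. All parameter values are
#' plausible fixtures (e.g. mean heights by gender, blood pressure rising
#' with age), not estimates of any real population.
#'
#' Because every continuous variable is linear-Gaussian given the categorical
#' ones, any regression chain on these variables is correctly specified,
#' which makes parameter recovery by the sequential-regression engine a fair
#' test of the implementation rather than of the model.
#'
#' @param n Population size (default mirrors the motivating design, 11614).
#' @param donor_fraction Fraction examined clinically (default 1508/11614).
#' @param truth_n Monte-Carlo size used to evaluate the true prevalences.
#' @param null_links If `TRUE`, sever every link between the common block and
#'   the clinical block (self-reported values become independent noise and
#'   demographic coefficients are zeroed); used as a null-calibration fixture
#'   in which no imputation method can systematically beat the marginal
#'   predictor.
#' @param ... Named overrides merged into the default list (nested lists are
#'   merged element-wise).
#' @return A list of class `population_params`.
#' @export
population_params <- function(n = 11614, donor_fraction = 1508 / 11614,
                              truth_n = 2e5, null_links = FALSE, ...) {
  p <- list(
    n = n, donor_fraction = donor_fraction, truth_n = truth_n,
    null_links = null_links,
    gender = c(Female = 0.52, Male = 0.48),
    age = list(min = 18, max = 94, shape1 = 1.2, shape2 = 1.4),
    education = c(Primary = 0.35, Secondary = 0.40, University = 0.25),
    smoking = c(`Non smoker` = 0.45, `Ex-smoker` = 0.22,
                `Occasional smoker` = 0.05, `Regular smoker` = 0.28),
    activity = c(Sedentary = 0.35, Light = 0.25, Moderate = 0.25,
                 Vigorous = 0.15),
    alcohol = c(`Non drinker` = 0.45, `Moderate drinker` = 0.45,
                `Risk drinker` = 0.10),
    declared = list(
      bp   = list(base = -4.4, age = 0.055, treat_share = 0.65),
      diab = list(base = -5.6, age = 0.055, treat_share = 0.70),
      chol = list(base = -4.4, age = 0.050, treat_share = 0.55)
    ),
    clin_height = list(intercept = 165, male = 13, age = -0.06, sd = 6.5),
    clin_weight = list(intercept = -42, height = 0.62, age = 0.12, male = 3,
                       sd = 8.5, skew_shape = 4),
    reporting = list(height_bias = 0, height_sd = 2.0,
                     weight_bias = 0, weight_sd = 2.5),
    waist = list(intercept = 22, bmi = 2.1, age = 0.12, male = 16,
                 age_male = -0.15, sd = 7, skew_shape = 1.5),
    sys_bp = list(intercept = 81, age = 0.55, bmi = 0.7,
                  bp_decl_untreated = 9, bp_decl_treated = 6, male = 16.25,
                  age_male = -0.25, sd = 11, skew_shape = 2.5),
    dia_bp = list(intercept = 7, sys = 0.38, bmi = 0.25, waist = 0.25,
                  sd = 9, skew_shape = 2),
    cholesterol = list(intercept = 34, age = 0.85, bmi = 1.2, waist = 1.0,
                       chol_decl_untreated = 28, chol_decl_treated = 12,
                       male = -4, sd = 34, skew_shape = 1.5),
    glucose = list(intercept = 0, age = 0.22, bmi = 1.1, chol = 0.08,
                   waist = 0.5, diab_decl_untreated = 46,
                   diab_decl_treated = 34, sd = 17, skew_shape = 0.8),
    latent = list(
      glucose = c(prob = 0.06, shift = 40)
    ),
    cvd = list(intercept = -11.15, age = 0.06, male = 0.35, bmi = 0.05,
               sys = 0.015, chol = 0.004, sedentary = 0.45, smoker = 0.35,
               waist = 0.008),
    diabetes = list(intercept = -13.05, age = 0.035, male = 0.25, bmi = 0.06,
                    glucose = 0.055, sedentary = 0.35)
  )
  overrides <- list(...)
  if (length(overrides) > 0) p <- modifyList(p, overrides)
  validate_population_params(p)
  structure(p, class = "population_params")
}

validate_population_params <- function(p) {
  for (nm in c("gender", "education", "smoking", "activity", "alcohol")) {
    probs <- p[[nm]]
    if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8) {
      abort(sprintf("category probabilities for '%s' must be >= 0 and sum to 1", nm))
    }
  }
  sds <- c(p$clin_height$sd, p$clin_weight$sd, p$waist$sd, p$sys_bp$sd,
           p$dia_bp$sd, p$cholesterol$sd, p$glucose$sd)
  if (any(sds <= 0)) abort("all clinical residual standard deviations must be > 0")
  if (any(c(p$reporting$height_sd, p$reporting$weight_sd) < 0)) {
    abort("reporting-error standard deviations must be >= 0")
  }
  if (p$n < 0) abort("population size must be >= 0")
  invisible(p)
}

age_group_levels <- function() {
  c("18:29 years", "30:44 years", "45:59 years", "60:74 years",
    "75 years & over")
}

#' Band a continuous age into the standard survey age groups
#' @param age Numeric vector of ages in years (>= 18).
#' @return Character vector of age-group labels.
#' @export
band_age <- function(age) {
  cut(age, breaks = c(18, 30, 45, 60, 75, Inf), right = FALSE,
      labels = age_group_levels(), include.lowest = TRUE) |> as.character()
}

# Centred residual draw: normal when shape is NULL, otherwise a centred
# gamma with the requested standard deviation (skewness = 2 / sqrt(shape)),
# emulating the right skew of real clinical measurements.
rresid <- function(n, sd, shape = NULL) {
  if (is.null(shape)) return(rnorm(n, 0, sd))
  rate <- sqrt(shape) / sd
  rgamma(n, shape = shape, rate = rate) - shape / rate
}

# Mean-centred latent spike: a small undiagnosed-condition subpopulation
# shifted upwards, independent of everything self-reported. Centring keeps
# all regression coefficients at their stated values.
rlatent <- function(n, cfg) {
  if (is.null(cfg)) return(numeric(n))
  cfg[["shift"]] * (rbinom(n, 1, cfg[["prob"]]) - cfg[["prob"]])
}

sample_levels <- function(n, probs) {
  if (n == 0) return(character())
  sample(names(probs), n, replace = TRUE, prob = probs)
}

declared_status <- function(age, cfg, levels) {
  n <- length(age)
  has <- rbinom(n, 1, plogis(cfg$base + cfg$age * age)) == 1
  treated <- rbinom(n, 1, cfg$treat_share) == 1
  out <- rep(levels[1], n)
  out[has & !treated] <- levels[2]
  out[has & treated] <- levels[3]
  out
}

# The generative chain, fully vectorised. Used both for the population and
# for the Monte-Carlo evaluation of true prevalences.
simulate_chain <- function(p, n) {
  male <- as.numeric(sample_levels(n, p$gender) == "Male")
  gender <- ifelse(male == 1, "Male", "Female")
  age <- p$age$min + (p$age$max - p$age$min) * rbeta(n, p$age$shape1, p$age$shape2)
  null <- isTRUE(p$null_links)
  z <- function(x) if (null) 0 else x   # sever X -> Y links in the null fixture

  education <- sample_levels(n, p$education)
  smoking <- sample_levels(n, p$smoking)
  activity <- sample_levels(n, p$activity)
  alcohol <- sample_levels(n, p$alcohol)
  bp_decl <- declared_status(age, p$declared$bp,
                             c("No high BP", "BP without treat", "BP with treat"))
  diab_decl <- declared_status(age, p$declared$diab,
                               c("No Diab", "Diab without treat", "Diab with treat"))
  chol_decl <- declared_status(age, p$declared$chol,
                               c("No high Chol", "Chol without treat", "Chol with treat"))

  ph <- p$clin_height
  clin_height <- ph$intercept + z(ph$male) * male + z(ph$age) * age +
    rnorm(n, 0, ph$sd)
  pw <- p$clin_weight
  clin_weight <- pw$intercept + pw$height * clin_height + z(pw$age) * age +
    z(pw$male) * male + rresid(n, pw$sd, pw$skew_shape)
  if (null) {
    self_height <- rnorm(n, ph$intercept, ph$sd)
    self_weight <- rnorm(n, pw$intercept + pw$height * ph$intercept, pw$sd)
  } else {
    self_height <- clin_height + p$reporting$height_bias +
      rnorm(n, 0, p$reporting$height_sd)
    self_weight <- clin_weight + p$reporting$weight_bias +
      rnorm(n, 0, p$reporting$weight_sd)
  }
  bmi <- clin_weight / (clin_height / 100)^2

  pa <- p$waist
  waist <- pa$intercept + pa$bmi * bmi + z(pa$age) * age + z(pa$male) * male +
    z(pa$age_male) * age * male + rresid(n, pa$sd, pa$skew_shape)
  ps <- p$sys_bp
  sys_bp <- ps$intercept + z(ps$age) * age + ps$bmi * bmi +
    z(ps$bp_decl_untreated) * (bp_decl == "BP without treat") +
    z(ps$bp_decl_treated) * (bp_decl == "BP with treat") +
    z(ps$male) * male + z(ps$age_male) * age * male +
    rlatent(n, p$latent$sys_bp) + rresid(n, ps$sd, ps$skew_shape)
  pd <- p$dia_bp
  dia_bp <- pd$intercept + pd$sys * sys_bp + pd$bmi * bmi +
    pd$waist * waist + rresid(n, pd$sd, pd$skew_shape)
  pc <- p$cholesterol
  cholesterol <- pc$intercept + z(pc$age) * age + pc$bmi * bmi +
    pc$waist * waist +
    z(pc$chol_decl_untreated) * (chol_decl == "Chol without treat") +
    z(pc$chol_decl_treated) * (chol_decl == "Chol with treat") +
    z(pc$male) * male + rlatent(n, p$latent$cholesterol) +
    rresid(n, pc$sd, pc$skew_shape)
  pg <- p$glucose
  glucose <- pg$intercept + z(pg$age) * age + pg$bmi * bmi +
    pg$chol * cholesterol + pg$waist * waist +
    z(pg$diab_decl_untreated) * (diab_decl == "Diab without treat") +
    z(pg$diab_decl_treated) * (diab_decl == "Diab with treat") +
    rlatent(n, p$latent$glucose) + rresid(n, pg$sd, pg$skew_shape)

  pv <- p$cvd
  eta_cvd <- pv$intercept + z(pv$age) * age + z(pv$male) * male +
    pv$bmi * bmi + pv$sys * sys_bp + pv$chol * cholesterol +
    z(pv$sedentary) * (activity == "Sedentary") +
    z(pv$smoker) * (smoking == "Regular smoker") + pv$waist * waist
  cvd <- ifelse(rbinom(n, 1, plogis(eta_cvd)) == 1, "Yes", "No")
  pb <- p$diabetes
  eta_diab <- pb$intercept + z(pb$age) * age + z(pb$male) * male +
    pb$bmi * bmi + pb$glucose * glucose +
    z(pb$sedentary) * (activity == "Sedentary")
  diabetes <- ifelse(rbinom(n, 1, plogis(eta_diab)) == 1, "Yes", "No")

  tibble::tibble(
    gender, age_cont = age, age_group = band_age(age), education, smoking,
    activity, alcohol, bp_decl, diab_decl, chol_decl,
    self_height, self_weight,
    clin_height, clin_weight, bmi, waist, sys_bp, dia_bp, cholesterol,
    glucose, cvd, diabetes
  )
}

#' Schema of the synthetic population
#' @return A [survey_schema()] covering all generated variables.
#' @export
synthetic_schema <- function() {
  survey_schema(
    variable = c("gender", "age_cont", "age_group", "education", "smoking",
                 "activity", "alcohol", "bp_decl", "diab_decl", "chol_decl",
                 "self_height", "self_weight",
                 "clin_height", "clin_weight", "bmi", "waist", "sys_bp",
                 "dia_bp", "cholesterol", "glucose", "cvd", "diabetes"),
    role = c(rep("common", 12), rep("specific", 10)),
    kind = c("categorical", "continuous", "categorical", "categorical",
             "categorical", "categorical", "categorical", "categorical",
             "categorical", "categorical", "continuous", "continuous",
             rep("continuous", 8), "categorical", "categorical"),
    levels = list(
      c("Female", "Male"), NULL, age_group_levels(),
      c("Primary", "Secondary", "University"),
      c("Non smoker", "Ex-smoker", "Occasional smoker", "Regular smoker"),
      c("Sedentary", "Light", "Moderate", "Vigorous"),
      c("Non drinker", "Moderate drinker", "Risk drinker"),
      c("No high BP", "BP without treat", "BP with treat"),
      c("No Diab", "Diab without treat", "Diab with treat"),
      c("No high Chol", "Chol without treat", "Chol with treat"),
      NULL, NULL, NULL, NULL, NULL, NULL, NULL, NULL, NULL, NULL,
      c("No", "Yes"), c("No", "Yes")
    ),
    units = c(NA, "years", NA, NA, NA, NA, NA, NA, NA, NA, "cm", "kg",
              "cm", "kg", "kg/m2", "cm", "mmHg", "mmHg", "mg/dL", "mg/dL",
              NA, NA)
  )
}

#' Fusion spec of the synthetic scenario
#' @return A [fusion_spec()]: self-report block as common variables, clinical
#'   block (including condition flags) as specific variables.
#' @export
synthetic_fusion_spec <- function() {
  sch <- synthetic_schema()
  fusion_spec(common = schema_vars(sch, role = "common"),
              specific = schema_vars(sch, role = "specific"))
}

#' Fusion spec restricted to the continuous clinical block
#'
#' The method-comparison experiment validates the fusion of the measured
#' risk factors (height, weight, BMI, abdominal perimeter, blood pressure,
#' cholesterol, glucose); condition status is predicted downstream from the
#' imputed risk factors by the health pipeline, mirroring the two-phase
#' application process.
#' @return A [fusion_spec()].
#' @export
clinical_fusion_spec <- function() {
  sch <- synthetic_schema()
  fusion_spec(common = schema_vars(sch, role = "common"),
              specific = c("clin_height", "clin_weight", "bmi", "waist",
                           "sys_bp", "dia_bp", "cholesterol", "glucose"))
}

#' The generating chain of the synthetic population
#'
#' Returns the sequential-regression chain whose candidate sets coincide
#' exactly with the parents used by the generator, so that fitting it on a
#' synthetic donor is a correctly specified estimation problem (every
#' coefficient has a generating counterpart). This is the chain to use for
#' parameter-recovery and coverage studies; the curated epidemiological
#' scheme in [clinical_chain()] deliberately omits some of these links.
#'
#' @return A list of [chain_step()]s.
#' @export
synthetic_generating_chain <- function() {
  list(
    chain_step("clin_height", candidates = c("gender", "age_cont")),
    chain_step("clin_weight", candidates = c("clin_height", "age_cont",
                                             "gender")),
    chain_step("bmi", derive = ~ clin_weight / (clin_height / 100)^2),
    chain_step("waist", candidates = c("bmi", "age_cont", "gender",
                                       "age_cont:gender")),
    chain_step("sys_bp", candidates = c("age_cont", "bmi", "bp_decl",
                                        "gender", "age_cont:gender")),
    chain_step("dia_bp", candidates = c("sys_bp", "bmi", "waist")),
    chain_step("cholesterol", candidates = c("age_cont", "bmi", "waist",
                                             "chol_decl", "gender")),
    chain_step("glucose", candidates = c("age_cont", "bmi", "cholesterol",
                                         "waist", "diab_decl")),
    chain_step("cvd", candidates = c("age_cont", "gender", "bmi", "sys_bp",
                                     "cholesterol", "activity", "smoking",
                                     "waist")),
    chain_step("diabetes", candidates = c("age_cont", "gender", "bmi",
                                          "glucose", "activity"))
  )
}

#' Generating coefficients in fitted-model parameterization
#'
#' Expresses the generator's coefficients in the parameterization a
#' regression fit of [synthetic_generating_chain()] estimates (treatment
#' coding against each factor's first level), so recovered coefficients can
#' be compared term by term. For the condition models the generator adds a
#' shift only for sedentary respondents; with `Sedentary` as the reference
#' level that surfaces as equal negative coefficients on the other activity
#' levels and a shifted intercept.
#'
#' @param params A [population_params()] list.
#' @return Tibble with columns `outcome`, `term`, `truth`.
#' @export
generating_coefficients <- function(params) {
  p <- params
  row <- function(outcome, term, truth) {
    tibble::tibble(outcome = outcome, term = term, truth = truth)
  }
  decl <- function(outcome, var, lev2, lev3, c2, c3) {
    dplyr::bind_rows(row(outcome, paste0(var, lev2), c2),
                     row(outcome, paste0(var, lev3), c3))
  }
  dplyr::bind_rows(
    row("clin_height", c("(Intercept)", "genderMale", "age_cont"),
        c(p$clin_height$intercept, p$clin_height$male, p$clin_height$age)),
    row("clin_weight", c("(Intercept)", "clin_height", "age_cont",
                         "genderMale"),
        c(p$clin_weight$intercept, p$clin_weight$height, p$clin_weight$age,
          p$clin_weight$male)),
    row("waist", c("(Intercept)", "bmi", "age_cont", "genderMale",
                   "age_cont:genderMale"),
        c(p$waist$intercept, p$waist$bmi, p$waist$age, p$waist$male,
          p$waist$age_male)),
    row("sys_bp", c("(Intercept)", "age_cont", "bmi", "genderMale",
                    "age_cont:genderMale"),
        c(p$sys_bp$intercept, p$sys_bp$age, p$sys_bp$bmi, p$sys_bp$male,
          p$sys_bp$age_male)),
    decl("sys_bp", "bp_decl", "BP without treat", "BP with treat",
         p$sys_bp$bp_decl_untreated, p$sys_bp$bp_decl_treated),
    row("dia_bp", c("(Intercept)", "sys_bp", "bmi", "waist"),
        c(p$dia_bp$intercept, p$dia_bp$sys, p$dia_bp$bmi, p$dia_bp$waist)),
    row("cholesterol", c("(Intercept)", "age_cont", "bmi", "waist",
                         "genderMale"),
        c(p$cholesterol$intercept, p$cholesterol$age, p$cholesterol$bmi,
          p$cholesterol$waist, p$cholesterol$male)),
    decl("cholesterol", "chol_decl", "Chol without treat", "Chol with treat",
         p$cholesterol$chol_decl_untreated, p$cholesterol$chol_decl_treated),
    row("glucose", c("(Intercept)", "age_cont", "bmi", "cholesterol",
                     "waist"),
        c(p$glucose$intercept, p$glucose$age, p$glucose$bmi, p$glucose$chol,
          p$glucose$waist)),
    decl("glucose", "diab_decl", "Diab without treat", "Diab with treat",
         p$glucose$diab_decl_untreated, p$glucose$diab_decl_treated),
    row("cvd", c("(Intercept)", "age_cont", "genderMale", "bmi", "sys_bp",
                 "cholesterol", "waist", "activityLight", "activityModerate",
                 "activityVigorous", "smokingEx-smoker",
                 "smokingOccasional smoker", "smokingRegular smoker"),
        c(p$cvd$intercept + p$cvd$sedentary, p$cvd$age, p$cvd$male,
          p$cvd$bmi, p$cvd$sys, p$cvd$chol, p$cvd$waist,
          -p$cvd$sedentary, -p$cvd$sedentary, -p$cvd$sedentary,
          0, 0, p$cvd$smoker)),
    row("diabetes", c("(Intercept)", "age_cont", "genderMale", "bmi",
                      "glucose", "activityLight", "activityModerate",
                      "activityVigorous"),
        c(p$diabetes$intercept + p$diabetes$sedentary, p$diabetes$age,
          p$diabetes$male, p$diabetes$bmi, p$diabetes$glucose,
          -p$diabetes$sedentary, -p$diabetes$sedentary,
          -p$diabetes$sedentary))
  )
}

#' Generate a synthetic population with known ground truth
#'
#' @param params A [population_params()] list.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A list with elements `population` (a fully observed survey tibble
#'   with a `.row_id` column), `truth` (a list carrying the generating
#'   parameters and a tibble of Monte-Carlo true prevalences per condition,
#'   globally and by gender, age group and physical activity), and `schema` /
#'   `spec` objects describing the table.
#' @export
generate_population <- function(params = population_params(), seed = 1L) {
  validate_population_params(params)
  seeds <- derive_seeds(seed, 2)
  population <- with_seed_if(seeds[1], simulate_chain(params, params$n))
  population <- ensure_row_id(population)
  truth_prev <- if (params$truth_n > 0) {
    true_prevalence(params, n = params$truth_n, seed = seeds[2])
  }
  list(
    population = population,
    truth = list(params = params, prevalence = truth_prev),
    schema = synthetic_schema(),
    spec = synthetic_fusion_spec()
  )
}

#' Monte-Carlo true prevalences implied by generator parameters
#'
#' @param params A [population_params()] list.
#' @param n Monte-Carlo sample size.
#' @param seed Integer seed.
#' @return Tibble with columns `condition`, `group_var`, `group`,
#'   `prevalence`, `mc_se`.
#' @export
true_prevalence <- function(params, n = 2e5, seed = 1L) {
  big <- with_seed_if(seed, simulate_chain(params, n))
  one <- function(cond, group_var, data) {
    grp <- if (group_var == "global") rep("global", nrow(data)) else data[[group_var]]
    data |>
      dplyr::mutate(.grp = grp, .pos = .data[[cond]] == "Yes") |>
      dplyr::summarise(prevalence = mean(.data$.pos), n_mc = dplyr::n(),
                       .by = ".grp") |>
      dplyr::transmute(condition = cond, group_var = group_var,
                       group = .data$.grp,
                       prevalence = .data$prevalence,
                       mc_se = sqrt(.data$prevalence * (1 - .data$prevalence) /
                                      .data$n_mc))
  }
  tidyr::expand_grid(cond = c("cvd", "diabetes"),
                     gv = c("global", "gender", "age_group", "activity")) |>
    purrr::pmap_dfr(function(cond, gv) one(cond, gv, big))
}

#' Split a population into a donor/recipient fusion scenario
#'
#' Donors are sampled without replacement; the clinical block is removed from
#' the remaining rows to form the recipient file, and the removed values are
#' kept aside as hidden truth for evaluation.
#'
#' @param population A fully observed survey tibble (from
#'   [generate_population()]).
#' @param donor_fraction Fraction of rows examined clinically (0 < f < 1).
#' @param seed Integer seed (split is deterministic given the seed).
#' @param spec Fusion spec; defaults to [synthetic_fusion_spec()].
#' @return List with `donor`, `recipient`, `hidden_truth` tibbles plus the
#'   `spec` and `schema`.
#' @export
make_fusion_scenario <- function(population, donor_fraction = 1508 / 11614,
                                 seed = 1L, spec = synthetic_fusion_spec()) {
  if (donor_fraction <= 0 || donor_fraction >= 1) {
    abort("donor_fraction must lie strictly between 0 and 1")
  }
  population <- ensure_row_id(population)
  n <- nrow(population)
  n0 <- round(n * donor_fraction)
  if (n0 < 2) abort("donor_fraction yields fewer than 2 donors")
  if (n0 >= n) abort("donor_fraction leaves an empty recipient file")
  idx <- with_seed_if(seed, sample.int(n, n0))
  donor <- population[sort(idx), , drop = FALSE]
  rest <- population[-sort(idx), , drop = FALSE]
  recipient <- dplyr::select(rest, -dplyr::any_of(spec$specific))
  hidden <- dplyr::select(rest, dplyr::all_of(c(".row_id", spec$specific)))
  list(donor = donor, recipient = recipient, hidden_truth = hidden,
       spec = spec, schema = synthetic_schema())
}
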