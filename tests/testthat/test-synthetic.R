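test_that("generator handles degenerate sizes and is seed-deterministic", {
  p0 <- population_params(n = 0, truth_n = 0)
  out0 <- generate_population(p0, seed = 1)
  expect_equal(nrow(out0$population), 0)

  p <- population_params(n = 400, truth_n = 0)
  a <- generate_population(p, seed = 7)$population
  b <- generate_population(p, seed = 7)$population
  expect_identical(a, b)
  expect_false(identical(a, generate_population(p, seed = 8)$population))
})

test_that("zero reporting error makes self-reported equal clinical values", {
  p <- population_params(n = 300, truth_n = 0,
                         reporting = list(height_bias = 0, height_sd = 0,
                                          weight_bias = 0, weight_sd = 0))
  pop <- generate_population(p, seed = 3)$population
  expect_equal(pop$self_height, pop$clin_height)
  expect_equal(pop$self_weight, pop$clin_weight)
})

test_that("invalid parameters are rejected", {
  expect_error(population_params(glucose = list(sd = -1)), "standard deviations")
  expect_error(population_params(gender = c(Female = 0.9, Male = 0.3)),
               "sum to 1")
})

test_that("generated tables satisfy the survey schema invariants", {
  pop <- generate_population(population_params(n = 500, truth_n = 0),
                             seed = 11)$population
  sch <- synthetic_schema()
  for (i in seq_len(nrow(sch))) {
    v <- sch$variable[i]
    if (sch$kind[i] == "categorical") {
      expect_true(all(pop[[v]] %in% sch$levels[[i]]), label = v)
    } else {
      expect_true(all(is.finite(pop[[v]])), label = v)
    }
  }
  expect_equal(pop$age_group, band_age(pop$age_cont))
  expect_equal(pop$bmi, pop$clin_weight / (pop$clin_height / 100)^2)
})

test_that("Monte-Carlo truth matches an independent brute-force oracle", {
  # oracle: recompute the condition probabilities directly from the logistic
  # coefficients on a generated population and average them (no Bernoulli
  # draw involved), independently of the generator's own tabulation
  p <- population_params(n = 60000, truth_n = 60000)
  out <- generate_population(p, seed = 19)
  pop <- out$population
  cv <- p$cvd
  eta <- cv$intercept + cv$age * pop$age_cont +
    cv$male * (pop$gender == "Male") + cv$bmi * pop$bmi +
    cv$sys * pop$sys_bp + cv$chol * pop$cholesterol +
    cv$sedentary * (pop$activity == "Sedentary") +
    cv$smoker * (pop$smoking == "Regular smoker") + cv$waist * pop$waist
  oracle <- mean(plogis(eta))
  truth <- out$truth$prevalence
  got <- truth$prevalence[truth$condition == "cvd" & truth$group == "global"]
  se <- truth$mc_se[truth$condition == "cvd" & truth$group == "global"]
  # both are Monte-Carlo estimates of the same quantity
  tol <- 3 * sqrt(se^2 + oracle * (1 - oracle) / nrow(pop))
  expect_lt(abs(got - oracle), tol)
})

test_that("fusion scenario splits reproduce the population exactly", {
  pop <- generate_population(population_params(n = 800, truth_n = 0),
                             seed = 5)$population
  sc <- make_fusion_scenario(pop, donor_fraction = 0.13, seed = 6)
  expect_equal(nrow(sc$donor), round(800 * 0.13))
  expect_equal(nrow(sc$donor) + nrow(sc$recipient), 800)
  # joining recipient X-block with hidden truth reconstructs the rows
  rebuilt <- dplyr::inner_join(sc$recipient, sc$hidden_truth, by = ".row_id")
  orig <- dplyr::semi_join(pop, rebuilt, by = ".row_id")
  expect_equal(nrow(rebuilt), nrow(sc$recipient))
  expect_equal(rebuilt[order(rebuilt$.row_id), names(orig)],
               orig[order(orig$.row_id), ])
  # determinism
  sc2 <- make_fusion_scenario(pop, donor_fraction = 0.13, seed = 6)
  expect_identical(sc$donor$.row_id, sc2$donor$.row_id)
  # degenerate fractions
  expect_error(make_fusion_scenario(pop, 1, seed = 1), "strictly between")
  expect_error(make_fusion_scenario(pop, 1e-5, seed = 1), "fewer than 2")
})

test_that("design-ratio split sizes mirror the motivating survey", {
  pop <- generate_population(population_params(n = 11614, truth_n = 0),
                             seed = 2)$population
  sc <- make_fusion_scenario(pop, donor_fraction = 1508 / 11614, seed = 3)
  expect_equal(nrow(sc$donor), 1508)
  expect_equal(nrow(sc$recipient), 10106)
})

test_that("with all cross-links severed no engine beats a marginal predictor", {
  p <- population_params(n = 900, truth_n = 0, null_links = TRUE)
  pop <- generate_population(p, seed = 30)$population
  spec <- clinical_fusion_spec()
  sc <- make_fusion_scenario(pop, donor_fraction = 300 / 900, seed = 31,
                             spec = spec)
  donor_x <- dplyr::select(sc$donor, -dplyr::all_of(spec$specific))
  model <- fit_knn_hotdeck(sc$donor, spec, sc$schema, k = 1)
  knn_tau <- imputation_accuracy(
    sc$donor, impute_knn(model, donor_x, seed = 32, exclude_self = TRUE),
    spec, sc$schema)$TAU
  # marginal predictor: a random permutation of the observed donor values
  marginal <- sc$donor
  perm <- withr::with_seed(33, sample.int(nrow(marginal)))
  for (v in spec$specific) marginal[[v]] <- sc$donor[[v]][perm]
  marg_tau <- imputation_accuracy(sc$donor, marginal, spec, sc$schema)$TAU
  # in a world where X carries no information, matching cannot add accuracy
  expect_lt(knn_tau, marg_tau + 0.05)
  expect_lt(knn_tau, 0.08)
})
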