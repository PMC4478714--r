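test_that("a single linear submodel matches the normal-equation oracle", {
  donor <- toy_table(10, seed = 20)
  donor$score <- 3 + 0.5 * donor$age + 2 * (donor$gender == "Male") +
    withr::with_seed(21, rnorm(10, 0, 2))
  spec <- fusion_spec(c("gender", "age"), "score")
  model <- fit_sequential_regression(
    donor, spec, toy_schema(),
    chain = list(chain_step("score", candidates = c("gender", "age"))),
    alpha = 1, min_rows_per_param = 1)
  sm <- model$submodels[[1]]

  X <- cbind(1, donor$gender == "Male", donor$age)
  beta_oracle <- solve(t(X) %*% X, t(X) %*% donor$score)
  resid <- donor$score - X %*% beta_oracle
  sigma_oracle <- sqrt(sum(resid^2) / (10 - 3))
  expect_equal(unname(sm$coef[c("(Intercept)", "genderMale", "age")]),
               drop(beta_oracle), tolerance = 1e-10)
  expect_equal(sm$sigma, sigma_oracle, tolerance = 1e-10)
})

test_that("zero residual SD with fixed parameters gives the conditional mean", {
  sc <- tiny_scenario(n = 700, donor_n = 330, seed = 22)
  model <- fit_sequential_regression(sc$donor, sc$spec, sc$schema,
                                     chain = clinical_chain())
  for (i in seq_along(model$submodels)) {
    if (identical(model$submodels[[i]]$type, "gaussian")) {
      model$submodels[[i]]$sigma <- 0
    }
  }
  a <- impute_sequential(model, sc$recipient, seed = 1)
  b <- impute_sequential(model, sc$recipient, seed = 2)
  cont <- c("clin_height", "clin_weight", "bmi", "waist", "sys_bp", "dia_bp",
            "cholesterol", "glucose")
  expect_equal(a[cont], b[cont])  # continuous block is deterministic
})

test_that("derived BMI equals drawn weight over drawn height squared", {
  sc <- tiny_scenario(n = 700, donor_n = 330, seed = 23)
  model <- fit_sequential_regression(sc$donor, sc$spec, sc$schema,
                                     chain = clinical_chain())
  got <- impute_sequential(model, sc$recipient, seed = 9)
  expect_equal(got$bmi, got$clin_weight / (got$clin_height / 100)^2)
})

test_that("repeated draws of one row average to the fitted conditional mean", {
  donor <- toy_table(60, seed = 24)
  donor$score <- 10 + donor$age * 0.8 + withr::with_seed(25, rnorm(60, 0, 3))
  spec <- fusion_spec(c("gender", "age"), "score")
  model <- fit_sequential_regression(
    donor, spec, toy_schema(),
    chain = list(chain_step("score", candidates = "age")), alpha = 1)
  sm <- model$submodels[[1]]
  row <- tibble::tibble(gender = "Female", age = 47, .row_id = "x")
  draws <- vapply(seq_len(800), function(i)
    impute_sequential(model, row, seed = 1000 + i)$score, numeric(1))
  mu <- sm$coef[["(Intercept)"]] + sm$coef[["age"]] * 47
  expect_lt(abs(mean(draws) - mu), 3 * sm$sigma / sqrt(800))
})

test_that("chain recovers generating coefficients on a synthetic donor", {
  p <- population_params(n = 2000, truth_n = 0)
  donor <- generate_population(p, seed = 26)$population
  model <- fit_sequential_regression(donor, synthetic_fusion_spec(),
                                     synthetic_schema(),
                                     chain = synthetic_generating_chain(),
                                     alpha = 1)
  est <- tidy(model)
  expected <- generating_coefficients(p)
  chk <- dplyr::inner_join(est, expected, by = c("outcome", "term"))
  expect_gt(nrow(chk), 25)
  off <- abs(chk$estimate - chk$truth) / chk$std.error
  expect_lt(mean(off > 3), 0.1)  # a rare 3-SE excursion is allowed
})

test_that("degenerate and ill-ordered chains are rejected", {
  sc <- tiny_scenario(n = 700, donor_n = 330, seed = 27)
  donor <- sc$donor
  donor$diabetes <- "No"
  chain <- clinical_chain()
  expect_error(
    fit_sequential_regression(donor, sc$spec, sc$schema, chain = chain),
    "single observed level")
  bad_chain <- clinical_chain()[c(3, 1, 2, 4:10)]  # BMI before height/weight
  expect_error(
    fit_sequential_regression(sc$donor, sc$spec, sc$schema, chain = bad_chain),
    "before it is available")
  expect_error(chain_step("x", candidates = character()), "empty candidate")
  expect_error(
    fit_sequential_regression(sc$donor, sc$spec, sc$schema,
                              chain = clinical_chain()[1:5]),
    "every specific variable exactly once")
})

test_that("unseen recipient factor levels are reported at imputation", {
  sch <- survey_schema(
    variable = c("region", "age", "score"),
    role = c("common", "common", "specific"),
    kind = c("categorical", "continuous", "continuous"),
    levels = list(c("north", "south", "islands"), NULL, NULL))
  donor <- withr::with_seed(28, tibble::tibble(
    region = sample(c("north", "south"), 40, TRUE),
    age = runif(40, 20, 80)))
  donor$score <- 2 + 0.1 * donor$age + (donor$region == "south") +
    withr::with_seed(29, rnorm(40, 0, 0.5))
  spec <- fusion_spec(c("region", "age"), "score")
  model <- fit_sequential_regression(
    donor, spec, sch,
    chain = list(chain_step("score", candidates = c("age", "region"))),
    alpha = 1)
  rec <- tibble::tibble(region = "islands", age = 30)
  expect_error(impute_sequential(model, rec, seed = 1),
               "not in the donor design")
})

test_that("backward elimination drops noise terms but keeps forced ones", {
  donor <- toy_table(150, seed = 29)
  donor$score <- 5 + 2 * donor$age + withr::with_seed(30, rnorm(150, 0, 4))
  spec <- fusion_spec(c("gender", "age"), "score")
  pruned <- fit_sequential_regression(
    donor, spec, toy_schema(),
    chain = list(chain_step("score", candidates = c("age", "gender"))))
  expect_false("genderMale" %in% names(pruned$submodels[[1]]$coef))
  forced <- fit_sequential_regression(
    donor, spec, toy_schema(),
    chain = list(chain_step("score", candidates = "age", forced = "gender")))
  expect_true("genderMale" %in% names(forced$submodels[[1]]$coef))
})

test_that("multicategory outcomes are fitted and drawn within levels", {
  sch <- survey_schema(
    variable = c("x", "y3"), role = c("common", "specific"),
    kind = c("continuous", "categorical"),
    levels = list(NULL, c("a", "b", "c")))
  donor <- withr::with_seed(31, {
    x <- runif(400, -2, 2)
    pr <- cbind(1, exp(1.2 * x), exp(-1.2 * x))
    y <- apply(pr, 1, function(p) sample(c("a", "b", "c"), 1, prob = p))
    tibble::tibble(x = x, y3 = y)
  })
  spec <- fusion_spec("x", "y3")
  model <- fit_sequential_regression(
    donor, spec, sch, chain = list(chain_step("y3", candidates = "x")),
    alpha = 1)
  expect_equal(model$submodels[[1]]$type, "multinomial")
  got <- impute_sequential(model, tibble::tibble(x = runif(200, -2, 2)),
                           seed = 3)
  expect_true(all(got$y3 %in% c("a", "b", "c")))
})
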