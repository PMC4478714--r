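test_that("perfect imputation attains every statistic's ideal value", {
  sc <- tiny_scenario(n = 300, donor_n = 120, seed = 60)
  rep <- validate_fusion(sc$donor, sc$donor, sc$spec, sc$schema)
  vals <- setNames(rep$statistics$value, rep$statistics$statistic)
  expect_equal(unname(vals[c("ASLm", "ASLs", "WC", "TAU", "RndRes")]),
               rep(1, 5))
  expect_equal(unname(vals[c("ACDi", "ACDe", "ASD")]), rep(0, 3))
  expect_true(rep$residuals_degenerate)
})

test_that("a marginal-preserving row permutation separates the statistics", {
  sc <- tiny_scenario(n = 1000, donor_n = 500, seed = 61)
  donor <- sc$donor
  perm <- withr::with_seed(62, sample.int(nrow(donor)))
  shuffled <- donor
  for (v in sc$spec$specific) shuffled[[v]] <- donor[[v]][perm]
  rep <- validate_fusion(donor, shuffled, sc$spec, sc$schema)
  vals <- setNames(rep$statistics$value, rep$statistics$statistic)
  # identical empirical distributions: ASL tests at their null, ASD exactly 0
  expect_equal(unname(vals[["ASD"]]), 0)
  expect_equal(unname(vals[["ASLm"]]), 1)
  expect_equal(unname(vals[["ASLs"]]), 1)
  # but links to X are destroyed and accuracy is gone
  expect_lt(vals[["TAU"]], 0.1)
  expect_gt(vals[["ACDe"]], 0.05)
  expect_lt(vals[["RndRes"]], 0.4)
  # within-Y structure is destroyed too (independent permutation per variable
  # would be needed for ACDi; a common permutation preserves it)
  expect_lt(vals[["ACDi"]], 0.05)
})

test_that("statistics are invariant to row order given identifier pairing", {
  sc <- tiny_scenario(n = 240, donor_n = 120, seed = 63)
  model <- fit_knn_hotdeck(sc$donor, sc$spec, sc$schema, k = 3)
  donor_x <- dplyr::select(sc$donor, -dplyr::all_of(sc$spec$specific))
  imp <- impute_knn(model, donor_x, seed = 5, exclude_self = TRUE)
  rep1 <- validate_fusion(sc$donor, imp, sc$spec, sc$schema)
  shuffle <- withr::with_seed(64, sample.int(nrow(imp)))
  rep2 <- validate_fusion(sc$donor, imp[shuffle, ], sc$spec, sc$schema)
  expect_equal(rep1$statistics, rep2$statistics)
})

test_that("ACD matches hand-computed correlation differences", {
  sch <- survey_schema(variable = c("x", "y1", "y2"),
                       role = c("common", "specific", "specific"),
                       kind = "continuous")
  spec <- fusion_spec("x", c("y1", "y2"))
  obs <- withr::with_seed(65, {
    x <- rnorm(40); y1 <- x + rnorm(40, 0, 0.4); y2 <- y1 + rnorm(40, 0, 0.6)
    tibble::tibble(x = x, y1 = y1, y2 = y2)
  })
  imp <- withr::with_seed(66, dplyr::mutate(obs, y2 = rnorm(40)))
  got <- correlation_discrepancy(obs, imp, spec, sch)
  expect_equal(got$ACDi, abs(cor(obs$y1, obs$y2) - cor(imp$y1, imp$y2)))
  expect_equal(got$ACDe, mean(c(abs(cor(obs$y1, obs$x) - cor(imp$y1, imp$x)),
                                abs(cor(obs$y2, obs$x) - cor(imp$y2, imp$x)))))
})

test_that("WC matches the closed form under a sign flip", {
  sch <- survey_schema(variable = c("x", "y1", "y2"),
                       role = c("common", "specific", "specific"),
                       kind = "continuous")
  spec <- fusion_spec("x", c("y1", "y2"))
  obs <- withr::with_seed(67, {
    y1 <- rnorm(60); y2 <- 0.7 * y1 + rnorm(60, 0, 0.5)
    tibble::tibble(x = rnorm(60), y1 = y1, y2 = y2)
  })
  flip <- dplyr::mutate(obs, y2 = -y2)
  got <- multivariate_congruence(obs, flip, spec, sch)
  # oracle: congruence of S and D S D with D = diag(1, -1), computed directly
  z <- scale(cbind(obs$y1, obs$y2), scale = c(sd(obs$y1), sd(obs$y2)))
  S1 <- crossprod(z)
  D <- diag(c(1, -1))
  S2 <- D %*% S1 %*% D
  expect_equal(got, sum(S1 * S2) / sqrt(sum(S1^2) * sum(S2^2)),
               tolerance = 1e-10)
  expect_lt(got, 1)
})

test_that("ASD combines KS distance and total variation as specified", {
  sch <- survey_schema(variable = c("x", "y", "g"),
                       role = c("common", "specific", "specific"),
                       kind = c("continuous", "continuous", "categorical"),
                       levels = list(NULL, NULL, c("A", "B")))
  spec <- fusion_spec("x", c("y", "g"))
  obs <- tibble::tibble(x = rnorm(10), y = 1:10,
                        g = rep(c("A", "B"), each = 5))
  imp <- tibble::tibble(x = obs$x, y = obs$y,
                        g = rep(c("A", "B"), c(7, 3)))
  got <- distribution_similarity(obs, imp, spec, sch)
  # categorical: (0.5, 0.5) vs (0.7, 0.3) -> total variation 0.2; KS = 0
  expect_equal(got$detail$distance[got$detail$variable == "g"], 0.2)
  expect_equal(got$ASD, 0.1)
  ks <- suppressWarnings(stats::ks.test(obs$y, obs$y + 2.5)$statistic)
  imp2 <- dplyr::mutate(obs, y = y + 2.5)
  got2 <- distribution_similarity(obs, imp2, spec, sch)
  expect_equal(unname(got2$detail$distance[got2$detail$variable == "y"]),
               unname(ks))
})

test_that("TAU uses chance-corrected agreement and error reduction", {
  sch <- survey_schema(variable = c("x", "g"),
                       role = c("common", "specific"),
                       kind = c("continuous", "categorical"),
                       levels = list(NULL, c("A", "B")))
  spec <- fusion_spec("x", "g")
  obs <- tibble::tibble(x = rnorm(100), g = rep(c("A", "B"), each = 50))
  imp <- obs
  # agreement table: 40 A-A, 10 A->B, 10 B->A, 40 B-B
  imp$g[41:50] <- "B"
  imp$g[51:60] <- "A"
  got <- imputation_accuracy(obs, imp, spec, sch)
  # closed form: po = 0.8, pe = 0.5, kappa = 0.6
  expect_equal(got$TAU, 0.6)

  # continuous: permutation destroys accuracy, floored at 0
  sch2 <- survey_schema(variable = c("x", "y"), role = c("common", "specific"),
                        kind = "continuous")
  spec2 <- fusion_spec("x", "y")
  obs2 <- withr::with_seed(68, tibble::tibble(x = rnorm(2000),
                                              y = rnorm(2000)))
  imp2 <- dplyr::mutate(obs2, y = withr::with_seed(69, sample(y)))
  got2 <- imputation_accuracy(obs2, imp2, spec2, sch2)
  expect_equal(got2$TAU, 0)
  # identical -> 1
  expect_equal(imputation_accuracy(obs2, obs2, spec2, sch2)$TAU, 1)
})

test_that("RndRes detects structured residuals and passes a null", {
  sch <- survey_schema(variable = c("x", "y"), role = c("common", "specific"),
                       kind = "continuous")
  spec <- fusion_spec("x", "y")
  obs <- withr::with_seed(70, tibble::tibble(x = rnorm(300),
                                             y = rnorm(300)))
  # residual exactly equal to the common variable -> maximal structure
  imp_structured <- dplyr::mutate(obs, y = y - x)
  got <- residual_randomness(obs, imp_structured, spec, sch)
  expect_lt(got$RndRes, 1e-6)
  # toy 8-row fixture: p equals the hand correlation-test formula
  obs8 <- tibble::tibble(x = c(1, 2, 3, 4, 5, 6, 7, 8),
                         y = c(2, 4, 5, 4, 5, 7, 8, 9))
  imp8 <- dplyr::mutate(obs8, y = c(1, 5, 4, 5, 5, 6, 9, 8))
  r <- obs8$y - imp8$y
  rho <- cor(r, obs8$x)
  tstat <- rho * sqrt(6 / (1 - rho^2))
  p_oracle <- 2 * stats::pt(-abs(tstat), df = 6)
  got8 <- residual_randomness(obs8, imp8, spec, sch)
  expect_equal(got8$RndRes, p_oracle, tolerance = 1e-12)
  # perfect imputation flagged degenerate with RndRes 1
  gotp <- residual_randomness(obs, obs, spec, sch)
  expect_true(gotp$degenerate)
  expect_equal(gotp$RndRes, 1)
})

test_that("predictive relevance spans the exact-fit and independence limits", {
  sch <- survey_schema(variable = c("x", "y"), role = c("common", "specific"),
                       kind = "continuous")
  spec <- fusion_spec("x", "y")
  exact <- tibble::tibble(x = 1:50, y = 2 * (1:50) + 3)
  got <- predictive_relevance(exact, spec, sch)
  expect_equal(got$power, 1, tolerance = 1e-12)
  indep <- withr::with_seed(71, tibble::tibble(x = rnorm(4000),
                                               y = rnorm(4000)))
  got2 <- predictive_relevance(indep, spec, sch)
  expect_lt(got2$power, 0.01)
  expect_true(got2$weak)
})

test_that("validation reports serialize and restore losslessly", {
  sc <- tiny_scenario(n = 200, donor_n = 100, seed = 72)
  model <- fit_knn_hotdeck(sc$donor, sc$spec, sc$schema, k = 2)
  donor_x <- dplyr::select(sc$donor, -dplyr::all_of(sc$spec$specific))
  imp <- impute_knn(model, donor_x, seed = 3, exclude_self = TRUE)
  rep <- validate_fusion(sc$donor, imp, sc$spec, sc$schema)
  path <- tempfile(fileext = ".json")
  write_validation_report(rep, path)
  back <- read_validation_report(path)
  expect_equal(back$statistics$value, rep$statistics$value)
  expect_equal(back$residuals_degenerate, rep$residuals_degenerate)
})
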