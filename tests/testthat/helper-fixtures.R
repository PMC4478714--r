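# Shared fixtures: built in code at test time, never stored on disk.

# Small fusion scenario from the synthetic generator.
tiny_scenario <- function(n = 900, donor_n = 250, seed = 42,
                          spec = synthetic_fusion_spec(), ...) {
  pop <- generate_population(population_params(n = n, truth_n = 0, ...),
                             seed = seed)
  make_fusion_scenario(pop$population, donor_fraction = donor_n / n,
                       seed = seed + 1, spec = spec)
}

# Hand-rolled two-variable schema for toy examples.
toy_schema <- function() {
  survey_schema(
    variable = c("gender", "age", "score", "grade"),
    role = c("common", "common", "specific", "specific"),
    kind = c("categorical", "continuous", "continuous", "categorical"),
    levels = list(c("Female", "Male"), NULL, NULL, c("low", "high")),
    codes = list(c("1" = "Female", "2" = "Male"), NULL, NULL, NULL)
  )
}

toy_spec <- function() fusion_spec(c("gender", "age"), c("score", "grade"))

toy_table <- function(n = 12, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    gender = sample(c("Female", "Male"), n, replace = TRUE),
    age = round(runif(n, 20, 80), 1),
    score = round(rnorm(n, 50, 10), 2),
    grade = sample(c("low", "high"), n, replace = TRUE),
    .row_id = paste0("r", seq_len(n))
  ))
}

write_toy_csv <- function(data, path = tempfile(fileext = ".csv")) {
  readr::write_csv(data, path, na = "")
  path
}
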