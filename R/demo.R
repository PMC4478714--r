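#' Default configuration for the end-to-end demo workflow
#'
#' @param seed Master seed.
#' @param out_dir Output directory for artifacts.
#' @param ... Overrides (`n`, `donor_fraction`, `n_boot`, `m`, `methods`,
#'   `da_burn_in`, `da_spacing`, `donor_path`, `recipient_path`,
#'   `schema_path`). When `donor_path`/`recipient_path` are given, those
#'   files are fused instead of a simulated scenario.
#' @return A list of class `run_config`.
#' @export
demo_config <- function(seed = 1L, out_dir = tempfile("surveyfuse_demo_"),
                        ...) {
  cfg <- modifyList(list(
    seed = seed, out_dir = out_dir, n = 3000, donor_fraction = 1508 / 11614,
    n_boot = 10, m = 5, methods = comparison_methods(),
    da_burn_in = 100, da_spacing = 10, truth_n = 50000,
    donor_path = NULL, recipient_path = NULL, schema_path = NULL
  ), list(...))
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file with the fields of [demo_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  do.call(demo_config, cfg)
}

validate_run_config <- function(cfg) {
  for (f in c("donor_path", "recipient_path", "schema_path")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      abort(sprintf("config error: %s '%s' does not exist", f, cfg[[f]]))
    }
  }
  if (!is_scalar_number(cfg$seed)) abort("config error: seed must be an integer")
  if (cfg$m < 2) abort("config error: m must be >= 2")
  invisible(cfg)
}

stage <- function(name, code) {
  t0 <- Sys.time()
  inform(sprintf("[%s] started", name))
  out <- tryCatch(code, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
  })
  inform(sprintf("[%s] done in %.1fs", name,
                 as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

#' Run the full fusion workflow end to end
#'
#' Generates (or loads) a donor/recipient scenario, compares the six
#' imputation methods on bootstrap resamples at the configured scale, ranks
#' them, multiply-imputes the recipient file with the clinical
#' sequential-regression chain, and writes the prevalence table with SD
#' ratios plus all reports, figures and a manifest to the output directory.
#'
#' @param config A [demo_config()] or [read_run_config()] result.
#' @return The output directory path, invisibly.
#' @export
run_demo <- function(config = demo_config()) {
  validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 5)

  scenario <- stage("scenario", {
    if (!is.null(config$donor_path)) {
      schema <- read_schema(config$schema_path)
      donor <- read_survey(config$donor_path, schema)
      recipient <- read_survey(config$recipient_path, schema)
      spec <- fusion_spec(schema_vars(schema, "common"),
                          schema_vars(schema, "specific"))
      list(donor = donor, recipient = recipient, spec = spec,
           schema = schema)
    } else {
      pop <- generate_population(
        population_params(n = config$n, truth_n = config$truth_n),
        seed = seeds[1])
      sc <- make_fusion_scenario(pop$population, config$donor_fraction,
                                 seed = seeds[2])
      write_survey(sc$donor, file.path(config$out_dir, "donor.csv"))
      write_survey(sc$recipient, file.path(config$out_dir, "recipient.csv"))
      sc
    }
  })

  comparison <- stage("comparison", {
    res <- run_comparison(
      scenario$donor, scenario$recipient, scenario$spec, scenario$schema,
      methods = config$methods, n_boot = config$n_boot, m = config$m,
      seed = seeds[3],
      control = list(chain = clinical_chain(), da_burn_in = config$da_burn_in,
                     da_spacing = config$da_spacing))
    readr::write_csv(res$values, file.path(config$out_dir, "comparison_values.csv"))
    readr::write_csv(res$summary, file.path(config$out_dir, "comparison_summary.csv"))
    plot_densities(res, file.path(config$out_dir, "statistic_densities.png"))
    res
  })

  ranking <- stage("ranking", {
    rk <- rank_methods(comparison)
    readr::write_csv(rk$by_statistic, file.path(config$out_dir, "method_ranking.csv"))
    rk
  })

  fused <- stage("multiple imputation", {
    mi <- multiply_impute(scenario$donor, scenario$recipient, scenario$spec,
                          scenario$schema, method = "sqreg", m = config$m,
                          seed = seeds[4], chain = clinical_chain())
    purrr::iwalk(mi$tables, function(tab, i) {
      write_survey(tab, file.path(config$out_dir, sprintf("imputation_%02d.csv", i)))
    })
    mi
  })

  prevalence <- stage("prevalence", {
    pt <- estimate_prevalence(scenario$donor, fused,
                              conditions = c("cvd", "diabetes"),
                              subgroup_vars = c("gender", "age_group", "activity"))
    readr::write_csv(pt, file.path(config$out_dir, "prevalence.csv"))
    pt
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("surveyfuse")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed, derived_seeds = seeds,
    settings = config[c("n", "donor_fraction", "n_boot", "m", "methods",
                        "da_burn_in", "da_spacing")]
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(config$out_dir)
}
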