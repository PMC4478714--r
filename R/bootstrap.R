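comparison_methods <- function() {
  c("1nn", "sqreg", "da", "mi_knn", "mi_sqreg", "mi_da")
}

# A bootstrap donor resample is degenerate when a categorical level present
# in the validation set vanishes from it: engines would face unseen levels.
resample_is_degenerate <- function(resample, reference, vars, schema) {
  for (v in vars) {
    if (schema_kind(schema, v) != "categorical") next
    if (length(setdiff(unique(reference[[v]]), unique(resample[[v]]))) > 0) {
      return(TRUE)
    }
  }
  FALSE
}

#' Compare imputation methods over bootstrap resamples
#'
#' Runs the method-comparison experiment: at each iteration the donor and
#' recipient files are resampled with replacement, every requested engine is
#' fitted on the bootstrap donor, the donors' specific block is re-imputed
#' from their common block only, and the eight validation statistics are
#' computed against the donors' actual values (validation on donors only;
#' since only donors carry the truth). For multiple-imputation cells each
#' statistic is computed on each of the `m` completed sets and the mean is
#' recorded. A donor may never donate to itself during this validation:
#' self-donation in the hot deck is excluded by row identity, otherwise
#' nearest-neighbour methods would be trivially perfect.
#'
#' Degenerate resamples (a categorical level vanishing from the bootstrap
#' donor) are rejected and redrawn; engine failures are logged, the
#' iteration redrawn, and the run aborts if the failure rate exceeds
#' `fail_ceiling`.
#'
#' @param donor,recipient Survey tibbles.
#' @param spec A [fusion_spec()]; @param schema A [survey_schema()].
#' @param methods Subset of `"1nn"`, `"sqreg"`, `"da"`, `"mi_knn"`,
#'   `"mi_sqreg"`, `"mi_da"`.
#' @param n_boot Number of bootstrap iterations.
#' @param m Imputation count for the MI cells.
#' @param seed Master integer seed; the full result is reproducible from it.
#' @param control List of engine settings: `knn_mi_k` (default 10), `alpha`,
#'   `chain`, `min_rows_per_param`, `da_burn_in` (default 500), `da_spacing`
#'   (default 100), `ridge`, `fail_ceiling` (default 0.2), `max_redraws`.
#' @return An object of class `comparison_result` with elements `values`
#'   (long tibble: iteration, method, statistic, value), `summary`,
#'   `settings`, `n_redraws`, `n_failures`.
#' @export
run_comparison <- function(donor, recipient, spec, schema,
                           methods = comparison_methods(), n_boot = 400,
                           m = 20, seed = 1L, control = list()) {
  methods <- match.arg(methods, comparison_methods(), several.ok = TRUE)
  if (length(methods) == 0) abort("method list is empty")
  if (nrow(donor) == 0) abort("donor file is empty")
  if (n_boot < 1) abort("n_boot must be >= 1")
  if (any(startsWith(methods, "mi_")) && m < 2) abort("MI methods need m >= 2")
  ctl <- modifyList(list(knn_mi_k = 10L, alpha = 0.05, chain = NULL,
                         min_rows_per_param = 10, da_burn_in = 500,
                         da_spacing = 100, ridge = 1e-6, fail_ceiling = 0.2,
                         max_redraws = 25L), control)
  donor <- ensure_row_id(donor, "d")
  recipient <- ensure_row_id(recipient)
  donor_x <- dplyr::select(donor, -dplyr::all_of(spec$specific))
  it_seeds <- derive_seeds(seed, n_boot)
  n_redraws <- 0L
  n_failures <- 0L

  run_iteration <- function(it_seed) {
    sub <- derive_seeds(it_seed, 6 + 2 * m)
    boot <- with_seed_if(sub[1], list(
      d = donor[sample.int(nrow(donor), replace = TRUE), , drop = FALSE],
      r = recipient[sample.int(nrow(recipient), replace = TRUE), , drop = FALSE]
    ))
    if (resample_is_degenerate(boot$d, donor, spec$common, schema)) {
      return(NULL)
    }
    rows <- list()
    add <- function(method, report_values) {
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        method = method,
        statistic = names(report_values),
        value = unname(report_values))
    }
    stat_values <- function(completed) {
      g <- glance(validate_fusion(donor, completed, spec, schema))
      unlist(g[1, ])
    }
    needs_knn <- "1nn" %in% methods
    needs_miknn <- "mi_knn" %in% methods
    if (needs_knn || needs_miknn) {
      if (needs_knn) {
        m1 <- fit_knn_hotdeck(boot$d, spec, schema, k = 1L)
        add("1nn", stat_values(
          impute_knn(m1, donor_x, seed = sub[2], exclude_self = TRUE)))
      }
      if (needs_miknn) {
        mk <- fit_knn_hotdeck(boot$d, spec, schema,
                              k = min(ctl$knn_mi_k, nrow(boot$d)))
        vals <- purrr::map(seq_len(m), function(j) stat_values(
          impute_knn(mk, donor_x, seed = sub[6 + j], exclude_self = TRUE)))
        add("mi_knn", colMeans(do.call(rbind, vals)))
      }
    }
    if (any(c("sqreg", "mi_sqreg") %in% methods)) {
      ms <- fit_sequential_regression(boot$d, spec, schema,
                                      chain = ctl$chain, alpha = ctl$alpha,
                                      min_rows_per_param = ctl$min_rows_per_param)
      if ("sqreg" %in% methods) {
        add("sqreg", stat_values(
          impute_sequential(ms, donor_x, seed = sub[3])))
      }
      if ("mi_sqreg" %in% methods) {
        vals <- purrr::map(seq_len(m), function(j) stat_values(
          impute_sequential(ms, donor_x, seed = sub[6 + m + j],
                            draw_parameters = TRUE)))
        add("mi_sqreg", colMeans(do.call(rbind, vals)))
      }
    }
    if ("da" %in% methods) {
      one <- da_impute(boot$d, donor_x, spec, schema,
                       burn_in = ctl$da_burn_in, n_draws = 1,
                       spacing = ctl$da_spacing, seed = sub[4],
                       ridge = ctl$ridge)
      add("da", stat_values(one[[1]]))
    }
    if ("mi_da" %in% methods) {
      draws <- da_impute(boot$d, donor_x, spec, schema,
                         burn_in = ctl$da_burn_in, n_draws = m,
                         spacing = ctl$da_spacing, seed = sub[5],
                         ridge = ctl$ridge)
      vals <- purrr::map(draws, stat_values)
      add("mi_da", colMeans(do.call(rbind, vals)))
    }
    dplyr::bind_rows(rows)
  }

  values <- purrr::map_dfr(seq_len(n_boot), function(i) {
    it_seed <- it_seeds[i]
    for (attempt in seq_len(ctl$max_redraws)) {
      out <- tryCatch(run_iteration(it_seed), error = function(e) e)
      if (is.null(out)) {
        n_redraws <<- n_redraws + 1L
      } else if (inherits(out, "error")) {
        n_failures <<- n_failures + 1L
        if (n_failures > max(5, ctl$fail_ceiling * n_boot)) {
          abort(sprintf("engine failure rate exceeded ceiling: %s",
                        conditionMessage(out)))
        }
      } else {
        return(dplyr::mutate(out, iteration = i, .before = 1))
      }
      it_seed <- derive_seeds(it_seed, 1)
    }
    abort(sprintf("iteration %d: no valid bootstrap draw after %d attempts",
                  i, ctl$max_redraws))
  })

  summary <- values |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     q25 = quantile(.data$value, 0.25),
                     q50 = quantile(.data$value, 0.5),
                     q75 = quantile(.data$value, 0.75),
                     .by = c("method", "statistic"))
  structure(list(
    values = values, summary = summary,
    settings = list(methods = methods, n_boot = n_boot, m = m, seed = seed,
                    control = ctl),
    n_redraws = n_redraws, n_failures = n_failures
  ), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %d iterations x %d method(s); %d redraws, %d failures\n",
              x$settings$n_boot, length(x$settings$methods),
              x$n_redraws, x$n_failures))
  print(x$summary)
  invisible(x)
}

#' @exportS3Method
tidy.comparison_result <- function(x, ...) x$values

#' @exportS3Method
glance.comparison_result <- function(x, ...) x$summary

#' Rank methods per validation statistic
#'
#' Orders methods by mean statistic value, respecting each statistic's
#' orientation, and reports the bootstrap dispersion of each cell to judge
#' stability. An aggregate (optionally weighted) mean rank is attached.
#'
#' @param result A `comparison_result`.
#' @param orientations Tibble like [statistic_orientations()].
#' @param weights Optional named weights per statistic for the aggregate.
#' @return List of class `method_ranking`: `by_statistic` tibble (statistic,
#'   method, mean, sd, rank) and `aggregate` tibble (method, mean_rank).
#' @export
rank_methods <- function(result, orientations = statistic_orientations(),
                         weights = NULL) {
  missing_or <- setdiff(unique(result$summary$statistic),
                        orientations$statistic)
  if (length(missing_or) > 0) {
    abort(sprintf("no orientation declared for statistic(s): %s",
                  paste(missing_or, collapse = ", ")))
  }
  by_stat <- result$summary |>
    dplyr::left_join(orientations, by = "statistic") |>
    dplyr::mutate(
      rank = rank(ifelse(.data$higher_better, -1, 1) * .data$mean,
                  ties.method = "average"),
      .by = "statistic") |>
    dplyr::select("statistic", "method", "mean", "sd", "rank") |>
    dplyr::arrange(.data$statistic, .data$rank)
  w <- setNames(rep(1, nrow(orientations)), orientations$statistic)
  if (!is.null(weights)) w[names(weights)] <- weights
  aggregate <- by_stat |>
    dplyr::mutate(wgt = w[.data$statistic]) |>
    dplyr::summarise(mean_rank = sum(.data$rank * .data$wgt) / sum(.data$wgt),
                     .by = "method") |>
    dplyr::arrange(.data$mean_rank)
  structure(list(by_statistic = by_stat, aggregate = aggregate),
            class = "method_ranking")
}

#' @export
print.method_ranking <- function(x, ...) {
  cat("<method_ranking> aggregate mean rank:\n")
  print(x$aggregate)
  invisible(x)
}

#' @exportS3Method
tidy.method_ranking <- function(x, ...) x$by_statistic

#' Density panels of the validation statistics across bootstrap iterations
#'
#' One panel per statistic, one curve per method, mirroring the standard
#' six-way comparison display.
#'
#' @param object A `comparison_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.comparison_result <- function(object, ...) {
  ggplot2::ggplot(object$values,
                  ggplot2::aes(x = .data$value, colour = .data$method,
                               linetype = .data$method)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~statistic, scales = "free") +
    ggplot2::labs(x = "statistic value", y = "bootstrap density",
                  colour = "method", linetype = "method") +
    ggplot2::theme_minimal()
}

#' Write the density panels to a figure file
#'
#' @param result A `comparison_result`.
#' @param path Output file (extension decides the device, e.g. `.png`).
#' @param width,height Figure size in inches.
#' @return `path`, invisibly.
#' @export
plot_densities <- function(result, path, width = 10, height = 6) {
  p <- autoplot.comparison_result(result)
  ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
  invisible(path)
}
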