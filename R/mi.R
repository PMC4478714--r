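#' Multiply impute a recipient file
#'
#' Repeats a stochastic imputation engine `m` times: the hot deck redraws a
#' donor among the k nearest per imputation; sequential regression redraws
#' submodel parameters (proper imputation) and residuals per imputation; data
#' augmentation retains `m` spaced draws of one chain. Per-imputation seeds
#' are derived from the master seed, so the whole object is reproducible.
#'
#' @param donor,recipient Survey tibbles.
#' @param spec A [fusion_spec()]; @param schema A [survey_schema()].
#' @param method One of `"knn"`, `"sqreg"`, `"da"`.
#' @param m Number of imputations (>= 2).
#' @param seed Master integer seed.
#' @param ... Engine settings: `k`, `class_vars` (knn); `chain`, `alpha`
#'   (sqreg); `burn_in`, `spacing`, `ridge` (da). A pre-fitted `model` can be
#'   supplied for knn/sqreg to skip refitting.
#' @return An object of class `multi_imputation`: list with `tables` (list of
#'   m completed tibbles), `m`, `method`, `seed`, `seeds`.
#' @export
multiply_impute <- function(donor, recipient, spec, schema,
                            method = c("sqreg", "knn", "da"), m = 20,
                            seed = 1L, ...) {
  method <- match.arg(method)
  if (m < 2) abort("multiple imputation needs m >= 2; use the engines directly for m = 1")
  dots <- list(...)
  seeds <- derive_seeds(seed, m)
  run_one <- function(i, fn) {
    tryCatch(fn(i), error = function(e) {
      abort(sprintf("imputation %d (%s) failed: %s", i, method,
                    conditionMessage(e)))
    })
  }
  if (method == "knn") {
    model <- dots$model %||% fit_knn_hotdeck(
      donor, spec, schema, k = dots$k %||% 10L,
      class_vars = dots$class_vars, weights = dots$weights)
    tables <- purrr::map(seq_len(m), function(i) run_one(i, function(i)
      impute_knn(model, recipient, seed = seeds[i],
                 exclude_self = isTRUE(dots$exclude_self))))
  } else if (method == "sqreg") {
    model <- dots$model %||% fit_sequential_regression(
      donor, spec, schema, chain = dots$chain,
      alpha = dots$alpha %||% 0.05,
      min_rows_per_param = dots$min_rows_per_param %||% 10)
    tables <- purrr::map(seq_len(m), function(i) run_one(i, function(i)
      impute_sequential(model, recipient, seed = seeds[i],
                        draw_parameters = TRUE)))
  } else {
    tables <- da_impute(donor, recipient, spec, schema,
                        burn_in = dots$burn_in %||% 500, n_draws = m,
                        spacing = dots$spacing %||% 100, seed = seeds[1],
                        ridge = dots$ridge %||% 1e-6)
    attr(tables, "settings") <- NULL
  }
  structure(list(tables = tables, m = m, method = method, seed = seed,
                 seeds = seeds),
            class = "multi_imputation")
}

#' @export
print.multi_imputation <- function(x, ...) {
  cat(sprintf("<multi_imputation: %d completed tables, method %s>\n",
              x$m, x$method))
  invisible(x)
}

#' Stack the completed tables of a multiple imputation
#'
#' Returns one long tibble with an `.imp` column, which is also the
#' "concatenated file" export some workflows expect.
#'
#' @param x A `multi_imputation` object.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method
tidy.multi_imputation <- function(x, ...) {
  dplyr::bind_rows(purrr::imap(x$tables, ~ dplyr::mutate(.x, .imp = .y)))
}

#' Combine per-imputation estimates with Rubin's rules
#'
#' Pools m point estimates and their sampling variances: the pooled estimate
#' is the mean, the within variance W is the mean sampling variance, the
#' between variance B is the sample variance of the estimates, and the total
#' variance is `T = W + (1 + 1/m) B`.
#'
#' @param estimates Numeric vector of m point estimates (m >= 2).
#' @param variances Numeric vector of m sampling variances (>= 0).
#' @return An object of class `pooled_estimate`: list with `qbar`, `within`,
#'   `between`, `total`, `sd`, `m`.
#' @export
pool_estimates <- function(estimates, variances) {
  m <- length(estimates)
  if (m < 2 || length(variances) != m) {
    abort("pooling needs m >= 2 estimates with matching variances")
  }
  if (any(!is.finite(estimates)) || any(!is.finite(variances))) {
    abort("estimates and variances must be finite")
  }
  if (any(variances < 0)) abort("sampling variances must be >= 0")
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- var(estimates)
  total <- W + (1 + 1 / m) * B
  structure(list(qbar = qbar, within = W, between = B, total = total,
                 sd = sqrt(total), m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("<pooled_estimate> qbar = %.6g, sd = %.6g (W = %.3g, B = %.3g, m = %d)\n",
              x$qbar, x$sd, x$within, x$between, x$m))
  invisible(x)
}

#' @exportS3Method
glance.pooled_estimate <- function(x, ...) {
  tibble::tibble(qbar = x$qbar, within = x$within, between = x$between,
                 total = x$total, sd = x$sd, m = x$m,
                 conf.low = x$qbar - 1.96 * x$sd,
                 conf.high = x$qbar + 1.96 * x$sd)
}

#' @exportS3Method
tidy.pooled_estimate <- function(x, ...) glance.pooled_estimate(x)
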