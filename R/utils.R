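#' @importFrom rlang %||% .data abort warn inform
#' @importFrom stats as.formula coef complete.cases cor cor.test lm glm vcov
#'   model.matrix pchisq pf plogis predict quantile rbeta rbinom rchisq rnorm
#'   runif sd setNames t.test var var.test terms delete.response chisq.test
#'   oneway.test rWishart binomial na.omit aggregate
#' @importFrom utils head modifyList
NULL

# Derive a stream of child seeds from one master seed, reproducibly and
# independently of the caller's RNG state. Values stay below 2^31.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# Ensure a stable per-row identifier column used for pairing, self-exclusion
# and split/join round trips.
ensure_row_id <- function(data, prefix = "r") {
  if (!".row_id" %in% names(data)) {
    data <- dplyr::mutate(data, .row_id = paste0(prefix, dplyr::row_number()))
  }
  data
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(data)
}

# additional modelling imports used across engines
#' @importFrom stats anova formula update .getXlevels
NULL
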