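#' Declare one step of a sequential-regression chain
#'
#' @param outcome Name of the specific variable this step imputes.
#' @param candidates Character vector of candidate predictor terms (common
#'   variables or outcomes of earlier steps; interaction terms such as
#'   `"gender:age_group"` are allowed).
#' @param forced Terms kept in the model regardless of significance.
#' @param derive Optional one-sided formula; if given, the step is a derived
#'   variable computed from already-available columns (e.g.
#'   `~ clin_weight / (clin_height / 100)^2` for BMI) and no model is fitted.
#' @param draw_parameters Per-step override of the imputation-time
#'   `draw_parameters` flag: `NULL` (default) inherits it, `FALSE` pins the
#'   step to its fitted coefficients. Terminal risk-prediction steps use
#'   `FALSE`: condition status is predicted from the fitted model on each
#'   completed set rather than re-imputed with parameter draws.
#' @return A list of class `chain_step`.
#' @export
chain_step <- function(outcome, candidates = character(), forced = character(),
                       derive = NULL, draw_parameters = NULL) {
  if (is.null(derive) && length(candidates) == 0) {
    abort(sprintf("submodel '%s' has an empty candidate predictor set", outcome))
  }
  structure(list(outcome = outcome, candidates = candidates, forced = forced,
                 derive = derive, draw_parameters = draw_parameters),
            class = "chain_step")
}

term_vars <- function(term_labels) {
  unique(unlist(strsplit(term_labels, "[:*]")))
}

prepare_model_frame <- function(data, schema, vars) {
  out <- data[intersect(vars, names(data))]
  for (v in names(out)) {
    lv <- schema_levels(schema, v)
    if (!is.null(lv) && length(lv) > 0) out[[v]] <- factor(out[[v]], levels = lv)
  }
  as.data.frame(out)
}

# Backward elimination by likelihood-ratio / F tests on the donor fit,
# honouring forced-in terms and term marginality.
eliminate_terms <- function(fit_fun, formula, data, alpha, forced) {
  fit <- fit_fun(formula)
  repeat {
    tt <- terms(fit)
    labels <- attr(tt, "term.labels")
    fac <- attr(tt, "factors")
    droppable <- setdiff(labels, forced)
    # a term contained in a surviving higher-order term cannot be dropped
    if (length(labels) > 1) {
      ord <- attr(tt, "order")
      for (lab in droppable) {
        vars_in <- rownames(fac)[fac[, lab] > 0]
        higher <- labels[ord > attr(tt, "order")[match(lab, labels)]]
        contained <- any(vapply(higher, function(h)
          all(vars_in %in% rownames(fac)[fac[, h] > 0]), logical(1)))
        if (contained) droppable <- setdiff(droppable, lab)
      }
    }
    if (length(droppable) == 0) break
    pvals <- vapply(droppable, function(lab) {
      reduced <- fit_fun(update(formula(fit), paste(". ~ . -", lab)))
      lrt_pvalue(fit, reduced)
    }, numeric(1))
    worst <- which.max(pvals)
    if (pvals[worst] <= alpha) break
    fit <- fit_fun(update(formula(fit), paste(". ~ . -", names(pvals)[worst])))
    if (length(attr(terms(fit), "term.labels")) == 0) break
  }
  fit
}

lrt_pvalue <- function(full, reduced) {
  if (inherits(full, "lm") && !inherits(full, "glm")) {
    a <- anova(reduced, full)
    return(a$`Pr(>F)`[2])
  }
  dev_r <- reduced$deviance
  dev_f <- full$deviance
  df <- abs(n_model_params(full) - n_model_params(reduced))
  if (df == 0) return(1)
  pchisq(dev_r - dev_f, df = df, lower.tail = FALSE)
}

n_model_params <- function(fit) {
  cf <- coef(fit)
  if (is.matrix(cf)) length(cf) else sum(!is.na(cf))
}

#' Fit a stochastic sequential-regression imputation model
#'
#' Each specific variable is modelled in chain order from common variables
#' and earlier outcomes: a linear submodel with residual standard deviation
#' for continuous outcomes, a binary or multicategory logistic submodel for
#' categorical outcomes, and a closed-form computation (no fit) for derived
#' variables. Candidate predictor sets are pruned by backward elimination at
#' the configured significance level, with a forced-in list available so
#' substantively required predictors are never dropped.
#'
#' @param donor Donor survey tibble.
#' @param spec A [fusion_spec()].
#' @param schema A [survey_schema()].
#' @param chain Optional list of [chain_step()]s covering every specific
#'   variable exactly once, in imputation order. By default each specific
#'   variable is regressed on all common variables plus earlier outcomes.
#' @param alpha Significance level for backward elimination; `alpha = 1`
#'   disables pruning.
#' @param min_rows_per_param Guard: minimum donor rows per fitted parameter.
#' @return An object of class `c("sequential_regression", "fusion_model")`.
#' @export
fit_sequential_regression <- function(donor, spec, schema, chain = NULL,
                                      alpha = 0.05, min_rows_per_param = 10) {
  check_spec_against_schema(spec, schema)
  assert_columns(donor, c(spec$common, spec$specific), "donor")
  if (is.null(chain)) {
    chain <- purrr::map(seq_along(spec$specific), function(i) {
      chain_step(spec$specific[i],
                 candidates = c(spec$common, spec$specific[seq_len(i - 1)]))
    })
  }
  outcomes <- purrr::map_chr(chain, "outcome")
  if (!setequal(outcomes, spec$specific) || anyDuplicated(outcomes)) {
    abort("chain must cover every specific variable exactly once")
  }
  available <- spec$common
  submodels <- vector("list", length(chain))
  for (i in seq_along(chain)) {
    st <- chain[[i]]
    used <- term_vars(c(st$candidates, st$forced))
    if (!is.null(st$derive)) used <- all.vars(st$derive)
    bad <- setdiff(used, available)
    if (length(bad) > 0) {
      abort(sprintf(
        "submodel '%s' uses '%s' before it is available in the chain",
        st$outcome, bad[1]))
    }
    if (!is.null(st$derive)) {
      submodels[[i]] <- list(outcome = st$outcome, type = "derived",
                             derive = st$derive)
    } else {
      submodels[[i]] <- fit_submodel(st, donor, schema, alpha,
                                     min_rows_per_param)
    }
    available <- c(available, st$outcome)
  }
  structure(list(method = "sequential_regression", spec = spec,
                 schema = schema, submodels = submodels, alpha = alpha),
            class = c("sequential_regression", "fusion_model"))
}

fit_submodel <- function(st, donor, schema, alpha, min_rows_per_param) {
  kind <- schema_kind(schema, st$outcome)
  vars <- unique(c(st$outcome, term_vars(c(st$candidates, st$forced))))
  df <- prepare_model_frame(donor, schema, vars)
  df <- droplevels(df)  # unused declared levels stay out of the design
  rhs <- paste(unique(c(st$candidates, st$forced)), collapse = " + ")
  fml <- as.formula(paste(st$outcome, "~", rhs))
  if (kind == "categorical") {
    obs_levels <- unique(as.character(df[[st$outcome]]))
    if (length(obs_levels) < 2) {
      abort(sprintf("outcome '%s' has a single observed level ('%s')",
                    st$outcome, obs_levels[1]))
    }
  }
  if (kind == "continuous") {
    fit_fun <- function(f) lm(f, data = df)
  } else if (length(schema_levels(schema, st$outcome)) == 2) {
    fit_fun <- function(f) glm(f, data = df, family = binomial())
  } else {
    fit_fun <- function(f) nnet::multinom(f, data = df, trace = FALSE,
                                          model = TRUE, Hess = TRUE)
  }
  probe <- fit_fun(fml)
  npar <- n_model_params(probe)
  if (nrow(df) < min_rows_per_param * max(npar, 1)) {
    abort(sprintf(
      "submodel '%s': %d donor rows for %d parameters (< %d rows/parameter)",
      st$outcome, nrow(df), npar, min_rows_per_param))
  }
  fit <- eliminate_terms(fit_fun, fml, df, alpha, st$forced)
  cf <- coef(fit)
  if (anyNA(cf)) {
    bad <- if (is.matrix(cf)) colnames(cf)[colSums(is.na(cf)) > 0] else names(cf)[is.na(cf)]
    abort(sprintf("submodel '%s': singular fit, offending term(s): %s",
                  st$outcome, paste(bad, collapse = ", ")))
  }
  type <- if (inherits(fit, "multinom")) "multinomial"
          else if (inherits(fit, "glm")) "binomial" else "gaussian"
  if (type != "gaussian") {
    se <- sqrt(diag(vcov(fit)))
    if (any(!is.finite(se)) || max(se) > 50) {
      worst <- names(se)[which.max(se)] %||% "(unknown)"
      abort(sprintf(
        "submodel '%s': (quasi-)separation detected, offending term: %s",
        st$outcome, worst))
    }
  }
  tt <- delete.response(terms(fit))
  attr(tt, ".Environment") <- baseenv()
  out <- list(
    outcome = st$outcome, type = type, terms = tt,
    draw_parameters = st$draw_parameters,
    xlevels = fit$xlevels %||% stats::.getXlevels(terms(fit), fit$model),
    coef = cf, vcov = vcov(fit),
    levels = if (type != "gaussian") schema_levels(schema, st$outcome)
  )
  if (type == "gaussian") {
    out$sigma <- summary(fit)$sigma
    out$df <- fit$df.residual
    out$std_error <- sqrt(diag(out$vcov))
  } else if (type == "binomial") {
    out$std_error <- sqrt(diag(out$vcov))
  } else {
    out$std_error <- sqrt(diag(out$vcov))
  }
  out
}

submodel_design <- function(sm, data, schema) {
  vars <- all.vars(sm$terms)
  df <- prepare_model_frame(data, schema, vars)
  for (v in names(sm$xlevels)) {
    seen <- unique(as.character(df[[v]]))
    extra <- setdiff(seen[!is.na(seen)], sm$xlevels[[v]])
    if (length(extra) > 0) {
      abort(sprintf(
        "recipient value '%s' of '%s' was not in the donor design for '%s'",
        extra[1], v, sm$outcome))
    }
    df[[v]] <- factor(df[[v]], levels = sm$xlevels[[v]])
  }
  model.matrix(sm$terms, df)
}

draw_gaussian_params <- function(sm) {
  sigma2 <- sm$sigma^2 * sm$df / rchisq(1, sm$df)
  scale <- if (sm$sigma > 0) sigma2 / sm$sigma^2 else 1
  beta <- MASS::mvrnorm(1, sm$coef, sm$vcov * scale)
  list(beta = beta, sigma = sqrt(sigma2))
}

softmax_rows <- function(eta) {
  e <- exp(cbind(0, eta))
  e / rowSums(e)
}

sample_categorical <- function(prob, levels) {
  u <- runif(nrow(prob))
  cum <- t(apply(prob, 1, cumsum))
  idx <- rowSums(u > cum) + 1L
  levels[pmin(idx, length(levels))]
}

#' Impute a recipient file with a sequential-regression model
#'
#' Variables are imputed in chain order. Continuous outcomes are drawn as
#' fitted mean plus a normal residual draw; categorical outcomes are drawn
#' from the fitted category probabilities; derived variables are computed
#' from already-imputed inputs. With `draw_parameters = TRUE`, each
#' submodel's coefficients are first perturbed by a draw from their estimated
#' sampling distribution (and the residual variance from its scaled
#' chi-square posterior), which is what makes repeated calls a proper
#' multiple imputation.
#'
#' @param model A model from [fit_sequential_regression()].
#' @param recipient Recipient survey tibble.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param draw_parameters Draw submodel parameters before imputing.
#' @return The completed recipient tibble.
#' @export
impute_sequential <- function(model, recipient, seed = NULL,
                              draw_parameters = FALSE) {
  assert_columns(recipient, model$spec$common, "recipient")
  draw_parameters_global <- draw_parameters
  completed <- ensure_row_id(recipient)
  with_seed_if(seed, {
    for (sm in model$submodels) {
      if (sm$type == "derived") {
        completed[[sm$outcome]] <-
          rlang::eval_tidy(sm$derive[[2]], data = completed)
        next
      }
      draw_parameters <- sm$draw_parameters %||% draw_parameters_global
      X <- submodel_design(sm, completed, model$schema)
      if (sm$type == "gaussian") {
        if (draw_parameters) {
          par <- draw_gaussian_params(sm)
        } else {
          par <- list(beta = sm$coef, sigma = sm$sigma)
        }
        mu <- drop(X %*% par$beta)
        completed[[sm$outcome]] <- mu + rnorm(nrow(X), 0, par$sigma)
      } else if (sm$type == "binomial") {
        beta <- if (draw_parameters) MASS::mvrnorm(1, sm$coef, sm$vcov) else sm$coef
        p <- plogis(drop(X %*% beta))
        completed[[sm$outcome]] <-
          ifelse(rbinom(nrow(X), 1, p) == 1, sm$levels[2], sm$levels[1])
      } else {
        cf <- sm$coef
        if (draw_parameters) {
          drawn <- MASS::mvrnorm(1, as.vector(t(cf)), sm$vcov)
          cf <- matrix(drawn, nrow = nrow(cf), byrow = TRUE,
                       dimnames = dimnames(cf))
        }
        eta <- X %*% t(cf)
        prob <- softmax_rows(eta)
        completed[[sm$outcome]] <- sample_categorical(prob, sm$levels)
      }
    }
  })
  completed
}

#' @exportS3Method
tidy.sequential_regression <- function(x, ...) {
  purrr::map_dfr(x$submodels, function(sm) {
    if (sm$type == "derived") {
      return(tibble::tibble(outcome = sm$outcome, term = "(derived)",
                            estimate = NA_real_, std.error = NA_real_,
                            type = "derived"))
    }
    cf <- sm$coef
    if (is.matrix(cf)) {
      est <- as.vector(t(cf))
      nm <- as.vector(t(outer(rownames(cf), colnames(cf), paste, sep = ":")))
    } else {
      est <- cf
      nm <- names(cf)
    }
    tibble::tibble(outcome = sm$outcome, term = nm, estimate = est,
                   std.error = sm$std_error, type = sm$type)
  })
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("<fusion_model: %s>\n", x$method))
  cat("  specific block:", paste(x$spec$specific, collapse = ", "), "\n")
  invisible(x)
}
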