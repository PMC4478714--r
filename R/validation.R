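#' Orientation of each validation statistic
#'
#' @return Tibble with columns `statistic` and `higher_better`. ASL-type
#'   statistics and agreement measures improve upwards; discrepancy and
#'   distance measures improve downwards.
#' @export
statistic_orientations <- function() {
  tibble::tibble(
    statistic = c("ASLm", "ASLs", "ACDi", "ACDe", "WC", "ASD", "TAU", "RndRes"),
    higher_better = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE)
  )
}

align_imputed <- function(observed, imputed) {
  if (nrow(observed) != nrow(imputed)) {
    abort("observed and imputed blocks must have the same number of rows")
  }
  if (".row_id" %in% names(observed) && ".row_id" %in% names(imputed) &&
      !identical(observed$.row_id, imputed$.row_id)) {
    idx <- match(observed$.row_id, imputed$.row_id)
    if (anyNA(idx)) abort("observed and imputed row identifiers do not match")
    imputed <- imputed[idx, , drop = FALSE]
  }
  imputed
}

welch_p <- function(x, y) {
  if (sd(x) == 0 && sd(y) == 0) return(as.numeric(mean(x) == mean(y)))
  t.test(x, y)$p.value
}

vartest_p <- function(x, y) {
  if (sd(x) == 0 && sd(y) == 0) return(NA_real_)
  var.test(x, y)$p.value
}

prop_table_p <- function(x, y, levels) {
  tab <- rbind(table(factor(x, levels = levels)),
               table(factor(y, levels = levels)))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2) return(1)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  pchisq(stat, df = ncol(tab) - 1, lower.tail = FALSE)
}

#' Averaged significance levels for marginal means and spreads (ASLm, ASLs)
#'
#' Runs, per specific variable, two-sample comparisons of the observed and
#' imputed donor values: a Welch test of equal means and an F test of equal
#' variances for continuous variables, and a proportions (chi-square) test
#' for categorical ones. Each statistic is the mean achieved significance
#' level across applicable variables, so values near 1 indicate preserved
#' marginal statistics.
#'
#' @param observed,imputed Donor tables (or Y-blocks) paired by `.row_id`.
#' @param spec A [fusion_spec()]; @param schema A [survey_schema()].
#' @return List with `ASLm`, `ASLs` and a per-variable `detail` tibble.
#' @export
marginal_asl <- function(observed, imputed, spec, schema) {
  imputed <- align_imputed(observed, imputed)
  vars <- spec$specific
  p_mean <- p_spread <- rep(NA_real_, length(vars))
  for (j in seq_along(vars)) {
    v <- vars[j]
    if (schema_kind(schema, v) == "continuous") {
      if (sd(observed[[v]]) == 0 && sd(imputed[[v]]) == 0) {
        warn(sprintf("variable '%s' constant in both blocks; variance test skipped", v))
      }
      p_mean[j] <- welch_p(observed[[v]], imputed[[v]])
      p_spread[j] <- vartest_p(observed[[v]], imputed[[v]])
    } else {
      p_mean[j] <- prop_table_p(observed[[v]], imputed[[v]],
                                schema_levels(schema, v))
    }
  }
  detail <- tibble::tibble(variable = vars, p_mean = p_mean,
                           p_spread = p_spread)
  list(ASLm = mean(p_mean, na.rm = TRUE),
       ASLs = if (all(is.na(p_spread))) NA_real_
              else mean(p_spread, na.rm = TRUE),
       detail = detail)
}

cramers_v <- function(x, y, lx, ly) {
  cramer_fast(match(x, lx), match(y, ly), length(lx), length(ly))
}

cramer_fast <- function(cx, cy, kx, ky) {
  tab <- matrix(tabulate((cy - 1L) * kx + cx, kx * ky), kx, ky)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) return(NA_real_)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  sqrt(stat / (sum(tab) * (min(dim(tab)) - 1)))
}

# within/total sum of squares of x across groups g (integer codes)
ss_by_group <- function(x, g) {
  s <- rowsum(x, g)
  s2 <- rowsum(x * x, g)
  cnt <- as.vector(rowsum(rep(1, length(x)), g))
  ssw <- sum(s2 - s^2 / cnt)
  sst <- sum(x * x) - sum(x)^2 / length(x)
  c(ssw = ssw, sst = sst, k = length(cnt))
}

eta_codes <- function(cont, codes) {
  ss <- ss_by_group(cont, codes)
  if (ss[["sst"]] <= 0) return(NA_real_)
  sqrt(max(0, 1 - ss[["ssw"]] / ss[["sst"]]))
}

eta_assoc <- function(cont, cat) {
  eta_codes(cont, as.integer(factor(cat)))
}

pair_assoc <- function(x, y, kx, ky, lx = NULL, ly = NULL) {
  if (kx == "continuous" && ky == "continuous") {
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  } else if (kx == "categorical" && ky == "categorical") {
    cramers_v(x, y, lx, ly)
  } else if (kx == "continuous") {
    eta_assoc(x, y)
  } else {
    eta_assoc(y, x)
  }
}

#' Association-discrepancy statistics (ACDi, ACDe)
#'
#' ACDi is the mean absolute difference between the observed and imputed
#' pairwise association matrices over specific-variable pairs; ACDe the same
#' over specific x common pairs. Associations are product-moment correlations
#' for continuous pairs, a correlation-ratio for mixed pairs and Cramer's V
#' for categorical pairs. Lower is better.
#'
#' @inheritParams marginal_asl
#' @param common_data Table carrying the common block (defaults to
#'   `observed`).
#' @return List with `ACDi`, `ACDe`, `detail`.
#' @export
correlation_discrepancy <- function(observed, imputed, spec, schema,
                                    common_data = observed) {
  imputed <- align_imputed(observed, imputed)
  allv <- c(spec$specific, spec$common)
  kinds <- setNames(schema$kind[match(allv, schema$variable)], allv)
  lvls <- setNames(schema$levels[match(allv, schema$variable)], allv)
  sp <- spec$specific
  pairs <- dplyr::bind_rows(
    if (length(sp) >= 2) {
      cb <- utils::combn(sp, 2)
      tibble::tibble(block = "internal", var1 = cb[1, ], var2 = cb[2, ])
    },
    tidyr::expand_grid(block = "external", var1 = sp, var2 = spec$common)
  )
  # cache numeric vectors / integer level codes per (variable, source)
  encode <- function(data, v) {
    if (kinds[[v]] == "continuous") list(x = as.numeric(data[[v]]))
    else list(c = match(data[[v]], lvls[[v]]), k = length(lvls[[v]]))
  }
  enc_obs <- lapply(sp, function(v) encode(observed, v))
  enc_imp <- lapply(sp, function(v) encode(imputed, v))
  names(enc_obs) <- names(enc_imp) <- sp
  enc_com <- lapply(spec$common, function(v) encode(common_data, v))
  names(enc_com) <- spec$common
  assoc_enc <- function(e1, e2) {
    if (!is.null(e1$x) && !is.null(e2$x)) {
      if (sd(e1$x) == 0 || sd(e2$x) == 0) return(NA_real_)
      cor(e1$x, e2$x)
    } else if (is.null(e1$x) && is.null(e2$x)) {
      cramer_fast(e1$c, e2$c, e1$k, e2$k)
    } else if (!is.null(e1$x)) {
      eta_codes(e1$x, e2$c)
    } else {
      eta_codes(e2$x, e1$c)
    }
  }
  one_side <- function(enc_sp) {
    vapply(seq_len(nrow(pairs)), function(j) {
      e1 <- enc_sp[[pairs$var1[j]]]
      e2 <- if (pairs$block[j] == "internal") enc_sp[[pairs$var2[j]]]
            else enc_com[[pairs$var2[j]]]
      assoc_enc(e1, e2)
    }, numeric(1))
  }
  a_obs <- one_side(enc_obs)
  a_imp <- one_side(enc_imp)
  detail <- dplyr::mutate(pairs, assoc_observed = a_obs, assoc_imputed = a_imp,
                          abs_diff = abs(a_obs - a_imp))
  internal <- detail$block == "internal"
  list(
    ACDi = if (!any(internal)) NA_real_
           else mean(detail$abs_diff[internal], na.rm = TRUE),
    ACDe = mean(detail$abs_diff[!internal], na.rm = TRUE),
    detail = detail
  )
}

numeric_block <- function(data, vars, schema, scale = NULL) {
  cols <- list()
  for (v in vars) {
    lv <- schema_levels(schema, v)
    if (is.null(lv) || length(lv) == 0) {
      cols[[v]] <- as.numeric(data[[v]])
    } else {
      for (l in lv[-1]) cols[[paste0(v, "=", l)]] <- as.numeric(data[[v]] == l)
    }
  }
  M <- do.call(cbind, cols)
  M <- scale(M, center = TRUE, scale = FALSE)
  if (!is.null(scale)) M <- sweep(M, 2, scale, "/")
  M
}

#' Multivariate congruence of scatter structures (WC)
#'
#' Matrix congruence (normalised Frobenius inner product) between the
#' centered cross-product matrices of the observed and imputed specific
#' blocks, with categorical variables expanded to centred indicators and
#' continuous columns standardised by the observed-block spread so no single
#' variable's units dominate. Equals 1 iff the two scatter structures are
#' proportional.
#'
#' @inheritParams marginal_asl
#' @return Scalar WC in `[0, 1]`.
#' @export
multivariate_congruence <- function(observed, imputed, spec, schema) {
  imputed <- align_imputed(observed, imputed)
  Mo <- numeric_block(observed, spec$specific, schema)
  sds <- apply(Mo, 2, sd)
  sds[sds == 0] <- 1
  Mo <- sweep(Mo, 2, sds, "/")
  Mi <- sweep(numeric_block(imputed, spec$specific, schema), 2, sds, "/")
  S1 <- crossprod(Mo)
  S2 <- crossprod(Mi)
  den <- sqrt(sum(S1^2)) * sqrt(sum(S2^2))
  if (den == 0) abort("degenerate (rank-0) specific block")
  sum(S1 * S2) / den
}

ecdf_sup_distance <- function(x, y) {
  w <- c(x, y)
  from_x <- rep(c(TRUE, FALSE), c(length(x), length(y)))
  ord <- order(w)
  steps <- cumsum(ifelse(from_x[ord], 1 / length(x), -1 / length(y)))
  ws <- w[ord]
  at_value_end <- c(ws[-1] != ws[-length(ws)], TRUE)
  max(abs(steps[at_value_end]))
}

#' Average distributional distance between observed and imputed values (ASD)
#'
#' Per continuous variable the two-sample empirical-CDF sup-distance
#' (Kolmogorov-Smirnov statistic), per categorical variable the total
#' variation distance between level frequencies; ASD is the average across
#' specific variables. Lower means the imputed marginal distributions track
#' the observed ones more closely.
#'
#' @inheritParams marginal_asl
#' @return List with `ASD` and per-variable `detail`.
#' @export
distribution_similarity <- function(observed, imputed, spec, schema) {
  imputed <- align_imputed(observed, imputed)
  vars <- spec$specific
  dist <- vapply(vars, function(v) {
    if (schema_kind(schema, v) == "continuous") {
      ecdf_sup_distance(observed[[v]], imputed[[v]])
    } else {
      lv <- schema_levels(schema, v)
      po <- tabulate(match(observed[[v]], lv), length(lv)) / nrow(observed)
      pi_ <- tabulate(match(imputed[[v]], lv), length(lv)) / nrow(imputed)
      sum(abs(po - pi_)) / 2
    }
  }, numeric(1))
  list(ASD = mean(dist),
       detail = tibble::tibble(variable = vars, distance = unname(dist)))
}

cohen_kappa <- function(x, y, levels) {
  tab <- table(factor(x, levels = levels), factor(y, levels = levels))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-12) return(as.numeric(po >= 1 - 1e-12))
  (po - pe) / (1 - pe)
}

#' Imputation accuracy (TAU)
#'
#' Chance-corrected agreement (Cohen's kappa) between observed and imputed
#' labels for categorical variables; standardised error reduction
#' `1 - MSE / var(observed)` for continuous variables; both floored at
#' `floor` so the average stays in `[0, 1]`. TAU is the mean across specific
#' variables; higher means imputed values closer to the truth.
#'
#' @inheritParams marginal_asl
#' @param floor Lower bound applied per variable (default 0).
#' @return List with `TAU` and per-variable `detail`.
#' @export
imputation_accuracy <- function(observed, imputed, spec, schema, floor = 0) {
  imputed <- align_imputed(observed, imputed)
  vars <- spec$specific
  taus <- vapply(vars, function(v) {
    if (schema_kind(schema, v) == "continuous") {
      v0 <- var(observed[[v]])
      if (v0 == 0) {
        warn(sprintf("variable '%s' has zero observed variance; skipped in TAU", v))
        return(NA_real_)
      }
      max(floor, 1 - mean((observed[[v]] - imputed[[v]])^2) / v0)
    } else {
      max(floor, cohen_kappa(observed[[v]], imputed[[v]],
                             schema_levels(schema, v)))
    }
  }, numeric(1))
  list(TAU = mean(taus, na.rm = TRUE),
       detail = tibble::tibble(variable = vars, tau = unname(taus)))
}

cor_test_p <- function(x, y) {
  n <- length(x)
  r <- cor(x, y)
  if (is.na(r) || abs(r) >= 1) return(if (is.na(r)) NA_real_ else 0)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

oneway_f_p <- function(x, g) {
  ss <- ss_by_group(x, g)
  k <- ss[["k"]]
  n <- length(x)
  if (k < 2 || n <= k || ss[["ssw"]] <= 0) return(NA_real_)
  f <- ((ss[["sst"]] - ss[["ssw"]]) / (k - 1)) / (ss[["ssw"]] / (n - k))
  pf(f, k - 1, n - k, lower.tail = FALSE)
}

no_assoc_p <- function(r, x, kind) {
  if (sd(r) == 0) return(NA_real_)
  if (kind == "continuous") {
    if (sd(x) == 0) return(NA_real_)
    cor_test_p(r, x)
  } else {
    oneway_f_p(r, as.integer(factor(x)))
  }
}

#' Randomness of imputation residuals (RndRes)
#'
#' For each continuous specific variable the residual observed minus imputed
#' is tested for association against every common variable (correlation test
#' for continuous commons, one-way F test across levels for categorical
#' commons). RndRes is the mean achieved significance level: values near the
#' uniform mean 0.5 indicate residuals free of structure, values near 0 mean
#' the imputation left systematic signal on the table. Exactly reproduced
#' values (zero residuals) are reported as RndRes = 1 with a degenerate flag.
#'
#' @inheritParams correlation_discrepancy
#' @return List with `RndRes`, `degenerate` flag and `detail`.
#' @export
residual_randomness <- function(observed, imputed, spec, schema,
                                common_data = observed) {
  imputed <- align_imputed(observed, imputed)
  cont <- spec$specific[vapply(spec$specific, function(v)
    schema_kind(schema, v) == "continuous", logical(1))]
  if (length(cont) == 0) abort("RndRes needs at least one continuous specific variable")
  kinds <- vapply(spec$common, function(v) schema_kind(schema, v), character(1))
  codes <- lapply(spec$common, function(v) {
    if (kinds[[v]] == "categorical") as.integer(factor(common_data[[v]]))
  })
  names(codes) <- spec$common
  degenerate <- TRUE
  nc <- length(spec$common)
  res_of <- rep(cont, each = nc)
  com <- rep(spec$common, times = length(cont))
  pvals <- rep(NA_real_, length(res_of))
  idx <- 0L
  for (v in cont) {
    r <- observed[[v]] - imputed[[v]]
    const <- sd(r) == 0
    if (!const) degenerate <- FALSE
    for (cv in spec$common) {
      idx <- idx + 1L
      if (const) next
      pvals[idx] <- if (kinds[[cv]] == "continuous") {
        if (sd(common_data[[cv]]) == 0) NA_real_
        else cor_test_p(r, common_data[[cv]])
      } else {
        oneway_f_p(r, codes[[cv]])
      }
    }
  }
  detail <- tibble::tibble(residual_of = res_of, common = com, p = pvals)
  val <- if (degenerate) 1 else mean(pvals, na.rm = TRUE)
  list(RndRes = val, degenerate = degenerate, detail = detail)
}

#' Explanatory power of the common block for each specific variable
#'
#' Diagnoses the predictive-relevance assumption behind any fusion: imputing
#' Y from X is only defensible if X explains most of the systematic
#' variability of Y. Reports variance explained (R-squared) for continuous
#' variables and a deviance-based analogue for categorical ones, flagging
#' weakly predicted variables.
#'
#' @param donor Donor survey tibble.
#' @param spec A [fusion_spec()]; @param schema A [survey_schema()].
#' @param warn_below Threshold under which a variable is flagged.
#' @return Tibble with `variable`, `kind`, `power`, `weak`.
#' @export
predictive_relevance <- function(donor, spec, schema, warn_below = 0.3) {
  df <- prepare_model_frame(donor, schema, c(spec$common, spec$specific))
  purrr::map_dfr(spec$specific, function(v) {
    kind <- schema_kind(schema, v)
    fml <- as.formula(paste(v, "~", paste(spec$common, collapse = " + ")))
    if (kind == "continuous") {
      power <- summary(lm(fml, data = df))$r.squared
    } else {
      y <- droplevels(df[[v]])
      if (nlevels(y) < 2) {
        power <- 0
      } else if (nlevels(y) == 2) {
        fit <- glm(fml, data = df, family = binomial())
        power <- 1 - fit$deviance / fit$null.deviance
      } else {
        fit <- nnet::multinom(fml, data = df, trace = FALSE)
        null <- nnet::multinom(as.formula(paste(v, "~ 1")), data = df,
                               trace = FALSE)
        power <- 1 - fit$deviance / null$deviance
      }
    }
    tibble::tibble(variable = v, kind = kind, power = power,
                   weak = power < warn_below)
  })
}

#' Full validation of a fused data set against observed donor values
#'
#' Assembles the eight statistics — ASLm, ASLs (marginal means/spreads),
#' ACDi, ACDe (association discrepancies), WC (multivariate congruence),
#' ASD (distributional distance), TAU (accuracy) and RndRes (residual
#' randomness) — comparing observed donor values with their imputed
#' counterparts, pairing rows by identifier.
#'
#' @param observed Donor table with the true specific block.
#' @param imputed The same rows with the specific block imputed.
#' @param spec A [fusion_spec()]; @param schema A [survey_schema()].
#' @param common_data Table carrying the common block (defaults to
#'   `observed`).
#' @return An object of class `validation_report`.
#' @export
validate_fusion <- function(observed, imputed, spec, schema,
                            common_data = observed) {
  asl <- marginal_asl(observed, imputed, spec, schema)
  acd <- correlation_discrepancy(observed, imputed, spec, schema, common_data)
  wc <- multivariate_congruence(observed, imputed, spec, schema)
  asd <- distribution_similarity(observed, imputed, spec, schema)
  tau <- imputation_accuracy(observed, imputed, spec, schema)
  rnd <- residual_randomness(observed, imputed, spec, schema, common_data)
  stats <- statistic_orientations() |>
    dplyr::mutate(value = c(asl$ASLm, asl$ASLs, acd$ACDi, acd$ACDe, wc,
                            asd$ASD, tau$TAU, rnd$RndRes)) |>
    dplyr::relocate("statistic", "value")
  structure(list(
    statistics = stats,
    residuals_degenerate = rnd$degenerate,
    detail = list(asl = asl$detail, acd = acd$detail, asd = asd$detail,
                  tau = tau$detail, rndres = rnd$detail)
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  print(x$statistics)
  if (x$residuals_degenerate) cat("  (residuals degenerate: perfect imputation)\n")
  invisible(x)
}

#' @exportS3Method
tidy.validation_report <- function(x, ...) x$statistics

#' @exportS3Method
glance.validation_report <- function(x, ...) {
  tidyr::pivot_wider(x$statistics[c("statistic", "value")],
                     names_from = "statistic", values_from = "value")
}

#' Serialise / restore a validation report (JSON)
#' @param report A `validation_report`.
#' @param path File path.
#' @return `path` (write) or a `validation_report` (read).
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(list(
    statistics = report$statistics,
    residuals_degenerate = report$residuals_degenerate,
    detail = report$detail
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_validation_report
#' @export
read_validation_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    statistics = tibble::as_tibble(raw$statistics),
    residuals_degenerate = raw$residuals_degenerate,
    detail = purrr::map(raw$detail, tibble::as_tibble)
  ), class = "validation_report")
}
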