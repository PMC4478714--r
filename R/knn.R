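#' Fit a k-nearest-neighbour hot-deck imputation model
#'
#' The hot deck transfers, for each recipient, the complete specific block of
#' a similar real donor, so within-donor associations are preserved exactly
#' and every imputed categorical value lies in its declared levels by
#' construction. Similarity is measured in common-variable space with a
#' Gower-type metric: range-normalised absolute difference for continuous
#' variables, simple mismatch (0/1) for categorical ones, equal weights by
#' default. An optional class partition (e.g. gender x age group) restricts
#' candidate donors to the recipient's own class.
#'
#' @param donor Donor survey tibble (common + specific block complete).
#' @param spec A [fusion_spec()].
#' @param schema A [survey_schema()].
#' @param k Number of nearest donors listed per recipient (k = 1 is plain
#'   nearest-neighbour; k > 1 draws uniformly among the k nearest).
#' @param class_vars Optional character vector of common categorical
#'   variables defining donation classes.
#' @param weights Optional named numeric vector of per-variable distance
#'   weights (default equal).
#' @return An object of class `c("knn_hotdeck", "fusion_model")`.
#' @export
fit_knn_hotdeck <- function(donor, spec, schema, k = 1L, class_vars = NULL,
                            weights = NULL) {
  check_spec_against_schema(spec, schema)
  assert_columns(donor, c(spec$common, spec$specific), "donor")
  donor <- ensure_row_id(donor, "d")
  if (k < 1) abort("k must be >= 1")
  if (!is.null(class_vars)) {
    assert_columns(donor, class_vars, "donor")
    sizes <- dplyr::count(donor, dplyr::across(dplyr::all_of(class_vars)))
    if (any(sizes$n < k)) {
      abort(sprintf("k = %d exceeds available donors in %d class(es)",
                    k, sum(sizes$n < k)))
    }
  } else if (k > nrow(donor)) {
    abort(sprintf("k = %d exceeds donor size %d", k, nrow(donor)))
  }
  match_vars <- setdiff(spec$common, class_vars)
  cont <- match_vars[vapply(match_vars, function(v)
    schema_kind(schema, v) == "continuous", logical(1))]
  ranges <- vapply(cont, function(v) {
    r <- diff(range(donor[[v]]))
    if (r <= 0) 1 else r
  }, numeric(1))
  w <- rep(1, length(match_vars))
  names(w) <- match_vars
  if (!is.null(weights)) w[names(weights)] <- weights
  structure(list(
    method = "knn_hotdeck", donor = donor, spec = spec, schema = schema,
    k = as.integer(k), class_vars = class_vars, match_vars = match_vars,
    cont_vars = cont, ranges = ranges, weights = w
  ), class = c("knn_hotdeck", "fusion_model"))
}

# Gower distance matrix between recipient block (rows) and donor block (cols).
gower_distances <- function(model, recipient, donor) {
  n1 <- nrow(recipient)
  n0 <- nrow(donor)
  d <- matrix(0, n1, n0)
  for (v in model$match_vars) {
    wv <- model$weights[[v]]
    if (v %in% model$cont_vars) {
      d <- d + wv * abs(outer(recipient[[v]], donor[[v]], "-")) / model$ranges[[v]]
    } else {
      d <- d + wv * outer(recipient[[v]], donor[[v]], "!=")
    }
  }
  d / sum(model$weights)
}

#' Impute a recipient file from a fitted hot-deck model
#'
#' Each recipient row receives the entire specific block of a single donor
#' (joint transfer). With `k = 1` the unique nearest donor is used; ties at
#' equal distance are broken uniformly at random (seeded). With `k > 1` one
#' donor is drawn uniformly among the k nearest, which is the stochastic
#' draw from the empirical conditional distribution that multiple hot-deck
#' imputation relies on.
#'
#' @param model A model from [fit_knn_hotdeck()].
#' @param recipient Recipient survey tibble.
#' @param seed Integer seed for the donor draws and tie-breaks.
#' @param exclude_self If `TRUE`, a donor may not donate to a recipient row
#'   carrying the same `.row_id` (used when validating by re-imputing the
#'   donors themselves, where self-donation would be trivially perfect).
#' @return The recipient tibble completed with the specific block and a
#'   `.donor_id` provenance column.
#' @export
impute_knn <- function(model, recipient, seed = NULL, exclude_self = FALSE) {
  if (nrow(recipient) == 0) abort("recipient table is empty")
  assert_columns(recipient, model$spec$common, "recipient")
  recipient <- ensure_row_id(recipient)
  donor <- model$donor
  if (!is.null(model$class_vars)) {
    rec_classes <- do.call(paste, c(recipient[model$class_vars], sep = "\r"))
    don_classes <- do.call(paste, c(donor[model$class_vars], sep = "\r"))
    missing <- setdiff(unique(rec_classes), unique(don_classes))
    if (length(missing) > 0) {
      abort(sprintf("recipient class(es) not covered by any donor: %s",
                    paste(gsub("\r", "/", missing), collapse = "; ")))
    }
  } else {
    rec_classes <- rep("all", nrow(recipient))
    don_classes <- rep("all", nrow(donor))
  }
  pick <- with_seed_if(seed, {
    out <- integer(nrow(recipient))
    for (cl in unique(rec_classes)) {
      all_ri <- which(rec_classes == cl)
      di <- which(don_classes == cl)
      for (chunk in split(all_ri, ceiling(seq_along(all_ri) / 1000))) {
      ri <- chunk
      d <- gower_distances(model, recipient[ri, , drop = FALSE],
                           donor[di, , drop = FALSE])
      if (exclude_self) {
        same <- outer(recipient$.row_id[ri], donor$.row_id[di], "==")
        d[same] <- Inf
      }
      for (j in seq_along(ri)) {
        dj <- d[j, ]
        usable <- which(is.finite(dj))
        if (length(usable) == 0) abort("no usable donor for a recipient row")
        k <- min(model$k, length(usable))
        ord <- usable[order(dj[usable])]
        kth <- dj[ord[k]]
        # ties straddling the k-th distance enter the candidate pool
        cand <- usable[dj[usable] <= kth + 1e-12]
        if (length(cand) > k) {
          exact <- usable[dj[usable] < kth - 1e-12]
          ties <- setdiff(cand, exact)
          need <- k - length(exact)
          cand <- c(exact, sample(ties, need))
        }
        out[ri[j]] <- di[if (length(cand) == 1) cand else sample(cand, 1)]
      }
      }
    }
    out
  })
  completed <- recipient
  for (v in model$spec$specific) completed[[v]] <- donor[[v]][pick]
  completed$.donor_id <- donor$.row_id[pick]
  completed
}
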