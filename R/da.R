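# Encode the specific block as a numeric latent matrix: continuous columns
# as-is, categorical columns as K-1 indicators against the first level.
encode_specific <- function(data, spec, schema) {
  cols <- list()
  meta <- list()
  for (v in spec$specific) {
    lv <- schema_levels(schema, v)
    if (is.null(lv) || length(lv) == 0) {
      cols[[v]] <- as.numeric(data[[v]])
      meta[[v]] <- list(kind = "continuous", columns = v)
    } else {
      for (l in lv[-1]) {
        nm <- paste0(v, "=", l)
        cols[[nm]] <- as.numeric(data[[v]] == l)
        meta[[v]] <- list(kind = "categorical", levels = lv,
                          columns = paste0(v, "=", lv[-1]))
      }
    }
  }
  list(Y = do.call(cbind, cols), meta = meta)
}

decode_specific <- function(Y, meta, into) {
  for (v in names(meta)) {
    m <- meta[[v]]
    if (m$kind == "continuous") {
      into[[v]] <- as.numeric(Y[, m$columns])
    } else {
      # nearest indicator vertex: reference level (all-zero vector) wins
      # unless some latent indicator exceeds 1/2
      scores <- cbind(0.5, Y[, m$columns, drop = FALSE])
      into[[v]] <- m$levels[max.col(scores, ties.method = "first")]
    }
  }
  into
}

common_design <- function(data, spec, schema) {
  df <- prepare_model_frame(data, schema, spec$common)
  model.matrix(~ ., data = df)
}

safe_chol <- function(S, ridge, where) {
  tryCatch(chol(S), error = function(e) {
    inform(sprintf("%s: scatter not positive definite, applying ridge inflation",
                   where))
    chol(S + ridge * mean(diag(S)) * diag(nrow(S)))
  })
}

#' Impute by data augmentation under a joint latent-normal model
#'
#' Alternates an I-step, drawing the recipients' missing specific block from
#' the current multivariate-normal model given their common variables, and a
#' P-step, drawing the regression and scatter parameters from their posterior
#' given the current completed data (normal-inverse-Wishart under a
#' noninformative prior). Categorical specific variables enter through
#' indicator coding and are decoded to the most probable level. Because the
#' P-step re-draws the parameters each cycle, retained imputations reflect
#' parameter uncertainty as well as residual variation, which is what makes
#' spaced chain draws usable directly as multiple imputations.
#'
#' @param donor Donor survey tibble (complete).
#' @param recipient Recipient survey tibble (specific block absent).
#' @param spec A [fusion_spec()].
#' @param schema A [survey_schema()].
#' @param burn_in Iterations discarded before the first retained draw.
#' @param n_draws Number of completed tables to retain.
#' @param spacing Iterations between retained draws.
#' @param seed Integer seed; the whole chain is deterministic given it.
#' @param ridge Relative ridge added to a non-positive-definite scatter.
#' @return A list of `n_draws` completed recipient tibbles, with the chain
#'   settings attached as attributes.
#' @export
da_impute <- function(donor, recipient, spec, schema, burn_in = 500,
                      n_draws = 1, spacing = 100, seed = NULL, ridge = 1e-6) {
  if (burn_in < 1 || n_draws < 1 || spacing < 1) {
    abort("burn_in, n_draws and spacing must all be >= 1")
  }
  check_spec_against_schema(spec, schema)
  assert_columns(donor, c(spec$common, spec$specific), "donor")
  assert_columns(recipient, spec$common, "recipient")
  recipient <- ensure_row_id(recipient)
  donor <- ensure_row_id(donor, "d")

  enc <- encode_specific(donor, spec, schema)
  Yd <- enc$Y
  Xd <- common_design(donor, spec, schema)
  Xr_df <- prepare_model_frame(recipient, schema, spec$common)
  # recipient levels must be representable in the donor design
  Xr <- model.matrix(~ ., data = Xr_df)
  if (!identical(colnames(Xr), colnames(Xd))) {
    keep <- intersect(colnames(Xd), colnames(Xr))
    if (length(keep) < ncol(Xd)) {
      abort("recipient common-variable levels are not covered by the donor design")
    }
    Xr <- Xr[, colnames(Xd), drop = FALSE]
  }
  p <- ncol(Xd); q <- ncol(Yd)
  n0 <- nrow(Xd); n1 <- nrow(Xr)
  if (n0 <= p + q) abort("donor too small for a stable joint latent-normal fit")

  draws <- with_seed_if(seed, {
    XtX <- crossprod(Xd)
    B <- solve(XtX, crossprod(Xd, Yd))
    res <- Yd - Xd %*% B
    S <- crossprod(res)
    R <- safe_chol(S / (n0 - p), ridge, "initialisation")
    Sigma <- crossprod(R)
    total_iter <- burn_in + (n_draws - 1) * spacing + 1
    kept <- vector("list", n_draws)
    k <- 0
    X <- rbind(Xd, Xr)
    XtX_all <- crossprod(X)
    XtX_inv <- chol2inv(chol(XtX_all))
    U <- chol(XtX_inv)
    for (it in seq_len(total_iter)) {
      # I-step: draw the missing block given current parameters
      Rs <- safe_chol(Sigma, ridge, sprintf("iteration %d", it))
      Yr <- Xr %*% B + matrix(rnorm(n1 * q), n1, q) %*% Rs
      # P-step: draw parameters from their posterior given completed data
      Y <- rbind(Yd, Yr)
      Bhat <- XtX_inv %*% crossprod(X, Y)
      resid <- Y - X %*% Bhat
      S <- crossprod(resid)
      Sinv_chol <- tryCatch(chol(solve(S)), error = function(e) {
        inform(sprintf("iteration %d: scatter not positive definite, ridge applied", it))
        chol(solve(S + ridge * mean(diag(S)) * diag(q)))
      })
      W <- rWishart(1, df = n0 + n1 - p, Sigma = crossprod(Sinv_chol))[, , 1]
      Sigma <- chol2inv(chol(W))
      Rsig <- safe_chol(Sigma, ridge, sprintf("iteration %d (P-step)", it))
      B <- Bhat + t(U) %*% matrix(rnorm(p * q), p, q) %*% Rsig
      if (it > burn_in && (it - burn_in - 1) %% spacing == 0 && k < n_draws) {
        k <- k + 1
        completed <- decode_specific(Xr %*% B + matrix(rnorm(n1 * q), n1, q) %*%
                                       safe_chol(Sigma, ridge, "retain"),
                                     enc$meta, recipient)
        kept[[k]] <- completed
      }
      if (k == n_draws) break
    }
    kept
  })
  attr(draws, "settings") <- list(burn_in = burn_in, n_draws = n_draws,
                                  spacing = spacing, seed = seed)
  draws
}
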