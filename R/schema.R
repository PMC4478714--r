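#' Describe the variables of a survey table
#'
#' A survey schema is a tibble with one row per variable. It fixes, for each
#' variable, its role in the fusion (a `common` variable observed in both
#' files, a `specific` variable observed only in donors, or an `identifier`),
#' its measurement kind (`continuous` or `categorical`), the admissible
#' category levels, optional numeric-code aliases used in the raw files
#' (e.g. `1 = "Female"`), and free-text units. Nothing about a survey table is
#' inferred from the data itself: the schema is the single source of truth, so
#' that codings such as `1='Female'` are never guessed.
#'
#' @param variable Character vector of variable names (unique).
#' @param role One of `"common"`, `"specific"`, `"identifier"` per variable.
#' @param kind One of `"continuous"`, `"categorical"` per variable.
#' @param levels List of character vectors of category labels; must be
#'   non-empty and unique for categorical variables and `NULL` for
#'   continuous ones.
#' @param codes Optional list of named character vectors mapping raw file
#'   codes to labels, e.g. `c("1" = "Female", "2" = "Male")`.
#' @param units Optional character vector of units (e.g. `"cm"`, `"mmHg"`).
#'
#' @return A tibble of class `survey_schema` with columns `variable`, `role`,
#'   `kind`, `levels` (list), `codes` (list), `units`.
#' @export
#' @examples
#' survey_schema(
#'   variable = c("gender", "age"),
#'   role     = c("common", "common"),
#'   kind     = c("categorical", "continuous"),
#'   levels   = list(c("Female", "Male"), NULL)
#' )
survey_schema <- function(variable, role, kind, levels = NULL,
                          codes = NULL, units = NULL) {
  n <- length(variable)
  if (anyDuplicated(variable)) {
    abort("schema variable names must be unique")
  }
  role <- rep_len(role, n)
  kind <- rep_len(kind, n)
  if (!all(role %in% c("common", "specific", "identifier"))) {
    abort("role must be one of 'common', 'specific', 'identifier'")
  }
  if (!all(kind %in% c("continuous", "categorical"))) {
    abort("kind must be one of 'continuous', 'categorical'")
  }
  levels <- levels %||% vector("list", n)
  codes <- codes %||% vector("list", n)
  units <- units %||% rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (kind[i] == "categorical") {
      lv <- levels[[i]]
      if (length(lv) == 0 || anyDuplicated(lv)) {
        abort(sprintf("categorical variable '%s' needs non-empty unique levels",
                      variable[i]))
      }
    } else if (length(levels[[i]]) > 0) {
      abort(sprintf("continuous variable '%s' must not declare levels",
                    variable[i]))
    }
  }
  out <- tibble::tibble(
    variable = as.character(variable), role = role, kind = kind,
    levels = levels, codes = codes, units = as.character(units)
  )
  class(out) <- c("survey_schema", class(out))
  out
}

#' Read a survey schema from a YAML config
#'
#' The config holds a `variables:` list, each entry with `name`, `role`,
#' `kind`, and for categoricals `levels` plus an optional `codes` map from
#' raw-file tokens to labels.
#'
#' @param path Path to a YAML file.
#' @return A [survey_schema()].
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) abort(sprintf("schema file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  vars <- cfg$variables %||% abort("schema config must contain a 'variables' list")
  survey_schema(
    variable = purrr::map_chr(vars, "name"),
    role = purrr::map_chr(vars, ~ .x$role %||% "common"),
    kind = purrr::map_chr(vars, ~ .x$kind %||% "continuous"),
    levels = purrr::map(vars, ~ as.character(.x$levels %||% character())),
    codes = purrr::map(vars, function(v) {
      if (is.null(v$codes)) return(NULL)
      setNames(as.character(unlist(v$codes)), names(v$codes))
    }),
    units = purrr::map_chr(vars, ~ .x$units %||% NA_character_)
  )
}

schema_vars <- function(schema, role = NULL, kind = NULL) {
  keep <- rep(TRUE, nrow(schema))
  if (!is.null(role)) keep <- keep & schema$role %in% role
  if (!is.null(kind)) keep <- keep & schema$kind %in% kind
  schema$variable[keep]
}

schema_levels <- function(schema, variable) {
  schema$levels[[match(variable, schema$variable)]]
}

schema_kind <- function(schema, variable) {
  schema$kind[match(variable, schema$variable)]
}

#' Declare the common/specific variable partition of a fusion
#'
#' @param common Character vector of common (bridge) variable names, present
#'   in donor and recipient files.
#' @param specific Character vector of specific (fusing) variable names,
#'   observed only in the donor file and to be imputed into the recipient.
#' @return A list of class `fusion_spec` with elements `common`, `specific`.
#' @export
fusion_spec <- function(common, specific) {
  common <- as.character(common)
  specific <- as.character(specific)
  if (length(common) == 0 || length(specific) == 0) {
    abort("fusion_spec needs non-empty common and specific variable sets")
  }
  if (length(intersect(common, specific)) > 0) {
    abort("common and specific variable sets must be disjoint")
  }
  structure(list(common = common, specific = specific), class = "fusion_spec")
}

#' @export
print.fusion_spec <- function(x, ...) {
  cat("<fusion_spec>\n")
  cat("  common  (X):", paste(x$common, collapse = ", "), "\n")
  cat("  specific(Y):", paste(x$specific, collapse = ", "), "\n")
  invisible(x)
}

check_spec_against_schema <- function(spec, schema, recipient_schema = NULL) {
  bad <- setdiff(c(spec$common, spec$specific), schema$variable)
  if (length(bad) > 0) {
    abort(sprintf("fusion_spec names not in schema: %s", paste(bad, collapse = ", ")))
  }
  invisible(spec)
}

# Validate a parsed data frame against a schema; returns data with categorical
# columns as character labels and continuous columns as doubles.
validate_survey_values <- function(data, schema, allow_missing_specific = TRUE,
                                   where = "data") {
  for (i in seq_len(nrow(schema))) {
    v <- schema$variable[i]
    if (!v %in% names(data)) next
    x <- data[[v]]
    if (schema$kind[i] == "continuous") {
      xn <- suppressWarnings(as.numeric(x))
      bad <- which(!is.na(x) & is.na(xn) | (!is.na(xn) & !is.finite(xn)))
      if (length(bad) > 0) {
        abort(sprintf(
          "%s: variable '%s' has non-numeric/non-finite value '%s' at row %d",
          where, v, as.character(x[bad[1]]), bad[1]))
      }
      data[[v]] <- xn
    } else {
      x <- as.character(x)
      codes <- schema$codes[[i]]
      if (length(codes) > 0) {
        mapped <- x %in% names(codes)
        x[mapped] <- unname(codes[x[mapped]])
      }
      lv <- schema$levels[[i]]
      bad <- which(!is.na(x) & !(x %in% lv))
      if (length(bad) > 0) {
        abort(sprintf(
          "%s: variable '%s' has value '%s' at row %d outside declared levels (%s)",
          where, v, x[bad[1]], bad[1], paste(lv, collapse = ", ")))
      }
      data[[v]] <- x
    }
    nas <- which(is.na(data[[v]]))
    if (length(nas) > 0 &&
        (schema$role[i] != "specific" || !allow_missing_specific)) {
      abort(sprintf("%s: variable '%s' (role %s) has a missing value at row %d",
                    where, v, schema$role[i], nas[1]))
    }
  }
  tibble::as_tibble(data)
}
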