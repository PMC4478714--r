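#' Load a delimited survey file against a schema
#'
#' Reads a CSV (or other delimited) respondent table and validates every value
#' against the declared schema: categorical values must fall in the declared
#' levels (numeric code aliases are translated via the schema's code maps),
#' continuous values must parse to finite numbers, and a missing-value
#' sentinel (empty field by default) is only accepted in specific variables.
#' Nothing is silently coerced; the first offending token is reported with its
#' row and variable.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema A [survey_schema()] describing (at least) the file's columns.
#' @param delim Field delimiter, default `","`.
#' @param na Missing-value sentinel token(s), default the empty field.
#' @return A validated tibble carrying a `.row_id` column.
#' @export
read_survey <- function(path, schema, delim = ",", na = "") {
  if (!file.exists(path)) abort(sprintf("survey file not found: %s", path))
  raw <- readr::read_delim(path, delim = delim, na = na,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(schema$variable, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("file header does not cover schema variable(s): %s",
                  paste(missing, collapse = ", ")))
  }
  out <- validate_survey_values(raw, schema, where = basename(path))
  ensure_row_id(out)
}

#' Write a survey table to delimited text
#'
#' @param data Survey tibble.
#' @param path Output path.
#' @param delim Field delimiter.
#' @param na Sentinel written for missing specific values.
#' @return `path`, invisibly.
#' @export
write_survey <- function(data, path, delim = ",", na = "") {
  readr::write_delim(data, path, delim = delim, na = na)
  invisible(path)
}

#' Split a combined survey into donor and recipient files
#'
#' Rows flagged by a binary indicator become the donor file (and must carry a
#' complete specific block); the remaining rows become the recipient file,
#' from which the specific block is dropped.
#'
#' @param data Combined survey tibble.
#' @param donor_flag Name of a logical/binary indicator column.
#' @param spec A [fusion_spec()] naming the specific block.
#' @return A list with elements `donor` and `recipient`.
#' @export
split_donor_recipient <- function(data, donor_flag, spec) {
  assert_columns(data, c(donor_flag, spec$common), "survey table")
  data <- ensure_row_id(data)
  flag <- data[[donor_flag]]
  if (is.character(flag)) flag <- flag %in% c("1", "TRUE", "true", "yes", "Yes")
  flag <- as.logical(flag)
  if (anyNA(flag)) abort(sprintf("'%s' must be a binary indicator", donor_flag))
  donor <- dplyr::filter(data, flag)
  recipient <- dplyr::filter(data, !flag)
  if (nrow(donor) == 0) abort("donor partition is empty")
  spec_cols <- intersect(spec$specific, names(donor))
  incomplete <- !complete.cases(donor[spec_cols])
  if (any(incomplete)) {
    abort(sprintf("donor row %s is missing a specific (clinical) value",
                  donor$.row_id[which(incomplete)[1]]))
  }
  if (nrow(recipient) == 0) {
    warn("recipient partition is empty: all rows were flagged as donors")
  }
  recipient <- dplyr::select(recipient, -dplyr::any_of(spec$specific))
  list(donor = donor, recipient = recipient)
}

#' Diagnose donor coverage of the recipient file
#'
#' Pure diagnostics ahead of imputation: for each common categorical variable,
#' lists recipient levels absent from the donor file (uncovered levels cannot
#' be matched or modelled); for each common continuous variable, compares the
#' recipient support to the donor support and flags extrapolation regions.
#'
#' @param donor,recipient Survey tibbles.
#' @param spec A [fusion_spec()].
#' @param schema A [survey_schema()].
#' @return A tibble with one row per common variable: `variable`, `kind`,
#'   `uncovered_levels` (list), `donor_min`, `donor_max`, `recipient_min`,
#'   `recipient_max`, `extrapolation_low`, `extrapolation_high`.
#' @export
validate_fusion_inputs <- function(donor, recipient, spec, schema) {
  check_spec_against_schema(spec, schema)
  purrr::map_dfr(spec$common, function(v) {
    kind <- schema_kind(schema, v)
    if (is.na(kind)) kind <- if (is.numeric(donor[[v]])) "continuous" else "categorical"
    if (kind == "categorical") {
      uncovered <- setdiff(unique(recipient[[v]]), unique(donor[[v]]))
      tibble::tibble(variable = v, kind = kind,
                     uncovered_levels = list(uncovered),
                     donor_min = NA_real_, donor_max = NA_real_,
                     recipient_min = NA_real_, recipient_max = NA_real_,
                     extrapolation_low = FALSE, extrapolation_high = FALSE)
    } else {
      dmin <- min(donor[[v]]); dmax <- max(donor[[v]])
      rmin <- min(recipient[[v]]); rmax <- max(recipient[[v]])
      tibble::tibble(variable = v, kind = kind,
                     uncovered_levels = list(character()),
                     donor_min = dmin, donor_max = dmax,
                     recipient_min = rmin, recipient_max = rmax,
                     extrapolation_low = rmin < dmin,
                     extrapolation_high = rmax > dmax)
    }
  })
}
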