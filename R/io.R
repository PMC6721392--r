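# Patient-table I/O and schema validation. Tables travel as comma-separated
# UTF-8 text with a header row, "." decimal separator and empty fields for
# missing values.

#' Read / write a patient table
#'
#' @param path File path of a comma-separated patient table.
#' @return [read_patient_table()]: tibble; logical flag columns are restored
#'   as logicals.
#' @export
read_patient_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "mixstrat_config_error")
  }
  data <- readr::read_csv(path, show_col_types = FALSE, na = "",
                          progress = FALSE)
  for (col in intersect(.binary_vars, names(data))) {
    data[[col]] <- as.logical(data[[col]])
  }
  data
}

#' @rdname read_patient_table
#' @param data Patient table.
#' @return [write_patient_table()]: `path`, invisibly. Doubles are written
#'   with round-trip precision.
#' @export
write_patient_table <- function(data, path) {
  readr::write_csv(data, path, na = "", progress = FALSE)
  invisible(path)
}

#' Expected patient-table schema
#'
#' One row per column: name, expected type, allowed range for numeric
#' columns, and whether the column is required. The ranges restate the
#' record invariants (T-scores in \[0, 100\], `ptau` > 0, `ab_ratio` in
#' (0, 1), positive CSF analytes, finite `md_z`).
#'
#' @return Tibble with columns `column`, `type`, `min`, `max`, `required`.
#' @export
patient_schema <- function() {
  num <- tibble(
    column = .continuous_vars,
    type = "numeric",
    min = vapply(.continuous_vars, function(v) .variable_bounds[[v]][1], 0),
    max = vapply(.continuous_vars, function(v) .variable_bounds[[v]][2], 0),
    required = TRUE
  )
  dplyr::bind_rows(
    tibble(column = "patient_id", type = "character", min = NA_real_,
           max = NA_real_, required = FALSE),
    tibble(column = "clinical_label", type = "character", min = NA_real_,
           max = NA_real_, required = TRUE),
    tibble(column = "biological_label", type = "character", min = NA_real_,
           max = NA_real_, required = FALSE),
    num,
    tibble(column = .binary_vars, type = "logical", min = NA_real_,
           max = NA_real_, required = TRUE)
  )
}

#' Validate a patient table against the expected schema
#'
#' Report-only: checks column presence, type and numeric ranges and lists
#' every offending row without raising an error.
#'
#' @param data Patient table.
#' @param schema Schema tibble as from [patient_schema()].
#' @return Tibble with columns `column`, `row` (`NA` for table-level
#'   issues) and `issue`; zero rows means the table is valid. The logical
#'   attribute `ok` mirrors that.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 5))
#' nrow(validate_table(cohort))
#' @export
validate_table <- function(data, schema = patient_schema()) {
  issues <- list()
  push <- function(column, row, issue) {
    issues[[length(issues) + 1]] <<- tibble(
      column = column, row = as.integer(row), issue = issue
    )
  }
  for (i in seq_len(nrow(schema))) {
    col <- schema$column[i]
    if (!col %in% names(data)) {
      if (schema$required[i]) push(col, NA, "required column is missing")
      next
    }
    x <- data[[col]]
    if (schema$type[i] == "numeric") {
      if (!is.numeric(x)) {
        push(col, NA, paste0("expected numeric, got ", class(x)[1]))
        next
      }
      lo <- schema$min[i]; hi <- schema$max[i]
      bad <- which(is.finite(x) & (x < lo | x > hi))
      for (r in bad) {
        push(col, r, paste0("value ", format(x[r]), " outside [",
                            lo, ", ", hi, "]"))
      }
    } else if (schema$type[i] == "logical") {
      if (!is.logical(x)) {
        push(col, NA, paste0("expected logical, got ", class(x)[1]))
      }
    } else {
      if (!is.character(x)) {
        push(col, NA, paste0("expected character, got ", class(x)[1]))
      }
    }
  }
  lab_cols <- intersect(c("clinical_label", "biological_label"), names(data))
  for (col in lab_cols) {
    bad <- which(!is.na(data[[col]]) &
                   !data[[col]] %in% c(diagnosis_labels(), unclassified_label()))
    for (r in bad) {
      push(col, r, paste0("unknown label `", data[[col]][r], "`"))
    }
  }
  out <- if (length(issues)) dplyr::bind_rows(issues) else {
    tibble(column = character(), row = integer(), issue = character())
  }
  attr(out, "ok") <- nrow(out) == 0
  out
}
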