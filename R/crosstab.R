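# Clinical-versus-biological contingency table with margins, the report
# format for comparing the office-visit diagnosis with the biomarker-based
# one.

#' Cross-tabulate clinical against biological diagnoses
#'
#' @param clinical_labels,biological_labels Equal-length character vectors
#'   of diagnosis labels; every value must appear in `label_order`.
#' @param label_order Labels defining row/column order; defaults to the five
#'   patient groups (SIVD, AD, MX, MI, LA), the conventional order of the
#'   clinical-versus-biological count table.
#' @return Object of class `crosstab`: `counts` (clinical rows x biological
#'   columns), `row_margins`, `col_margins`, `total`, `labels`.
#' @examples
#' ct <- crosstab(c("AD", "AD", "MX"), c("AD", "MX", "MX"))
#' ct$counts
#' @export
crosstab <- function(clinical_labels, biological_labels,
                     label_order = diagnosis_labels(include_control = FALSE)) {
  clinical_labels <- as.character(clinical_labels)
  biological_labels <- as.character(biological_labels)
  if (length(clinical_labels) != length(biological_labels)) {
    abort("clinical and biological label vectors must have equal length",
          class = "mixstrat_input_error")
  }
  stray <- setdiff(unique(c(clinical_labels, biological_labels)), label_order)
  if (length(stray)) {
    abort(paste0("label(s) outside `label_order`: ",
                 paste(stray, collapse = ", ")),
          class = "mixstrat_input_error")
  }
  counts <- table(
    clinical = factor(clinical_labels, levels = label_order),
    biological = factor(biological_labels, levels = label_order)
  )
  counts <- matrix(as.integer(counts), nrow = length(label_order),
                   dimnames = list(clinical = label_order,
                                   biological = label_order))
  structure(
    list(
      counts = counts,
      row_margins = rowSums(counts),
      col_margins = colSums(counts),
      total = sum(counts),
      labels = label_order
    ),
    class = "crosstab"
  )
}

#' @export
print.crosstab <- function(x, ...) {
  cat("<crosstab> clinical (rows) x biological (columns), n = ",
      x$total, "\n", sep = "")
  m <- cbind(x$counts, Total = x$row_margins)
  m <- rbind(m, Total = c(x$col_margins, x$total))
  print(m)
  invisible(x)
}

#' @rdname crosstab
#' @param x,object A `crosstab`.
#' @param ... Unused.
#' @return `tidy()`: long tibble with `clinical`, `biological`, `n`;
#'   `glance()`: one row with `total`, `n_agree`, `agreement`.
#' @exportS3Method generics::tidy
#' @export
tidy.crosstab <- function(x, ...) {
  out <- as_tibble(as.data.frame.table(x$counts, responseName = "n",
                                       stringsAsFactors = FALSE))
  names(out) <- c("clinical", "biological", "n")
  out$n <- as.integer(out$n)
  out
}

#' @rdname crosstab
#' @exportS3Method generics::glance
#' @export
glance.crosstab <- function(x, ...) {
  agree <- sum(diag(x$counts))
  tibble(
    total = x$total,
    n_agree = agree,
    agreement = if (x$total > 0) agree / x$total else NA_real_
  )
}

# Square data frame with margins, for delimited-text export.
.crosstab_frame <- function(x) {
  m <- cbind(x$counts, Total = x$row_margins)
  m <- rbind(m, Total = c(x$col_margins, x$total))
  out <- as.data.frame(m)
  tibble::as_tibble(cbind(clinical = rownames(m), out))
}
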