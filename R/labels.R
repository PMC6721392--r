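#' Diagnostic labels used throughout the package
#'
#' The five biologically defined dementia groups plus cognitively normal
#' controls: subcortical ischemic vascular disease (`SIVD`, also called
#' Binswanger's disease), Alzheimer's disease (`AD`), mixed dementia (`MX`),
#' multiple infarcts (`MI`), leukoaraiosis (`LA`) and `CONTROL`.
#'
#' @param include_control Include the `CONTROL` label? Cross-tabulations of
#'   clinical versus biological diagnoses conventionally cover patients only,
#'   so [crosstab()] defaults to the five patient labels.
#' @return Character vector of labels in the package's canonical order.
#' @examples
#' diagnosis_labels()
#' diagnosis_labels(include_control = FALSE)
#' @export
diagnosis_labels <- function(include_control = TRUE) {
  base <- c("SIVD", "AD", "MX", "MI", "LA")
  if (include_control) c(base, "CONTROL") else base
}

#' Label returned for records that cannot be classified
#'
#' @return The string `"UNCLASSIFIED"`.
#' @keywords internal
#' @export
unclassified_label <- function() "UNCLASSIFIED"

.assert_label <- function(label) {
  if (!(is.character(label) && length(label) == 1L &&
        label %in% diagnosis_labels())) {
    abort(
      paste0("`label` must be one of ",
             paste(diagnosis_labels(), collapse = ", ")),
      class = "mixstrat_input_error"
    )
  }
  label
}
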