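# Composite cognitive scores and control-referenced diffusivity z-scores.
# T-scores sit on a mean-50, SD-10 scale; composites are plain means of the
# available (non-missing) inputs.

.domain_names <- c("memory", "executive", "attention", "language", "speed")

#' Average several test T-scores into a domain composite
#'
#' @param test_tscores Numeric vector of per-test T-scores; `NA` marks a
#'   test that was not administered. Present values must lie in \[0, 100\].
#' @param min_tests Minimum number of non-missing tests required (default 1).
#' @return The arithmetic mean of the non-missing scores.
#' @examples
#' domain_composite(c(30, 40, 50))
#' domain_composite(c(44, NA))
#' @export
domain_composite <- function(test_tscores, min_tests = 1L) {
  if (!is.numeric(test_tscores)) {
    abort("`test_tscores` must be numeric", class = "mixstrat_input_error")
  }
  present <- test_tscores[!is.na(test_tscores)]
  if (length(present) < min_tests) {
    abort(
      paste0("domain composite needs at least ", min_tests,
             " non-missing test score(s); got ", length(present)),
      class = "mixstrat_missing_data"
    )
  }
  if (any(present < 0 | present > 100)) {
    abort("T-scores must lie in [0, 100]", class = "mixstrat_input_error")
  }
  mean(present)
}

#' Overall cognitive composite from domain T-scores
#'
#' The overall composite is the mean of the available domain composites
#' (memory, executive, attention, language, processing speed). The number of
#' domains that contributed is reported alongside the score.
#'
#' @param domains Named numeric vector or list with any of `memory`,
#'   `executive`, `attention`, `language`, `speed`; `NA` marks a missing
#'   domain.
#' @return List with `overall` (T-score) and `n_domains` (count of
#'   contributing domains).
#' @examples
#' overall_composite(c(memory = 30, executive = 40))
#' @export
overall_composite <- function(domains) {
  x <- unlist(domains)
  if (is.null(names(x)) || !all(names(x) %in% .domain_names)) {
    abort(
      paste0("`domains` must be named with a subset of: ",
             paste(.domain_names, collapse = ", ")),
      class = "mixstrat_input_error"
    )
  }
  present <- x[!is.na(x)]
  if (length(present) == 0) {
    abort("all domain scores are missing", class = "mixstrat_missing_data")
  }
  if (any(present < 0 | present > 100)) {
    abort("T-scores must lie in [0, 100]", class = "mixstrat_input_error")
  }
  list(overall = mean(present), n_domains = length(present))
}

#' Add overall-composite columns to a patient table
#'
#' Table-level, vectorized companion of [overall_composite()]: computes the
#' row-wise mean of the available `t_*` domain columns. Rows with no domain
#' score at all get `NA` (they are reported, not dropped).
#'
#' @param data Patient table with some of the columns `t_memory`,
#'   `t_executive`, `t_attention`, `t_language`, `t_speed`.
#' @return `data` with `t_overall` and `n_domains` columns appended.
#' @export
add_overall_composite <- function(data) {
  cols <- intersect(paste0("t_", .domain_names), names(data))
  if (length(cols) == 0) {
    abort("no domain T-score columns (t_memory, t_executive, ...) found",
          class = "mixstrat_input_error")
  }
  m <- as.matrix(data[, cols, drop = FALSE])
  n_dom <- rowSums(!is.na(m))
  overall <- rowMeans(m, na.rm = TRUE)
  overall[n_dom == 0] <- NA_real_
  dplyr::mutate(data, t_overall = overall, n_domains = n_dom)
}

#' Fit the control reference for diffusivity normalization
#'
#' Estimates the control-group mean and standard deviation (n - 1
#' denominator) of the white-matter mean-diffusivity summary, against which
#' patient values are z-scored so that normal sits near zero and damaged
#' white matter in the 1-3 range.
#'
#' @param control_md_values Numeric vector of control MD summaries; at least
#'   two finite values with non-zero spread.
#' @return Object of class `control_reference` with fields `md_mean`,
#'   `md_sd`, `n_controls`.
#' @examples
#' fit_control_reference(c(1, 3))
#' @export
fit_control_reference <- function(control_md_values) {
  x <- control_md_values[is.finite(control_md_values)]
  if (length(x) < 2) {
    abort("need at least 2 finite control MD values",
          class = "mixstrat_degenerate_reference")
  }
  s <- sd(x)
  if (s == 0) {
    abort("control MD values have zero spread; cannot form z-scores",
          class = "mixstrat_degenerate_reference")
  }
  structure(
    list(md_mean = mean(x), md_sd = s, n_controls = length(x)),
    class = "control_reference"
  )
}

#' @export
print.control_reference <- function(x, ...) {
  cat("<control_reference> mean =", format(x$md_mean),
      " sd =", format(x$md_sd), " n =", x$n_controls, "\n")
  invisible(x)
}

#' @rdname fit_control_reference
#' @param x,object A `control_reference`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.control_reference <- function(x, ...) {
  tibble(term = c("md_mean", "md_sd"), estimate = c(x$md_mean, x$md_sd))
}

#' @rdname fit_control_reference
#' @exportS3Method generics::glance
#' @export
glance.control_reference <- function(x, ...) {
  tibble(md_mean = x$md_mean, md_sd = x$md_sd, n_controls = x$n_controls)
}

#' Z-score a mean-diffusivity value against the control reference
#'
#' @param md Numeric vector of MD summaries (same units as the reference);
#'   all values must be finite.
#' @param ref A [fit_control_reference()] object.
#' @return `(md - md_mean) / md_sd`.
#' @examples
#' ref <- fit_control_reference(c(1, 3))
#' md_zscore(2, ref)
#' @export
md_zscore <- function(md, ref) {
  if (!inherits(ref, "control_reference")) {
    abort("`ref` must be a control_reference object", class = "mixstrat_input_error")
  }
  if (!is.numeric(md) || any(!is.finite(md))) {
    abort("`md` must be finite numeric", class = "mixstrat_input_error")
  }
  (md - ref$md_mean) / ref$md_sd
}

#' Add an `md_z` column to a patient table
#'
#' Lenient table companion of [md_zscore()]: `NA` MD values yield `NA`
#' z-scores instead of an error, so incomplete records survive to be counted
#' as unclassifiable downstream.
#'
#' @param data Patient table.
#' @param ref A [fit_control_reference()] object.
#' @param md_col Name of the raw MD column (default `"md"`).
#' @return `data` with an `md_z` column appended.
#' @export
add_md_zscore <- function(data, ref, md_col = "md") {
  if (!md_col %in% names(data)) {
    abort(paste0("column `", md_col, "` not found"), class = "mixstrat_input_error")
  }
  md <- data[[md_col]]
  z <- rep(NA_real_, length(md))
  ok <- is.finite(md)
  if (any(ok)) z[ok] <- md_zscore(md[ok], ref)
  dplyr::mutate(data, md_z = z)
}
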