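# Rule-based biological classification. Two independent severity axes: the
# Alzheimer axis from CSF analytes (elevated Ptau, lowered amyloid 42/40
# ratio) and the vascular axis from the white-matter mean-diffusivity
# z-score. Crossing the two dichotomies partitions non-infarct patients into
# LA / AD / SIVD / MX; an infarct flag overrides to MI.

#' Classification thresholds
#'
#' Cut-points binarizing each biomarker. No numeric cut-points are published
#' for this stratification; the defaults are package choices (documented in
#' the methods vignette) that separate the printed group means:
#' `md_z_high = 2` sits between the vascular groups (SIVD 2.94, MX 3.20) and
#' the non-vascular ones (AD 0.74, LA 1.02); `ptau_high = 68` pg/mL between
#' AD/MX (87.75/118.86) and SIVD/LA (47.43/46.05); `ab_ratio_low = 0.07`
#' between the amyloid-positive (0.05) and amyloid-negative (0.10) defaults.
#' Positivity holds at the exact cut (`>=` for "high" markers, `<=` for
#' "low" markers).
#'
#' @param ptau_high CSF Ptau cut (pg/mL); at or above is tau-positive.
#' @param ab_ratio_low Amyloid 42/40 ratio cut; at or below is
#'   amyloid-positive.
#' @param md_z_high Mean-diffusivity z cut; at or above is vascular-positive.
#' @param t_memory_low,t_executive_low T-score cuts; at or below marks a
#'   deficit (default 40, one population SD below the mean).
#' @param albumin_index_high Albumin-index cut; at or above marks
#'   blood-brain-barrier leakage (used by the feature matcher only).
#' @param ad_axis_rule How the two CSF analytes combine into the Alzheimer
#'   axis: `"either"` (default), `"both"`, `"ptau_only"` or
#'   `"amyloid_only"`.
#' @return Object of class `thresholds`.
#' @examples
#' thresholds()
#' thresholds(ad_axis_rule = "both")
#' @export
thresholds <- function(ptau_high = 68,
                       ab_ratio_low = 0.07,
                       md_z_high = 2,
                       t_memory_low = 40,
                       t_executive_low = 40,
                       albumin_index_high = 7,
                       ad_axis_rule = c("either", "both", "ptau_only",
                                        "amyloid_only")) {
  ad_axis_rule <- match.arg(ad_axis_rule)
  cuts <- c(ptau_high = ptau_high, ab_ratio_low = ab_ratio_low,
            md_z_high = md_z_high, t_memory_low = t_memory_low,
            t_executive_low = t_executive_low,
            albumin_index_high = albumin_index_high)
  if (!all(is.finite(cuts))) {
    abort("all threshold cuts must be finite", class = "mixstrat_input_error")
  }
  structure(
    c(as.list(cuts), list(ad_axis_rule = ad_axis_rule)),
    class = "thresholds"
  )
}

#' @rdname thresholds
#' @export
default_thresholds <- function() thresholds()

#' @export
print.thresholds <- function(x, ...) {
  cat("<thresholds>\n")
  for (nm in setdiff(names(x), "ad_axis_rule")) {
    cat("  ", format(nm, width = 19), format(x[[nm]]), "\n", sep = "")
  }
  cat("  ad_axis_rule       ", x$ad_axis_rule, "\n", sep = "")
  invisible(x)
}

# Pulls a column, insisting it exists and is complete; the classifier's
# strict path. `kind` picks the finiteness check (logical flags have no
# notion of finite).
.get_complete <- function(data, col, kind = c("numeric", "logical")) {
  kind <- match.arg(kind)
  if (!col %in% names(data)) {
    abort(paste0("required column `", col, "` is missing"),
          class = "mixstrat_missing_data")
  }
  x <- data[[col]]
  bad <- if (kind == "numeric") !is.finite(as.numeric(x)) else is.na(x)
  if (any(bad)) {
    abort(paste0("missing or non-finite values in `", col, "` (",
                 sum(bad), " record(s))"),
          class = "mixstrat_missing_data")
  }
  if (kind == "logical") as.logical(x) else as.numeric(x)
}

#' Alzheimer-axis positivity from CSF analytes
#'
#' @param data Patient table (or single-row record) with `ptau` and
#'   `ab_ratio` columns; values must be present and finite.
#' @param th A [thresholds()] object.
#' @return Logical vector, one value per row.
#' @examples
#' ad_axis_positive(tibble::tibble(ptau = 118.86, ab_ratio = 0.05))
#' @export
ad_axis_positive <- function(data, th = default_thresholds()) {
  ptau <- .get_complete(data, "ptau")
  ab <- .get_complete(data, "ab_ratio")
  tau_pos <- ptau >= th$ptau_high
  amy_pos <- ab <= th$ab_ratio_low
  switch(th$ad_axis_rule,
    either = tau_pos | amy_pos,
    both = tau_pos & amy_pos,
    ptau_only = tau_pos,
    amyloid_only = amy_pos
  )
}

#' Vascular-axis positivity from the diffusivity z-score
#'
#' @inheritParams ad_axis_positive
#' @return Logical vector: `md_z >= md_z_high` per row.
#' @examples
#' vascular_axis_positive(tibble::tibble(md_z = c(2.94, 0.74)))
#' @export
vascular_axis_positive <- function(data, th = default_thresholds()) {
  .get_complete(data, "md_z") >= th$md_z_high
}

#' Double-dichotomy biological diagnosis
#'
#' Crosses the Alzheimer axis with the vascular axis: both positive is mixed
#' dementia (MX), Alzheimer only is AD, vascular only is SIVD, neither is
#' leukoaraiosis (LA). A present infarct overrides the quadrants and returns
#' MI.
#'
#' @param data Patient table with `ptau`, `ab_ratio`, `md_z` and logical
#'   `infarct` columns, all complete.
#' @param th A [thresholds()] object.
#' @return Character vector of labels in `{MI, MX, AD, SIVD, LA}`.
#' @examples
#' classify_dichotomy(tibble::tibble(
#'   ptau = c(118.86, 46.05), ab_ratio = c(0.05, 0.10),
#'   md_z = c(3.2, 1.0), infarct = c(FALSE, FALSE)
#' ))
#' @export
classify_dichotomy <- function(data, th = default_thresholds()) {
  infarct <- .get_complete(data, "infarct", "logical")
  ad <- ad_axis_positive(data, th)
  vasc <- vascular_axis_positive(data, th)
  dplyr::case_when(
    infarct ~ "MI",
    ad & vasc ~ "MX",
    ad ~ "AD",
    vasc ~ "SIVD",
    .default = "LA"
  )
}

.feature_names <- c(
  "hyperreflexia", "imbalance", "executive_deficit", "memory_deficit",
  "wmh_flair", "md_dti_high", "amyloid_positive", "ptau_positive",
  "albumin_index_high"
)

#' Expected feature signs per diagnostic group
#'
#' The nine-feature sign table used by the feature matcher: clinical signs
#' (hyperreflexia, imbalance), neuropsychology (executive and memory
#' deficits), MRI (white-matter hyperintensities on FLAIR, elevated
#' diffusivity on DTI) and CSF (amyloid positivity, Ptau positivity, raised
#' albumin index) for SIVD, AD, MX and LA.
#'
#' @return 9 x 4 logical matrix, features in rows, labels in columns.
#' @export
default_feature_matrix <- function() {
  m <- matrix(
    c( # SIVD    AD     MX     LA
      TRUE,  FALSE, TRUE,  FALSE,  # hyperreflexia
      TRUE,  FALSE, TRUE,  FALSE,  # imbalance
      TRUE,  FALSE, FALSE, FALSE,  # executive_deficit
      FALSE, TRUE,  TRUE,  FALSE,  # memory_deficit
      TRUE,  FALSE, TRUE,  TRUE,   # wmh_flair
      TRUE,  FALSE, TRUE,  FALSE,  # md_dti_high
      FALSE, TRUE,  TRUE,  FALSE,  # amyloid_positive
      FALSE, TRUE,  TRUE,  FALSE,  # ptau_positive
      TRUE,  FALSE, TRUE,  FALSE   # albumin_index_high
    ),
    ncol = 4, byrow = TRUE,
    dimnames = list(.feature_names, c("SIVD", "AD", "MX", "LA"))
  )
  m
}

#' Binarize a patient record into the nine-feature vector
#'
#' Deterministic thresholding: deficits at or below the T-score cuts,
#' positivity at or above the "high" cuts / at or below the "low" cuts;
#' clinical sign flags are copied through.
#'
#' @param data Patient table with `t_memory`, `t_executive`, `md_z`, `ptau`,
#'   `ab_ratio`, `albumin_index` and logical `hyperreflexia`, `imbalance`,
#'   `wmh_present` columns, all complete.
#' @param th A [thresholds()] object.
#' @return Tibble of nine logical columns, one row per record.
#' @export
feature_vector <- function(data, th = default_thresholds()) {
  tibble(
    hyperreflexia = .get_complete(data, "hyperreflexia", "logical"),
    imbalance = .get_complete(data, "imbalance", "logical"),
    executive_deficit = .get_complete(data, "t_executive") <= th$t_executive_low,
    memory_deficit = .get_complete(data, "t_memory") <= th$t_memory_low,
    wmh_flair = .get_complete(data, "wmh_present", "logical"),
    md_dti_high = vascular_axis_positive(data, th),
    amyloid_positive = .get_complete(data, "ab_ratio") <= th$ab_ratio_low,
    ptau_positive = .get_complete(data, "ptau") >= th$ptau_high,
    albumin_index_high = .get_complete(data, "albumin_index") >= th$albumin_index_high
  )
}

#' Nearest-archetype diagnosis from a feature vector
#'
#' Scores each candidate label by the number of the nine features whose
#' observed value matches the label's expected sign and returns the
#' best-scoring label. Ties are broken by the fixed precedence
#' MX > SIVD > AD > LA, favouring the treatment-relevant dual-pathology
#' call.
#'
#' @param fv Tibble from [feature_vector()] (any number of rows).
#' @param fm Sign matrix from [default_feature_matrix()].
#' @return Tibble with `label` and one `score_<label>` column per candidate.
#' @examples
#' fm <- default_feature_matrix()
#' fv <- tibble::as_tibble(t(fm[, "MX"]))
#' classify_feature_matrix(fv, fm)
#' @export
classify_feature_matrix <- function(fv, fm = default_feature_matrix()) {
  if (!all(rownames(fm) %in% names(fv))) {
    abort(paste0("`fv` must contain all feature columns: ",
                 paste(rownames(fm), collapse = ", ")),
          class = "mixstrat_input_error")
  }
  obs <- as.matrix(fv[, rownames(fm), drop = FALSE])
  if (anyNA(obs)) {
    abort("feature vectors must be complete (no NA) at classification time",
          class = "mixstrat_missing_data")
  }
  labs <- colnames(fm)
  scores <- vapply(labs, function(l) {
    rowSums(obs == matrix(fm[, l], nrow(obs), nrow(fm), byrow = TRUE))
  }, numeric(nrow(obs)))
  scores <- matrix(scores, nrow = nrow(obs),
                   dimnames = list(NULL, labs))
  precedence <- intersect(c("MX", "SIVD", "AD", "LA"), labs)
  label <- apply(scores[, precedence, drop = FALSE], 1L, function(s) {
    precedence[which.max(s)]
  })
  out <- tibble(label = unname(as.character(label)))
  for (l in labs) out[[paste0("score_", l)]] <- unname(scores[, l])
  out
}

# Per-method required columns; a record missing any of them is UNCLASSIFIED.
.required_columns <- function(method) {
  switch(method,
    dichotomy = list(numeric = c("ptau", "ab_ratio", "md_z"),
                     logical = "infarct"),
    feature_matrix = list(
      numeric = c("t_memory", "t_executive", "md_z", "ptau", "ab_ratio",
                  "albumin_index"),
      logical = c("hyperreflexia", "imbalance", "wmh_present")
    )
  )
}

#' Classify every record of a patient table
#'
#' Applies the double dichotomy (default) or the feature matcher row by row.
#' Records with a missing or non-finite required field get the label
#' `UNCLASSIFIED` instead of raising an error; the per-row reasons are
#' attached as the `unclassified_reasons` attribute and counted in
#' `n_unclassified`.
#'
#' @param data Patient table.
#' @param th A [thresholds()] object.
#' @param method `"dichotomy"` or `"feature_matrix"`.
#' @param fm Sign matrix for the feature matcher.
#' @return `data` with a `biological_label_predicted` column appended (and,
#'   for the feature matcher, per-label `score_*` columns).
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 7))
#' classified <- classify_cohort(cohort)
#' table(classified$biological_label_predicted)
#' @export
classify_cohort <- function(data, th = default_thresholds(),
                            method = c("dichotomy", "feature_matrix"),
                            fm = default_feature_matrix()) {
  method <- match.arg(method)
  req <- .required_columns(method)
  n <- nrow(data)
  ok <- rep(TRUE, n)
  reasons <- rep(NA_character_, n)
  for (col in req$numeric) {
    miss <- if (col %in% names(data)) !is.finite(as.numeric(data[[col]])) else rep(TRUE, n)
    reasons[miss & is.na(reasons)] <- paste0("missing `", col, "`")
    ok <- ok & !miss
  }
  for (col in req$logical) {
    miss <- if (col %in% names(data)) is.na(data[[col]]) else rep(TRUE, n)
    reasons[miss & is.na(reasons)] <- paste0("missing `", col, "`")
    ok <- ok & !miss
  }
  label <- rep(unclassified_label(), n)
  out <- data
  if (method == "feature_matrix") {
    for (l in colnames(fm)) out[[paste0("score_", l)]] <- NA_real_
  }
  if (any(ok)) {
    sub <- data[ok, , drop = FALSE]
    if (method == "dichotomy") {
      label[ok] <- classify_dichotomy(sub, th)
    } else {
      res <- classify_feature_matrix(feature_vector(sub, th), fm)
      label[ok] <- res$label
      for (l in colnames(fm)) {
        out[[paste0("score_", l)]][ok] <- res[[paste0("score_", l)]]
      }
    }
  }
  out$biological_label_predicted <- label
  bad <- which(!ok)
  attr(out, "n_unclassified") <- length(bad)
  attr(out, "unclassified_reasons") <-
    tibble(row = bad, reason = reasons[bad])
  out
}
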