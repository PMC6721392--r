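# Nonparametric group comparison: per-group summaries, Kruskal-Wallis
# omnibus tests, pairwise Mann-Whitney with family-wise correction. The
# tests themselves are delegated to stats::kruskal.test / stats::wilcox.test;
# this layer fixes conventions (tie handling, exactness, orientation,
# correction family) and returns tidy tables.

#' Kruskal-Wallis omnibus test over a list of samples
#'
#' Tie-corrected H statistic with a chi-square approximation on k - 1
#' degrees of freedom. When every pooled value is identical the statistic is
#' 0 and p is reported as 1 (package convention for the fully degenerate
#' case, where the tie correction is undefined).
#'
#' @param samples List of >= 2 numeric vectors, each with >= 1 finite value
#'   and >= 3 finite values in total.
#' @return List with `statistic` (H), `df` and `p_value`.
#' @examples
#' kruskal_wallis(list(1:3, 4:6, 7:9))
#' @export
kruskal_wallis <- function(samples) {
  if (!is.list(samples) || length(samples) < 2) {
    abort("`samples` must be a list of at least 2 groups",
          class = "mixstrat_input_error")
  }
  samples <- lapply(samples, function(x) as.numeric(x[is.finite(x)]))
  sizes <- lengths(samples)
  if (any(sizes < 1) || sum(sizes) < 3) {
    abort("each group needs >= 1 finite value and >= 3 in total",
          class = "mixstrat_input_error")
  }
  x <- unlist(samples, use.names = FALSE)
  g <- factor(rep(seq_along(samples), sizes))
  if (length(unique(x)) == 1L) {
    return(list(statistic = 0, df = length(samples) - 1L, p_value = 1))
  }
  kt <- kruskal.test(x, g)
  list(statistic = unname(kt$statistic),
       df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Two-sided Mann-Whitney U test for two samples
#'
#' U is oriented to the first sample: the number of (x, y) pairs with
#' x > y, counting ties as one half (identical to the `W` of
#' [stats::wilcox.test()]), so fully disjoint samples with all of `x` below
#' `y` give U = 0. The p-value is exact (enumeration) when both samples have
#' at most 20 values and no ties are present; otherwise the normal
#' approximation with tie and continuity correction is used.
#'
#' @param x,y Numeric vectors; non-finite values are dropped.
#' @return List with `statistic` (U), `p_value` and `exact` (logical).
#' @examples
#' mann_whitney(c(1, 2, 3), c(10, 11, 12))
#' @export
mann_whitney <- function(x, y) {
  x <- as.numeric(x[is.finite(x)])
  y <- as.numeric(y[is.finite(y)])
  if (length(x) < 1 || length(y) < 1) {
    abort("both samples need at least one finite value",
          class = "mixstrat_input_error")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && max(length(x), length(y)) <= 20
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic),
       p_value = min(wt$p.value, 1),
       exact = exact)
}

#' Pairwise Mann-Whitney tests with family-wise correction
#'
#' Tests every unordered pair of groups, two-sided, separately for each
#' variable; the multiple-comparison family is the set of pairs within one
#' variable. The default correction is Holm's step-down (uniformly more
#' powerful than Bonferroni at the same family-wise error rate), with
#' Bonferroni available.
#'
#' @param data Patient table.
#' @param variables Character vector of numeric column names to test.
#' @param group_col Grouping column name (default `"biological_label"`).
#' @param correction `"holm"` (default) or `"bonferroni"`.
#' @return Tibble with one row per (variable, pair): `variable`, `group1`,
#'   `group2`, `n1`, `n2`, `statistic` (U for group1), `p_value`,
#'   `p_adjusted`, `exact`, `correction`.
#' @export
pairwise_mannwhitney <- function(data, variables,
                                 group_col = "biological_label",
                                 correction = c("holm", "bonferroni")) {
  correction <- match.arg(correction)
  if (!group_col %in% names(data)) {
    abort(paste0("grouping column `", group_col, "` not found"),
          class = "mixstrat_input_error")
  }
  bad <- setdiff(variables, names(data))
  if (length(bad)) {
    abort(paste0("unknown variable(s): ", paste(bad, collapse = ", ")),
          class = "mixstrat_input_error")
  }
  groups <- unique(as.character(data[[group_col]]))
  out <- purrr::map_dfr(variables, function(v) {
    vals <- lapply(groups, function(g) {
      x <- data[[v]][data[[group_col]] == g]
      as.numeric(x[is.finite(x)])
    })
    names(vals) <- groups
    usable <- groups[lengths(vals) >= 1]
    skipped <- setdiff(groups, usable)
    if (length(skipped)) {
      warn(paste0("`", v, "`: skipping group(s) with no data: ",
                  paste(skipped, collapse = ", ")))
    }
    if (length(usable) < 2) return(tibble())
    pairs <- utils::combn(usable, 2)
    res <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
      g1 <- pairs[1, i]; g2 <- pairs[2, i]
      mw <- mann_whitney(vals[[g1]], vals[[g2]])
      tibble(
        variable = v, group1 = g1, group2 = g2,
        n1 = length(vals[[g1]]), n2 = length(vals[[g2]]),
        statistic = mw$statistic, p_value = mw$p_value, exact = mw$exact
      )
    })
    res$p_adjusted <- p.adjust(res$p_value, method = correction)
    res$correction <- correction
    res
  })
  out
}

#' Per-group summaries with Kruskal-Wallis omnibus tests
#'
#' For each variable, reports each group's n, mean and standard deviation
#' (n - 1 denominator; `NA` where n < 2) together with the tie-corrected
#' Kruskal-Wallis H and p over all groups with data. Missing values are
#' excluded per variable.
#'
#' @param data Patient table.
#' @param variables Character vector of numeric column names to summarize.
#' @param group_col Grouping column name (default `"biological_label"`).
#' @return Tibble of class `group_summary`, one row per (variable, group):
#'   `variable`, `group`, `n`, `mean`, `sd`, `statistic`, `df`, `p_value`
#'   (omnibus columns repeated within a variable).
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 3))
#' summarize_groups(cohort, c("ptau", "md_z"))
#' @export
summarize_groups <- function(data, variables,
                             group_col = "biological_label") {
  if (!group_col %in% names(data)) {
    abort(paste0("grouping column `", group_col, "` not found"),
          class = "mixstrat_input_error")
  }
  bad <- setdiff(variables, names(data))
  if (length(bad)) {
    abort(paste0("unknown variable(s): ", paste(bad, collapse = ", ")),
          class = "mixstrat_input_error")
  }
  groups <- unique(as.character(data[[group_col]]))
  out <- purrr::map_dfr(variables, function(v) {
    vals <- lapply(groups, function(g) {
      x <- data[[v]][data[[group_col]] == g]
      as.numeric(x[is.finite(x)])
    })
    names(vals) <- groups
    usable <- vals[lengths(vals) >= 1]
    omni <- if (length(usable) >= 2 && sum(lengths(usable)) >= 3) {
      kruskal_wallis(usable)
    } else {
      list(statistic = NA_real_, df = NA_real_, p_value = NA_real_)
    }
    tibble(
      variable = v,
      group = groups,
      n = unname(lengths(vals)),
      mean = unname(vapply(vals, function(x) if (length(x)) mean(x) else NA_real_, 0)),
      sd = unname(vapply(vals, function(x) if (length(x) >= 2) sd(x) else NA_real_, 0)),
      statistic = omni$statistic,
      df = omni$df,
      p_value = omni$p_value
    )
  })
  class(out) <- c("group_summary", class(out))
  attr(out, "group_col") <- group_col
  out
}
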