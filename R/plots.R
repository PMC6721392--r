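# ggplot2 views of the main result types.

#' Scatter of the two diagnostic axes
#'
#' Plots each record in the (diffusivity z, Ptau) plane with the two
#' threshold lines, the visual form of the double dichotomy: the upper-right
#' quadrant is mixed dementia, upper-left AD, lower-right SIVD, lower-left
#' LA.
#'
#' @param data Patient table with `md_z` and `ptau` columns.
#' @param th A [thresholds()] object (drawn as dashed lines).
#' @param colour_by Optional label column to colour points by (default
#'   `biological_label_predicted` if present, else `biological_label` if
#'   present).
#' @return A ggplot object.
#' @export
plot_dichotomy <- function(data, th = default_thresholds(),
                           colour_by = NULL) {
  colour_by <- colour_by %||%
    intersect(c("biological_label_predicted", "biological_label"),
              names(data))[1]
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$md_z, y = .data$ptau))
  if (!is.na(colour_by) && !is.null(colour_by)) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(colour = .data[[colour_by]]), alpha = 0.8
    ) + ggplot2::labs(colour = colour_by)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.8)
  }
  p +
    ggplot2::geom_vline(xintercept = th$md_z_high, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = th$ptau_high, linetype = "dashed") +
    ggplot2::labs(
      x = "white-matter MD z-score (vascular axis)",
      y = "CSF Ptau, pg/mL (Alzheimer axis)"
    )
}

#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.group_summary <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd)
    ) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "group mean ± SD")
}

#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.crosstab <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$biological, y = .data$clinical,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "biological diagnosis", y = "clinical diagnosis",
                  fill = "count")
}
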