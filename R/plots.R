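#' Plot per-clone breeding values from a fit
#'
#' Histogram of the EBVs/GEBVs with the selected top fraction highlighted.
#'
#' @param object A [fit_blup()] result.
#' @param top_fraction Fraction to highlight (default 0.10).
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot gs_fit
#' @export
autoplot.gs_fit <- function(object, top_fraction = 0.10, ...) {
  bv <- tidy(object)
  cut <- sort(bv$bv, decreasing = TRUE)[ceiling(top_fraction * nrow(bv))]
  ggplot(bv, aes(x = .data$bv, fill = .data$bv >= cut)) +
    geom_histogram(bins = 30, show.legend = FALSE) +
    scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "#2c7fb8")) +
    labs(
      x = paste0(
        if (object$kind == "genomic") "GEBV" else "EBV",
        " (", object$trait, ")"
      ),
      y = "Clones",
      title = paste0(
        object$kind, " breeding values, top ",
        round(100 * top_fraction), "% highlighted"
      )
    ) +
    theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' Dot plot of predictive ability, accuracy and bias across folds with the
#' fold means.
#'
#' @param object A [cross_validate()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot gs_cv
#' @export
autoplot.gs_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$folds, c("pa", "accuracy", "bias"),
    names_to = "metric", values_to = "value"
  )
  ggplot(long, aes(x = .data$metric, y = .data$value)) +
    geom_jitter(width = 0.08, alpha = 0.6) +
    stat_summary(fun = mean, geom = "crossbar", width = 0.4, colour = "#d95f02") +
    labs(
      x = NULL, y = NULL,
      title = paste0(
        object$k, "-fold CV, ", object$kind, " analysis, ",
        object$trait
      )
    ) +
    theme_minimal()
}

#' Scatter plot of backsolved SNP effects
#'
#' Simple marker-index scatter of allele-substitution effects (a Manhattan-
#' style overview when marker order follows the genome).
#'
#' @param effects Tibble from [backsolve_snp_effects()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
plot_snp_effects <- function(effects, ...) {
  effects <- dplyr::mutate(effects, index = dplyr::row_number())
  ggplot(effects, aes(x = .data$index, y = .data$effect)) +
    geom_point(size = 0.4, alpha = 0.5) +
    labs(x = "Marker index", y = "SNP effect") +
    theme_minimal()
}
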