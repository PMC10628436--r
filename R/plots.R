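#' @importFrom ggplot2 ggplot aes geom_density geom_boxplot geom_col
#'   geom_jitter labs theme_minimal autoplot coord_flip
NULL

#' @export
ggplot2::autoplot

#' Skipping-ratio distribution by class
#'
#' Density of the per-window skipping ratio stratified by label. dsRNA
#' windows sit in a unimodal low mode (template switching hits a minor
#' fraction of molecules); control windows containing splice junctions are
#' bimodal, mirroring exon inclusion levels.
#'
#' @param features Labelled feature table (needs `skip_ratio` and `label`).
#' @return A ggplot object.
#' @export
plot_skip_ratio_distribution <- function(features) {
  df <- mutate(features,
               class = ifelse(.data$label == 1, "dsRNA", "control"))
  ggplot(df, aes(x = .data$skip_ratio, fill = .data$class)) +
    geom_density(alpha = 0.5, adjust = 0.6) +
    labs(x = "skipping ratio", y = "density", fill = NULL) +
    theme_minimal()
}

#' @describeIn cross_validate Box plot of per-fold accuracies.
#' @param object A `dsrna_cv`.
#' @param ... Unused.
#' @method autoplot dsrna_cv
#' @export
autoplot.dsrna_cv <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = "", y = .data$accuracy)) +
    geom_boxplot(width = 0.3, outlier.shape = NA) +
    geom_jitter(width = 0.08, alpha = 0.6) +
    labs(x = NULL, y = "held-out fold accuracy",
         title = paste0(object$k, "-fold cross-validation")) +
    theme_minimal()
}

#' @describeIn permutation_importance Bar plot of contribution scores.
#' @param object A `dsrna_importance`.
#' @param ... Unused.
#' @method autoplot dsrna_importance
#' @export
autoplot.dsrna_importance <- function(object, ...) {
  df <- utils::head(object$scores, 10)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot(df, aes(x = .data$feature, y = .data$contribution)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = expression(paste("decrease in ", R^2)),
         title = "Permutation feature contributions") +
    theme_minimal()
}
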