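#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
print.dsrna_model <- function(x, ...) {
  cat("Window random-forest dsRNA classifier\n")
  cat("  trees:", x$config$n_trees, " mtry:", x$mtry,
      " leaf size:", x$config$min_samples_leaf, "\n")
  cat("  features:", length(x$feature_names),
      " training rows:", x$n_train, "\n")
  cat("  fingerprint:", x$fingerprint, "\n")
  invisible(x)
}

#' Tidy a fitted dsRNA model into per-feature importance
#'
#' @param x A `dsrna_model`.
#' @param ... Unused.
#' @return A tibble with `feature` and the forest's mean decrease in Gini
#'   impurity.
#' @method tidy dsrna_model
#' @export
tidy.dsrna_model <- function(x, ...) {
  imp <- x$forest$importance
  tibble(feature = rownames(imp),
         gini_decrease = as.numeric(imp[, "MeanDecreaseGini"])) |>
    arrange(desc(.data$gini_decrease))
}

#' One-row summary of a fitted dsRNA model
#'
#' @param x A `dsrna_model`.
#' @param ... Unused.
#' @return A one-row tibble: tree count, mtry, leaf size, training size,
#'   out-of-bag error.
#' @method glance dsrna_model
#' @export
glance.dsrna_model <- function(x, ...) {
  err <- x$forest$err.rate
  tibble(n_trees = x$config$n_trees, mtry = x$mtry,
         min_samples_leaf = x$config$min_samples_leaf,
         n_train = x$n_train,
         oob_error = as.numeric(err[nrow(err), "OOB"]))
}

#' @export
print.dsrna_cv <- function(x, ...) {
  cat(x$k, "-fold cross-validation\n", sep = "")
  cat("  mean accuracy:", round(mean(x$fold_accuracy), 4), "\n")
  cat("  ROC AUC:", round(x$roc_auc, 4), " AUPRC:", round(x$auprc, 4), "\n")
  invisible(x)
}

#' Per-fold cross-validation accuracies
#'
#' @param x A `dsrna_cv`.
#' @param ... Unused.
#' @return A tibble with `fold` and `accuracy`.
#' @method tidy dsrna_cv
#' @export
tidy.dsrna_cv <- function(x, ...) {
  tibble(fold = seq_along(x$fold_accuracy), accuracy = x$fold_accuracy)
}

#' One-row summary of a cross-validation run
#'
#' @param x A `dsrna_cv`.
#' @param ... Unused.
#' @return A one-row tibble: fold count, mean/sd accuracy, ROC AUC, AUPRC.
#' @method glance dsrna_cv
#' @export
glance.dsrna_cv <- function(x, ...) {
  tibble(k = x$k, mean_accuracy = mean(x$fold_accuracy),
         sd_accuracy = sd(x$fold_accuracy),
         roc_auc = x$roc_auc, auprc = x$auprc)
}

#' @export
print.dsrna_importance <- function(x, ...) {
  cat("Permutation feature contributions (baseline R^2 =",
      round(x$baseline_r2, 4), ")\n")
  print(utils::head(x$scores, 5))
  invisible(x)
}

#' Per-feature permutation contributions
#'
#' @param x A `dsrna_importance`.
#' @param ... Unused.
#' @return The `scores` tibble (`feature`, `contribution`), sorted.
#' @method tidy dsrna_importance
#' @export
tidy.dsrna_importance <- function(x, ...) x$scores

#' One-row summary of a permutation-importance run
#'
#' @param x A `dsrna_importance`.
#' @param ... Unused.
#' @return A one-row tibble: baseline R-squared, repeats, top feature.
#' @method glance dsrna_importance
#' @export
glance.dsrna_importance <- function(x, ...) {
  tibble(baseline_r2 = x$baseline_r2, repeats = x$repeats,
         top_feature = x$scores$feature[1])
}
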