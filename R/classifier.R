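#' @importFrom randomForest randomForest
NULL

#' Random-forest hyperparameter configuration
#'
#' Defaults are the tuned values adopted for the window classifier: Gini
#' split criterion, bootstrapped samples, unlimited depth, minimum split
#' size 2, minimum leaf size 4, 20% of features considered per split, 100
#' trees. They map onto [randomForest::randomForest()] as `ntree`,
#' `nodesize` (leaf minimum), `mtry = floor(0.2 * n_features)` and
#' `replace`; the Gini criterion and split minimum of 2 are that
#' implementation's fixed behaviour for classification, recorded here for
#' provenance.
#'
#' @param n_trees Number of trees.
#' @param min_samples_leaf Minimum samples per leaf (`nodesize`).
#' @param min_samples_split Minimum samples to split (informational; 2 is
#'   the implementation's behaviour).
#' @param max_features_fraction Fraction of features tried per split.
#' @param bootstrap Whether trees are fit on bootstrap samples.
#' @param max_depth Depth limit (`NULL` = unlimited).
#' @param seed Integer seed used when fitting.
#' @return A named list of class `model_config`.
#' @export
model_config <- function(n_trees = 100L, min_samples_leaf = 4L,
                         min_samples_split = 2L,
                         max_features_fraction = 0.20, bootstrap = TRUE,
                         max_depth = NULL, seed = 1L) {
  structure(
    list(split_criterion = "gini", bootstrap = bootstrap,
         max_depth = max_depth, min_samples_split = as.integer(min_samples_split),
         min_samples_leaf = as.integer(min_samples_leaf),
         max_features_fraction = max_features_fraction,
         n_trees = as.integer(n_trees), seed = as.integer(seed)),
    class = "model_config"
  )
}

# widen intervals symmetrically to at least `width` nt, clipped to chromosome
pad_intervals <- function(intervals, genome, width) {
  for (k in seq_len(nrow(intervals))) {
    w <- intervals$end[k] - intervals$start[k]
    if (w >= width) next
    clen <- length(genome[[intervals$chrom[k]]])
    s <- max(0, intervals$start[k] - ceiling((width - w) / 2))
    e <- min(clen, s + width)
    intervals$start[k] <- max(0, e - width)
    intervals$end[k] <- e
  }
  intervals
}

# windows overlap when they share >= 1 base on the same chromosome
overlaps_any <- function(chrom, start, end, intervals) {
  if (nrow(intervals) == 0L) return(FALSE)
  any(intervals$chrom == chrom & intervals$start < end & intervals$end > start)
}

#' Assemble a balanced training set
#'
#' Positive rows are feature vectors over curated dsRNA intervals that pass
#' the candidate filter (at least `min_reads` overlapping reads and one
#' region-skipping read). Negative rows are uniformly sampled windows of
#' `window_size` nt, rejected when they overlap any positive interval or
#' fail the same read filter, resampled until the class counts match.
#'
#' @param positives Tibble of curated dsRNA intervals (`chrom`, `start`,
#'   `end`), e.g. from [curate_positive_regions()].
#' @param genome Named [Biostrings::DNAStringSet].
#' @param reads Read table from [read_alignments()].
#' @param window_size Control window size (nt); positive intervals narrower
#'   than this are widened symmetrically to it (clipped at chromosome ends)
#'   so both classes are profiled over comparable spans and boundary skips
#'   of the dsRNA are not lost.
#' @param seed Integer seed for control sampling.
#' @param min_reads,min_skip_len Candidate filter parameters.
#' @param max_attempt_factor Sampling attempts allowed per needed control.
#' @return A feature table with a binary `label` column (1 = dsRNA
#'   positive, 0 = random control); `chrom`, `start`, `end` record
#'   provenance.
#' @export
curate_training_set <- function(positives, genome, reads, window_size = 2500,
                                seed = 1L, min_reads = 6, min_skip_len = 20,
                                max_attempt_factor = 100) {
  stopifnot(nrow(positives) > 0L)
  positives <- pad_intervals(positives, genome, window_size)
  pos_rows <- list()
  for (k in seq_len(nrow(positives))) {
    idx <- index_reads_by_window(reads, positives$chrom[k], positives$start[k],
                                 positives$end[k], min_skip_len = min_skip_len)
    if (idx$total_reads >= min_reads && idx$skipping_reads >= 1L) {
      pos_rows[[length(pos_rows) + 1L]] <-
        extract_features(reads, genome, positives$chrom[k], positives$start[k],
                         positives$end[k], min_skip_len = min_skip_len)
    }
  }
  pos_tbl <- bind_rows(pos_rows)
  if (nrow(pos_tbl) == 0L) {
    abort("no positive interval passes the read filter")
  }
  needed <- nrow(pos_tbl)
  chroms <- names(genome)
  lens <- setNames(Biostrings::width(genome), chroms)
  set.seed(seed)
  ctl_rows <- list(); attempts <- 0L
  while (length(ctl_rows) < needed) {
    attempts <- attempts + 1L
    if (attempts > max_attempt_factor * needed) {
      abort(paste0("could not sample enough control windows: found ",
                   length(ctl_rows), " of ", needed))
    }
    chrom <- if (length(chroms) == 1L) chroms else {
      sample(chroms, 1, prob = lens / sum(lens))
    }
    if (lens[[chrom]] <= window_size) next
    start <- floor(runif(1, 0, lens[[chrom]] - window_size))
    end <- start + window_size
    if (overlaps_any(chrom, start, end, positives)) next
    idx <- index_reads_by_window(reads, chrom, start, end,
                                 min_skip_len = min_skip_len)
    if (idx$total_reads < min_reads || idx$skipping_reads < 1L) next
    ctl_rows[[length(ctl_rows) + 1L]] <-
      extract_features(reads, genome, chrom, start, end,
                       min_skip_len = min_skip_len)
  }
  bind_rows(mutate(pos_tbl, label = 1L), mutate(bind_rows(ctl_rows), label = 0L))
}

#' Train the window random forest
#'
#' @param training A feature table with a binary `label` column, balanced,
#'   at least two rows per class.
#' @param config A [model_config()].
#' @return An object of class `dsrna_model`: the fitted forest, the feature
#'   name order required at prediction time, the config, and a fingerprint
#'   of the training rows.
#' @export
train_model <- function(training, config = model_config()) {
  feats <- feature_names()
  missing <- setdiff(c(feats, "label"), names(training))
  if (length(missing) > 0L) {
    abort(paste0("training table lacks columns: ", paste(missing, collapse = ", ")))
  }
  y <- factor(training$label, levels = c(0L, 1L))
  if (length(unique(training$label)) < 2L) {
    abort("training set contains a single class")
  }
  x <- as.data.frame(training[, feats])
  mtry <- max(1L, floor(config$max_features_fraction * length(feats)))
  set.seed(config$seed)
  forest <- randomForest::randomForest(
    x = x, y = y, ntree = config$n_trees, mtry = mtry,
    nodesize = config$min_samples_leaf, replace = config$bootstrap,
    importance = FALSE
  )
  structure(
    list(forest = forest, feature_names = feats, config = config,
         mtry = mtry, n_train = nrow(training),
         fingerprint = rlang::hash(training[, c(feats, "label")])),
    class = "dsrna_model"
  )
}

#' Predict dsRNA probability for feature rows
#'
#' Columns are aligned by name to the model's training order, so column
#' order in `features` is irrelevant.
#'
#' @param model A `dsrna_model`.
#' @param features Feature table (any superset of the model's features).
#' @return Numeric vector of positive-class probabilities in \[0, 1\]
#'   (forest vote fractions).
#' @export
predict_proba <- function(model, features) {
  missing <- setdiff(model$feature_names, names(features))
  if (length(missing) > 0L) {
    abort(paste0("missing feature column(s): ", paste(missing, collapse = ", ")))
  }
  x <- as.data.frame(features[, model$feature_names])
  unname(stats::predict(model$forest, x, type = "prob")[, "1"])
}

#' Save / load a trained model
#'
#' The single-file artifact embeds the forest, feature order, config and
#' training fingerprint; a reloaded model reproduces probabilities exactly.
#'
#' @param model A `dsrna_model`.
#' @param path File path.
#' @export
write_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "dsrna_model")) abort("file is not a saved dsrna_model")
  model
}

# step-interpolated average precision over distinct thresholds
average_precision <- function(labels, probs) {
  o <- order(probs, decreasing = TRUE)
  labels <- labels[o]; probs <- probs[o]
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) return(NA_real_)
  tp <- cumsum(labels == 1L)
  fp <- cumsum(labels == 0L)
  keep <- c(probs[-1] != probs[-length(probs)], TRUE)  # last index of each tie
  tp <- tp[keep]; fp <- fp[keep]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Stratified k-fold cross-validation
#'
#' Rows are shuffled within class under `seed` and dealt round-robin into
#' `k` folds; each fold is held out once. Accuracy uses the 0.5 probability
#' threshold; out-of-fold probabilities are pooled into one ROC AUC and one
#' area under the precision-recall curve.
#'
#' @param training Labelled feature table as for [train_model()].
#' @param k Number of folds.
#' @param config A [model_config()].
#' @param seed Integer seed for fold assignment.
#' @return An object of class `dsrna_cv`: `fold_accuracy` (length `k`),
#'   `roc_auc`, `auprc`, and the pooled out-of-fold table `oof`.
#' @export
cross_validate <- function(training, k = 20L, config = model_config(),
                           seed = 1L) {
  n <- nrow(training)
  if (k > n) abort(paste0("k = ", k, " exceeds ", n, " rows"))
  set.seed(seed)
  fold <- integer(n)
  for (cls in unique(training$label)) {
    idx <- sample(which(training$label == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  oof <- tibble(row = seq_len(n), label = training$label, fold = fold,
                prob = NA_real_)
  acc <- numeric(k)
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    cfg <- config
    cfg$seed <- config$seed + f
    model <- train_model(training[-test_idx, ], cfg)
    p <- predict_proba(model, training[test_idx, ])
    oof$prob[test_idx] <- p
    acc[f] <- mean(as.integer(p > 0.5) == training$label[test_idx])
  }
  roc_auc <- as.numeric(pROC::auc(pROC::roc(
    response = oof$label, predictor = oof$prob,
    levels = c(0, 1), direction = "<", quiet = TRUE
  )))
  structure(
    list(fold_accuracy = acc, roc_auc = roc_auc,
         auprc = average_precision(oof$label, oof$prob),
         oof = oof, k = k, seed = seed),
    class = "dsrna_cv"
  )
}

#' Permutation-based feature contributions
#'
#' The coefficient of determination (R-squared) between predicted
#' positive-class probability and the 0/1 label is computed on held-out
#' rows; each feature column is then permuted (others fixed) and the
#' R-squared recomputed. The contribution score of a feature is the mean
#' decrease across repeats.
#'
#' @param model A `dsrna_model`.
#' @param heldout Labelled feature table disjoint from the training rows.
#' @param repeats Permutations per feature.
#' @param seed Integer seed.
#' @return An object of class `dsrna_importance`: `baseline_r2` and a
#'   `scores` tibble (`feature`, `contribution`) sorted by contribution.
#' @export
permutation_importance <- function(model, heldout, repeats = 5L, seed = 1L) {
  if (nrow(heldout) == 0L) abort("held-out set is empty")
  y <- heldout$label
  r2 <- function(p) 1 - sum((y - p)^2) / sum((y - mean(y))^2)
  baseline <- r2(predict_proba(model, heldout))
  set.seed(seed)
  scores <- map_dbl(model$feature_names, function(f) {
    drops <- map_dbl(seq_len(repeats), function(r) {
      perm <- heldout
      perm[[f]] <- sample(perm[[f]])
      baseline - r2(predict_proba(model, perm))
    })
    mean(drops)
  })
  structure(
    list(baseline_r2 = baseline,
         scores = arrange(tibble(feature = model$feature_names,
                                 contribution = scores),
                          desc(.data$contribution)),
         repeats = repeats, seed = seed),
    class = "dsrna_importance"
  )
}

#' Stratified train/held-out split of a labelled feature table
#'
#' @param training Labelled feature table.
#' @param heldout_fraction Fraction of rows held out, per class.
#' @param seed Integer seed.
#' @return A list with `train` and `heldout` tibbles.
#' @export
split_heldout <- function(training, heldout_fraction = 0.2, seed = 1L) {
  set.seed(seed)
  hold <- unlist(lapply(unique(training$label), function(cls) {
    idx <- which(training$label == cls)
    sample(idx, max(1L, round(heldout_fraction * length(idx))))
  }))
  list(train = training[-hold, ], heldout = training[hold, ])
}
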