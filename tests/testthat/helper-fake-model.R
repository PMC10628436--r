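# a controllable stand-in classifier: emits fixed probabilities keyed by the
# value planted in the skip_ratio column (coordinates are what the tests
# control; the forest interface is honoured via an S3 predict method)
fake_model <- function(prob_by_key) {
  forest <- structure(list(prob_by_key = prob_by_key),
                      class = "fake_forest")
  structure(list(forest = forest, feature_names = feature_names(),
                 config = model_config(), mtry = 7L, n_train = 0L,
                 fingerprint = "fake"),
            class = "dsrna_model")
}

predict.fake_forest <- function(object, newdata, type = "prob", ...) {
  p <- unname(object$prob_by_key[as.character(newdata$skip_ratio)])
  matrix(c(1 - p, p), ncol = 2, dimnames = list(NULL, c("0", "1")))
}
registerS3method("predict", "fake_forest", predict.fake_forest)

# feature rows for fake scoring: only coordinates matter
fake_candidates <- function(starts, chrom = "sim1", width = 2500) {
  df <- tibble::as_tibble(setNames(
    as.data.frame(matrix(0, nrow = length(starts),
                         ncol = length(feature_names()))),
    feature_names()
  ))
  df$chrom <- chrom
  df$start <- starts
  df$end <- starts + width
  df$skip_ratio <- starts   # lookup key for the stand-in model
  df
}
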