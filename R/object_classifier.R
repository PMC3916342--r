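#' Train the object-level Random Forest
#'
#' Second-stage classifier separating true synapses from false candidates
#' using the 29 object features; 100 trees grown to purity by default.
#'
#' @param features numeric matrix or data frame, one row per candidate,
#'   columns the object features (see [compute_object_features()]).
#' @param labels logical or 0/1 vector (`TRUE` = true synapse), or a factor
#'   with levels `not_synapse`/`true_synapse`; both classes must be present.
#' @param n_trees number of trees (default 100).
#' @param seed integer seed; training is deterministic given the seed.
#' @return Object of class `object_classifier`.
#' @export
train_object_classifier <- function(features, labels, n_trees = 100,
                                    seed = 1) {
  xmat <- as.matrix(features)
  if (is.factor(labels)) labels <- labels == "true_synapse"
  labels <- as.logical(labels)
  if (length(labels) != nrow(xmat))
    stop("`labels` must have one entry per feature row")
  if (length(unique(labels)) < 2)
    stop("both classes (true and false candidates) must be present")
  yfac <- factor(ifelse(labels, "true_synapse", "not_synapse"),
                 levels = c("not_synapse", "true_synapse"))
  forest <- ranger::ranger(
    x = xmat, y = yfac, num.trees = n_trees, probability = TRUE,
    min.node.size = 1, mtry = max(1L, round(sqrt(ncol(xmat)))),
    seed = seed, num.threads = 1, verbose = FALSE)
  structure(list(forest = forest, n_trees = n_trees,
                 feature_names = colnames(xmat)),
            class = "object_classifier")
}

#' @export
print.object_classifier <- function(x, ...) {
  cat(sprintf("<object_classifier> %d trees, %d features\n",
              x$n_trees, length(x$feature_names)))
  invisible(x)
}

#' Score and threshold synapse candidates
#'
#' Scores each candidate with the object-level forest and accepts those
#' with `score >= threshold`. Raising the threshold never enlarges the
#' accepted set (monotone precision/recall trade-off).
#'
#' @param classifier an [train_object_classifier()] result.
#' @param features feature matrix with the training columns.
#' @param threshold acceptance threshold in `[0, 1]` (default 0.5).
#' @return Data frame with columns `candidate_id`, `score`, `accepted`.
#' @export
classify_candidates <- function(classifier, features, threshold = 0.5) {
  stopifnot(inherits(classifier, "object_classifier"))
  if (!(threshold >= 0 && threshold <= 1))
    stop("`threshold` must lie in [0, 1]")
  xmat <- as.matrix(features)
  if (!is.null(classifier$feature_names)) {
    if (is.null(colnames(xmat)) ||
        !identical(colnames(xmat), classifier$feature_names))
      stop("feature columns do not match the classifier's training columns")
  }
  pr <- predict(classifier$forest, data = xmat, num.threads = 1,
                verbose = FALSE)$predictions
  score <- pr[, "true_synapse"]
  data.frame(candidate_id = seq_len(nrow(xmat)), score = score,
             accepted = score >= threshold)
}
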