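PIXEL_CLASSES <- c("synapse", "membrane", "other")

#' Sparse voxel labels
#'
#' Sparse per-voxel class annotations used to train the pixel classifier.
#' Internally voxel coordinates are 1-based R indices in `(z, y, x)` order;
#' on-disk CSV files use 0-based coordinates (see [read_sparse_labels()]).
#'
#' @param z,y,x integer voxel coordinates (1-based).
#' @param class character or factor with levels among
#'   `"synapse"`, `"membrane"`, `"other"`.
#' @param volume_shape optional `(nz, ny, nx)` used to validate bounds.
#' @return A `data.frame` of class `sparse_labels`.
#' @export
sparse_labels <- function(z, y, x, class, volume_shape = NULL) {
  df <- data.frame(z = as.integer(z), y = as.integer(y), x = as.integer(x),
                   class = as.character(class), stringsAsFactors = FALSE)
  if (!all(df$class %in% PIXEL_CLASSES))
    stop("classes must be among: ", paste(PIXEL_CLASSES, collapse = ", "))
  if (!is.null(volume_shape)) {
    ok <- df$z >= 1 & df$z <= volume_shape[1] &
      df$y >= 1 & df$y <= volume_shape[2] &
      df$x >= 1 & df$x <= volume_shape[3]
    if (!all(ok)) stop("label coordinates out of volume bounds")
  }
  key <- paste(df$z, df$y, df$x)
  if (anyDuplicated(key)) {
    agg <- tapply(df$class, key, function(cl) length(unique(cl)))
    if (any(agg > 1))
      stop("duplicate label coordinates with conflicting classes")
    df <- df[!duplicated(key), ]
  }
  class(df) <- c("sparse_labels", "data.frame")
  df
}

#' Read sparse labels from CSV
#'
#' Expects columns `z, y, x, class` with 0-based voxel coordinates in
#' `(z, y, x)` order (converted to 1-based on read).
#'
#' @param path CSV file path.
#' @param volume_shape optional bounds check, `(nz, ny, nx)`.
#' @return A [sparse_labels()] data frame.
#' @export
read_sparse_labels <- function(path, volume_shape = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sparse_labels(df$z + 1L, df$y + 1L, df$x + 1L, df$class, volume_shape)
}

#' Train the 3-class pixel Random Forest
#'
#' Learns synapse / membrane / other voxel classes from sparse labels on a
#' feature stack. Trees are grown to purity with `sqrt(n_channels)` features
#' per split; the out-of-bag misclassification rate is recorded.
#'
#' @param fs a [compute_feature_stack()] result.
#' @param labels a [sparse_labels()] data frame, with at least one label per
#'   class; coordinates refer to the grid of `fs`.
#' @param n_trees number of trees (default 100).
#' @param seed integer seed; training is deterministic given the seed.
#' @return An object of class `pixel_classifier` with elements `forest`,
#'   `n_trees`, `channel_names`, `oob_error`, `classes`.
#' @export
train_pixel_classifier <- function(fs, labels, n_trees = 100, seed = 1) {
  stopifnot(inherits(fs, "feature_stack"))
  if (!inherits(labels, "sparse_labels"))
    labels <- sparse_labels(labels$z, labels$y, labels$x, labels$class)
  d <- dim(fs$data)[2:4]
  if (any(labels$z < 1 | labels$z > d[1] | labels$y < 1 | labels$y > d[2] |
          labels$x < 1 | labels$x > d[3]))
    stop("label coordinates out of feature-stack bounds")
  missing <- setdiff(PIXEL_CLASSES, unique(labels$class))
  if (length(missing) > 0)
    stop("class with zero labels: ", paste(missing, collapse = ", "))
  if (n_trees < 1) stop("`n_trees` must be >= 1")

  vox <- labels$z + d[1] * (labels$y - 1L + d[2] * (labels$x - 1L))
  xmat <- feature_matrix(fs, vox)
  colnames(xmat) <- fs$channel_names
  yfac <- factor(labels$class, levels = PIXEL_CLASSES)
  forest <- ranger::ranger(
    x = xmat, y = yfac, num.trees = n_trees, probability = TRUE,
    min.node.size = 1, mtry = max(1L, round(sqrt(ncol(xmat)))),
    seed = seed, num.threads = 1, verbose = FALSE)
  oob_prob <- forest$predictions
  pred <- PIXEL_CLASSES[max.col(oob_prob, ties.method = "first")]
  oob_error <- mean(pred != as.character(yfac), na.rm = TRUE)
  structure(list(forest = forest, n_trees = n_trees,
                 channel_names = fs$channel_names,
                 oob_error = oob_error, classes = PIXEL_CLASSES,
                 flat = flatten_probability_forest(forest)),
            class = "pixel_classifier")
}

# export ranger trees into flat arrays for fast voxelwise evaluation;
# traversal semantics identical to predict.ranger (validated by test)
flatten_probability_forest <- function(forest) {
  nt <- forest$num.trees
  infos <- lapply(seq_len(nt), function(k) ranger::treeInfo(forest, k))
  predcols <- paste0("pred.", forest$forest$levels)
  sizes <- vapply(infos, nrow, 1L)
  offsets <- cumsum(c(0L, sizes[-nt]))
  all <- do.call(rbind, infos)
  leafprob <- as.matrix(all[, predcols])
  leafprob[is.na(leafprob)] <- 0
  list(offsets = as.integer(offsets),
       left = as.integer(ifelse(is.na(all$leftChild), -1L, all$leftChild)),
       right = as.integer(ifelse(is.na(all$rightChild), -1L, all$rightChild)),
       splitvar = as.integer(ifelse(is.na(all$splitvarID), 0L,
                                    all$splitvarID)),
       splitval = as.numeric(ifelse(is.na(all$splitval), 0, all$splitval)),
       leafprob = leafprob,
       levels = forest$forest$levels)
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf("<pixel_classifier> %d trees, %d channels, OOB error %.3f\n",
              x$n_trees, length(x$channel_names), x$oob_error))
  invisible(x)
}

#' Predict per-voxel class probabilities
#'
#' Applies the pixel classifier to every voxel of a feature stack and
#' returns a 3-class probability map in the fixed class order
#' (synapse, membrane, other). Prediction is chunked to bound memory.
#'
#' @param classifier a [train_pixel_classifier()] result.
#' @param fs a [compute_feature_stack()] result with matching channels.
#' @param chunk_size voxels per prediction chunk.
#' @return A [probability_map()] on the grid of `fs`.
#' @export
predict_probabilities <- function(classifier, fs, chunk_size = 500000L) {
  stopifnot(inherits(classifier, "pixel_classifier"),
            inherits(fs, "feature_stack"))
  if (!identical(classifier$channel_names, fs$channel_names))
    stop("feature channels do not match the classifier's training channels")
  d <- dim(fs$data)
  n <- prod(d[2:4])
  probs <- matrix(0, nrow = n, ncol = 3)
  # chunk along x (the slowest axis) so rows stay in voxel linear order
  # without copying the whole stack
  plane <- prod(d[2:3])
  xs_per_chunk <- max(1L, as.integer(chunk_size %/% plane))
  x0 <- 1L
  while (x0 <= d[4]) {
    x1 <- min(d[4], x0 + xs_per_chunk - 1L)
    sub <- fs$data[, , , x0:x1, drop = FALSE]
    xmat <- t(matrix(sub, nrow = d[1]))
    rows <- ((x0 - 1L) * plane + 1L):(x1 * plane)
    if (!is.null(classifier$flat)) {
      fl <- classifier$flat
      pr <- predict_flat_forest_cpp(xmat, fl$offsets, fl$left, fl$right,
                                    fl$splitvar, fl$splitval, fl$leafprob)
      colnames(pr) <- fl$levels
    } else {
      colnames(xmat) <- fs$channel_names
      pr <- predict(classifier$forest, data = xmat, num.threads = 1,
                    verbose = FALSE)$predictions
    }
    probs[rows, ] <- pr[, PIXEL_CLASSES, drop = FALSE]
    x0 <- x1 + 1L
  }
  probs <- probs / rowSums(probs)
  pm <- array(0, c(3L, d[2:4]))
  for (j in 1:3) pm[j, , , ] <- probs[, j]
  probability_map(pm, PIXEL_CLASSES, fs$voxel_size)
}
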