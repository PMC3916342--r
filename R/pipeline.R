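#' Pipeline configuration
#'
#' All tunable parameters of the detection pipeline, serializable to YAML.
#' Defaults follow the reference ssTEM setting: upsample the stack by 2
#' along z before 3D filtering, threshold the synapse probability at 0.5,
#' keep components of 100 to 1e6 native-grid voxels, enlarge candidate
#' boxes by a 500 nm halo, and accept candidates scoring at least 0.5 in
#' the object stage.
#'
#' @param voxel_size voxel extent in nm `(z, y, x)`.
#' @param upsample_factor integer z-upsampling factor before filtering.
#' @param features a [feature_config()].
#' @param n_trees_pixel,n_trees_object forest sizes for the two stages.
#' @param detection_threshold synapse-probability threshold.
#' @param size_min,size_max inclusive component voxel-count bounds
#'   (native grid).
#' @param halo_nm bounding-box enlargement and blockwise halo in nm.
#' @param beta Ising pairwise constant; `NULL` means calibrate on the
#'   built-in probability phantom at first use (see [default_beta()]).
#' @param object_threshold object-stage acceptance threshold.
#' @param neighborhood object-neighborhood radii in voxels `(x, y, z)`.
#' @param matching_tolerance_nm evaluation matching tolerance.
#' @param connectivity detection component connectivity (6, 18 or 26).
#' @param block_shape optional lateral block shape `(y, x)` for blockwise
#'   processing.
#' @param seed top-level seed from which all stage seeds derive.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(voxel_size = c(45, 4.5, 4.5),
                            upsample_factor = 2,
                            features = feature_config(),
                            n_trees_pixel = 100,
                            n_trees_object = 100,
                            detection_threshold = 0.5,
                            size_min = 100,
                            size_max = 1000000,
                            halo_nm = 500,
                            beta = NULL,
                            object_threshold = 0.5,
                            neighborhood = c(30, 30, 1),
                            matching_tolerance_nm = 250,
                            connectivity = 26,
                            block_shape = NULL,
                            seed = 1) {
  stopifnot(upsample_factor >= 1,
            detection_threshold > 0, detection_threshold < 1,
            size_min <= size_max, halo_nm >= 0,
            object_threshold >= 0, object_threshold <= 1,
            connectivity %in% c(6, 18, 26))
  if (!is.null(beta) && beta < 0) stop("`beta` must be nonnegative")
  cfg <- as.list(environment())
  cfg$version <- 1L
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param cfg a [pipeline_config()].
#' @param path YAML file path.
#' @return `path` invisibly; `read_pipeline_config()` returns the config.
#' @export
write_pipeline_config <- function(cfg, path) {
  lst <- unclass(cfg)
  lst$features <- unclass(lst$features)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lst <- yaml::read_yaml(path)
  fc <- do.call(feature_config, lst$features)
  lst$features <- NULL
  lst$version <- NULL
  do.call(pipeline_config, c(lst, list(features = fc)))
}

#' Calibrated default for the Ising pairwise constant
#'
#' Runs [calibrate_beta()] against a set of built-in probability phantoms
#' over a geometric beta grid, mirroring calibration against a handful of
#' manually segmented synapses. The calibration phantoms carry realistic
#' probability noise (object voxels dip below the 0.5 threshold and
#' background speckle rises above it), so a positive smoothing constant is
#' genuinely needed to recover the reference masks.
#'
#' @param seed phantom seed.
#' @param grid candidate beta values.
#' @param n_phantoms number of calibration phantoms.
#' @return The calibrated beta.
#' @export
default_beta <- function(seed = 1,
                         grid = c(0, 0.05, 0.1, 0.2, 0.4, 0.8, 1.6),
                         n_phantoms = 4) {
  crops <- list()
  masks <- list()
  for (i in seq_len(n_phantoms)) {
    ph <- generate_probability_phantom(shape = c(8, 48, 48), n_objects = 2,
                                       high = 0.72, noise_sd = 0.22,
                                       seed = seed + i)
    crops[[i]] <- ph$prob$data[1, , , ]
    dim(crops[[i]]) <- dim(ph$prob$data)[2:4]
    m <- ph$truth[[1]]
    for (t2 in ph$truth[-1]) m <- m | t2
    masks[[i]] <- m
  }
  calibrate_beta(crops, masks, grid)
}

# crop a 3D array by a 0-based half-open box (z0,y0,x0,z1,y1,x1)
crop_box <- function(a, box) {
  a[(box[1] + 1):box[4], (box[2] + 1):box[5], (box[3] + 1):box[6],
    drop = FALSE]
}

# synapse-class plane of a probability map as a plain 3D array
synapse_plane <- function(p) {
  ci <- match("synapse", p$class_names)
  out <- p$data[ci, , , ]
  dim(out) <- dim(p$data)[2:4]
  out
}

#' Run the full synapse-detection pipeline
#'
#' Executes upsample, 3D features, pixel probabilities, downsample to the
#' native slice grid, detection (threshold, connected components, size
#' filter, 500 nm box enlargement), per-box graph-cut segmentation, object
#' features and object classification. Either stage classifier may be
#' supplied pre-trained, or trained in-run from labels.
#'
#' @param volume an [anisotropic_volume()] on the native grid.
#' @param config a [pipeline_config()].
#' @param pixel_classifier optional pre-trained [train_pixel_classifier()]
#'   result; if `NULL`, `pixel_labels` must be given.
#' @param pixel_labels optional [sparse_labels()] on the native grid used
#'   to train the pixel stage in-run.
#' @param object_classifier optional pre-trained
#'   [train_object_classifier()] result; if `NULL`, `object_labeler` must
#'   be given.
#' @param object_labeler optional function `(candidates) -> logical` that
#'   labels the segmented candidates so the object stage can be trained
#'   in-run (e.g. from phantom truth).
#' @param object_negatives,object_positives optional lists of
#'   candidate-like objects (each with `mask` and `box`) appended to object
#'   training as negative / positive examples — annotated structures that
#'   supplement the segmented candidates (see [distractor_objects()]).
#' @return Object of class `synapse_detection`: candidate list (each with
#'   `mask`, `box`, `component_id`, `centroid`, `voxel_count`,
#'   `boundary`), `scores` data frame, accepted candidate ids, the native
#'   probability map, detection table, trained classifiers, config, and a
#'   per-stage log of timings and counts.
#' @export
run_pipeline <- function(volume, config = pipeline_config(),
                         pixel_classifier = NULL, pixel_labels = NULL,
                         object_classifier = NULL, object_labeler = NULL,
                         object_negatives = NULL, object_positives = NULL) {
  if (is.null(object_classifier) && is.null(object_labeler))
    stop("configuration error: no object classifier and no object labels")
  det <- detect_candidates(volume, config, pixel_classifier, pixel_labels)
  log <- det$log
  tick <- function(stage, t0, count) {
    log[[stage]] <<- list(seconds = as.numeric(Sys.time()) - t0,
                          count = count)
  }
  candidates <- det$candidates
  feats <- det$features
  pixel_classifier <- det$pixel_classifier

  if (is.null(object_classifier)) {
    t0 <- as.numeric(Sys.time())
    labels <- object_labeler(candidates)
    train_feats <- feats
    for (extra in list(list(objs = object_positives, lab = TRUE),
                       list(objs = object_negatives, lab = FALSE))) {
      if (is.null(extra$objs) || length(extra$objs) == 0) next
      train_feats <- rbind(train_feats,
                           candidate_features(volume, extra$objs,
                                              config$neighborhood))
      labels <- c(labels, rep(extra$lab, length(extra$objs)))
    }
    object_classifier <- train_object_classifier(
      train_feats, labels, n_trees = config$n_trees_object,
      seed = config$seed + 1)
    tick("train_object", t0, length(labels))
  }

  t0 <- as.numeric(Sys.time())
  scores <- if (length(candidates) > 0) {
    classify_candidates(object_classifier, feats, config$object_threshold)
  } else {
    data.frame(candidate_id = integer(0), score = numeric(0),
               accepted = logical(0))
  }
  scores$boundary <- vapply(candidates, `[[`, logical(1), "boundary")
  tick("classify", t0, sum(scores$accepted))

  structure(list(
    candidates = candidates,
    scores = scores,
    accepted = scores$candidate_id[scores$accepted],
    prob_map = det$prob_map,
    detections = det$detections,
    features = feats,
    pixel_classifier = pixel_classifier,
    object_classifier = object_classifier,
    beta = det$beta,
    config = config,
    log = log), class = "synapse_detection")
}

#' Run the pipeline up to segmented candidates
#'
#' The first stage of [run_pipeline()]: upsampling, 3D features, pixel
#' probabilities on the native slice grid, detection, per-box graph-cut
#' segmentation and object features — everything except the object-level
#' classification. Useful for harvesting candidate objects to label.
#'
#' @inheritParams run_pipeline
#' @return List of class `synapse_candidates` with `candidates`,
#'   `features`, `prob_map`, `detections`, `pixel_classifier`, `beta`,
#'   `config` and a per-stage `log`.
#' @export
detect_candidates <- function(volume, config = pipeline_config(),
                              pixel_classifier = NULL, pixel_labels = NULL) {
  stopifnot(inherits(volume, "aniso_volume"),
            inherits(config, "pipeline_config"))
  if (is.null(pixel_classifier) && is.null(pixel_labels))
    stop("configuration error: no pixel classifier and no training labels")
  log <- list()
  tick <- function(stage, t0, count) {
    log[[stage]] <<- list(seconds = as.numeric(Sys.time()) - t0,
                          count = count)
  }

  beta <- config$beta
  if (is.null(beta)) beta <- default_beta(seed = config$seed)

  f <- config$upsample_factor
  t0 <- as.numeric(Sys.time())
  up <- upsample_z(volume, f)
  tick("upsample", t0, dim(up$data)[1])

  t0 <- as.numeric(Sys.time())
  # only the original slices survive the z-downsampling of the predictions,
  # so only they are stored and classified (identical output, half the work)
  keep <- seq(1L, dim(up$data)[1], by = f)
  fs <- compute_feature_stack(up, config$features, z_keep = keep)
  fs$voxel_size <- volume$voxel_size
  rm(up); gc(FALSE)
  tick("features", t0, length(fs$channel_names))

  if (is.null(pixel_classifier)) {
    t0 <- as.numeric(Sys.time())
    pixel_classifier <- train_pixel_classifier(
      fs, pixel_labels, n_trees = config$n_trees_pixel, seed = config$seed)
    tick("train_pixel", t0, nrow(pixel_labels))
  }

  t0 <- as.numeric(Sys.time())
  prob <- predict_probabilities(pixel_classifier, fs)
  rm(fs); gc(FALSE)
  tick("predict", t0, prod(dim(prob$data)[2:4]))

  t0 <- as.numeric(Sys.time())
  psyn <- synapse_plane(prob)
  mask <- psyn > config$detection_threshold
  cc <- connected_components(mask, config$connectivity)
  dets <- filter_components_by_size(cc$table, config$size_min,
                                    config$size_max)
  dets <- enlarge_bounding_boxes(dets, config$halo_nm, volume$voxel_size,
                                 dim(volume$data))
  tick("detect", t0, nrow(dets))

  t0 <- as.numeric(Sys.time())
  candidates <- segment_candidates(psyn, cc$labels, dets, beta)
  candidates <- merge_candidates(candidates, dim(volume$data))
  tick("segment", t0, length(candidates))

  t0 <- as.numeric(Sys.time())
  feats <- candidate_features(volume, candidates, config$neighborhood)
  tick("object_features", t0, nrow(feats))

  structure(list(
    candidates = candidates, features = feats, prob_map = prob,
    detections = dets, pixel_classifier = pixel_classifier,
    beta = beta, config = config, log = log),
    class = "synapse_candidates")
}

#' Train both pipeline stages on phantom volumes
#'
#' Phantom analogue of the full training protocol: the pixel classifier is
#' learned from sparse labels on the first phantom; the object classifier
#' is learned from segmented candidates pooled over several phantom blocks
#' (labeled against truth) plus each block's annotated synapse and
#' distractor masks as additional positives/negatives. Using multiple
#' blocks for the object stage mirrors the original workflow, where the
#' object labels came from extra training blocks.
#'
#' @param config a [pipeline_config()].
#' @param phantom_seeds phantom seeds; the first block also trains the
#'   pixel stage.
#' @param n_labels_per_class sparse pixel labels per class.
#' @param label_seed seed for label sampling.
#' @param spec_fn function mapping a seed to a [phantom_spec()].
#' @return List with `pixel_classifier`, `object_classifier`,
#'   `n_object_examples`, `beta`.
#' @export
train_phantom_classifiers <- function(config = pipeline_config(),
                                      phantom_seeds = c(2, 3, 4),
                                      n_labels_per_class = 400,
                                      label_seed = 11,
                                      spec_fn = function(seed)
                                        phantom_spec(seed = seed)) {
  beta <- config$beta
  if (is.null(beta)) beta <- default_beta(seed = config$seed)
  config$beta <- beta
  pixel_classifier <- NULL
  feats <- NULL
  labs <- logical(0)
  for (seed in phantom_seeds) {
    ph <- generate_phantom(spec_fn(seed))
    shape <- dim(ph$volume$data)
    if (is.null(pixel_classifier)) {
      labels <- sample_phantom_labels(ph, n_labels_per_class, label_seed)
      det <- detect_candidates(ph$volume, config, pixel_labels = labels)
      pixel_classifier <- det$pixel_classifier
    } else {
      det <- detect_candidates(ph$volume, config,
                               pixel_classifier = pixel_classifier)
    }
    dobj <- distractor_objects(ph$truth, shape)
    sobj <- distractor_objects(ph$truth, shape, "synapses")
    feats <- rbind(det$features,
                   candidate_features(ph$volume, c(dobj, sobj),
                                      config$neighborhood),
                   feats)
    labs <- c(label_candidates_by_truth(det$candidates, ph$truth, shape),
              rep(FALSE, length(dobj)), rep(TRUE, length(sobj)), labs)
    rm(det, ph); gc(FALSE)
  }
  object_classifier <- train_object_classifier(
    feats, labs, n_trees = config$n_trees_object, seed = config$seed + 1)
  list(pixel_classifier = pixel_classifier,
       object_classifier = object_classifier,
       n_object_examples = length(labs),
       beta = beta)
}

# graph-cut segmentation of every detected component inside its enlarged
# box. The candidate is the part of the graph-cut output connected to its
# seeding component (an enlarged box may also contain unrelated objects);
# candidates with no overlap are dropped.
segment_candidates <- function(psyn, cc_labels, dets, beta) {
  candidates <- list()
  d <- dim(psyn)
  for (i in seq_len(nrow(dets))) {
    box <- as.integer(dets[i, c("ez0", "ey0", "ex0", "ez1", "ey1", "ex1")])
    crop <- crop_box(psyn, box)
    seg <- segment_graphcut(crop, beta)
    if (!any(seg)) next
    comp_crop <- crop_box(cc_labels, box) == dets$component_id[i]
    if (!any(seg & comp_crop)) next
    seg_cc <- label_cc3d_cpp(seg, dim(seg), 26L)
    seeded <- setdiff(unique(seg_cc[comp_crop]), 0L)
    seg <- array(seg_cc %in% seeded, dim(seg))
    idx <- which(seg, arr.ind = TRUE)
    centroid <- c(mean(idx[, 1]) + box[1], mean(idx[, 2]) + box[2],
                  mean(idx[, 3]) + box[3])
    zmin <- min(idx[, 1]) + box[1]; zmax <- max(idx[, 1]) + box[1]
    ymin <- min(idx[, 2]) + box[2]; ymax <- max(idx[, 2]) + box[2]
    xmin <- min(idx[, 3]) + box[3]; xmax <- max(idx[, 3]) + box[3]
    boundary <- zmin == 1 || ymin == 1 || xmin == 1 ||
      zmax == d[1] || ymax == d[2] || xmax == d[3]
    # store the mask as a tight crop around the segmented object
    tight <- as.integer(c(zmin - 1, ymin - 1, xmin - 1, zmax, ymax, xmax))
    seg <- seg[(zmin - box[1]):(zmax - box[1]),
               (ymin - box[2]):(ymax - box[2]),
               (xmin - box[3]):(xmax - box[3]), drop = FALSE]
    candidates[[length(candidates) + 1]] <- list(
      mask = seg, box = tight,
      component_id = dets$component_id[i],
      centroid = centroid,
      voxel_count = nrow(idx),
      boundary = boundary)
  }
  candidates
}

# merge candidates whose segmented masks share voxels: fragments of one
# object detected as several components segment to (parts of) the same
# region, and must be reported once. Greedy union over shared voxels; the
# merged mask is the union, the box its bounding box.
merge_candidates <- function(candidates, volume_shape) {
  if (length(candidates) <= 1) return(candidates)
  nzy <- volume_shape[1] * volume_shape[2]
  vox <- lapply(candidates, function(cand) {
    idx <- which(cand$mask, arr.ind = TRUE)
    as.integer((idx[, 1] + cand$box[1]) +
                 volume_shape[1] * ((idx[, 2] + cand$box[2] - 1) +
                                      volume_shape[2] *
                                      (idx[, 3] + cand$box[3] - 1)))
  })
  n <- length(candidates)
  group <- seq_len(n)
  find <- function(i) { while (group[i] != i) i <- group[i]; i }
  owner <- integer(prod(volume_shape))
  for (i in seq_len(n)) {
    hits <- setdiff(unique(owner[vox[[i]]]), 0L)
    for (j in hits) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) group[max(ri, rj)] <- min(ri, rj)
    }
    owner[vox[[i]]] <- i
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- list()
  for (r in unique(roots)) {
    members <- which(roots == r)
    if (length(members) == 1) {
      out[[length(out) + 1]] <- candidates[[members]]
      next
    }
    allvox <- unique(unlist(vox[members]))
    coords <- cbind(((allvox - 1) %% volume_shape[1]) + 1,
                    (((allvox - 1) %/% volume_shape[1]) %% volume_shape[2]) + 1,
                    ((allvox - 1) %/% nzy) + 1)
    box <- as.integer(c(min(coords[, 1]) - 1, min(coords[, 2]) - 1,
                        min(coords[, 3]) - 1,
                        max(coords[, 1]), max(coords[, 2]), max(coords[, 3])))
    mask <- array(FALSE, box[4:6] - box[1:3])
    mask[cbind(coords[, 1] - box[1], coords[, 2] - box[2],
               coords[, 3] - box[3])] <- TRUE
    out[[length(out) + 1]] <- list(
      mask = mask, box = box,
      component_id = min(vapply(candidates[members], `[[`, integer(1),
                                "component_id")),
      centroid = colMeans(coords),
      voxel_count = nrow(coords),
      boundary = any(vapply(candidates[members], `[[`, logical(1),
                            "boundary")))
  }
  out
}

# object feature matrix for a candidate list
candidate_features <- function(volume, candidates, neighborhood) {
  if (length(candidates) == 0) {
    m <- matrix(numeric(0), 0, length(OBJECT_FEATURE_NAMES))
    colnames(m) <- OBJECT_FEATURE_NAMES
    return(m)
  }
  rows <- lapply(candidates, function(cand)
    compute_object_features(volume, cand$mask, cand$box, neighborhood))
  m <- do.call(rbind, rows)
  colnames(m) <- OBJECT_FEATURE_NAMES
  m
}

#' @export
print.synapse_detection <- function(x, ...) {
  cat(sprintf(
    "<synapse_detection> %d detections -> %d candidates -> %d accepted\n",
    nrow(x$detections), length(x$candidates), length(x$accepted)))
  invisible(x)
}

#' @export
summary.synapse_detection <- function(object, ...) {
  cat("Pipeline stages:\n")
  for (nm in names(object$log))
    cat(sprintf("  %-16s %8.2fs  (count %s)\n", nm,
                object$log[[nm]]$seconds, object$log[[nm]]$count))
  print(object)
  invisible(object)
}

#' Centroids of accepted candidates
#'
#' @param result a [run_pipeline()] or [blockwise_process()] result.
#' @return Matrix with columns `z, y, x` (1-based voxel coordinates), one
#'   row per accepted candidate, ordered by z, then y, then x.
#' @export
accepted_centroids <- function(result) {
  ids <- result$accepted
  if (length(ids) == 0)
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("z", "y", "x"))))
  cent <- t(vapply(result$candidates[ids], `[[`, numeric(3), "centroid"))
  colnames(cent) <- c("z", "y", "x")
  cent[order(cent[, 1], cent[, 2], cent[, 3]), , drop = FALSE]
}

#' Export detection results
#'
#' Writes the candidate scores as CSV, the accepted candidates' centroids
#' as a 0-based `(z, y, x)` point list, and a label volume (candidate id
#' per voxel, 16-bit multi-page TIFF) next to the given prefix.
#'
#' @param result a [run_pipeline()] or [blockwise_process()] result.
#' @param prefix output path prefix; files get suffixes
#'   `_scores.csv`, `_centroids.csv`, `_labels.tif`.
#' @param volume_shape `(nz, ny, nx)`; taken from the probability map when
#'   omitted.
#' @return Invisibly, the written paths.
#' @export
write_detections <- function(result, prefix, volume_shape = NULL) {
  if (is.null(volume_shape)) volume_shape <- dim(result$prob_map$data)[2:4]
  scores_path <- paste0(prefix, "_scores.csv")
  utils::write.csv(result$scores, scores_path, row.names = FALSE)

  cent <- accepted_centroids(result)
  cent_path <- paste0(prefix, "_centroids.csv")
  con <- file(cent_path, "w")
  writeLines("# 0-based voxel coordinates, axis order z,y,x", con)
  utils::write.csv(data.frame(z = cent[, 1] - 1, y = cent[, 2] - 1,
                              x = cent[, 3] - 1), con, row.names = FALSE)
  close(con)

  labels <- array(0, volume_shape)
  for (id in result$accepted) {
    cand <- result$candidates[[id]]
    idx <- which(cand$mask, arr.ind = TRUE)
    labels[cbind(idx[, 1] + cand$box[1], idx[, 2] + cand$box[2],
                 idx[, 3] + cand$box[3])] <- id
  }
  labels_path <- paste0(prefix, "_labels.tif")
  write_volume(anisotropic_volume(labels, result$config$voxel_size),
               labels_path, bits = 16)
  invisible(c(scores_path, cent_path, labels_path))
}

#' Blockwise pipeline execution with halos
#'
#' Processes the volume in a lateral block grid, adding a halo (default
#' 500 nm per side, from the config) around each block so every owned voxel
#' sees full filter context. Phase 1 computes per-block probability maps
#' and stitches the owned regions; phase 2 detects per block in the
#' block+halo crop, assigns each component to the block containing its
#' centroid (deduplicating objects that straddle block boundaries),
#' segments each owned candidate from the stitched map, and classifies.
#' For objects whose reach stays under the halo, output equals the
#' whole-volume run.
#'
#' @param volume an [anisotropic_volume()].
#' @param config a [pipeline_config()].
#' @param pixel_classifier,object_classifier pre-trained stage classifiers
#'   (blockwise mode does not train).
#' @param block_shape lateral block shape `(y, x)` in voxels; defaults to
#'   `config$block_shape`.
#' @return A `synapse_detection` object (candidates from all blocks).
#' @export
blockwise_process <- function(volume, config, pixel_classifier,
                              object_classifier, block_shape = NULL) {
  stopifnot(inherits(volume, "aniso_volume"),
            inherits(config, "pipeline_config"))
  if (is.null(block_shape)) block_shape <- config$block_shape
  if (is.null(block_shape)) stop("no block shape configured")
  d <- dim(volume$data)
  block_shape <- as.integer(block_shape)
  if (any(block_shape < 1) || any(block_shape > d[2:3]))
    stop("block shape must fit in the volume")
  halo <- as.integer(ceiling(config$halo_nm / volume$voxel_size[2:3]))
  if (any(halo > block_shape))
    stop("halo larger than block")
  beta <- config$beta
  if (is.null(beta)) beta <- default_beta(seed = config$seed)

  starts_y <- seq(0L, d[2] - 1L, by = block_shape[1])
  starts_x <- seq(0L, d[3] - 1L, by = block_shape[2])
  blocks <- expand.grid(y0 = starts_y, x0 = starts_x)
  blocks$y1 <- pmin(d[2], blocks$y0 + block_shape[1])
  blocks$x1 <- pmin(d[3], blocks$x0 + block_shape[2])

  # phase 1: per-block pixel probabilities, stitched by ownership
  stitched <- array(0, c(3L, d))
  f <- config$upsample_factor
  for (b in seq_len(nrow(blocks))) {
    hy0 <- max(0L, blocks$y0[b] - halo[1]); hy1 <- min(d[2], blocks$y1[b] + halo[1])
    hx0 <- max(0L, blocks$x0[b] - halo[2]); hx1 <- min(d[3], blocks$x1[b] + halo[2])
    sub <- anisotropic_volume(
      volume$data[, (hy0 + 1):hy1, (hx0 + 1):hx1, drop = FALSE],
      volume$voxel_size)
    up <- upsample_z(sub, f)
    keep <- seq(1L, dim(up$data)[1], by = f)
    fs <- compute_feature_stack(up, config$features, z_keep = keep)
    fs$voxel_size <- volume$voxel_size
    rm(up)
    pr <- predict_probabilities(pixel_classifier, fs)
    rm(fs); gc(FALSE)
    oy <- (blocks$y0[b] + 1):blocks$y1[b]
    ox <- (blocks$x0[b] + 1):blocks$x1[b]
    stitched[, , oy, ox] <- pr$data[, , oy - hy0, ox - hx0, drop = FALSE]
    rm(pr)
  }
  prob <- probability_map(stitched, PIXEL_CLASSES, volume$voxel_size)
  psyn <- synapse_plane(prob)

  # phase 2: per-block detection with centroid ownership, segmentation from
  # the stitched map
  candidates <- list()
  dets_all <- NULL
  for (b in seq_len(nrow(blocks))) {
    hy0 <- max(0L, blocks$y0[b] - halo[1]); hy1 <- min(d[2], blocks$y1[b] + halo[1])
    hx0 <- max(0L, blocks$x0[b] - halo[2]); hx1 <- min(d[3], blocks$x1[b] + halo[2])
    crop <- psyn[, (hy0 + 1):hy1, (hx0 + 1):hx1, drop = FALSE]
    mask <- crop > config$detection_threshold
    cc <- connected_components(mask, config$connectivity)
    tab <- filter_components_by_size(cc$table, config$size_min,
                                     config$size_max)
    if (nrow(tab) == 0) next
    # ownership: component centroid inside the block proper
    idx <- which(cc$labels > 0, arr.ind = TRUE)
    lab <- cc$labels[cc$labels > 0]
    cy <- tapply(idx[, 2], lab, mean) + hy0  # volume frame, 1-based
    cx <- tapply(idx[, 3], lab, mean) + hx0
    own <- cy[as.character(tab$component_id)] > blocks$y0[b] + 0.5 &
      cy[as.character(tab$component_id)] <= blocks$y1[b] + 0.5 &
      cx[as.character(tab$component_id)] > blocks$x0[b] + 0.5 &
      cx[as.character(tab$component_id)] <= blocks$x1[b] + 0.5
    tab <- tab[own, , drop = FALSE]
    if (nrow(tab) == 0) next
    # shift boxes to the volume frame and enlarge there
    tab$y0 <- tab$y0 + hy0; tab$y1 <- tab$y1 + hy0
    tab$x0 <- tab$x0 + hx0; tab$x1 <- tab$x1 + hx0
    tab <- enlarge_bounding_boxes(tab, config$halo_nm, volume$voxel_size, d)
    # labels volume for seeding-overlap checks, in the volume frame
    lab_vol <- array(0L, d)
    lab_vol[, (hy0 + 1):hy1, (hx0 + 1):hx1] <- cc$labels
    cand <- segment_candidates(psyn, lab_vol, tab, beta)
    candidates <- c(candidates, cand)
    dets_all <- rbind(dets_all, tab)
  }
  candidates <- merge_candidates(candidates, d)

  feats <- candidate_features(volume, candidates, config$neighborhood)
  scores <- if (length(candidates) > 0) {
    classify_candidates(object_classifier, feats, config$object_threshold)
  } else {
    data.frame(candidate_id = integer(0), score = numeric(0),
               accepted = logical(0))
  }
  scores$boundary <- vapply(candidates, `[[`, logical(1), "boundary")

  structure(list(
    candidates = candidates,
    scores = scores,
    accepted = scores$candidate_id[scores$accepted],
    prob_map = prob,
    detections = if (is.null(dets_all)) {
      data.frame()
    } else {
      dets_all
    },
    features = feats,
    pixel_classifier = pixel_classifier,
    object_classifier = object_classifier,
    beta = beta,
    config = config,
    log = list()), class = "synapse_detection")
}
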