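#' Ising segmentation energy
#'
#' Energy of a binary labeling of a probability crop under the unary +
#' constant-Ising model: `E = sum_p D_p(L_p) + beta * #cut`, where
#' `D_p(background) = 2 * p_syn`, `D_p(synapse) = 2 * (1 - p_syn)` and
#' `#cut` counts 6-neighbor pairs with unequal labels. The unary convention
#' ("synapse probability multiplied by 2" as the cost of labeling a voxel
#' background) makes the `beta = 0` limit coincide with the 0.5 detection
#' threshold.
#'
#' @param labeling logical or 0/1 3D array.
#' @param p numeric 3D array of synapse probabilities, same shape.
#' @param beta nonnegative pairwise constant.
#' @return The scalar energy.
#' @export
ising_energy <- function(labeling, p, beta) {
  if (beta < 0) stop("`beta` must be nonnegative")
  if (!identical(dim(labeling), dim(p))) stop("shape mismatch")
  L <- array(as.integer(labeling), dim(p))
  unary <- sum(ifelse(L == 1L, 2 * (1 - p), 2 * p))
  d <- dim(p)
  cut <- 0L
  if (d[1] > 1) cut <- cut + sum(L[-d[1], , , drop = FALSE] !=
                                   L[-1, , , drop = FALSE])
  if (d[2] > 1) cut <- cut + sum(L[, -d[2], , drop = FALSE] !=
                                   L[, -1, , drop = FALSE])
  if (d[3] > 1) cut <- cut + sum(L[, , -d[3], drop = FALSE] !=
                                   L[, , -1, drop = FALSE])
  unary + beta * cut
}

#' Graph-cut segmentation of a probability crop
#'
#' Returns a labeling attaining the global minimum of [ising_energy()] via
#' max-flow/min-cut on the 6-connected voxel grid (the energy is submodular
#' for `beta >= 0`, so the optimum is exact). At `beta = 0` the result
#' equals voxelwise thresholding `p > 0.5` (ties to background); for very
#' large `beta` the labeling floods to the single class with lower total
#' unary cost.
#'
#' @param p numeric 3D array of synapse probabilities.
#' @param beta nonnegative pairwise constant.
#' @return Logical 3D array (`TRUE` = synapse).
#' @export
segment_graphcut <- function(p, beta) {
  if (is.null(dim(p)) || length(dim(p)) != 3L) {
    if (length(p) == 0) stop("empty crop")
    stop("`p` must be a 3D array")
  }
  if (length(p) == 0) stop("empty crop")
  if (beta < 0) stop("`beta` must be nonnegative")
  # merged terminal capacities: cut s->v (cap 2p) iff background,
  # cut v->t (cap 2(1-p)) iff synapse
  tcap <- 4 * as.numeric(p) - 2
  lab <- grid_maxflow_cpp(tcap, as.integer(dim(p)), beta)
  mask <- lab == 1L
  dim(mask) <- dim(p)
  mask
}

#' Hysteresis thresholding of a probability crop
#'
#' Union of connected components of `p > low` that contain at least one
#' voxel with `p > high`. The faster alternative to graph cut; prone to
#' attaching long thin protrusions to correctly detected objects.
#'
#' @param p numeric 3D array of synapse probabilities.
#' @param high upper threshold (the 0.5 detection threshold by default).
#' @param low lower threshold, `0 < low <= high`.
#' @param connectivity component connectivity (default 26).
#' @return Logical 3D array.
#' @export
segment_hysteresis <- function(p, high = 0.5, low, connectivity = 26) {
  if (!(low > 0 && high < 1)) stop("thresholds must lie in (0, 1)")
  if (low > high) stop("`low` must be <= `high`")
  loose <- p > low
  if (!any(loose)) return(loose)
  cc <- connected_components(loose, connectivity)
  seeds <- unique(cc$labels[p > high])
  seeds <- seeds[seeds > 0]
  mask <- array(cc$labels %in% seeds, dim(p))
  mask
}

#' Jaccard index of two binary masks
#'
#' `|A n B| / |A u B|`; defined as 1 when both masks are empty.
#'
#' @param a,b logical arrays of identical shape.
#' @return Scalar in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) return(1)
  inter / uni
}

#' Calibrate the Ising pairwise constant by grid search
#'
#' Chooses the `beta` maximizing the mean Jaccard index between
#' [segment_graphcut()] output and reference segmentations, mirroring
#' calibration against a handful of manually segmented synapses. Ties are
#' broken toward the smallest `beta`.
#'
#' @param crops list of probability crops (3D arrays).
#' @param gt_masks list of reference binary masks, same shapes.
#' @param grid numeric vector of candidate `beta` values.
#' @return The selected `beta` (scalar).
#' @export
calibrate_beta <- function(crops, gt_masks, grid) {
  if (length(crops) == 0 || length(crops) != length(gt_masks))
    stop("need >= 1 (crop, mask) pair with matching lengths")
  if (length(grid) == 0) stop("`grid` must be nonempty")
  for (i in seq_along(crops))
    if (!identical(dim(crops[[i]]), dim(gt_masks[[i]])))
      stop("shape mismatch between crop and mask ", i)
  grid <- sort(as.numeric(grid))
  best_beta <- grid[1]
  best_score <- -Inf
  for (b in grid) {
    score <- mean(vapply(seq_along(crops), function(i) {
      jaccard(segment_graphcut(crops[[i]], b), gt_masks[[i]])
    }, 0))
    if (score > best_score) {  # strict: ties keep the smaller beta
      best_score <- score
      best_beta <- b
    }
  }
  best_beta
}
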