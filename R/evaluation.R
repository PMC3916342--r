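#' Match detections to ground-truth synapse points
#'
#' A ground-truth point matches a candidate if it lies inside the
#' candidate's mask (distance 0) or within `tolerance_nm` of it under the
#' anisotropic (physical) distance. Matching is greedy one-to-one by
#' increasing distance; unmatched ground truth counts as false negative,
#' unmatched candidates as false positive.
#'
#' @param candidates list of candidates, each with elements `mask` (logical
#'   crop) and `box` (0-based half-open `(z0, y0, x0, z1, y1, x1)`), e.g.
#'   the `candidates` element of a [run_pipeline()] result.
#' @param gt data frame of ground-truth points with columns `z, y, x`
#'   (1-based voxel coordinates).
#' @param voxel_size voxel extent in nm, `(z, y, x)`.
#' @param tolerance_nm matching tolerance in nm (default 250, half the
#'   500 nm synapse-extent prior).
#' @return Object of class `evaluation_report`: `n_gt`, `n_detected`,
#'   `n_fn`, `n_fp`, `matches` (per-GT candidate id or `NA`), `fp_ids`.
#' @export
match_detections <- function(candidates, gt, voxel_size,
                             tolerance_nm = 250) {
  if (tolerance_nm < 0) stop("`tolerance_nm` must be >= 0")
  n_gt <- nrow(gt)
  n_cand <- length(candidates)
  vs <- as.numeric(voxel_size)
  # distance matrix gt x candidate (nm)
  dist <- matrix(Inf, n_gt, max(n_cand, 1))
  for (j in seq_len(n_cand)) {
    cand <- candidates[[j]]
    idx <- which(cand$mask, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    # mask voxel coordinates, 1-based volume frame
    mz <- (idx[, 1] + cand$box[1]) * vs[1]
    my <- (idx[, 2] + cand$box[2]) * vs[2]
    mx <- (idx[, 3] + cand$box[3]) * vs[3]
    for (i in seq_len(n_gt)) {
      dz <- gt$z[i] * vs[1] - mz
      dy <- gt$y[i] * vs[2] - my
      dx <- gt$x[i] * vs[3] - mx
      dist[i, j] <- sqrt(min(dz^2 + dy^2 + dx^2))
    }
  }
  matches <- rep(NA_integer_, n_gt)
  if (n_gt > 0 && n_cand > 0) {
    repeat {
      m <- which(dist == min(dist), arr.ind = TRUE)
      if (!is.finite(dist[m[1, 1], m[1, 2]]) ||
          dist[m[1, 1], m[1, 2]] > tolerance_nm) break
      i <- m[1, 1]; j <- m[1, 2]
      matches[i] <- j
      dist[i, ] <- Inf
      dist[, j] <- Inf
      if (all(!is.finite(dist))) break
    }
  }
  matched <- sum(!is.na(matches))
  structure(list(
    n_gt = n_gt,
    n_detected = n_cand,
    n_fn = n_gt - matched,
    n_fp = n_cand - matched,
    matches = matches,
    fp_ids = setdiff(seq_len(n_cand), matches[!is.na(matches)])),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> %d GT, %d detected; %d FN (%.1f%%), %d FP (%.1f%%)\n",
    x$n_gt, x$n_detected, x$n_fn, 100 * x$n_fn / max(x$n_gt, 1),
    x$n_fp, 100 * x$n_fp / max(x$n_gt, 1)))
  invisible(x)
}

#' False-negative and false-positive fractions
#'
#' Both rates are normalized by the ground-truth count (so 16 false
#' positives against 238 synapses report as 6.7%, printed as 7%).
#'
#' @param report an [match_detections()] report, or any list with `n_fn`,
#'   `n_fp`, `n_gt`.
#' @return Named vector `(fn_fraction, fp_fraction)`.
#' @export
error_rates <- function(report) {
  if (report$n_gt == 0) stop("error rates undefined for zero ground truth")
  c(fn_fraction = report$n_fn / report$n_gt,
    fp_fraction = report$n_fp / report$n_gt)
}

#' Mean cross-section area over the 5 central slices
#'
#' In-slice voxel count averaged over the 5 slices centered on the midpoint
#' of the mask's z-extent (all slices if the mask spans fewer than 5), the
#' cross-section-size morphometric used in detectability analyses.
#'
#' @param mask nonempty logical 3D array `(z, y, x)`.
#' @return Mean in-slice voxel count.
#' @export
mean_xy_area <- function(mask) {
  if (!any(mask)) stop("empty mask")
  per_slice <- apply(mask, 1, sum)
  occ <- which(per_slice > 0)
  z0 <- min(occ); z1 <- max(occ)
  mid <- (z0 + z1) / 2
  lo <- max(z0, ceiling(mid - 2))
  hi <- min(z1, lo + 4)
  lo <- max(z0, hi - 4)
  mean(per_slice[lo:hi])
}

#' Number of slices where a mask is visible
#'
#' Count of distinct z-slices containing at least one mask voxel (occupancy
#' count, not span), the z-continuity morphometric.
#'
#' @param mask logical 3D array.
#' @return Integer slice count.
#' @export
z_range <- function(mask) {
  sum(apply(mask, 1, any))
}

#' Skeleton-based synapse size
#'
#' Per slice, the 2D medial-axis skeleton of the mask's cross-section is
#' measured as skeleton voxel count times the lateral voxel size; the
#' summed slice lengths are multiplied by the slice thickness, giving a
#' sheet-area estimate in nm^2. Synapses lying nearly parallel to the
#' cutting plane are underestimated by construction.
#'
#' @param mask nonempty logical 3D array `(z, y, x)`.
#' @param voxel_size voxel extent in nm, `(z, y, x)`; lateral size taken
#'   from the x axis.
#' @return Size in nm^2.
#' @export
skeleton_size <- function(mask, voxel_size) {
  if (!any(mask)) stop("empty mask")
  d <- dim(mask)
  total_len <- 0
  for (z in seq_len(d[1])) {
    sl <- mask[z, , ]
    if (is.null(dim(sl))) dim(sl) <- d[2:3]
    if (!any(sl)) next
    skel <- thin_zs_cpp(sl)
    total_len <- total_len + sum(skel) * voxel_size[3]
  }
  total_len * voxel_size[1]
}

#' Perforation count of a synapse mask
#'
#' Number of z-slices whose 2D cross-section (8-connectivity) splits into
#' exactly two connected components; perforated synapses are reported to be
#' easier to detect. With `at_least_two = TRUE`, slices with two or more
#' components count.
#'
#' @param mask logical 3D array `(z, y, x)`.
#' @param at_least_two count slices with >= 2 components instead of
#'   exactly 2.
#' @return Integer slice count.
#' @export
perforation_count <- function(mask, at_least_two = FALSE) {
  d <- dim(mask)
  count <- 0L
  for (z in seq_len(d[1])) {
    sl <- mask[z, , ]
    if (!any(sl)) next
    sl3 <- array(sl, c(1L, d[2], d[3]))
    ncomp <- max(label_cc3d_cpp(sl3, dim(sl3), 26L))
    if ((at_least_two && ncomp >= 2) || (!at_least_two && ncomp == 2))
      count <- count + 1L
  }
  count
}

#' Per-synapse morphometrics table
#'
#' @param candidates list of candidates with `mask` and `box` elements.
#' @param voxel_size voxel extent in nm, `(z, y, x)`.
#' @return Data frame with `candidate_id`, `voxel_count`, `mean_xy_area`,
#'   `z_range`, `skeleton_size_nm2`, `perforation_count`.
#' @export
morphometrics_table <- function(candidates, voxel_size) {
  rows <- lapply(seq_along(candidates), function(i) {
    m <- candidates[[i]]$mask
    data.frame(candidate_id = i,
               voxel_count = sum(m),
               mean_xy_area = mean_xy_area(m),
               z_range = z_range(m),
               skeleton_size_nm2 = skeleton_size(m, voxel_size),
               perforation_count = perforation_count(m))
  })
  do.call(rbind, rows)
}
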