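#' Object neighborhood by anisotropic distance transform
#'
#' Voxels outside the object whose anisotropically scaled distance to the
#' object is within the ellipsoidal bound defined by per-axis radii
#' (scaled distance <= 1, each axis normalized by its radius). The default
#' radii `(30, 30, 1)` in `(x, y, z)` order give the in-plane context ring
#' used by the neighborhood intensity features; the object itself is always
#' excluded. A zero radius forbids any offset along that axis.
#'
#' @param mask nonempty logical 3D array `(z, y, x)`.
#' @param radii numeric length-3 radii in voxels, `(x, y, z)` order
#'   (the convention such parameters are quoted in).
#' @return Logical 3D array of the neighborhood.
#' @export
object_neighborhood <- function(mask, radii = c(30, 30, 1)) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (!any(mask)) stop("empty mask")
  if (any(radii < 0)) stop("radii must be >= 0")
  rzyx <- c(radii[3], radii[2], radii[1])
  w <- ifelse(rzyx > 0, 1 / rzyx, Inf)
  d2 <- edt_sq_cpp(mask, as.integer(dim(mask)), w)
  nbh <- !mask & d2 <= 1 + 1e-9
  dim(nbh) <- dim(mask)
  nbh
}

#' Running central-moment accumulator
#'
#' Accumulates `n`, mean and the 2nd-4th centered power sums of a sample,
#' in a form that merges exactly across sub-blocks (pairwise update
#' formulas), so blockwise computation of mean/variance/skewness/kurtosis
#' agrees with whole-sample computation.
#'
#' @param values numeric vector (may be empty).
#' @return List with `n`, `mean`, `M2`, `M3`, `M4`.
#' @export
moment_accumulate <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n == 0) return(list(n = 0, mean = 0, M2 = 0, M3 = 0, M4 = 0))
  m <- mean(values)
  d <- values - m
  list(n = n, mean = m, M2 = sum(d^2), M3 = sum(d^3), M4 = sum(d^4))
}

#' Merge two moment accumulators
#'
#' @param a,b accumulators from [moment_accumulate()] or previous merges.
#' @return Merged accumulator.
#' @export
moment_merge <- function(a, b) {
  if (a$n == 0) return(b)
  if (b$n == 0) return(a)
  na <- a$n; nb <- b$n; n <- na + nb
  delta <- b$mean - a$mean
  mean <- a$mean + delta * nb / n
  M2 <- a$M2 + b$M2 + delta^2 * na * nb / n
  M3 <- a$M3 + b$M3 + delta^3 * na * nb * (na - nb) / n^2 +
    3 * delta * (na * b$M2 - nb * a$M2) / n
  M4 <- a$M4 + b$M4 +
    delta^4 * na * nb * (na^2 - na * nb + nb^2) / n^3 +
    6 * delta^2 * (na^2 * b$M2 + nb^2 * a$M2) / n^2 +
    4 * delta * (na * b$M3 - nb * a$M3) / n
  list(n = n, mean = mean, M2 = M2, M3 = M3, M4 = M4)
}

#' Summary statistics from a moment accumulator
#'
#' @param acc accumulator from [moment_accumulate()] / [moment_merge()].
#' @return Named vector `(mean, variance, skewness, kurtosis)`.
#' @keywords internal
moment_statistics <- function(acc) {
  n <- acc$n
  out <- c(mean = 0, variance = 0, skewness = 0, kurtosis = 0)
  if (n == 0) {
    warning("no values: all summary statistics set to 0", call. = FALSE)
    return(out)
  }
  out["mean"] <- acc$mean
  if (n < 2) {
    warning("fewer than 2 values: variance/skewness/kurtosis set to 0",
            call. = FALSE)
    return(out)
  }
  out["variance"] <- acc$M2 / (n - 1)
  m2 <- acc$M2 / n
  if (m2 <= 0) {
    warning("zero variance: skewness/kurtosis set to 0", call. = FALSE)
    return(out)
  }
  out["skewness"] <- (acc$M3 / n) / m2^1.5
  out["kurtosis"] <- (acc$M4 / n) / m2^2
  out
}

#' Mean, variance, skewness and kurtosis of a sample
#'
#' Mean; unbiased variance; skewness `m3 / m2^(3/2)` and (non-excess)
#' kurtosis `m4 / m2^2` from population central moments. Statistics that a
#' degenerate sample cannot support (constant or too-short input) are set
#' to 0 with a warning rather than raising, so candidate feature rows stay
#' aligned.
#'
#' @param values numeric vector.
#' @return Named vector `(mean, variance, skewness, kurtosis)`.
#' @export
summary_statistics <- function(values) {
  moment_statistics(moment_accumulate(values))
}

#' Uniform local-binary-pattern histogram of a region
#'
#' Rotation-invariant uniform LBP (`P = 8`, `R = 1`) computed per z-slice in
#' 2D (the descriptor is inherently planar) and pooled over all region
#' voxels into `P + 2 = 10` bins: 9 uniform classes (0-8 ones) plus one
#' non-uniform class; normalized to sum 1. Slices are padded by 1 reflected
#' pixel so border region voxels have full neighborhoods; callers that can
#' supply real context should pass a crop already grown by 1 pixel.
#'
#' @param intensity numeric 3D array `(z, y, x)`.
#' @param region logical 3D array selecting the voxels to pool.
#' @param P,R descriptor parameters; only `P = 8`, `R = 1` is implemented.
#' @return Numeric length-10 histogram (all zeros, with a warning, for an
#'   empty region).
#' @export
lbp_histogram <- function(intensity, region, P = 8, R = 1) {
  if (P != 8 || R != 1) stop("only P = 8, R = 1 is implemented")
  stopifnot(identical(dim(intensity), dim(region)))
  counts <- numeric(10)
  if (!any(region)) {
    warning("empty region: LBP histogram set to all zeros", call. = FALSE)
    return(counts)
  }
  d <- dim(intensity)
  for (z in seq_len(d[1])) {
    rmask <- region[z, , ]
    if (!any(rmask)) next
    sl <- intensity[z, , ]
    if (is.null(dim(sl))) dim(sl) <- d[2:3]
    # reflect-pad by 1 pixel
    ri <- c(1, seq_len(d[2]), d[2])
    ci <- c(1, seq_len(d[3]), d[3])
    padded <- sl[ri, ci, drop = FALSE]
    codes <- lbp_codes_cpp(padded)[2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE]
    counts <- counts + tabulate(codes[rmask] + 1L, 10L)
  }
  counts / sum(counts)
}

#' Ratio of largest to smallest principal component
#'
#' Square-rooted eigenvalue ratio of the covariance of the object's voxel
#' coordinates scaled to nm (anisotropy respected), a scale describing shape
#' elongation: near 1 for compact blobs, large for sheets and lines. The
#' smallest standard deviation is floored at `eps` (default 1e-8 nm) so
#' planar/linear objects give a finite, monotone value.
#'
#' @param mask logical 3D array `(z, y, x)`.
#' @param voxel_size voxel extent in nm, `(z, y, x)`.
#' @param eps floor for the smallest standard deviation, in nm.
#' @return Scalar ratio >= 1 (0 with a warning for < 3 voxels).
#' @export
principal_component_ratio <- function(mask, voxel_size, eps = 1e-8) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 3) {
    warning("fewer than 3 voxels: principal-component ratio set to 0",
            call. = FALSE)
    return(0)
  }
  coords <- sweep(idx, 2, as.numeric(voxel_size), "*")
  ev <- eigen(stats::cov(coords), symmetric = TRUE, only.values = TRUE)$values
  s <- sqrt(pmax(ev, 0))
  max(s) / max(min(s), eps)
}

OBJECT_FEATURE_NAMES <- c(
  "mean", "nbh_mean", "variance", "nbh_variance",
  "skewness", "nbh_skewness", "kurtosis", "nbh_kurtosis",
  paste0("lbp_", 0:9), paste0("nbh_lbp_", 0:9), "pc_ratio")

#' Object-level feature vector of a synapse candidate
#'
#' Assembles the 29 object features in fixed documented order: object and
#' neighborhood grayscale mean/variance/skewness/kurtosis (interleaved),
#' 10-bin uniform LBP histograms of the object and of its neighborhood, and
#' the principal-component ratio. Neighborhood radii default to
#' `(30, 30, 1)` voxels in `(x, y, z)` order. Grayscale context is read
#' from the volume itself wherever the grown crop stays in bounds.
#'
#' @param v an [anisotropic_volume()] (native grid).
#' @param mask candidate mask: logical 3D array, either full-volume or a
#'   crop accompanied by `box`.
#' @param box optional 0-based half-open crop box
#'   `(z0, y0, x0, z1, y1, x1)` locating `mask` inside `v`.
#' @param neighborhood radii in voxels, `(x, y, z)`.
#' @return Named numeric vector of length 29.
#' @export
compute_object_features <- function(v, mask, box = NULL,
                                    neighborhood = c(30, 30, 1)) {
  stopifnot(inherits(v, "aniso_volume"))
  d <- dim(v$data)
  if (is.null(box)) {
    stopifnot(identical(dim(mask), d))
    idx <- which(mask, arr.ind = TRUE)
    if (nrow(idx) == 0) stop("empty candidate mask")
    box <- c(min(idx[, 1]) - 1L, min(idx[, 2]) - 1L, min(idx[, 3]) - 1L,
             max(idx[, 1]), max(idx[, 2]), max(idx[, 3]))
    mask <- mask[(box[1] + 1):box[4], (box[2] + 1):box[5],
                 (box[3] + 1):box[6], drop = FALSE]
  }
  # grow the crop: neighborhood radii plus 1 pixel of LBP context
  g <- c(neighborhood[3], neighborhood[2] + 1, neighborhood[1] + 1)  # z,y,x
  w0 <- pmax(c(0L, 0L, 0L), box[1:3] - g)
  w1 <- pmin(d, box[4:6] + g)
  crop <- v$data[(w0[1] + 1):w1[1], (w0[2] + 1):w1[2], (w0[3] + 1):w1[3],
                 drop = FALSE]
  cmask <- array(FALSE, dim(crop))
  off <- box[1:3] - w0
  cmask[(off[1] + 1):(off[1] + dim(mask)[1]),
        (off[2] + 1):(off[2] + dim(mask)[2]),
        (off[3] + 1):(off[3] + dim(mask)[3])] <- mask
  nbh <- object_neighborhood(cmask, neighborhood)

  obj_stats <- summary_statistics(crop[cmask])
  nbh_stats <- summary_statistics(crop[nbh])
  obj_lbp <- lbp_histogram(crop, cmask)
  nbh_lbp <- lbp_histogram(crop, nbh)
  pcr <- principal_component_ratio(cmask, v$voxel_size)

  out <- c(obj_stats["mean"], nbh_stats["mean"],
           obj_stats["variance"], nbh_stats["variance"],
           obj_stats["skewness"], nbh_stats["skewness"],
           obj_stats["kurtosis"], nbh_stats["kurtosis"],
           obj_lbp, nbh_lbp, pcr)
  names(out) <- OBJECT_FEATURE_NAMES
  out
}
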