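#' Sampled Gaussian (derivative) kernel
#'
#' Discrete kernels used by the 3D filter bank, calibrated so that smoothing
#' preserves constants and linear ramps exactly, the first derivative of a
#' unit ramp is exactly 1, and the second derivative of `x^2` is exactly 2.
#' Kernel radius is `max(1, ceiling(3 * sigma))` taps.
#'
#' @param sigma scale in pixels, > 0.
#' @param order derivative order: 0, 1 or 2.
#' @return Numeric vector of odd length (correlation convention).
#' @keywords internal
gaussian_kernel <- function(sigma, order = 0) {
  if (!is.finite(sigma) || sigma <= 0) stop("`sigma` must be > 0")
  r <- max(1L, ceiling(3 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  if (order == 0) {
    g / sum(g)
  } else if (order == 1) {
    k <- x / sigma^2 * g           # g'(-j) for the correlation convention
    k / sum(k * x)
  } else if (order == 2) {
    k <- (x^2 / sigma^4 - 1 / sigma^2) * g
    k <- k - mean(k)               # zero response to constants
    k * (2 / sum(k * x^2))         # unit response to curvature
  } else {
    stop("`order` must be 0, 1 or 2")
  }
}

# separable Gaussian-derivative filtering along (z, y, x); reflective boundary
gauss_deriv3 <- function(a, orders, sigma) {
  d <- dim(a)
  storage.mode(a) <- "double"
  for (axis in 1:3) {
    k <- gaussian_kernel(sigma, orders[axis])
    a <- conv_axis_cpp(a, as.integer(d), k, axis - 1L)
  }
  a
}

#' Gaussian smoothing of a 3D grid
#'
#' Isotropic (in pixels) separable Gaussian convolution with reflective
#' boundary handling; preserves constants.
#'
#' @param a numeric 3D array `(z, y, x)`.
#' @param sigma scale in pixels of the (upsampled) grid, > 0.
#' @return Smoothed 3D array.
#' @export
gaussian_smoothing <- function(a, sigma) {
  gauss_deriv3(a, c(0, 0, 0), sigma)
}

#' Eigenvalues of the Gaussian Hessian matrix
#'
#' Second-derivative matrix at scale `sigma`, eigenvalues sorted descending
#' per voxel. Strongly negative paired eigenvalues flag dark sheet-like
#' structures such as the postsynaptic density.
#'
#' @inheritParams gaussian_smoothing
#' @return 4D array `(3, z, y, x)`: eigenvalues `ev1 >= ev2 >= ev3`.
#' @export
hessian_eigenvalues <- function(a, sigma) {
  d <- dim(a)
  hzz <- gauss_deriv3(a, c(2, 0, 0), sigma)
  hzy <- gauss_deriv3(a, c(1, 1, 0), sigma)
  hzx <- gauss_deriv3(a, c(1, 0, 1), sigma)
  hyy <- gauss_deriv3(a, c(0, 2, 0), sigma)
  hyx <- gauss_deriv3(a, c(0, 1, 1), sigma)
  hxx <- gauss_deriv3(a, c(0, 0, 2), sigma)
  ev <- eig3_sym_cpp(hzz, hzy, hzx, hyy, hyx, hxx)
  out <- array(0, c(3L, d))
  for (j in 1:3) out[j, , , ] <- ev[, j]
  out
}

#' Laplacian of Gaussian
#'
#' Trace of the Gaussian Hessian (sum of the three second derivatives);
#' vanishes on constants and linear ramps.
#'
#' @inheritParams gaussian_smoothing
#' @return 3D array.
#' @export
laplacian_of_gaussian <- function(a, sigma) {
  gauss_deriv3(a, c(2, 0, 0), sigma) +
    gauss_deriv3(a, c(0, 2, 0), sigma) +
    gauss_deriv3(a, c(0, 0, 2), sigma)
}

#' Difference of Gaussians
#'
#' `smooth(a, sigma) - smooth(a, 0.66 * sigma)`; the inner scale follows the
#' filter bank's convention of a second Gaussian at `0.66 * sigma`.
#'
#' @inheritParams gaussian_smoothing
#' @return 3D array.
#' @export
difference_of_gaussians <- function(a, sigma) {
  gaussian_smoothing(a, sigma) - gaussian_smoothing(a, 0.66 * sigma)
}

#' Eigenvalues of the structure tensor
#'
#' Outer product of Gaussian gradients at inner scale `sigma / 2`, smoothed
#' component-wise at outer scale `sigma`; eigenvalues sorted descending.
#' All eigenvalues are nonnegative (positive-semidefinite tensor).
#'
#' @inheritParams gaussian_smoothing
#' @param sigma outer integration scale in pixels; the gradient (inner)
#'   scale is `sigma / 2`.
#' @return 4D array `(3, z, y, x)`.
#' @export
structure_tensor_eigenvalues <- function(a, sigma) {
  d <- dim(a)
  gz <- gauss_deriv3(a, c(1, 0, 0), sigma / 2)
  gy <- gauss_deriv3(a, c(0, 1, 0), sigma / 2)
  gx <- gauss_deriv3(a, c(0, 0, 1), sigma / 2)
  smooth0 <- function(x) {
    dim(x) <- d
    gauss_deriv3(x, c(0, 0, 0), sigma)
  }
  tzz <- smooth0(gz * gz); tzy <- smooth0(gz * gy); tzx <- smooth0(gz * gx)
  tyy <- smooth0(gy * gy); tyx <- smooth0(gy * gx); txx <- smooth0(gx * gx)
  ev <- eig3_sym_cpp(tzz, tzy, tzx, tyy, tyx, txx)
  out <- array(0, c(3L, d))
  for (j in 1:3) out[j, , , ] <- ev[, j]
  out
}

#' Pixel feature bank configuration
#'
#' Per-filter sigma lists (pixels of the z-upsampled grid, identical in all
#' three dimensions). The default configuration defines the standard
#' 26-channel bank: Gaussian smoothing at 6 scales, Hessian eigenvalues at 4
#' scales (3 channels each), Laplacian of Gaussian at 3 scales, difference
#' of Gaussians at 2 scales, structure-tensor eigenvalues at 1 scale
#' (3 channels).
#'
#' @param gaussian,hessian,log,dog,structure_tensor numeric vectors of
#'   sigmas (pixels), each > 0 and sorted ascending; may be empty to drop a
#'   filter family.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(gaussian = c(0.7, 1.0, 1.6, 3.5, 5.0, 10.0),
                           hessian = c(1.6, 3.5, 5.0, 10.0),
                           log = c(3.5, 5.0, 10.0),
                           dog = c(5.0, 10.0),
                           structure_tensor = 5.0) {
  cfg <- list(gaussian = as.numeric(gaussian), hessian = as.numeric(hessian),
              log = as.numeric(log), dog = as.numeric(dog),
              structure_tensor = as.numeric(structure_tensor))
  for (nm in names(cfg)) {
    s <- cfg[[nm]]
    if (any(!is.finite(s)) || any(s <= 0))
      stop("sigmas for '", nm, "' must be positive")
    if (is.unsorted(s, strictly = TRUE) && length(s) > 1)
      stop("sigmas for '", nm, "' must be sorted ascending")
  }
  if (sum(lengths(cfg)) == 0) stop("feature config must name at least one filter")
  structure(cfg, class = "feature_config")
}

feature_channel_names <- function(cfg) {
  nms <- character(0)
  for (s in cfg$gaussian) nms <- c(nms, sprintf("gaussian@%g", s))
  for (s in cfg$hessian)
    nms <- c(nms, sprintf("hessian@%g:ev%d", s, 1:3))
  for (s in cfg$log) nms <- c(nms, sprintf("log@%g", s))
  for (s in cfg$dog) nms <- c(nms, sprintf("dog@%g", s))
  for (s in cfg$structure_tensor)
    nms <- c(nms, sprintf("st@%g:ev%d", s, 1:3))
  nms
}

#' Compute the pixel feature stack
#'
#' Runs the full 3D filter bank on a (z-upsampled) volume and concatenates
#' the channels in the fixed documented order: Gaussian smoothing, Hessian
#' eigenvalues, Laplacian of Gaussian, difference of Gaussians,
#' structure-tensor eigenvalues; within each family by ascending sigma. The
#' default configuration yields exactly 26 channels.
#'
#' @param v an [anisotropic_volume()], already upsampled along z per the
#'   pipeline configuration.
#' @param cfg a [feature_config()].
#' @param z_keep optional indices of z-slices to retain in the output
#'   stack. The filters always see the full grid; this only subsets what is
#'   stored, which the pipeline uses to keep just the slices that survive
#'   z-downsampling of the predictions.
#' @return An object of class `feature_stack`: `data` 4D
#'   `(channel, z, y, x)`, `channel_names`, `voxel_size`.
#' @export
compute_feature_stack <- function(v, cfg = feature_config(), z_keep = NULL) {
  stopifnot(inherits(v, "aniso_volume"), inherits(cfg, "feature_config"))
  a <- v$data
  storage.mode(a) <- "double"
  d <- dim(a)
  if (is.null(z_keep)) z_keep <- seq_len(d[1])
  nms <- feature_channel_names(cfg)
  out <- array(0, c(length(nms), length(z_keep), d[2], d[3]))
  ch <- 0L
  big <- prod(d) > 1e6  # bound temporary buildup on large volumes
  store <- function(channel) {
    ch <<- ch + 1L
    out[ch, , , ] <<- channel[z_keep, , , drop = FALSE]
    if (big) gc(FALSE)
  }
  for (s in cfg$gaussian) store(gaussian_smoothing(a, s))
  for (s in cfg$hessian) {
    ev <- hessian_eigenvalues(a, s)
    for (j in 1:3) store(array(ev[j, , , ], d))
  }
  for (s in cfg$log) store(laplacian_of_gaussian(a, s))
  for (s in cfg$dog) store(difference_of_gaussians(a, s))
  for (s in cfg$structure_tensor) {
    ev <- structure_tensor_eigenvalues(a, s)
    for (j in 1:3) store(array(ev[j, , , ], d))
  }
  structure(list(data = out, channel_names = nms, voxel_size = v$voxel_size),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<feature_stack> %d channels over %d x %d x %d (z,y,x)\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

# n_voxels x n_channels matrix of feature vectors at the given voxel
# linear indices (z fastest, then y, then x), without materializing a full
# copy of the stack
feature_matrix <- function(fs, voxels) {
  d <- dim(fs$data)
  nch <- d[1]
  out <- matrix(0, length(voxels), nch)
  base <- (voxels - 1) * nch
  for (ch in seq_len(nch)) out[, ch] <- fs$data[base + ch]
  out
}
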