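#' Anisotropic 3D volume
#'
#' Container for a 3D scalar grid with a physical voxel size per axis.
#' Arrays are stored in `(z, y, x)` order throughout the package; serial
#' sections are the first axis, so lateral (in-plane) pixels are `(y, x)`.
#' Parameters quoted in the field's usual `(x, y, z)` order (such as object
#' neighborhood radii) are converted at the API boundary.
#'
#' @param data numeric 3D array, `(z, y, x)` order.
#' @param voxel_size numeric length-3, voxel extent in nm per axis in
#'   `(z, y, x)` order. The reference ssTEM resolution is `c(45, 4.5, 4.5)`.
#' @return An object of class `aniso_volume` with elements `data` and
#'   `voxel_size`.
#' @examples
#' v <- anisotropic_volume(array(0, c(2, 4, 4)), c(45, 4.5, 4.5))
#' dim(v$data)
#' @export
anisotropic_volume <- function(data, voxel_size) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array in (z, y, x) order")
  if (any(dim(data) < 1L))
    stop("volume must have at least 1 slice and 1 pixel per slice")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be 3 positive values (z, y, x) in nm")
  storage.mode(data) <- "double"
  structure(list(data = data, voxel_size = voxel_size),
            class = "aniso_volume")
}

#' @export
print.aniso_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<aniso_volume> %d x %d x %d (z,y,x), voxel %g x %g x %g nm\n",
              d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Per-voxel class probability map
#'
#' @param data numeric 4D array `(class, z, y, x)`.
#' @param class_names character vector naming the classes, in array order.
#' @param voxel_size voxel extent in nm, `(z, y, x)`.
#' @return An object of class `prob_map`.
#' @export
probability_map <- function(data, class_names, voxel_size) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array in (class, z, y, x) order")
  if (dim(data)[1] != length(class_names))
    stop("first dimension must match `class_names`")
  sums <- colSums(data, dims = 1)
  if (max(abs(sums - 1)) > 1e-6)
    stop("per-voxel probabilities must sum to 1 (tolerance 1e-6)")
  if (min(data) < -1e-9 || max(data) > 1 + 1e-9)
    stop("probabilities must lie in [0, 1]")
  structure(list(data = data, class_names = as.character(class_names),
                 voxel_size = as.numeric(voxel_size)),
            class = "prob_map")
}

#' @export
print.prob_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<prob_map> %s over %d x %d x %d (z,y,x)\n",
              paste(x$class_names, collapse = "/"), d[2], d[3], d[4]))
  invisible(x)
}

#' Read a grayscale volume from a multi-page TIFF
#'
#' Grayscale values of integer TIFFs (8/16-bit) are preserved bit-exactly.
#' The voxel size is never guessed from the file; it must be supplied.
#'
#' @param path path to a multi-page TIFF file.
#' @param voxel_size voxel extent in nm, `(z, y, x)`.
#' @return An [anisotropic_volume()].
#' @export
read_volume <- function(path, voxel_size) {
  if (!file.exists(path)) stop("cannot read volume: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- lapply(pages, dim)
  if (any(vapply(dims, length, 1L) != 2L))
    stop("format error: TIFF pages must be single-channel grayscale")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("format error: TIFF pages differ in shape")
  ny <- dims[[1]][1]; nx <- dims[[1]][2]
  a <- array(0, c(length(pages), ny, nx))
  for (k in seq_along(pages)) a[k, , ] <- pages[[k]]
  anisotropic_volume(a, voxel_size)
}

#' Write a grayscale volume to a multi-page TIFF
#'
#' @param v an [anisotropic_volume()].
#' @param path output file path.
#' @param bits bits per sample: 8 or 16 for integer data (values are taken
#'   as raw gray levels), 32 for float.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, bits = 8) {
  stopifnot(inherits(v, "aniso_volume"), bits %in% c(8, 16, 32))
  nz <- dim(v$data)[1]
  scale <- if (bits == 32) 1 else 2^bits - 1
  pages <- lapply(seq_len(nz), function(k) v$data[k, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Upsample a volume along z by linear interpolation
#'
#' Partially compensates the axial anisotropy of serial sections before 3D
#' filtering. Edge-aligned convention: the output has `(nz - 1) * factor + 1`
#' slices and reproduces the original slices exactly at indices
#' `0, factor, 2 * factor, ...` (0-based); no data is invented past the last
#' slice. The axial voxel size is divided by `factor`.
#'
#' @param v an [anisotropic_volume()].
#' @param factor integer upsampling factor, >= 1.
#' @return An [anisotropic_volume()] on the finer axial grid.
#' @export
upsample_z <- function(v, factor) {
  stopifnot(inherits(v, "aniso_volume"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("`factor` must be an integer >= 1")
  if (factor == 1L) return(v)
  d <- dim(v$data)
  nz <- d[1]
  nzo <- if (nz == 1L) 1L else (nz - 1L) * factor + 1L
  out <- array(0, c(nzo, d[2], d[3]))
  for (k in seq_len(nzo) - 1L) {
    i0 <- k %/% factor
    r <- k %% factor
    if (r == 0L) {
      out[k + 1L, , ] <- v$data[i0 + 1L, , ]
    } else {
      w <- r / factor
      out[k + 1L, , ] <- (1 - w) * v$data[i0 + 1L, , ] +
        w * v$data[i0 + 2L, , ]
    }
  }
  anisotropic_volume(out, c(v$voxel_size[1] / factor, v$voxel_size[2:3]))
}

#' Downsample along z by slice subsampling
#'
#' Returns predictions made on a z-upsampled grid to the native slice grid:
#' keeps every `factor`-th slice starting at the first, and multiplies the
#' axial voxel size by `factor`. The round trip
#' `upsample_z()` then `downsample_z()` is the identity on original slices.
#'
#' @param x a [probability_map()] or [anisotropic_volume()].
#' @param factor integer subsampling factor, >= 1.
#' @return Object of the same class on the coarser axial grid.
#' @export
downsample_z <- function(x, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("`factor` must be an integer >= 1")
  if (inherits(x, "prob_map")) {
    nz <- dim(x$data)[2]
    keep <- seq(1L, nz, by = factor)
    probability_map(x$data[, keep, , , drop = FALSE], x$class_names,
                    c(x$voxel_size[1] * factor, x$voxel_size[2:3]))
  } else if (inherits(x, "aniso_volume")) {
    nz <- dim(x$data)[1]
    keep <- seq(1L, nz, by = factor)
    anisotropic_volume(x$data[keep, , , drop = FALSE],
                       c(x$voxel_size[1] * factor, x$voxel_size[2:3]))
  } else {
    stop("`x` must be a prob_map or aniso_volume")
  }
}
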