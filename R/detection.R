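#' Threshold the synapse probability map
#'
#' @param p a [probability_map()].
#' @param t threshold in (0, 1); voxels with synapse-class probability
#'   strictly greater than `t` are kept (values exactly at `t` are excluded).
#' @param class_name class whose probability is thresholded.
#' @return Logical 3D array `(z, y, x)`.
#' @export
threshold_probability <- function(p, t = 0.5, class_name = "synapse") {
  stopifnot(inherits(p, "prob_map"))
  if (!(t > 0 && t < 1)) stop("`t` must lie strictly between 0 and 1")
  ci <- match(class_name, p$class_names)
  if (is.na(ci)) stop("unknown class: ", class_name)
  mask <- p$data[ci, , , ] > t
  dim(mask) <- dim(p$data)[2:4]
  mask
}

#' Connected components of a binary 3D mask
#'
#' Labels maximal connected regions (6, 18 or 26 connectivity) with distinct
#' positive ids in deterministic scan order; background is 0. The component
#' table lists voxel counts and 0-based half-open bounding boxes in
#' `(z, y, x)` order.
#'
#' @param mask logical 3D array.
#' @param connectivity 6, 18 or 26 (default 26, the most forgiving of
#'   z-anisotropy: a tilted synapse may connect only diagonally).
#' @return List with `labels` (integer 3D array) and `table` (data frame
#'   with columns `component_id`, `voxel_count`,
#'   `z0, y0, x0, z1, y1, x1`).
#' @export
connected_components <- function(mask, connectivity = 26) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  labels <- label_cc3d_cpp(mask, as.integer(dim(mask)),
                           as.integer(connectivity))
  n <- max(labels)
  if (n == 0) {
    tab <- data.frame(component_id = integer(0), voxel_count = integer(0),
                      z0 = integer(0), y0 = integer(0), x0 = integer(0),
                      z1 = integer(0), y1 = integer(0), x1 = integer(0))
    return(list(labels = labels, table = tab))
  }
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  tab <- data.frame(
    component_id = seq_len(n),
    voxel_count = as.integer(tabulate(lab, n)),
    z0 = as.integer(tapply(idx[, 1], lab, min) - 1L),
    y0 = as.integer(tapply(idx[, 2], lab, min) - 1L),
    x0 = as.integer(tapply(idx[, 3], lab, min) - 1L),
    z1 = as.integer(tapply(idx[, 1], lab, max)),
    y1 = as.integer(tapply(idx[, 2], lab, max)),
    x1 = as.integer(tapply(idx[, 3], lab, max)))
  rownames(tab) <- NULL
  list(labels = labels, table = tab)
}

#' Filter components by voxel count
#'
#' Discards specks and slab-scale blobs: keeps components with
#' `min_size <= voxel_count <= max_size` (bounds inclusive, matching the
#' "less than 100 / more than 1000000 pixels" discard rule). Sizes refer to
#' voxels of the native (non-upsampled) grid.
#'
#' @param table component table from [connected_components()].
#' @param min_size,max_size inclusive voxel-count bounds.
#' @return Filtered component table.
#' @export
filter_components_by_size <- function(table, min_size = 100,
                                      max_size = 1000000) {
  if (min_size > max_size) stop("`min_size` must be <= `max_size`")
  table[table$voxel_count >= min_size & table$voxel_count <= max_size, ,
        drop = FALSE]
}

#' Enlarge component bounding boxes by a physical halo
#'
#' Grows each box by `ceiling(halo_nm / voxel_size)` voxels per side per
#' axis so the enlarged box can be assumed to contain the full extent of the
#' detected synapse, then clips to the volume.
#'
#' @param table component table.
#' @param halo_nm halo in nm (default 500, the synapse-extent prior).
#' @param voxel_size `(z, y, x)` voxel extent in nm.
#' @param volume_shape `(nz, ny, nx)`.
#' @return Table with added columns `ez0, ey0, ex0, ez1, ey1, ex1`
#'   (0-based half-open).
#' @export
enlarge_bounding_boxes <- function(table, halo_nm = 500, voxel_size,
                                   volume_shape) {
  if (halo_nm < 0) stop("`halo_nm` must be >= 0")
  g <- as.integer(ceiling(halo_nm / voxel_size))  # (z, y, x) voxel growth
  volume_shape <- as.integer(volume_shape)
  table$ez0 <- pmax(0L, table$z0 - g[1])
  table$ey0 <- pmax(0L, table$y0 - g[2])
  table$ex0 <- pmax(0L, table$x0 - g[3])
  table$ez1 <- pmin(volume_shape[1], table$z1 + g[1])
  table$ey1 <- pmin(volume_shape[2], table$y1 + g[2])
  table$ex1 <- pmin(volume_shape[3], table$x1 + g[3])
  table
}

#' Export a component table as CSV
#'
#' Coordinates are written 0-based, half-open, in `(z, y, x)` axis order;
#' a comment line in the header records the convention.
#'
#' @param table component table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_component_table <- function(table, path) {
  con <- file(path, "w")
  writeLines("# coordinates: 0-based half-open voxel boxes, axis order z,y,x",
             con)
  utils::write.csv(table, con, row.names = FALSE)
  close(con)
  invisible(path)
}
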