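#' Phantom volume specification
#'
#' Parameters of the synthetic ssTEM-like phantom: dark curved synapse
#' sheets with one-sided vesicle-like speckle, plus distractors that share
#' the darkness but not the sheet+speckle conjunction (mitochondrion-like
#' blobs and thin membrane-like sheets). The phantom emulates appearance
#' statistics relevant to the pipeline, not EM physics.
#'
#' @param shape volume shape `(nz, ny, nx)`.
#' @param voxel_size voxel extent in nm `(z, y, x)`; default the reference
#'   ssTEM resolution `c(45, 4.5, 4.5)`.
#' @param n_synapses number of planted synapses.
#' @param extent_nm range of the sheet's major extent in nm.
#' @param thickness_nm sheet thickness in nm (the thickened pre/postsynaptic
#'   membranes plus cleft appear as a single dark sheet at this resolution).
#' @param tilt_low_fraction fraction of synapses oriented at a low angle to
#'   the cutting plane (sheet normal tilted 55-75 degrees from the plane),
#'   the hard-to-detect orientation; the remainder are steep sheets
#'   (normal within 30 degrees of the plane).
#' @param n_mito,n_membrane distractor counts.
#' @param membrane_thickness_nm thickness of the membrane-like distractor
#'   sheets (labeled as the membrane class during training).
#' @param n_apposition number of membrane-apposition distractors: dark
#'   sheets at synapse-like thickness (42-55 nm) without vesicle speckle.
#'   Unlike membranes they are never offered as training labels, mirroring
#'   structures an annotator never marked; they are the phantom's analogue
#'   of the dominant false-positive sources (membrane appositions, myelin),
#'   there to make the first stage over-detect so the object stage has real
#'   negatives to learn from.
#' @param n_clutter number of small dark specks scattered through the
#'   neuropil background, decorrelating per-voxel context from the
#'   synapse/apposition distinction.
#' @param background,synapse_intensity,membrane_intensity,mito_intensity,vesicle_intensity
#'   mean gray levels in `[0, 1]` (EM-dark objects on lighter neuropil).
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param separation_nm minimum clearance kept between planted objects.
#' @param seed integer seed fixing all randomness.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32, 384, 384),
                         voxel_size = c(45, 4.5, 4.5),
                         n_synapses = 20,
                         extent_nm = c(200, 800),
                         thickness_nm = 50,
                         tilt_low_fraction = 0.2,
                         n_mito = 6,
                         n_membrane = 8,
                         membrane_thickness_nm = 25,
                         n_apposition = 8,
                         n_clutter = 500,
                         background = 0.62,
                         synapse_intensity = 0.20,
                         membrane_intensity = 0.22,
                         mito_intensity = 0.34,
                         vesicle_intensity = 0.30,
                         noise_sd = 0.04,
                         separation_nm = 70,
                         seed = 1) {
  stopifnot(length(shape) == 3, all(shape >= 1), n_synapses >= 0,
            all(extent_nm > 0), thickness_nm > 0,
            tilt_low_fraction >= 0, tilt_low_fraction <= 1)
  structure(as.list(environment()), class = "phantom_spec")
}

# orthonormal tangent basis for a unit normal (axis order z, y, x); the
# first tangent is kept close to the cutting plane (sections are thin, so a
# sheet's major extent lies mostly laterally), rotated in-plane by psi
tangent_basis <- function(n, psi = 0) {
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  zhat <- c(1, 0, 0)
  u0 <- cross(n, zhat)
  if (sqrt(sum(u0^2)) < 1e-6) u0 <- cross(n, c(0, 1, 0))
  u0 <- u0 / sqrt(sum(u0^2))
  v0 <- cross(n, u0)
  list(u = cos(psi) * u0 + sin(psi) * v0,
       v = -sin(psi) * u0 + cos(psi) * v0)
}

# voxel indices (linear, 1-based) of a curved sheet patch; returns NULL if
# the patch cannot fit at this center
sheet_voxels <- function(center, normal, a, b, half_th, curv_radius,
                         shape, vs, tb = tangent_basis(normal)) {
  sag <- (max(a, b))^2 / (2 * abs(curv_radius))
  r_nm <- abs(tb$u) * a + abs(tb$v) * b + abs(normal) * (half_th + sag)
  lo <- floor((center - r_nm) / vs) - 1
  hi <- ceiling((center + r_nm) / vs) + 1
  if (any(lo < 0) || any(hi > shape)) return(NULL)
  zi <- (lo[1] + 1):hi[1]; yi <- (lo[2] + 1):hi[2]; xi <- (lo[3] + 1):hi[3]
  # voxel centers in nm
  zc <- (zi - 0.5) * vs[1] - center[1]
  yc <- (yi - 0.5) * vs[2] - center[2]
  xc <- (xi - 0.5) * vs[3] - center[3]
  nzb <- length(zi); nyb <- length(yi); nxb <- length(xi)
  dz <- array(zc, c(nzb, nyb, nxb))
  dy <- aperm(array(yc, c(nyb, nzb, nxb)), c(2, 1, 3))
  dx <- aperm(array(xc, c(nxb, nzb, nyb)), c(2, 3, 1))
  s <- tb$u[1] * dz + tb$u[2] * dy + tb$u[3] * dx
  t <- tb$v[1] * dz + tb$v[2] * dy + tb$v[3] * dx
  w <- normal[1] * dz + normal[2] * dy + normal[3] * dx
  inside <- (s / a)^2 + (t / b)^2 <= 1 &
    abs(w - (s^2 + t^2) / (2 * curv_radius)) <= half_th
  if (!any(inside)) return(NULL)
  idx <- which(inside, arr.ind = TRUE)
  vox <- (zi[idx[, 1]]) + shape[1] * ((yi[idx[, 2]] - 1) +
                                        shape[2] * (xi[idx[, 3]] - 1))
  list(vox = as.integer(vox),
       frame = list(center = center, normal = normal, u = tb$u, v = tb$v,
                    a = a, b = b, curv_radius = curv_radius))
}

# voxel indices of an axis-aligned-in-frame ellipsoid
ellipsoid_voxels <- function(center, radii_nm, shape, vs) {
  lo <- floor((center - radii_nm) / vs) - 1
  hi <- ceiling((center + radii_nm) / vs) + 1
  if (any(lo < 0) || any(hi > shape)) return(NULL)
  zi <- (lo[1] + 1):hi[1]; yi <- (lo[2] + 1):hi[2]; xi <- (lo[3] + 1):hi[3]
  zc <- ((zi - 0.5) * vs[1] - center[1]) / radii_nm[1]
  yc <- ((yi - 0.5) * vs[2] - center[2]) / radii_nm[2]
  xc <- ((xi - 0.5) * vs[3] - center[3]) / radii_nm[3]
  nzb <- length(zi); nyb <- length(yi); nxb <- length(xi)
  dz <- array(zc, c(nzb, nyb, nxb))
  dy <- aperm(array(yc, c(nyb, nzb, nxb)), c(2, 1, 3))
  dx <- aperm(array(xc, c(nxb, nzb, nyb)), c(2, 3, 1))
  q <- dz^2 + dy^2 + dx^2
  idx <- which(q <= 1, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  vox <- (zi[idx[, 1]]) + shape[1] * ((yi[idx[, 2]] - 1) +
                                        shape[2] * (xi[idx[, 3]] - 1))
  list(vox = as.integer(vox), q = q[q <= 1])
}

# sample a sheet normal: steep (near-perpendicular to the cutting plane) or
# low-angle-to-plane
sample_normal <- function(low_angle) {
  phi <- runif(1, 0, 2 * pi)
  elev <- if (low_angle) runif(1, 55, 75) else runif(1, 0, 30)
  e <- elev * pi / 180
  c(sin(e), cos(e) * cos(phi), cos(e) * sin(phi))
}

#' Generate a phantom ssTEM volume with ground truth
#'
#' Deterministic given the spec's seed. Every planted synapse is a dark
#' curved sheet with vesicle-like speckle on one side; distractors share the
#' darkness but lack the sheet+speckle conjunction. Truth masks record the
#' exact generating geometry and are pairwise disjoint (a minimum physical
#' separation is enforced during placement).
#'
#' @param spec a [phantom_spec()].
#' @param max_retries placement attempts per object before giving up (default 1000).
#' @return List with `volume` (an [anisotropic_volume()]) and `truth`, a
#'   list with per-synapse voxel indices and centroids plus distractor
#'   voxel sets (`membranes`, `mitos`, `vesicles`).
#' @export
generate_phantom <- function(spec, max_retries = 1000) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed)

  shape <- as.integer(spec$shape)
  vs <- spec$voxel_size
  vol_nm <- shape * vs
  n <- prod(shape)
  img <- array(spec$background, shape)
  # `blocked` holds placed objects dilated by the separation margin, so a
  # candidate only needs its own voxels tested (the dilation is computed
  # once per placed object, not per attempt)
  blocked <- logical(n)

  place_sheet <- function(extent_range, thickness, low_angle_frac, sep) {
    for (try in seq_len(max_retries)) {
      e1 <- runif(1, extent_range[1], extent_range[2])
      e2 <- max(extent_range[1], e1 * runif(1, 0.55, 0.9))
      a <- e1 / 2; b <- e2 / 2
      normal <- sample_normal(runif(1) < low_angle_frac)
      curv <- sample(c(-1, 1), 1) * runif(1, 1000, 4000)
      psi <- runif(1, -25, 25) * pi / 180
      tb <- tangent_basis(normal, psi)
      # axis-wise reach of the padded sheet, for feasible center sampling
      sag <- (max(a, b) + sep)^2 / (2 * abs(curv))
      reach <- abs(tb$u) * (a + sep) + abs(tb$v) * (b + sep) +
        abs(normal) * (thickness / 2 + sep + sag)
      margin <- reach + 2 * vs
      if (any(vol_nm <= 2 * margin)) next
      center <- runif(3, margin, vol_nm - margin)
      sv <- sheet_voxels(center, normal, a, b, thickness / 2, curv,
                         shape, vs, tb)
      if (is.null(sv)) next
      if (any(blocked[sv$vox])) next
      # claim the sheet padded by the separation margin
      pad <- sheet_voxels(center, normal, a + sep, b + sep,
                          thickness / 2 + sep, curv, shape, vs, tb)
      if (is.null(pad)) next
      return(list(sv = sv, pad = pad, extent = c(e1, e2),
                  center = center, normal = normal))
    }
    NULL
  }

  # mitochondrion-like blobs first: they need large free pockets, while
  # the thin sheets placed later slot in around them
  mitos <- list()
  for (i in seq_len(spec$n_mito)) {
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      radii <- c(runif(1, 100, 180), runif(1, 120, 250), runif(1, 120, 250))
      margin <- max(radii) + spec$separation_nm + 2 * vs
      if (any(vol_nm < 2 * margin)) break
      cen <- runif(3, margin, vol_nm - margin)
      core <- ellipsoid_voxels(cen, radii_nm = radii, shape = shape, vs = vs)
      if (is.null(core) || any(blocked[core$vox])) next
      pad <- ellipsoid_voxels(cen, radii_nm = radii + spec$separation_nm,
                              shape = shape, vs = vs)
      if (is.null(pad)) next
      blocked[pad$vox] <- TRUE
      # darker rim, mildly textured interior
      rim <- core$q >= 0.75
      img[core$vox[rim]] <- spec$membrane_intensity + 0.02
      interior <- core$vox[!rim]
      if (length(interior) > 0) {
        tex <- 0.05 * sin(arrayInd(interior, shape)[, 2] * vs[2] / 30)
        img[interior] <- spec$mito_intensity + tex
      }
      mitos[[length(mitos) + 1]] <- list(voxels = core$vox)
      placed <- TRUE
      break
    }
    if (!placed) break
  }

  synapses <- list()
  vesicle_vox <- integer(0)
  for (i in seq_len(spec$n_synapses)) {
    pl <- place_sheet(spec$extent_nm, spec$thickness_nm,
                      spec$tilt_low_fraction, spec$separation_nm)
    if (is.null(pl))
      stop(sprintf("could not place synapse %d of %d without overlap",
                   i, spec$n_synapses))
    blocked[pl$pad$vox] <- TRUE
    img[pl$sv$vox] <- spec$synapse_intensity
    # vesicle-like speckle on the positive-normal side of the sheet
    fr <- pl$sv$frame
    area_nm2 <- pi * fr$a * fr$b
    n_ves <- max(6L, round(area_nm2 / 12000))
    ves_this <- integer(0)
    for (k in seq_len(n_ves)) {
      ang <- runif(1, 0, 2 * pi)
      rad <- sqrt(runif(1)) * 0.85
      s <- rad * fr$a * cos(ang); t <- rad * fr$b * sin(ang)
      off <- runif(1, 50, 140)
      cen <- fr$center + s * fr$u + t * fr$v +
        (off + (s^2 + t^2) / (2 * fr$curv_radius)) * fr$normal
      if (any(cen < 0) || any(cen > vol_nm)) next
      r_ves <- runif(1, 18, 25)
      ev <- ellipsoid_voxels(cen, radii_nm = rep(r_ves, 3),
                             shape = shape, vs = vs)
      if (is.null(ev)) next
      keep <- setdiff(ev$vox, pl$sv$vox)
      img[keep] <- spec$vesicle_intensity
      ves_this <- c(ves_this, keep)
    }
    blocked[ves_this] <- TRUE
    vesicle_vox <- c(vesicle_vox, ves_this)
    coords <- arrayInd(pl$sv$vox, shape)
    synapses[[i]] <- list(
      voxels = pl$sv$vox,
      centroid = colMeans(coords),
      extent_nm = pl$extent,
      normal = pl$normal)
  }

  membranes <- list()
  for (i in seq_len(spec$n_membrane)) {
    pl <- place_sheet(spec$extent_nm, spec$membrane_thickness_nm, 0.1,
                      spec$separation_nm)
    if (is.null(pl)) break  # distractor shortfall is tolerable
    blocked[pl$pad$vox] <- TRUE
    img[pl$sv$vox] <- spec$membrane_intensity
    membranes[[length(membranes) + 1]] <- list(voxels = pl$sv$vox)
  }

  appositions <- list()
  for (i in seq_len(spec$n_apposition)) {
    pl <- place_sheet(spec$extent_nm, runif(1, 42, 55), 0.15,
                      spec$separation_nm)
    if (is.null(pl)) break
    blocked[pl$pad$vox] <- TRUE
    img[pl$sv$vox] <- spec$synapse_intensity + 0.01
    appositions[[length(appositions) + 1]] <- list(voxels = pl$sv$vox)
  }

  # small dark specks sprinkled through the neuropil
  clutter_vox <- integer(0)
  for (i in seq_len(spec$n_clutter)) {
    r <- runif(1, 15, 30)
    cen <- runif(3, r + vs, vol_nm - r - vs)
    ev <- ellipsoid_voxels(cen, radii_nm = rep(r, 3), shape = shape, vs = vs)
    if (is.null(ev) || any(blocked[ev$vox])) next
    img[ev$vox] <- spec$vesicle_intensity + runif(1, -0.02, 0.04)
    clutter_vox <- c(clutter_vox, ev$vox)
  }

  img <- img + stats::rnorm(n, 0, spec$noise_sd)
  img <- pmin(pmax(img, 0.01), 0.99)
  dim(img) <- shape

  truth <- list(synapses = synapses,
                membranes = membranes,
                mitos = mitos,
                appositions = appositions,
                vesicles = sort(unique(vesicle_vox)),
                clutter = sort(unique(clutter_vox)))
  list(volume = anisotropic_volume(img, vs), truth = truth)
}

#' Ground-truth synapse points of a phantom
#'
#' @param truth the `truth` element of [generate_phantom()].
#' @return Data frame with 1-based voxel coordinates `z, y, x` (centroids).
#' @export
phantom_gt_points <- function(truth) {
  if (length(truth$synapses) == 0)
    return(data.frame(z = numeric(0), y = numeric(0), x = numeric(0)))
  cent <- t(vapply(truth$synapses, function(s) s$centroid, numeric(3)))
  data.frame(z = cent[, 1], y = cent[, 2], x = cent[, 3])
}

#' Sample sparse training labels from phantom truth
#'
#' Emulates the sparse interactive labeling used to train the pixel
#' classifier: synapse labels from the synapse sheets, membrane labels from
#' the membrane-like distractors, and "other" labels split between plain
#' background, mitochondrion interiors and vesicle speckle so the classifier
#' sees every confuser.
#'
#' @param phantom result of [generate_phantom()].
#' @param n_per_class labels per class.
#' @param seed sampling seed.
#' @return A [sparse_labels()] data frame on the native grid.
#' @export
sample_phantom_labels <- function(phantom, n_per_class = 200, seed = 1) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  shape <- dim(phantom$volume$data)
  truth <- phantom$truth
  syn_vox <- unlist(lapply(truth$synapses, `[[`, "voxels"))
  mem_vox <- unlist(lapply(truth$membranes, `[[`, "voxels"))
  mito_vox <- unlist(lapply(truth$mitos, `[[`, "voxels"))
  ves_vox <- truth$vesicles
  if (length(syn_vox) == 0 || length(mem_vox) == 0)
    stop("phantom must contain synapses and membrane distractors to label")
  pick <- function(vox, k) vox[sample.int(length(vox), min(k, length(vox)))]
  syn <- pick(syn_vox, n_per_class)
  mem <- pick(mem_vox, n_per_class)
  n_bg <- ceiling(n_per_class * 0.4)
  n_mito <- ceiling(n_per_class * 0.3)
  n_ves <- n_per_class - n_bg - n_mito
  # appositions are deliberately never offered as labels: like unmarked
  # structures in a real volume, the classifier only meets them at
  # prediction time
  app_vox <- unlist(lapply(truth$appositions, `[[`, "voxels"))
  taken <- c(syn_vox, mem_vox, mito_vox, ves_vox, app_vox)
  bg_pool <- setdiff(sample.int(prod(shape), 20 * n_bg), taken)
  other <- c(pick(bg_pool, n_bg),
             if (length(mito_vox) > 0) pick(mito_vox, n_mito),
             if (length(ves_vox) > 0) pick(ves_vox, n_ves))
  vox <- c(syn, mem, other)
  cls <- c(rep("synapse", length(syn)), rep("membrane", length(mem)),
           rep("other", length(other)))
  coords <- arrayInd(vox, shape)
  sparse_labels(coords[, 1], coords[, 2], coords[, 3], cls, shape)
}

#' Label candidates against phantom truth
#'
#' A candidate is a true synapse when a sufficient fraction of its voxels
#' overlaps a planted synapse mask.
#'
#' @param candidates candidate list (elements with `mask` and `box`).
#' @param truth phantom truth.
#' @param volume_shape `(nz, ny, nx)`.
#' @param min_overlap minimum fraction of candidate voxels on truth.
#' @return Logical vector, one per candidate.
#' @export
label_candidates_by_truth <- function(candidates, truth, volume_shape,
                                      min_overlap = 0.25) {
  syn_vox <- unlist(lapply(truth$synapses, `[[`, "voxels"))
  is_syn <- logical(prod(volume_shape))
  is_syn[syn_vox] <- TRUE
  vapply(candidates, function(cand) {
    idx <- which(cand$mask, arr.ind = TRUE)
    vox <- (idx[, 1] + cand$box[1]) +
      volume_shape[1] * ((idx[, 2] + cand$box[2] - 1) +
                           volume_shape[2] * (idx[, 3] + cand$box[3] - 1))
    mean(is_syn[vox]) >= min_overlap
  }, logical(1))
}

#' Phantom truth masks as candidate-like objects
#'
#' Packages annotated phantom structures as `mask`/`box` objects usable to
#' augment object-classifier training: distractors (membranes, appositions,
#' mitochondria) as negative examples and, with `types = "synapses"`, the
#' synapse masks as positives — the phantom counterpart of labeling
#' objects as synapse / not-a-synapse.
#'
#' @param truth phantom truth from [generate_phantom()].
#' @param volume_shape `(nz, ny, nx)`.
#' @param types which truth sets to include (default: the distractors).
#' @return List of objects with `mask` (logical crop) and `box` (0-based
#'   half-open).
#' @export
distractor_objects <- function(truth, volume_shape,
                               types = c("membranes", "appositions",
                                         "mitos")) {
  out <- list()
  for (ty in types) {
    for (obj in truth[[ty]]) {
      coords <- arrayInd(obj$voxels, volume_shape)
      box <- as.integer(c(min(coords[, 1]) - 1, min(coords[, 2]) - 1,
                          min(coords[, 3]) - 1,
                          max(coords[, 1]), max(coords[, 2]),
                          max(coords[, 3])))
      mask <- array(FALSE, box[4:6] - box[1:3])
      mask[cbind(coords[, 1] - box[1], coords[, 2] - box[2],
                 coords[, 3] - box[3])] <- TRUE
      out[[length(out) + 1]] <- list(mask = mask, box = box, type = ty)
    }
  }
  out
}

#' Generate a synthetic probability map with known truth
#'
#' Isolates segmentation-stage behavior from the classifier: synapse-class
#' probability is high (~0.9) on planted sheet-like objects and low
#' elsewhere, with optional adversarial structures — a thin moderately
#' bright protrusion attached to an object (the structure hysteresis
#' thresholding tends to keep and graph cut tends to remove) and an
#' under-threshold "bridge" between two objects.
#'
#' @param shape volume shape `(nz, ny, nx)`.
#' @param n_objects number of planted slab objects.
#' @param high mean probability on objects.
#' @param noise_sd background/object probability noise.
#' @param protrusion attach a thin protrusion (probability ~0.55) to the
#'   first object.
#' @param bridge connect the first two objects by a line of probability 0.4.
#' @param voxel_size voxel extent in nm `(z, y, x)`.
#' @param seed integer seed.
#' @return List with `prob` (a 3-class [probability_map()]), `truth` (list
#'   of logical masks), and index sets `protrusion_voxels`,
#'   `bridge_voxels` when requested.
#' @export
generate_probability_phantom <- function(shape = c(10, 80, 80),
                                         n_objects = 3,
                                         high = 0.9,
                                         noise_sd = 0.05,
                                         protrusion = FALSE,
                                         bridge = FALSE,
                                         voxel_size = c(45, 4.5, 4.5),
                                         seed = 1) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  p <- array(abs(stats::rnorm(prod(shape), 0.05, noise_sd)), shape)
  p[p > 0.99] <- 0.99
  truth <- list()
  centers <- list()
  for (i in seq_len(n_objects)) {
    for (try in 1:200) {
      sz <- c(sample(2:4, 1), sample(8:16, 1), sample(3:6, 1))
      z0 <- sample(seq_len(shape[1] - sz[1]), 1)
      y0 <- sample(seq_len(shape[2] - sz[2]), 1)
      x0 <- sample(seq_len(shape[3] - sz[3]), 1)
      m <- array(FALSE, shape)
      m[z0:(z0 + sz[1] - 1), y0:(y0 + sz[2] - 1), x0:(x0 + sz[3] - 1)] <- TRUE
      clash <- FALSE
      for (t2 in truth) if (any(t2 & m)) { clash <- TRUE; break }
      # also keep a 2-voxel clearance so objects stay separate components
      if (!clash && length(truth) > 0) {
        grown <- array(FALSE, shape)
        gz <- max(1, z0 - 2):min(shape[1], z0 + sz[1] + 1)
        gy <- max(1, y0 - 2):min(shape[2], y0 + sz[2] + 1)
        gx <- max(1, x0 - 2):min(shape[3], x0 + sz[3] + 1)
        grown[gz, gy, gx] <- TRUE
        for (t2 in truth) if (any(t2 & grown)) { clash <- TRUE; break }
      }
      if (!clash) {
        truth[[i]] <- m
        centers[[i]] <- c(z0 + sz[1] %/% 2, y0 + sz[2] %/% 2,
                          x0 + sz[3] %/% 2)
        p[m] <- pmin(0.99, pmax(0.02, high + stats::rnorm(sum(m), 0, noise_sd)))
        break
      }
    }
  }
  protrusion_voxels <- integer(0)
  if (protrusion && length(truth) >= 1) {
    c1 <- centers[[1]]
    len <- min(20L, shape[3] - c1[3] - 1L)
    xs <- (c1[3] + 1):(c1[3] + len)
    xs <- xs[!truth[[1]][c1[1], c1[2], xs]]
    p[c1[1], c1[2], xs] <- 0.55
    protrusion_voxels <- c1[1] + shape[1] * ((c1[2] - 1) + shape[2] * (xs - 1))
  }
  bridge_voxels <- integer(0)
  if (bridge && length(truth) >= 2) {
    c1 <- centers[[1]]; c2 <- centers[[2]]
    steps <- 40
    tt <- seq(0, 1, length.out = steps)
    zz <- round(c1[1] + tt * (c2[1] - c1[1]))
    yy <- round(c1[2] + tt * (c2[2] - c1[2]))
    xx <- round(c1[3] + tt * (c2[3] - c1[3]))
    vox <- unique(zz + shape[1] * ((yy - 1) + shape[2] * (xx - 1)))
    on_truth <- truth[[1]][vox] | truth[[2]][vox]
    vox <- vox[!on_truth]
    p[vox] <- 0.4
    bridge_voxels <- vox
  }
  pm <- array(0, c(3L, shape))
  pm[1, , , ] <- p
  pm[2, , , ] <- 0
  pm[3, , , ] <- 1 - p
  list(prob = probability_map(pm, c("synapse", "membrane", "other"),
                              voxel_size),
       truth = truth,
       protrusion_voxels = protrusion_voxels,
       bridge_voxels = bridge_voxels)
}
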