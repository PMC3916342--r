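test_that("object neighborhood follows the anisotropic ellipsoid bound", {
  m <- array(FALSE, c(3, 9, 9)); m[2, 5, 5] <- TRUE
  expect_false(any(object_neighborhood(m, c(0, 0, 0))))

  nb <- object_neighborhood(m, c(1, 1, 0))
  expect_identical(sum(nb), 4L)            # in-slice 4-neighbors only
  expect_true(all(which(nb, arr.ind = TRUE)[, 1] == 2))

  nb2 <- object_neighborhood(m, c(2, 2, 1))
  expect_false(any(nb2 & m))               # object always excluded
  expect_identical(sum(nb2[1, , ]), 1L)    # adjacent slice: directly above
  expect_identical(sum(nb2[2, , ]), 12L)   # radius-2 disc minus center
  expect_error(object_neighborhood(array(FALSE, c(2, 2, 2))), "empty")
})

test_that("summary statistics match direct formulas and degrade gracefully", {
  expect_equal(unname(summary_statistics(c(0, 0, 0, 1))["mean"]), 0.25)

  set.seed(1)
  x <- rnorm(300, 2, 3)
  s <- summary_statistics(x)
  m2 <- mean((x - mean(x))^2)
  expect_equal(unname(s["mean"]), mean(x))
  expect_equal(unname(s["variance"]), var(x))
  expect_equal(unname(s["skewness"]), mean((x - mean(x))^3) / m2^1.5)
  expect_equal(unname(s["kurtosis"]), mean((x - mean(x))^4) / m2^2)

  expect_warning(sc <- summary_statistics(rep(4, 10)), "zero variance")
  expect_equal(unname(sc), c(4, 0, 0, 0))
  expect_warning(s1 <- summary_statistics(5), "fewer than 2")
  expect_equal(unname(s1), c(5, 0, 0, 0))
})

test_that("blockwise moment accumulation merges exactly", {
  set.seed(2)
  x <- rnorm(1000, -1, 2)
  whole <- summary_statistics(x)
  parts <- split(x, rep(1:4, each = 250))
  acc <- Reduce(moment_merge, lapply(parts, moment_accumulate))
  merged <- emsynapse:::moment_statistics(acc)
  expect_equal(merged, whole, tolerance = 1e-9)
})

test_that("uniform LBP histograms have 10 bins and known fixtures", {
  cst <- array(5, c(2, 6, 6))
  h <- lbp_histogram(cst, array(TRUE, dim(cst)))
  expect_length(h, 10)
  expect_equal(sum(h), 1)
  expect_identical(which(h > 0), 9L)  # all-ones code (ties count as >=)

  # single bright center in a 3x3 slice: center sees all-darker neighbors
  # (code 0), every other pixel sees only >= neighbors (code 8)
  img <- array(0, c(1, 3, 3)); img[1, 2, 2] <- 1
  h2 <- lbp_histogram(img, array(TRUE, dim(img)))
  expect_equal(h2[1], 1 / 9)
  expect_equal(h2[9], 8 / 9)

  set.seed(3)
  noisy <- array(rnorm(4 * 8 * 8), c(4, 8, 8))
  h3 <- lbp_histogram(noisy, noisy > -10)
  expect_equal(sum(h3), 1)
  expect_true(all(h3 >= 0))
  expect_warning(he <- lbp_histogram(noisy, noisy > 10), "empty")
  expect_equal(he, numeric(10))
})

test_that("principal-component ratio reflects shape anisotropy", {
  cube <- array(TRUE, c(5, 5, 5))
  expect_equal(principal_component_ratio(cube, c(1, 1, 1)), 1,
               tolerance = 1e-9)

  line <- function(n) {
    m <- array(FALSE, c(1, 1, n)); m[1, 1, ] <- TRUE; m
  }
  r10 <- principal_component_ratio(line(10), c(1, 1, 1))
  r20 <- principal_component_ratio(line(20), c(1, 1, 1))
  expect_gt(r10, 1e6)          # epsilon-floored, very large
  expect_gt(r20, r10)          # monotone in length

  # axis permutation invariance under isotropic scaling
  set.seed(4)
  m <- array(runif(4 * 5 * 6) > 0.5, c(4, 5, 6))
  expect_equal(principal_component_ratio(m, c(2, 2, 2)),
               principal_component_ratio(aperm(m, c(3, 1, 2)), c(2, 2, 2)))

  two <- array(FALSE, c(2, 2, 2)); two[1:2] <- TRUE
  expect_warning(r <- principal_component_ratio(two, c(1, 1, 1)), "3 voxels")
  expect_equal(r, 0)
})

test_that("object feature vector has 29 stable, context-sensitive entries", {
  set.seed(5)
  vol <- anisotropic_volume(array(runif(8 * 40 * 40, 0.4, 0.8), c(8, 40, 40)),
                            c(45, 4.5, 4.5))
  mask <- array(FALSE, c(8, 40, 40))
  mask[4:5, 18:24, 18:24] <- TRUE
  fv <- compute_object_features(vol, mask)
  expect_length(fv, 29)
  expect_identical(names(fv), emsynapse:::OBJECT_FEATURE_NAMES)
  expect_identical(fv, compute_object_features(vol, mask))  # deterministic

  # same object, different surround: neighborhood features change
  vol2 <- vol
  vol2$data[mask] <- vol$data[mask]  # object untouched
  ring <- array(FALSE, dim(mask)); ring[3:6, 10:32, 10:32] <- TRUE
  vol2$data[ring & !mask] <- 0.1
  fv2 <- compute_object_features(vol2, mask)
  expect_equal(unname(fv["mean"]), unname(fv2["mean"]))
  expect_false(isTRUE(all.equal(fv["nbh_mean"], fv2["nbh_mean"])))

  # constant volume: degenerate statistics, LBP mass in one bin
  cvol <- anisotropic_volume(array(0.5, c(6, 30, 30)), c(45, 4.5, 4.5))
  cmask <- array(FALSE, c(6, 30, 30)); cmask[3:4, 12:18, 12:18] <- TRUE
  w <- capture_warnings(cf <- compute_object_features(cvol, cmask))
  expect_true(any(grepl("zero variance", w)))  # object and neighborhood
  expect_equal(unname(cf["variance"]), 0)
  expect_equal(unname(cf["skewness"]), 0)
  expect_identical(which(cf[9:18] > 0), c(lbp_8 = 9L))
})

test_that("disjoint candidates are processed independently", {
  set.seed(6)
  vol <- anisotropic_volume(array(runif(6 * 60 * 60), c(6, 60, 60)),
                            c(45, 4.5, 4.5))
  m1 <- array(FALSE, dim(vol$data)); m1[2:3, 5:12, 5:12] <- TRUE
  m2 <- array(FALSE, dim(vol$data)); m2[4:5, 45:52, 45:52] <- TRUE
  a1 <- compute_object_features(vol, m1)
  b1 <- compute_object_features(vol, m2)
  b2 <- compute_object_features(vol, m2)  # other order
  a2 <- compute_object_features(vol, m1)
  expect_identical(a1, a2)
  expect_identical(b1, b2)
})
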