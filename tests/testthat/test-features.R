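test_that("default filter bank yields exactly 26 uniquely named channels", {
  v <- anisotropic_volume(array(rnorm(6 * 10 * 10), c(6, 10, 10)),
                          c(22.5, 4.5, 4.5))
  fs <- compute_feature_stack(v)
  expect_identical(dim(fs$data)[1], 26L)
  expect_length(fs$channel_names, 26)
  expect_false(anyDuplicated(fs$channel_names) > 0)
  # family cardinalities: 6*1 + 4*3 + 3*1 + 2*1 + 1*3
  expect_length(grep("^gaussian@", fs$channel_names), 6)
  expect_length(grep("^hessian@", fs$channel_names), 12)
  expect_length(grep("^log@", fs$channel_names), 3)
  expect_length(grep("^dog@", fs$channel_names), 2)
  expect_length(grep("^st@", fs$channel_names), 3)

  only_gauss <- feature_config(hessian = numeric(0), log = numeric(0),
                               dog = numeric(0), structure_tensor = numeric(0))
  expect_identical(dim(compute_feature_stack(v, only_gauss)$data)[1], 6L)
  expect_error(feature_config(gaussian = numeric(0), hessian = numeric(0),
                              log = numeric(0), dog = numeric(0),
                              structure_tensor = numeric(0)),
               "at least one")
  expect_error(feature_config(gaussian = c(1, -2)), "positive")
})

test_that("smoothing preserves constants, ramps and unit mass", {
  cst <- array(3.7, c(8, 10, 10))
  expect_equal(gaussian_smoothing(cst, 2), cst)
  expect_error(gaussian_smoothing(cst, 0), "sigma")

  ramp <- array(rep(seq_len(24), each = 10 * 10) * 0.5, c(10, 10, 24))
  sm <- gaussian_smoothing(ramp, 1.5)  # ramp runs along x (3rd axis)
  expect_lt(max(abs((sm - ramp)[, , 8:17])), 1e-10)

  imp <- array(0, c(11, 11, 11)); imp[6, 6, 6] <- 1
  expect_equal(sum(gaussian_smoothing(imp, 1)), 1)
})

test_that("Hessian eigenvalues match the analytic quadratic and stay sorted", {
  d <- c(17, 17, 17)
  co <- expand.grid(z = 1:17, y = 1:17, x = 1:17)
  q <- array(-((co$z - 9)^2 + (co$y - 9)^2 + (co$x - 9)^2), d)
  ev <- hessian_eigenvalues(q * 1.0, 1.0)
  expect_equal(as.numeric(ev[, 9, 9, 9]), c(-2, -2, -2), tolerance = 1e-8)
  # finite-difference oracle on the smoothed volume, center voxel
  smq <- gaussian_smoothing(q * 1.0, 1.0)
  fd_xx <- smq[9, 9, 10] - 2 * smq[9, 9, 9] + smq[9, 9, 8]
  expect_equal(sum(ev[, 9, 9, 9]), 3 * fd_xx, tolerance = 1e-6)

  set.seed(3)
  a <- array(rnorm(6 * 8 * 8), c(6, 8, 8))
  eva <- hessian_eigenvalues(a, 2)
  expect_true(all(eva[1, , , ] >= eva[2, , , ]))
  expect_true(all(eva[2, , , ] >= eva[3, , , ]))
  expect_equal(hessian_eigenvalues(array(5, c(4, 4, 4)), 1.6),
               array(0, c(3, 4, 4, 4)))
})

test_that("Laplacian equals the Hessian trace and vanishes on ramps", {
  set.seed(4)
  a <- array(rnorm(8 * 9 * 9), c(8, 9, 9))
  lg <- laplacian_of_gaussian(a, 2)
  ev <- hessian_eigenvalues(a, 2)
  expect_lt(max(abs(lg - (ev[1, , , ] + ev[2, , , ] + ev[3, , , ]))), 1e-6)
  expect_equal(laplacian_of_gaussian(array(2, c(4, 4, 4)), 3.5),
               array(0, c(4, 4, 4)))
  ramp <- array(rep(1:12, each = 36), c(6, 6, 12))
  expect_lt(max(abs(laplacian_of_gaussian(ramp * 1.0, 1)[, , 5:8])), 1e-9)
})

test_that("difference of Gaussians matches its definition", {
  set.seed(5)
  a <- array(rnorm(6 * 8 * 8), c(6, 8, 8))
  expect_lt(max(abs(difference_of_gaussians(a, 3) -
                      (gaussian_smoothing(a, 3) -
                         gaussian_smoothing(a, 0.66 * 3)))), 1e-12)
  expect_equal(difference_of_gaussians(array(1, c(4, 4, 4)), 5),
               array(0, c(4, 4, 4)))
  # narrower Gaussian has the larger central peak
  imp <- array(0, c(15, 15, 15)); imp[8, 8, 8] <- 1
  expect_lt(difference_of_gaussians(imp, 2)[8, 8, 8], 0)
})

test_that("structure tensor is positive semidefinite and orientation-selective", {
  expect_equal(structure_tensor_eigenvalues(array(4, c(5, 5, 5)), 2),
               array(0, c(3, 5, 5, 5)))
  set.seed(6)
  a <- array(rnorm(6 * 10 * 10), c(6, 10, 10))
  ev <- structure_tensor_eigenvalues(a, 3)
  expect_gte(min(ev), -1e-9)
  # ramp along x only: one dominant eigenvalue in the interior
  ramp <- array(rep(1:24, each = 100) * 1.0, c(10, 10, 24))
  evr <- structure_tensor_eigenvalues(ramp, 4)
  expect_gt(evr[1, 5, 5, 12], 0.5)
  expect_lt(abs(evr[2, 5, 5, 12]), 1e-8)
  expect_lt(abs(evr[3, 5, 5, 12]), 1e-8)
})

test_that("feature computation is deterministic with stable channel order", {
  set.seed(7)
  v1 <- anisotropic_volume(array(rnorm(5 * 8 * 8), c(5, 8, 8)),
                           c(22.5, 4.5, 4.5))
  v2 <- anisotropic_volume(array(rnorm(5 * 8 * 8), c(5, 8, 8)),
                           c(22.5, 4.5, 4.5))
  fs1a <- compute_feature_stack(v1)
  fs1b <- compute_feature_stack(v1)
  expect_identical(fs1a$data, fs1b$data)
  expect_identical(fs1a$channel_names, compute_feature_stack(v2)$channel_names)
})
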