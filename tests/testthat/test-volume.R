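test_that("TIFF I/O round-trips integer grayscale bit-exactly", {
  set.seed(1)
  a <- array(sample(0:255, 2 * 4 * 4, TRUE), c(2, 4, 4))
  v <- anisotropic_volume(a, c(45, 4.5, 4.5))
  path <- tempfile(fileext = ".tif")
  write_volume(v, path, bits = 8)
  v2 <- read_volume(path, c(45, 4.5, 4.5))
  expect_identical(dim(v2$data), c(2L, 4L, 4L))
  expect_equal(v2$data, v$data)

  a16 <- array(sample(0:65535, 3 * 5 * 6, TRUE), c(3, 5, 6))
  path16 <- tempfile(fileext = ".tif")
  write_volume(anisotropic_volume(a16, c(45, 4.5, 4.5)), path16, bits = 16)
  expect_equal(read_volume(path16, c(45, 4.5, 4.5))$data, a16 * 1.0)

  zeros <- anisotropic_volume(array(0, c(2, 4, 4)), c(45, 4.5, 4.5))
  pz <- tempfile(fileext = ".tif")
  write_volume(zeros, pz)
  expect_true(all(read_volume(pz, c(45, 4.5, 4.5))$data == 0))
})

test_that("volume reading rejects unreadable or non-grayscale input", {
  expect_error(read_volume(tempfile(), c(45, 4.5, 4.5)), "cannot read")
  rgb <- array(runif(4 * 4 * 3), c(4, 4, 3))
  path <- tempfile(fileext = ".tif")
  tiff::writeTIFF(rgb, path)
  expect_error(read_volume(path, c(45, 4.5, 4.5)), "format error")
})

test_that("volume container enforces its invariants", {
  expect_error(anisotropic_volume(array(0, c(2, 2)), c(45, 4.5, 4.5)), "3D")
  expect_error(anisotropic_volume(array(0, c(2, 2, 2)), c(0, 4.5, 4.5)),
               "positive")
  expect_error(probability_map(array(0.4, c(3, 2, 2, 2)),
                               c("synapse", "membrane", "other"),
                               c(45, 4.5, 4.5)),
               "sum to 1")
})

test_that("z-upsampling is edge-aligned linear interpolation", {
  a <- array(rep(c(0, 10, 20), 4), c(3, 2, 2))
  v <- anisotropic_volume(a, c(45, 4, 4))
  expect_identical(upsample_z(v, 1), v)
  u <- upsample_z(v, 2)
  expect_identical(dim(u$data)[1], 5L)
  expect_equal(u$data[c(1, 3, 5), , ], v$data)     # originals survive
  expect_true(all(u$data[2, , ] == 5))             # linear midpoint
  expect_true(all(u$data[4, , ] == 15))
  expect_equal(u$voxel_size, c(22.5, 4, 4))
  expect_error(upsample_z(v, 0), "factor")
})

test_that("z-downsampling inverts upsampling on original slices", {
  set.seed(2)
  v <- anisotropic_volume(array(runif(4 * 3 * 3), c(4, 3, 3)), c(45, 4, 4))
  rt <- downsample_z(upsample_z(v, 3), 3)
  expect_equal(rt$data, v$data)
  expect_equal(rt$voxel_size, v$voxel_size)

  pm <- array(runif(3 * 5 * 2 * 2, 0.2, 0.4), c(3, 5, 2, 2))
  pm <- sweep(pm, 2:4, colSums(pm, dims = 1), "/")
  p <- probability_map(pm, c("synapse", "membrane", "other"), c(22.5, 4, 4))
  dp <- downsample_z(p, 2)
  expect_identical(dim(dp$data)[2], 3L)
  expect_equal(dp$data, pm[, c(1, 3, 5), , , drop = FALSE])
  expect_equal(dp$voxel_size[1], 45)
  expect_equal(downsample_z(p, 1)$data, p$data)
})
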