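make_prob <- function(p3d) {
  d <- dim(p3d)
  a <- array(0, c(3, d))
  a[1, , , ] <- p3d
  a[3, , , ] <- 1 - p3d
  probability_map(a, c("synapse", "membrane", "other"), c(45, 4.5, 4.5))
}

test_that("probability thresholding is strict and monotone", {
  p <- make_prob(array(0, c(2, 3, 3)))
  expect_false(any(threshold_probability(p)))

  p2 <- make_prob(array(0.5, c(2, 2, 2)))
  expect_false(any(threshold_probability(p2, 0.5)))  # exactly t excluded

  set.seed(1)
  pr <- array(runif(4 * 6 * 6), c(4, 6, 6))
  p3 <- make_prob(pr)
  m4 <- threshold_probability(p3, 0.4)
  m6 <- threshold_probability(p3, 0.6)
  expect_true(all(m4 | !m6))  # raising t never adds voxels
  # complement symmetry with the <= mask
  expect_identical(threshold_probability(p3, 0.3), !(pr <= 0.3))
  expect_error(threshold_probability(p3, 0), "between")
})

test_that("connected components respect connectivity and partition voxels", {
  m <- array(FALSE, c(1, 2, 2))
  m[1, 1, 1] <- TRUE; m[1, 2, 2] <- TRUE  # share only a corner
  expect_identical(nrow(connected_components(m, 26)$table), 1L)
  expect_identical(nrow(connected_components(m, 6)$table), 2L)

  empty <- connected_components(array(FALSE, c(2, 3, 3)))
  expect_identical(nrow(empty$table), 0L)

  set.seed(2)
  m2 <- array(runif(5 * 8 * 8) > 0.6, c(5, 8, 8))
  cc <- connected_components(m2, 6)
  expect_identical(sum(cc$table$voxel_count), sum(m2))
  # bounding boxes contain their components
  for (i in seq_len(nrow(cc$table))) {
    idx <- which(cc$labels == cc$table$component_id[i], arr.ind = TRUE)
    expect_true(all(idx[, 1] > cc$table$z0[i] & idx[, 1] <= cc$table$z1[i]))
    expect_true(all(idx[, 3] > cc$table$x0[i] & idx[, 3] <= cc$table$x1[i]))
  }
})

test_that("size filter keeps inclusive bounds", {
  tab <- data.frame(component_id = 1:4,
                    voxel_count = c(99, 100, 1000000, 1000001),
                    z0 = 0, y0 = 0, x0 = 0, z1 = 1, y1 = 1, x1 = 1)
  kept <- filter_components_by_size(tab)
  expect_identical(kept$voxel_count, c(100, 1000000))
  expect_identical(nrow(filter_components_by_size(tab[0, ])), 0L)
  expect_identical(filter_components_by_size(tab, 1, Inf), tab)
  expect_error(filter_components_by_size(tab, 10, 5), "<=")
})

test_that("box enlargement converts the 500 nm halo per axis and clips", {
  tab <- data.frame(component_id = 1L, voxel_count = 500L,
                    z0 = 10L, y0 = 200L, x0 = 200L,
                    z1 = 12L, y1 = 220L, x1 = 230L)
  out <- enlarge_bounding_boxes(tab, 500, c(45, 4.5, 4.5), c(40, 800, 800))
  expect_identical(out$ez0, 10L - 12L + 2L)   # ceil(500/45) = 12
  expect_identical(out$ez1, 12L + 12L)
  expect_identical(out$ey0, 200L - 112L)      # ceil(500/4.5) = 112
  expect_identical(out$ex1, 230L + 112L)

  zero <- enlarge_bounding_boxes(tab, 0, c(45, 4.5, 4.5), c(40, 800, 800))
  expect_identical(zero$ez0, tab$z0)
  expect_identical(zero$ex1, tab$x1)

  edge <- data.frame(component_id = 1L, voxel_count = 5L,
                     z0 = 0L, y0 = 0L, x0 = 790L,
                     z1 = 2L, y1 = 5L, x1 = 800L)
  oe <- enlarge_bounding_boxes(edge, 500, c(45, 4.5, 4.5), c(40, 800, 800))
  expect_identical(oe$ez0, 0L)
  expect_identical(oe$ex1, 800L)
})
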