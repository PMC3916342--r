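cand_from_mask <- function(mask, box = c(0L, 0L, 0L, dim(mask))) {
  list(mask = mask, box = as.integer(box))
}

test_that("matching is one-to-one, greedy by distance, and conserves counts", {
  vs <- c(45, 4.5, 4.5)
  m <- array(FALSE, c(4, 10, 10)); m[2, 4:6, 4:6] <- TRUE
  cand <- cand_from_mask(m)
  gt_in <- data.frame(z = 2, y = 5, x = 5)
  rep1 <- match_detections(list(cand), gt_in, vs, tolerance_nm = 0)
  expect_identical(rep1$n_fn, 0L)
  expect_identical(rep1$n_fp, 0L)

  rep0 <- match_detections(list(), gt_in, vs)
  expect_identical(rep0$n_fn, 1L)
  expect_identical(rep0$n_fp, 0L)

  gt2 <- data.frame(z = c(2, 2), y = c(5, 6), x = c(5, 6))
  rep2 <- match_detections(list(cand), gt2, vs)
  expect_identical(sum(!is.na(rep2$matches)), 1L)
  expect_identical(rep2$n_fn, 1L)
  expect_identical(rep2$n_fn + sum(!is.na(rep2$matches)), rep2$n_gt)

  # reordering candidates cannot change the counts
  m2 <- array(FALSE, c(4, 10, 10)); m2[3, 8, 8] <- TRUE
  ra <- match_detections(list(cand, cand_from_mask(m2)), gt2, vs)
  rb <- match_detections(list(cand_from_mask(m2), cand), gt2, vs)
  expect_identical(ra$n_fn, rb$n_fn)
  expect_identical(ra$n_fp, rb$n_fp)
})

test_that("error rates normalize both error types by the GT count", {
  er <- error_rates(list(n_fn = 28, n_fp = 16, n_gt = 238))
  expect_equal(unname(er["fn_fraction"]), 28 / 238)
  expect_equal(unname(er["fp_fraction"]), 16 / 238)
  expect_equal(round(100 * er[["fn_fraction"]], 1), 11.8)
  expect_equal(round(100 * er[["fp_fraction"]]), 7)
  expect_equal(unname(error_rates(list(n_fn = 0, n_fp = 0, n_gt = 5))),
               c(0, 0))
  expect_error(error_rates(list(n_fn = 0, n_fp = 0, n_gt = 0)), "undefined")
})

test_that("mean cross-section area uses the 5 central slices", {
  const <- array(FALSE, c(7, 10, 10))
  for (z in 1:7) const[z, 1:2, 1:5] <- TRUE      # 10 voxels per slice
  expect_equal(mean_xy_area(const), 10)

  single <- array(FALSE, c(3, 10, 10)); single[2, 1:5, 1:5] <- TRUE
  expect_equal(mean_xy_area(single), 25)

  ramp <- array(FALSE, c(7, 20, 20))
  sizes <- c(2, 4, 6, 8, 10, 12, 14)
  for (z in 1:7) ramp[z, 1, seq_len(sizes[z])] <- TRUE
  expect_equal(mean_xy_area(ramp), 8)            # central five: 4..12
  expect_error(mean_xy_area(array(FALSE, c(2, 2, 2))), "empty")
})

test_that("z-range counts occupied slices, not the span", {
  single <- array(FALSE, c(5, 4, 4)); single[3, 2, 2] <- TRUE
  expect_identical(z_range(single), 1L)

  gaps <- array(FALSE, c(8, 4, 4))
  gaps[c(3, 4, 7), 2, 2] <- TRUE
  expect_identical(z_range(gaps), 3L)            # occupancy, not 5
  bb_extent <- diff(range(which(apply(gaps, 1, any)))) + 1L
  expect_lte(z_range(gaps), bb_extent)
})

test_that("skeleton size scales with voxel size and slice count", {
  line <- array(FALSE, c(1, 3, 12)); line[1, 2, 2:11] <- TRUE
  px <- skeleton_size(line, c(45, 4.5, 4.5)) / (4.5 * 45)
  expect_lte(abs(px - 10), 1)                    # medial axis of a line

  expect_equal(skeleton_size(line, c(45, 9, 9)),
               2 * skeleton_size(line, c(45, 4.5, 4.5)))

  multi <- array(FALSE, c(3, 3, 12))
  for (z in 1:3) multi[z, 2, 2:11] <- TRUE
  expect_equal(skeleton_size(multi, c(45, 4.5, 4.5)),
               3 * skeleton_size(line, c(45, 4.5, 4.5)))
  expect_error(skeleton_size(array(FALSE, c(1, 2, 2)), c(45, 4.5, 4.5)),
               "empty")
})

test_that("perforation counts slices split into exactly two pieces", {
  solid <- array(FALSE, c(4, 8, 8)); solid[2:3, 3:6, 3:6] <- TRUE
  expect_identical(perforation_count(solid), 0L)

  split2 <- array(FALSE, c(5, 8, 8))
  for (z in 2:4) { split2[z, 2:3, 2:3] <- TRUE; split2[z, 6:7, 6:7] <- TRUE }
  expect_identical(perforation_count(split2), 3L)

  split3 <- array(FALSE, c(1, 12, 12))
  split3[1, 1:2, 1:2] <- TRUE; split3[1, 6:7, 6:7] <- TRUE
  split3[1, 11:12, 11:12] <- TRUE
  expect_identical(perforation_count(split3), 0L)   # three pieces: excluded
  expect_identical(perforation_count(split3, at_least_two = TRUE), 1L)
})

test_that("morphometrics table aggregates per candidate", {
  m <- array(FALSE, c(4, 10, 10)); m[2:3, 3:6, 3:6] <- TRUE
  tab <- morphometrics_table(list(cand_from_mask(m)), c(45, 4.5, 4.5))
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$voxel_count, sum(m))
  expect_identical(tab$z_range, 2L)
})
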