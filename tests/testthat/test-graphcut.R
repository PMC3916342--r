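test_that("Ising energy matches hand evaluation and a per-term oracle", {
  p0 <- array(0, c(2, 2, 2))
  expect_equal(ising_energy(array(0L, c(2, 2, 2)), p0, 0.5), 0)

  # 1x1x2 crop, p = (1, 0), labels (synapse, background): unary 0, one cut
  p <- array(c(1, 0), c(1, 1, 2))
  L <- array(c(1L, 0L), c(1, 1, 2))
  expect_equal(ising_energy(L, p, 0.7), 0.7)

  set.seed(1)
  for (i in 1:10) {
    d <- c(sample(1:3, 1), sample(1:3, 1), sample(1:3, 1))
    pr <- array(runif(prod(d)), d)
    Lr <- array(sample(0:1, prod(d), TRUE), d)
    b <- runif(1, 0, 2)
    expect_equal(ising_energy(Lr, pr, b), ising_energy_slow(Lr, pr, b))
  }
  expect_error(ising_energy(L, p, -1), "nonnegative")
})

test_that("graph cut reaches the exhaustive minimum on tiny crops", {
  set.seed(2)
  for (i in 1:60) {
    d <- c(sample(1:2, 1), sample(1:2, 1), sample(1:3, 1))
    p <- array(sample(seq(0, 1, 0.1), prod(d), TRUE), d)
    beta <- sample(c(0, 0.2, 0.5, 1), 1)
    seg <- segment_graphcut(p, beta)
    expect_equal(ising_energy(seg, p, beta), enumerate_ising_min(p, beta),
                 tolerance = 1e-9)
  }
})

test_that("graph cut limits: threshold at beta 0, flooding at large beta", {
  set.seed(3)
  p <- array(runif(5 * 6 * 6), c(5, 6, 6))
  expect_identical(segment_graphcut(p, 0), p > 0.5)
  p[2, 3, 3] <- 0.5                       # tie goes to background
  expect_false(segment_graphcut(p, 0)[2, 3, 3])

  lo <- array(runif(60, 0, 0.45), c(3, 4, 5)); lo[1:4] <- 0.9
  expect_false(any(segment_graphcut(lo, 1000)))   # background wins overall
  hi <- array(runif(60, 0.55, 1), c(3, 4, 5)); hi[1:4] <- 0.1
  expect_true(all(segment_graphcut(hi, 1000)))    # synapse wins overall
  expect_error(segment_graphcut(array(0.5, c(0, 2, 2)), 0.1), "empty")
  expect_error(segment_graphcut(p, -0.1), "nonnegative")
})

test_that("graph cut energy certifies optimality against random proposals", {
  set.seed(4)
  p <- array(runif(4 * 7 * 7), c(4, 7, 7))
  beta <- 0.4
  seg <- segment_graphcut(p, beta)
  e <- ising_energy(seg, p, beta)
  for (i in 1:50) {
    prop <- array(sample(0:1, length(p), TRUE), dim(p))
    expect_lte(e, ising_energy(prop, p, beta) + 1e-12)
  }
})

test_that("graph cut agrees with an independent min-cut solver", {
  set.seed(5)
  for (i in 1:4) {
    d <- c(3, 5, 5)
    p <- array(runif(prod(d)), d)
    beta <- runif(1, 0.05, 0.8)
    seg <- segment_graphcut(p, beta)
    # igraph max-flow value equals the minimal energy by duality
    n <- prod(d)
    idx <- array(seq_len(n), d)
    el <- rbind(cbind(as.vector(idx[-d[1], , ]), as.vector(idx[-1, , ])),
                cbind(as.vector(idx[, -d[2], ]), as.vector(idx[, -1, ])),
                cbind(as.vector(idx[, , -d[3]]), as.vector(idx[, , -1])))
    edges <- rbind(el, el[, 2:1],
                   cbind(rep(n + 1L, n), 1:n), cbind(1:n, rep(n + 2L, n)))
    caps <- c(rep(beta, 2 * nrow(el)), 2 * as.numeric(p), 2 * (1 - as.numeric(p)))
    g <- igraph::graph_from_edgelist(edges, directed = TRUE)
    val <- igraph::max_flow(g, n + 1L, n + 2L, capacity = caps)$value
    expect_equal(ising_energy(seg, p, beta), val, tolerance = 1e-9)
  }
})

test_that("graph cut is deterministic and padding-invariant", {
  set.seed(6)
  p <- array(runif(3 * 6 * 6), c(3, 6, 6))
  expect_identical(segment_graphcut(p, 0.3), segment_graphcut(p, 0.3))

  # padding with zero-probability voxels leaves an interior optimum
  # untouched (a low-probability margin keeps the foreground off the crop
  # boundary, where extra background neighbors could otherwise bite)
  q <- array(runif(4 * 8 * 8, 0, 0.2), c(4, 8, 8))
  q[2:3, 3:6, 3:6] <- runif(2 * 4 * 4, 0.7, 0.95)
  padded <- array(0, c(4, 12, 12))
  padded[, 3:10, 3:10] <- q
  segp <- segment_graphcut(padded, 0.3)
  expect_identical(segp[, 3:10, 3:10], segment_graphcut(q, 0.3))
  expect_false(any(segp[, c(1, 2, 11, 12), ]))
})

test_that("hysteresis thresholding follows its set definition", {
  p <- array(0, c(2, 8, 8))
  p[1, 2:4, 2:4] <- 0.7          # seeded component
  p[1, 2:4, 5:7] <- 0.4          # connected extension above low
  p[2, 6:7, 6:7] <- 0.45         # isolated, never above high
  m <- segment_hysteresis(p, high = 0.5, low = 0.3)
  expect_true(all(m[1, 2:4, 2:7]))
  expect_false(any(m[2, , ]))

  set.seed(7)
  pr <- array(runif(3 * 6 * 6), c(3, 6, 6))
  expect_identical(segment_hysteresis(pr, 0.5, 0.5),
                   pr > 0.5)      # degenerate low == high
  m2 <- segment_hysteresis(pr, 0.5, 0.2)
  m3 <- segment_hysteresis(pr, 0.5, 0.35)
  expect_true(all(m2 | !m3))      # monotone nonincreasing in low
  expect_error(segment_hysteresis(pr, 0.4, 0.6), "low")
})

test_that("Jaccard index counts overlaps", {
  a <- array(FALSE, c(2, 3, 3)); a[1, 1:2, 1] <- TRUE
  expect_equal(jaccard(a, a), 1)
  b <- array(FALSE, c(2, 3, 3)); b[2, 3, 3] <- TRUE
  expect_equal(jaccard(a, b), 0)
  x <- array(FALSE, c(2, 2, 2)); x[1:4] <- TRUE
  y <- array(FALSE, c(2, 2, 2)); y[3:8] <- TRUE
  expect_equal(jaccard(x, y), 2 / 8)
  expect_equal(jaccard(b & FALSE, b & FALSE), 1)
  expect_error(jaccard(a, array(FALSE, c(1, 3, 3))), "mismatch")
})

test_that("beta calibration maximizes mean Jaccard with ties to smallest", {
  set.seed(8)
  crop <- array(runif(4 * 6 * 6), c(4, 6, 6))
  expect_equal(calibrate_beta(list(crop), list(crop > 0.5), 0.7), 0.7)
  # reference equal to the beta = 0 segmentation, 0 in grid
  expect_equal(calibrate_beta(list(crop), list(segment_graphcut(crop, 0)),
                              c(0, 0.2, 0.5)), 0)
  expect_error(calibrate_beta(list(), list(), 1), "pair")
  expect_error(calibrate_beta(list(crop), list(crop[1, , , drop = FALSE] > 0.5),
                              1), "mismatch")
})
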