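# a compact spec keeps unit tests fast; the default spec is exercised by
# the end-to-end acceptance checks
small_spec <- function(seed = 1, n_synapses = 4)
  phantom_spec(shape = c(22, 160, 160), n_synapses = n_synapses,
               extent_nm = c(150, 350), n_mito = 0, n_membrane = 3,
               n_apposition = 2, n_clutter = 80, seed = seed)

test_that("phantom generation is deterministic and honors its spec", {
  ph1 <- generate_phantom(small_spec())
  ph2 <- generate_phantom(small_spec())
  expect_identical(ph1$volume$data, ph2$volume$data)
  expect_identical(lapply(ph1$truth$synapses, `[[`, "voxels"),
                   lapply(ph2$truth$synapses, `[[`, "voxels"))
  expect_length(ph1$truth$synapses, 4)

  # different seed gives a different volume
  ph3 <- generate_phantom(small_spec(seed = 3))
  expect_false(identical(ph1$volume$data, ph3$volume$data))
})

test_that("an empty phantom is textured background only", {
  sp <- small_spec(n_synapses = 0)
  sp$n_mito <- 0; sp$n_membrane <- 0
  sp$n_apposition <- 0; sp$n_clutter <- 0
  ph <- generate_phantom(sp)
  expect_length(ph$truth$synapses, 0)
  expect_identical(nrow(phantom_gt_points(ph$truth)), 0L)
  expect_lt(abs(mean(ph$volume$data) - sp$background), 0.02)
})

test_that("planted synapse masks are disjoint and within the size filter", {
  ph <- generate_phantom(small_spec(seed = 5))
  vox <- lapply(ph$truth$synapses, `[[`, "voxels")
  expect_false(any(duplicated(unlist(vox))))  # pairwise disjoint
  counts <- lengths(vox)
  expect_true(all(counts >= 100 & counts <= 1e6))
  # synapse voxels are dark relative to the background
  expect_lt(mean(ph$volume$data[unlist(vox)]), 0.35)
})

test_that("sampled training labels land on the correct structures", {
  ph <- generate_phantom(small_spec(seed = 2))
  labs <- sample_phantom_labels(ph, n_per_class = 50, seed = 1)
  expect_setequal(unique(labs$class), c("synapse", "membrane", "other"))
  shape <- dim(ph$volume$data)
  syn <- labs[labs$class == "synapse", ]
  vox <- syn$z + shape[1] * (syn$y - 1 + shape[2] * (syn$x - 1))
  expect_true(all(vox %in% unlist(lapply(ph$truth$synapses, `[[`, "voxels"))))
})

test_that("probability phantoms expose segmentation-stage behaviors", {
  # noiseless-ish map: beta = 0 graph cut recovers the truth exactly
  ph <- generate_probability_phantom(shape = c(8, 60, 60), n_objects = 3,
                                     noise_sd = 0.01, seed = 4)
  psyn <- ph$prob$data[1, , , ]
  dim(psyn) <- dim(ph$prob$data)[2:4]
  seg <- segment_graphcut(psyn, 0)
  truth_all <- Reduce(`|`, ph$truth)
  expect_identical(seg, truth_all)

  # bridge stays under the detection threshold: objects remain separate
  phb <- generate_probability_phantom(shape = c(8, 60, 60), n_objects = 2,
                                      noise_sd = 0.01, bridge = TRUE,
                                      seed = 6)
  pb <- phb$prob$data[1, , , ]
  dim(pb) <- dim(phb$prob$data)[2:4]
  expect_gt(length(phb$bridge_voxels), 0)
  expect_true(all(pb[phb$bridge_voxels] <= 0.5))
  cc <- connected_components(pb > 0.5, 26)
  expect_gte(nrow(cc$table), 2L)
})

test_that("graph cut trims protrusions that hysteresis keeps", {
  ph <- generate_probability_phantom(shape = c(8, 60, 60), n_objects = 1,
                                     noise_sd = 0.01, protrusion = TRUE,
                                     seed = 8)
  p <- ph$prob$data[1, , , ]
  dim(p) <- dim(ph$prob$data)[2:4]
  expect_gt(length(ph$protrusion_voxels), 5)

  hyst <- segment_hysteresis(p, high = 0.5, low = 0.3)
  beta <- default_beta(seed = 1)
  gc_mask <- segment_graphcut(p, beta)
  expect_lt(sum(gc_mask[ph$protrusion_voxels]),
            sum(hyst[ph$protrusion_voxels]))
  # the object body itself is kept by both
  expect_gt(jaccard(gc_mask & ph$truth[[1]], ph$truth[[1]]), 0.8)
})
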