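test_that("phantom specs validate their invariants", {
  expect_error(phantom_spec(blob_gray_mean = 200), "below background")
  expect_error(phantom_spec(min_separation_vox = 1), "separation")
  expect_error(phantom_spec(blob_voxel_range = c(10, 5)), "blob_voxel_range")
})

test_that("phantom stacks are reproducible with exact truth", {
  spec <- phantom_spec(dims = c(64, 64, 16), n_junctions = 6,
                       blob_voxel_range = c(30, 60))
  a <- generate_phantom_stack(spec, seed = 5)
  b <- generate_phantom_stack(spec, seed = 5)
  expect_identical(a$grid$data, b$grid$data)
  expect_identical(a$truth$voxels, b$truth$voxels)
  expect_equal(nrow(a$truth), 6L)
  # blob sizes respect the configured range exactly
  expect_true(all(a$truth$n_voxels >= 30 & a$truth$n_voxels <= 60))
  # truth voxel sets are pairwise separated and 6-connected
  d <- spec$dims
  for (m in a$truth$voxels) {
    comps <- oracle_flood_fill(`[<-`(array(FALSE, d), m, TRUE), 6)
    expect_equal(length(comps), 1L)
  }
  # zero junctions -> pure noise
  z <- generate_phantom_stack(phantom_spec(dims = c(32, 32, 8),
                                           n_junctions = 0), seed = 1)
  expect_equal(nrow(z$truth), 0L)
  # infeasible packing errors out
  expect_error(generate_phantom_stack(
    phantom_spec(dims = c(12, 12, 4), n_junctions = 50,
                 blob_voxel_range = c(30, 40)), seed = 1), "packing")
})

test_that("default phantoms are recovered one-to-one by the segmenter", {
  ph <- generate_phantom_stack(phantom_spec(), seed = 33)
  sm <- gaussian_preprocess(ph$grid, 1, 0)
  j <- segment_junctions(sm, 100, min_voxels = 20)
  rec <- junction_recovery(ph$truth, j, dim(ph$grid$data))
  expect_gte(rec$recovery_pct, 95)
  expect_equal(rec$n_merged, 0L)
  expect_equal(rec$n_split, 0L)
})

test_that("network specs validate and generation is deterministic", {
  expect_error(network_spec(volume_um3 = 0), "> 0")
  expect_error(network_spec(terminal_frac = 1.2), "fractions")
  expect_error(network_spec(length_density_m_per_mm3 = c(bogus = 1)),
               "unknown fiber class")
  spec <- network_spec(volume_um3 = 60)
  a <- generate_fiber_network(spec, seed = 4)
  b <- generate_fiber_network(spec, seed = 4)
  expect_identical(a$network$nodes, b$network$nodes)
  expect_identical(a$synapses, b$synapses)
})

test_that("generated networks satisfy every fiber invariant", {
  nw <- generate_fiber_network(network_spec(volume_um3 = 150), seed = 9)
  expect_equal(nrow(validate_fibers(nw$network, nw$synapses)), 0L)
  # realized lengths per generated class land within 5% of target
  spec <- network_spec(volume_um3 = 150)
  sl <- shaft_length(nw$network, spec$factors)
  intent <- nw$network$fibers$intended_class[match(sl$fiber_id,
                                                   nw$network$fibers$fiber_id)]
  realized <- tapply(sl$shaft_length_um, intent, sum)
  target <- spec$length_density_m_per_mm3 * 1e-3 * 150
  for (cls in names(target))
    expect_lt(abs(realized[[cls]] - target[[cls]]) / target[[cls]], 0.05)
  # analysis-side classification agrees with generated labels
  cls <- classify_fibers(nw$network, nw$synapses)
  expect_equal(cls$fiber_class, nw$network$fibers$fiber_class)
  # derived targets equal generated truth labels exactly
  syn <- assign_targets(nw$synapses[, setdiff(names(nw$synapses),
                                              c("target", "axon_id",
                                                "dendrite_id"))],
                        nw$network)
  expect_equal(syn$target, nw$synapses$target)
  expect_equal(syn$axon_id, nw$synapses$axon_id)
})

test_that("all-zero densities give an empty network and closure holds", {
  spec <- network_spec(volume_um3 = 50,
                       length_density_m_per_mm3 = c(excitatory_axon = 0))
  nw <- generate_fiber_network(spec, seed = 2)
  expect_equal(nrow(nw$network$fibers), 0L)
  expect_equal(nrow(nw$synapses), 0L)
  # only non-synaptic fibers requested -> every fiber stays non-synaptic
  spec2 <- network_spec(volume_um3 = 50,
                        length_density_m_per_mm3 = c(non_synaptic = 2000))
  nw2 <- generate_fiber_network(spec2, seed = 2)
  expect_true(all(nw2$network$fibers$fiber_class == "non_synaptic"))
  expect_equal(nrow(nw2$network$attachments), 0L)
})

test_that("axon synapse rates are recovered from the generated ensemble", {
  spec <- network_spec(volume_um3 = 300)
  nw <- generate_fiber_network(spec, seed = 11)
  fb <- nw$network$fibers
  sl <- shaft_length(nw$network, spec$factors)
  exc <- fb$fiber_id[fb$intended_class == "excitatory_axon"]
  L <- sum(sl$shaft_length_um[sl$fiber_id %in% exc])
  n <- sum(nw$network$attachments$side == "pre" &
             nw$network$attachments$fiber_id %in% exc)
  expect_lt(abs(n / L - 0.38), 3 * sqrt(0.38 / L))
})

test_that("the published fixture is wired as printed", {
  fx <- table1_fixture()
  expect_equal(fx$lengths$length_m_per_mm3[
    fx$lengths$region == "SR" &
      fx$lengths$fiber_class == "excitatory_axon"], 6761.19)
  expect_equal(fx$synapse_density$ss_per_um3[
    fx$synapse_density$region == "L1"], 0.20)
  expect_true(all(fx$lengths$length_m_per_mm3 > 0))
  expect_true(all(fx$totals$printed_total_m_per_mm3 > 0))
})

test_that("junction point clouds are seeded Poisson draws", {
  a <- simulate_junction_points(c(0, 0, 0), c(5, 5, 5), 2, seed = 3)
  b <- simulate_junction_points(c(0, 0, 0), c(5, 5, 5), 2, seed = 3)
  expect_identical(a, b)
  expect_true(all(a$x_um >= 0 & a$x_um <= 5))
  expect_error(simulate_junction_points(c(0, 0, 0), c(0, 1, 1), 2), "exceed")
})
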