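test_that("polyline length is the 3D arc length", {
  expect_equal(polyline_length(rbind(c(0, 0, 0), c(3, 4, 0))), 5)
  expect_equal(polyline_length(cbind(1, 2, 3)), 0)
  set.seed(13)
  m <- matrix(rnorm(300), ncol = 3)
  want <- sum(vapply(2:100, function(i) sqrt(sum((m[i, ] - m[i - 1, ])^2)),
                     numeric(1)))
  expect_equal(polyline_length(m), want)
})

test_that("shaft length excludes spines and corrects shrinkage", {
  toy <- toy_network()
  sl <- shaft_length(toy$network)
  expect_equal(sl$shaft_length_um[sl$fiber_id == 1], 4 / 0.96)
  expect_equal(sl$spine_length_um[sl$fiber_id == 1], (0.4 + 0.4 + 0.5) / 0.96)
  sl1 <- shaft_length(toy$network, no_shrinkage())
  expect_equal(sl1$shaft_length_um[sl1$fiber_id == 1], 4)
  # scaling all coordinates by c scales every length by c
  net2 <- toy$network
  net2$nodes$x_um <- net2$nodes$x_um * 2
  net2$nodes$y_um <- net2$nodes$y_um * 2
  net2$nodes$z_um <- net2$nodes$z_um * 2
  expect_equal(shaft_length(net2)$shaft_length_um,
               sl$shaft_length_um * 2)
})

test_that("fibers classify from attachments, spines and myelin", {
  toy <- toy_network()
  cls <- classify_fibers(toy$network, toy$synapses)
  expect_equal(cls$fiber_class,
               c("spiny_dendrite", "smooth_dendrite", "excitatory_axon",
                 "inhibitory_axon", "non_synaptic"))
  # myelin flag wins over junction type
  net <- toy$network
  net$fibers$myelinated[3] <- TRUE
  expect_equal(classify_fibers(net, toy$synapses)$fiber_class[3],
               "myelinated_axon")
  # mixed AS/SS axon is surfaced, not silently resolved
  syn <- toy$synapses
  syn$syn_type[2] <- "SS"
  expect_error(classify_fibers(toy$network, syn), "AS and SS")
  flagged <- classify_fibers(toy$network, syn, on_conflict = "flag")
  expect_true(is.na(flagged$fiber_class[3]))
  expect_match(flagged$conflict[3], "AS and SS")
})

test_that("linear densities split by target and apply the 3 um filter", {
  toy <- toy_network()
  rec <- linear_synapse_density(toy$network, toy$synapses, no_shrinkage())
  r1 <- rec[rec$fiber_id == 1, ]
  expect_equal(r1$n_syn_total, 3L)
  expect_equal(r1$n_syn_spines, 2L)
  expect_equal(r1$n_syn_shaft, 1L)
  expect_equal(r1$density_total, 0.75)
  expect_equal(r1$density_spines, 0.5)
  expect_equal(r1$density_shaft, 0.25)
  expect_true(r1$included)
  # smooth dendrite of 2 um is excluded but retained as a marker
  r2 <- rec[rec$fiber_id == 2, ]
  expect_false(r2$included)
  expect_true(is.na(r2$density_total))
  # axons count all presynaptic attachments
  r3 <- rec[rec$fiber_id == 3, ]
  expect_equal(r3$n_syn_total, 3L)
  expect_equal(r3$density_total, 0.75)
  expect_true(is.na(r3$density_spines))
  # invariant: totals decompose
  dend <- rec[rec$fiber_class %in% c("spiny_dendrite", "smooth_dendrite"), ]
  expect_equal(dend$n_syn_total, dend$n_syn_spines + dend$n_syn_shaft)
})

test_that("spec arithmetic example: 10 um shaft with 5 + 2 synapses", {
  nodes <- tibble::tibble(
    fiber_id = 1L, node_id = 1:14,
    parent_id = c(NA, 1:10, 3L, 5L, 7L),
    x_um = c(0:10, 2, 4, 6), y_um = c(rep(0, 11), 1, 1, 1), z_um = 0,
    role = c(rep("shaft", 11), rep("spine", 3)))
  att <- tibble::tibble(synapse_id = 1:7, fiber_id = 1L,
                        node_id = c(12L, 12L, 13L, 13L, 14L, 2L, 6L),
                        side = "post")
  net <- fiber_network(tibble::tibble(fiber_id = 1L,
                                      fiber_class = "spiny_dendrite",
                                      myelinated = FALSE), nodes, att)
  rec <- linear_synapse_density(net, NULL, no_shrinkage())
  expect_equal(rec$density_total, 0.7)
  expect_equal(rec$density_spines, 0.5)
  expect_equal(rec$density_shaft, 0.2)
})

test_that("length report converts to m/mm^3 and sums percentages to 100", {
  toy <- toy_network()
  lr <- length_report(toy$network, 1000, no_shrinkage())
  bc <- tidy(lr)
  # one 1 um fiber in 1000 um^3 equals 1 m/mm^3
  expect_equal(bc$length_m_per_mm3[bc$fiber_class == "non_synaptic"], 1)
  expect_equal(lr$total_m_per_mm3, 13)
  expect_equal(sum(bc$pct), 100, tolerance = 1e-9)
  expect_equal(lr$synaptic_total_m_per_mm3, 12)
  # spine length can be included on request, clearly changing the total
  lr2 <- length_report(toy$network, 1000, no_shrinkage(),
                       include_spines = TRUE)
  expect_equal(lr2$total_m_per_mm3, 13 + 1.3)
  # shrinkage coherence: disabling correction scales lengths by 0.96
  lr3 <- length_report(toy$network, 1000)
  expect_equal(lr3$total_m_per_mm3 * 0.96, 13)
})

test_that("target distribution partitions the synapse set", {
  toy <- toy_network()
  td <- synapse_target_distribution(toy$synapses, toy$network)
  expect_equal(td$fourway$pct, c(50, 25, 25, 0))
  expect_equal(sum(td$fourway$n), 4L)
  expect_equal(td$by_dendrite_type$pct, c(50, 25, 25))
  expect_equal(sum(td$by_dendrite_type$pct), 100)
  syn_all_spine <- toy$synapses[c(1, 4), ]
  td2 <- synapse_target_distribution(syn_all_spine, toy$network)
  expect_equal(td2$fourway$pct, c(100, 0, 0, 0))
  expect_error(synapse_target_distribution(toy$synapses[0, ], toy$network),
               "empty")
})

test_that("spine attachments split into head and neck by arc position", {
  toy <- toy_network()
  syn <- assign_targets(toy$synapses, toy$network)
  expect_equal(syn$target, c("spine_head", "shaft", "shaft", "spine_head"))
  # re-attach synapse 1 to the neck node (node 6, 50% of the branch)
  net <- toy$network
  net$attachments$node_id[net$attachments$synapse_id == 1 &
                            net$attachments$side == "post"] <- 6L
  syn2 <- assign_targets(toy$synapses, net)
  expect_equal(syn2$target[1], "spine_neck")
  # a stricter head threshold reclassifies the head node too
  syn3 <- assign_targets(toy$synapses, toy$network, head_threshold = 1)
  expect_equal(syn3$target[1], "spine_neck")
})

test_that("multi-contact summary matches exhaustive enumeration", {
  toy <- toy_network()
  mc <- multi_contact_summary(toy$network, toy$synapses)
  expect_equal(mc$summary$n_axons_ge2, 1L)
  expect_equal(mc$summary$pct_axons_multihit_same_dendrite, 100)
  expect_equal(mc$summary$pct_dendrites_with_repeated_partner, 50)

  # random bipartite graphs vs a brute-force pair enumeration
  set.seed(8)
  for (rep in 1:20) {
    n_ax <- sample(2:4, 1); n_de <- sample(2:4, 1); n_sy <- sample(1:8, 1)
    ax <- sample(n_ax, n_sy, TRUE); de <- sample(n_de, n_sy, TRUE)
    net <- make_bipartite_network(n_ax, n_de, ax, de)
    mc <- multi_contact_summary(net$network, net$synapses)
    # oracle: loop over every axon / dendrite pair
    multihit <- vapply(seq_len(n_ax), function(a) {
      if (sum(ax == a) < 2) return(NA)
      any(vapply(seq_len(n_de), function(d) sum(ax == a & de == d) >= 2,
                 logical(1)))
    }, logical(1))
    expect_equal(mc$summary$n_axons_ge2, sum(!is.na(multihit)))
    expect_equal(mc$summary$n_axons_multihit, sum(multihit, na.rm = TRUE))
    rep_d <- vapply(sort(unique(de)), function(d)
      any(vapply(seq_len(n_ax), function(a) sum(ax == a & de == d) >= 2,
                 logical(1))), logical(1))
    expect_equal(mc$summary$n_dendrites_with_repeated_partner, sum(rep_d))
  }
})

test_that("bouton shape distinguishes leaf from interior attachments", {
  toy <- toy_network()
  bs <- bouton_shape_summary(toy$network, toy$synapses)
  exc <- bs[bs$fiber_class == "excitatory_axon", ]
  expect_equal(exc$n_en_passant, 2L)     # interior nodes 2, 3
  expect_equal(exc$n_terminal, 1L)       # leaf node 5
  expect_equal(exc$pct_en_passant + exc$pct_terminal, 100)
  inh <- bs[bs$fiber_class == "inhibitory_axon", ]
  expect_equal(inh$pct_terminal, 100)
  # censoring: the leaf of fiber 3 sits at x = 4; with bounds ending there
  # the apparent terminal is a truncation artifact and is dropped
  bs2 <- bouton_shape_summary(toy$network, toy$synapses,
                              bounds = list(lo = c(0, 0, 0),
                                            hi = c(4, 5, 5)),
                              censor_margin_um = 0.25)
  exc2 <- bs2[bs2$fiber_class == "excitatory_axon", ]
  expect_equal(exc2$n_censored, 1L)
  expect_equal(exc2$pct_en_passant, 100)
})

test_that("spine/shaft density correlation follows the direct formula", {
  rec <- tibble::tibble(
    fiber_id = 1:6, fiber_class = "spiny_dendrite",
    shaft_length_um = 10, n_syn_total = 0L, n_syn_spines = 0L,
    n_syn_shaft = 0L,
    density_spines = c(1, 2, 3, 4, 5, 6),
    density_shaft = c(2, 4, 6, 8, 10, 12),
    density_total = 0, included = TRUE)
  expect_equal(spine_shaft_correlation(rec)$r_squared, 1)
  rec$density_shaft <- rep(3, 6)
  expect_true(is.na(spine_shaft_correlation(rec)$r_squared))
  set.seed(4)
  rec$density_spines <- runif(6); rec$density_shaft <- runif(6)
  x <- rec$density_spines; y <- rec$density_shaft
  want <- (sum((x - mean(x)) * (y - mean(y))) /
             sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))^2
  expect_equal(spine_shaft_correlation(rec)$r_squared, want)
  expect_error(spine_shaft_correlation(rec[1:2, ]), "3")
})
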