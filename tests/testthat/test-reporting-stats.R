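test_that("chi-square matches the O/E formula on random tables", {
  # identical row proportions -> statistic 0, p = 1
  res <- chi_square_independence(rbind(c(10, 20), c(30, 60)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(chi_square_independence(rbind(c(5, 5, 5), c(3, 3, 4)))$df, 2)
  set.seed(12)
  for (i in 1:10) {
    tab <- matrix(sample(5:60, 6), nrow = 2)
    res <- chi_square_independence(tab)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - e)^2 / e)
    expect_equal(res$statistic, stat)
    expect_equal(res$p_value, pchisq(stat, 2, lower.tail = FALSE))
  }
  expect_error(chi_square_independence(rbind(c(0, 0), c(1, 2))), "marginal")
  expect_error(chi_square_independence(rbind(c(0.5, 1), c(1, 2))), "integer")
})

test_that("Mann-Whitney handles separation, symmetry and exact enumeration", {
  res <- mann_whitney(1:4, 11:14)           # complete separation a < b
  expect_equal(res$u, 0)
  a <- c(1, 3, 5, 9)
  expect_equal(mann_whitney(a, a)$p_value, 1)  # identical multisets
  # exact p equals full enumeration of the 252 labelings at n1 = n2 = 5
  set.seed(23)
  x <- rnorm(5); y <- rnorm(5) + 0.8
  res <- mann_whitney(x, y)
  expect_equal(res$method, "exact")
  pooled <- c(x, y)
  combos <- combn(10, 5)
  u_all <- apply(combos, 2, function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - 5 * 6 / 2
  })
  u_obs <- res$u
  p_enum <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
  expect_equal(res$p_value, p_enum)
  # large/tied samples take the normal approximation
  expect_equal(mann_whitney(rep(1:5, 3), rep(2:6, 3))$method, "normal_approx")
})

test_that("Kruskal-Wallis H is tie-corrected and degenerate-safe", {
  g <- list(a = c(1, 1, 1), b = c(1, 1), c = c(1, 1, 1))
  res <- kruskal_wallis_bonferroni(g)
  expect_equal(res$h, 0)
  expect_equal(res$p_value, 1)
  # H equals the reference implementation, with and without ties
  set.seed(3)
  for (i in 1:5) {
    gs <- lapply(1:3, function(j) sample(1:6, sample(3:6, 1), TRUE))
    res <- kruskal_wallis_bonferroni(gs, p_method = "asymptotic")
    ref <- kruskal.test(unlist(gs),
                        factor(rep(seq_along(gs), lengths(gs))))
    expect_equal(res$h, unname(ref$statistic))
    expect_equal(res$p_value, ref$p.value)
  }
})

test_that("exact Kruskal-Wallis p matches a permutation null", {
  set.seed(14)
  gs <- list(a = c(0.3, 1.2, 2.4), b = c(1.9, 3.3, 0.7), c = c(4.1, 2.8, 5))
  res <- kruskal_wallis_bonferroni(gs)
  expect_equal(res$method, "exact")
  # independent Monte-Carlo permutation oracle
  x <- unlist(gs)
  g <- factor(rep(1:3, each = 3))
  h_obs <- synaptometry:::kw_h_statistic(x, g)
  nmc <- 4000
  h_mc <- replicate(nmc, synaptometry:::kw_h_statistic(sample(x), g))
  p_mc <- mean(h_mc >= h_obs - 1e-12)
  expect_lt(abs(res$p_value - p_mc),
            3 * sqrt(p_mc * (1 - p_mc) / nmc) + 1e-6)
})

test_that("pairwise comparisons are Bonferroni-multiplied and capped", {
  set.seed(6)
  gs <- list(a = rnorm(6), b = rnorm(6) + 2, c = rnorm(6))
  res <- kruskal_wallis_bonferroni(gs, p_method = "asymptotic")
  pw <- tidy(res)
  expect_equal(nrow(pw), 3L)
  expect_equal(pw$p_adj, pmin(1, pw$p_raw * 3))
  expect_true(all(pw$p_adj >= pw$p_raw))
  expect_true(all(pw$p_raw >= 0 & pw$p_adj <= 1))
  raw_ab <- mann_whitney(gs$a, gs$b)$p_value
  expect_equal(pw$p_raw[pw$group1 == "a" & pw$group2 == "b"], raw_ab)
  # Dunn's alternative returns valid probabilities too
  res_d <- kruskal_wallis_bonferroni(gs, posthoc = "dunn",
                                     p_method = "asymptotic")
  expect_true(all(tidy(res_d)$p_adj >= tidy(res_d)$p_raw))
  gl <- glance(res)
  expect_named(gl, c("h", "df", "p_value", "method"))
})

test_that("region reports assemble, summarize and serialize deterministically", {
  toy <- toy_network()
  rep1 <- build_region_report("toy", toy$network, toy$synapses,
                              volume_um3 = 1000, factors = no_shrinkage())
  expect_equal(rep1$density$n[3], 4L)
  expect_equal(rep1$density$density_per_um3[3], 0.004)
  expect_equal(sum(rep1$composition$n), 5L)
  expect_equal(rep1$composition_shares$pct[1], 50)  # 1 of 2 dendrites spiny
  expect_equal(rep1$lengths$total_m_per_mm3, 13)
  gl <- glance(rep1)
  expect_equal(gl$n_fibers, 5L)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_region_report(rep1, p1)
  rep2 <- build_region_report("toy", toy$network, toy$synapses,
                              volume_um3 = 1000, factors = no_shrinkage())
  write_region_report(rep2, p2)
  expect_identical(readLines(p1), readLines(p2))
  js <- jsonlite::fromJSON(p1)
  expect_equal(js$schema, "synaptometry/region_report")
  expect_equal(js$length_total_m_per_mm3, 13)
})

test_that("empty fiber sets give a zero-count, flagged report", {
  net <- fiber_network(
    tibble::tibble(fiber_id = integer(), fiber_class = character(),
                   myelinated = logical()),
    tibble::tibble(fiber_id = integer(), node_id = integer(),
                   parent_id = integer(), x_um = numeric(), y_um = numeric(),
                   z_um = numeric(), role = character()))
  rep0 <- build_region_report("empty", net,
                              synaptometry:::empty_synapse_table(),
                              volume_um3 = 100)
  expect_true(rep0$empty)
  expect_equal(rep0$density$n[3], 0L)
  expect_equal(rep0$lengths$total_m_per_mm3, 0)
})

test_that("region comparisons reuse the nonparametric machinery", {
  set.seed(9)
  mk <- function(mu, n) tibble::tibble(
    fiber_id = seq_len(n), fiber_class = "spiny_dendrite",
    shaft_length_um = 10, n_syn_total = 1L, n_syn_spines = 1L,
    n_syn_shaft = 0L, density_total = rnorm(n, mu, 0.2),
    density_spines = 0, density_shaft = 0, included = TRUE)
  recs <- list(SR = mk(3.3, 12), L1 = mk(1.8, 12), L3 = mk(1.9, 12))
  res <- compare_region_densities(recs, p_method = "asymptotic")
  expect_s3_class(res, "kw_test")
  expect_lt(glance(res)$p_value, 0.01)
  two <- compare_region_densities(recs[1:2])
  expect_true(all(c("u", "p_value") %in% names(two)))
  chi <- compare_region_counts(list(SR = c(AS = 268, SS = 8),
                                    L1 = c(AS = 160, SS = 20)))
  expect_lt(chi$p_value, 0.05)
})
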