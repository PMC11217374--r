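test_that("Gaussian preprocessing preserves constants and identity cases", {
  g <- voxel_grid(array(77, dim = c(8, 8, 4)))
  expect_equal(gaussian_preprocess(g, 0, 0)$data, g$data)
  sm <- gaussian_preprocess(g, 1.5, 1)
  expect_equal(sm$data, g$data, tolerance = 1e-12)
  expect_identical(dim(sm$data), dim(g$data))
  expect_error(gaussian_preprocess(g, -1), ">= 0")
})

test_that("separable smoothing equals direct discrete convolution", {
  d <- c(9, 8, 7)
  for (sig in list(c(1, 0.5), c(1.3, 0))) {
    set.seed(11)
    a <- array(runif(prod(d), 0, 255), dim = d)
    g <- voxel_grid(array(0, dim = d))
    g$data <- a  # keep continuous values
    got <- gaussian_preprocess(g, sig[1], sig[2])$data
    want <- oracle_convolve(a, sig[1], sig[2])
    expect_equal(got, want, tolerance = 1e-10)
  }
  # unit impulse
  a <- array(0, dim = d); a[5, 4, 4] <- 1
  g <- voxel_grid(a, bit_depth = 8)
  got <- gaussian_preprocess(g, 1, 0.5)$data
  expect_equal(got, oracle_convolve(a, 1, 0.5), tolerance = 1e-12)
  expect_equal(sum(got), 1, tolerance = 1e-9)  # kernel is normalized
})

test_that("thresholding extracts dark components with a size filter", {
  a <- array(200L, dim = c(10, 10, 3))
  g <- voxel_grid(a)
  expect_equal(nrow(segment_junctions(g, 100)), 0L)  # all bright

  # one dark 2x2x1 blob: below min_voxels it disappears
  a[3:4, 3:4, 2] <- 10L
  g <- voxel_grid(a)
  expect_equal(nrow(segment_junctions(g, 100, min_voxels = 5)), 0L)
  j <- segment_junctions(g, 100, min_voxels = 4)
  expect_equal(nrow(j), 1L)
  expect_equal(j$n_voxels, 4L)
  # ties at the threshold are foreground
  a[8, 8, 1] <- 100L
  j2 <- segment_junctions(voxel_grid(a), 100, min_voxels = 1)
  expect_equal(sum(j2$n_voxels), 5L)
})

test_that("components match an independent flood fill and form a partition", {
  set.seed(42)
  d <- c(14, 12, 6)
  a <- array(sample(c(40L, 200L), prod(d), replace = TRUE, prob = c(.25, .75)),
             dim = d)
  g <- voxel_grid(a)
  mask <- a <= 100
  for (conn in c(6L, 18L, 26L)) {
    j <- segment_junctions(g, 100, min_voxels = 1, connectivity = conn)
    want <- oracle_flood_fill(mask, conn)
    expect_identical(canon_components(j$voxels, d),
                     canon_components(want, d))
    # partition of the foreground
    flat <- unlist(lapply(j$voxels, function(m)
      (m[, 1] - 1) + (m[, 2] - 1) * d[1] + (m[, 3] - 1) * d[1] * d[2]))
    expect_equal(sort(flat), which(mask) - 1)
  }
})

test_that("6-connected components refine 26-connected ones", {
  set.seed(7)
  d <- c(12, 12, 5)
  a <- array(sample(c(0L, 255L), prod(d), TRUE, prob = c(.3, .7)), dim = d)
  g <- voxel_grid(a)
  j6 <- segment_junctions(g, 0, connectivity = 6)
  j26 <- segment_junctions(g, 0, connectivity = 26)
  expect_gte(nrow(j6), nrow(j26))
  # every 6-component is inside exactly one 26-component
  flat <- function(m) (m[, 1] - 1) + (m[, 2] - 1) * d[1] +
    (m[, 3] - 1) * d[1] * d[2]
  owner <- integer(prod(d))
  for (i in seq_len(nrow(j26))) owner[flat(j26$voxels[[i]]) + 1] <- i
  for (m in j6$voxels)
    expect_equal(length(unique(owner[flat(m) + 1])), 1L)
})

test_that("threshold and min_voxels act monotonically", {
  set.seed(9)
  d <- c(16, 16, 4)
  a <- array(sample(0:255, prod(d), TRUE), dim = d)
  g <- voxel_grid(a)
  fg <- function(th) sum(vapply(segment_junctions(g, th)$voxels, nrow,
                                integer(1)))
  expect_true(all(diff(vapply(c(40, 90, 140, 200), fg, numeric(1))) >= 0))
  nj <- function(mv) nrow(segment_junctions(g, 120, min_voxels = mv))
  expect_true(all(diff(vapply(c(1, 2, 4, 8), nj, numeric(1))) <= 0))
})

test_that("centroids are voxel-center means", {
  expect_equal(junction_centroid(cbind(1L, 1L, 1L)), c(0.0025, 0.0025, 0.01))
  # two voxels symmetric about a point -> midpoint
  expect_equal(junction_centroid(rbind(c(1L, 5L, 2L), c(9L, 1L, 4L))),
               colMeans(voxel_centers_um(rbind(c(1, 5, 2), c(9, 1, 4)))))
  set.seed(3)
  m <- cbind(sample(1:40, 50, TRUE), sample(1:40, 50, TRUE),
             sample(1:10, 50, TRUE))
  want <- c(mean((m[, 1] - 0.5) * 5e-3), mean((m[, 2] - 0.5) * 5e-3),
            mean((m[, 3] - 0.5) * 20e-3))
  expect_equal(junction_centroid(m), want)
  expect_error(junction_centroid(matrix(integer(), ncol = 3)), "empty")
})

test_that("label volumes assign AS/SS by majority vote", {
  a <- array(200L, dim = c(8, 8, 2))
  a[2:3, 2:3, 1] <- 10L
  a[6:7, 6:7, 1] <- 10L
  lab <- array(0L, dim = dim(a))
  lab[2:3, 2:3, 1] <- 1L
  lab[6:7, 6:7, 1] <- 2L
  j <- segment_junctions(voxel_grid(a), 100, label_grid = lab)
  expect_setequal(j$syn_type, c("AS", "SS"))
})

test_that("thickness heuristic separates slabs from sheets", {
  # 10x10x10 voxel block at 5 nm: slab thickness ~50 nm -> AS
  thick <- as.matrix(expand.grid(1:10, 1:10, 1:2))  # 2 sections of 20 nm
  thin <- as.matrix(expand.grid(1:12, 1:2, 1))      # single section strip
  j <- tibble::tibble(junction_id = 1:2, voxels = list(thick, thin))
  out <- estimate_syn_type(j, voxel_size = c(5, 5, 20))
  expect_equal(out$syn_type[1], "AS")   # two 20 nm sections -> ~35 nm slab
  expect_equal(out$syn_type[2], "SS")   # thin in-plane strip
})
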