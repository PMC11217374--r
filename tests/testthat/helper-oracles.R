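# Independent oracles and hand-built fixtures shared across tests.

# Direct dense 3D convolution with a separable Gaussian kernel and mirror
# boundary (triple loop; independent of the package's separable code path).
oracle_convolve <- function(a, sigma_xy, sigma_z) {
  kern1 <- function(sigma) {
    if (sigma <= 0) return(1)
    r <- max(1L, ceiling(4 * sigma))
    k <- exp(-((-r:r)^2) / (2 * sigma^2))
    k / sum(k)
  }
  reflect <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n - i + 1
    }
    i
  }
  kx <- kern1(sigma_xy); ky <- kern1(sigma_xy); kz <- kern1(sigma_z)
  rx <- (length(kx) - 1) / 2; ry <- (length(ky) - 1) / 2
  rz <- (length(kz) - 1) / 2
  d <- dim(a)
  out <- array(0, dim = d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    acc <- 0
    for (di in seq_along(kx)) for (dj in seq_along(ky))
      for (dk in seq_along(kz)) {
        ii <- reflect(i + di - 1 - rx, d[1])
        jj <- reflect(j + dj - 1 - ry, d[2])
        kk <- reflect(k + dk - 1 - rz, d[3])
        acc <- acc + a[ii, jj, kk] * kx[di] * ky[dj] * kz[dk]
      }
    out[i, j, k] <- acc
  }
  out
}

# Brute-force BFS flood fill over a logical mask; returns a list of
# integer (i, j, k) matrices, one per component.
oracle_flood_fill <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(offs))
  offs <- offs[nz > 0 & nz <= switch(as.character(connectivity),
                                     "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  labels <- array(0L, dim = d)
  comps <- list()
  fg <- which(mask)
  for (s in fg) {
    if (labels[s] != 0L) next
    id <- length(comps) + 1L
    queue <- list(arrayInd(s, d)[1, ])
    labels[s] <- id
    members <- list()
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      members[[length(members) + 1L]] <- v
      for (r in seq_len(nrow(offs))) {
        w <- v + offs[r, ]
        if (any(w < 1) || any(w > d)) next
        if (mask[w[1], w[2], w[3]] && labels[w[1], w[2], w[3]] == 0L) {
          labels[w[1], w[2], w[3]] <- id
          queue[[length(queue) + 1L]] <- w
        }
      }
    }
    comps[[id]] <- do.call(rbind, members)
  }
  comps
}

# Canonical form of a set of voxel sets: sorted flat-index strings.
canon_components <- function(voxel_list, dims) {
  sort(vapply(voxel_list, function(m) {
    flat <- sort((m[, 1] - 1) + (m[, 2] - 1) * dims[1] +
                   (m[, 3] - 1) * dims[1] * dims[2])
    paste(flat, collapse = ",")
  }, character(1)))
}

# Bipartite attachment fixture: ax[i]/de[i] give the axon and dendrite of
# synapse i. Geometry is trivial; only the attachment graph matters.
make_bipartite_network <- function(n_ax, n_de, ax, de) {
  fibers <- tibble::tibble(
    fiber_id = c(seq_len(n_ax), 100L + seq_len(n_de)),
    fiber_class = c(rep("excitatory_axon", n_ax),
                    rep("smooth_dendrite", n_de)),
    myelinated = FALSE)
  nodes <- tibble::tibble(
    fiber_id = rep(fibers$fiber_id, each = 2L),
    node_id = rep(1:2, n_ax + n_de),
    parent_id = rep(c(NA_integer_, 1L), n_ax + n_de),
    x_um = as.numeric(rep(seq_len(n_ax + n_de), each = 2L)),
    y_um = rep(c(0, 1), n_ax + n_de), z_um = 0, role = "shaft")
  n_sy <- length(ax)
  attachments <- tibble::tibble(
    synapse_id = rep(seq_len(n_sy), each = 2L),
    fiber_id = as.integer(rbind(ax, 100L + de)),
    node_id = 1L,
    side = rep(c("pre", "post"), n_sy))
  synapses <- tibble::tibble(synapse_id = seq_len(n_sy), syn_type = "AS",
                             x_um = 0, y_um = 0, z_um = 0)
  list(network = fiber_network(fibers, nodes, attachments),
       synapses = synapses)
}

# A small hand-built network used across the metric tests:
#   fiber 1  spiny dendrite, shaft (0..4, 0, 0), two spine branches
#            (neck+head off node 3; single-node spine off node 4)
#   fiber 2  smooth dendrite along y at x = 10
#   fiber 3  excitatory axon along x at z = 1 (5 nodes)
#   fiber 4  inhibitory axon along y at z = 2 (3 nodes)
#   fiber 5  non-synaptic fiber
# synapses: 1 AS on spine head (f1 node 7, axon 3 interior node 2)
#           2 AS on f1 shaft node 2 (axon 3 interior node 3)
#           3 SS on f2 shaft node 2 (axon 4 leaf node 3)
#           4 AS on f1 spine (single-node branch, node 8; axon 3 leaf 5)
toy_network <- function() {
  fibers <- tibble::tibble(
    fiber_id = 1:5,
    fiber_class = c("spiny_dendrite", "smooth_dendrite", "excitatory_axon",
                    "inhibitory_axon", "non_synaptic"),
    myelinated = FALSE)
  nodes <- tibble::tibble(
    fiber_id = c(rep(1L, 8), rep(2L, 3), rep(3L, 5), rep(4L, 3), rep(5L, 2)),
    node_id = c(1:8, 1:3, 1:5, 1:3, 1:2),
    parent_id = c(NA, 1L, 2L, 3L, 4L, 3L, 6L, 4L,
                  NA, 1L, 2L,
                  NA, 1L, 2L, 3L, 4L,
                  NA, 1L, 2L,
                  NA, 1L),
    x_um = c(0, 1, 2, 3, 4, 2, 2, 3,
             10, 10, 10,
             0, 1, 2, 3, 4,
             5, 5, 5,
             8, 9),
    y_um = c(0, 0, 0, 0, 0, 0.4, 0.8, 0.5,
             0, 1, 2,
             0, 0, 0, 0, 0,
             0, 1, 2,
             8, 8),
    z_um = c(0, 0, 0, 0, 0, 0, 0, 0,
             0, 0, 0,
             1, 1, 1, 1, 1,
             2, 2, 2,
             0, 0),
    role = c(rep("shaft", 5), "spine", "spine", "spine",
             rep("shaft", 3), rep("shaft", 5), rep("shaft", 3),
             rep("shaft", 2)))
  attachments <- tibble::tibble(
    synapse_id = c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L),
    fiber_id = c(1L, 3L, 1L, 3L, 2L, 4L, 1L, 3L),
    node_id = c(7L, 2L, 2L, 3L, 2L, 3L, 8L, 5L),
    side = c("post", "pre", "post", "pre", "post", "pre", "post", "pre"))
  synapses <- tibble::tibble(
    synapse_id = 1:4,
    syn_type = c("AS", "AS", "SS", "AS"),
    x_um = c(2, 1, 10, 3), y_um = c(0.8, 0, 1, 0.5), z_um = c(0, 0, 0, 0))
  list(network = fiber_network(fibers, nodes, attachments),
       synapses = synapses)
}
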