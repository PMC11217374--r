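# Seeded generators of phantom image stacks and fiber networks with known
# ground truth, plus the packaged fixture of published summary values.
# Generator defaults emulate the hippocampal stratum radiatum (SR)
# conditions; every draw is reproducible from an integer seed.

#' Phantom-stack specification
#'
#' Describes a synthetic FIB-SEM-like stack: Gaussian background noise with
#' dark blob-shaped junctions grown by random aggregation (so component-
#' connectivity choices are exercised, unlike spheres). Blob gray levels
#' must be darker than the background mean and blobs are kept pairwise
#' separated by a Chebyshev distance larger than one voxel so that they
#' never merge under 26-connectivity.
#'
#' @param dims Grid dimensions `(nx, ny, nz)` in voxels.
#' @param voxel_size Voxel pitch in nm.
#' @param bg_mean,bg_sd Background gray mean and sd (8-bit scale).
#' @param n_junctions Number of blobs.
#' @param blob_voxel_range Inclusive range of blob sizes in voxels.
#' @param blob_gray_mean,blob_gray_sd Blob gray mean (below `bg_mean`) and
#'   sd.
#' @param min_separation_vox Minimum Chebyshev separation between blobs
#'   (> 1).
#' @param as_fraction Probability that a blob is labeled AS (vs SS).
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(dims = c(192, 192, 48), voxel_size = c(5, 5, 20),
                         bg_mean = 160, bg_sd = 12, n_junctions = 30,
                         blob_voxel_range = c(150, 500), blob_gray_mean = 60,
                         blob_gray_sd = 8, min_separation_vox = 2,
                         as_fraction = 0.971) {
  if (blob_gray_mean >= bg_mean) abort("blob gray must be below background")
  if (min_separation_vox <= 1) abort("blob separation must exceed 1 voxel")
  if (length(dims) != 3L || any(dims < 1)) abort("`dims` must be 3 positive")
  if (blob_voxel_range[1] < 1 || blob_voxel_range[2] < blob_voxel_range[1])
    abort("invalid `blob_voxel_range`")
  if (as_fraction < 0 || as_fraction > 1) abort("`as_fraction` in [0, 1]")
  structure(list(dims = as.integer(dims), voxel_size = voxel_size,
                 bg_mean = bg_mean, bg_sd = bg_sd,
                 n_junctions = as.integer(n_junctions),
                 blob_voxel_range = as.integer(blob_voxel_range),
                 blob_gray_mean = blob_gray_mean, blob_gray_sd = blob_gray_sd,
                 min_separation_vox = as.integer(min_separation_vox),
                 as_fraction = as_fraction),
            class = "phantom_spec")
}

# Grow one blob as a random-walk core path dilated by 6-neighborhood
# shells until `size` voxels (a compact sausage rather than a sphere, so
# connectivity choices are exercised). Avoids `forbidden` voxels; returns
# an integer matrix of (i, j, k) or NULL if stuck.
grow_blob <- function(seed_vox, size, dims, forbidden) {
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  occ <- forbidden
  ok <- function(v) all(v >= 1L) && all(v <= dims) &&
    !occ[v[1], v[2], v[3]]
  if (!ok(seed_vox)) return(NULL)
  vox <- matrix(as.integer(seed_vox), ncol = 3)
  occ[seed_vox[1], seed_vox[2], seed_vox[3]] <- TRUE
  pos <- seed_vox
  # core path prefers in-plane steps: junction densities span many 5 nm
  # pixels in-plane but only a few 20 nm sections
  step_prob <- c(0.225, 0.225, 0.225, 0.225, 0.05, 0.05)
  for (s in seq_len(max(2L, ceiling(size / 15)))) {
    for (try in seq_len(6L)) {
      cand <- pos + nb[sample.int(6L, 1L, prob = step_prob), ]
      if (ok(cand)) {
        occ[cand[1], cand[2], cand[3]] <- TRUE
        vox <- rbind(vox, cand)
        pos <- cand
        break
      }
    }
  }
  while (nrow(vox) < size) {
    cand <- vox[rep(seq_len(nrow(vox)), each = 6L), , drop = FALSE] +
      nb[rep(seq_len(6L), times = nrow(vox)), , drop = FALSE]
    inside <- cand[, 1] >= 1L & cand[, 1] <= dims[1] &
              cand[, 2] >= 1L & cand[, 2] <= dims[2] &
              cand[, 3] >= 1L & cand[, 3] <= dims[3]
    cand <- unique(cand[inside, , drop = FALSE])
    free <- !occ[cand]
    cand <- cand[free, , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    need <- size - nrow(vox)
    if (nrow(cand) > need)
      cand <- cand[sample.int(nrow(cand), need), , drop = FALSE]
    occ[cand] <- TRUE
    vox <- rbind(vox, cand)
  }
  storage.mode(vox) <- "integer"
  vox
}

#' Generate a phantom image stack with ground truth
#'
#' Draws a noisy background, grows `n_junctions` dark blobs at locations
#' kept pairwise separated, and returns the stack plus the exact
#' ground-truth voxel sets and AS/SS labels. Reproducible given `seed`;
#' infeasible packings (too many blobs for the volume) raise an error
#' after bounded retries.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed.
#' @return List with `grid` (a [voxel_grid()]) and `truth` (a junction
#'   tibble with `junction_id`, `syn_type`, `n_voxels`, centroid columns
#'   and a `voxels` list-column).
#' @export
generate_phantom_stack <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(seed, {
    dims <- spec$dims
    clamp <- function(x) pmin(255, pmax(0, round(x)))
    data <- array(clamp(rnorm(prod(dims), spec$bg_mean, spec$bg_sd)),
                  dim = dims)
    forbidden <- array(FALSE, dim = dims)
    sep <- spec$min_separation_vox
    blobs <- vector("list", spec$n_junctions)
    for (b in seq_len(spec$n_junctions)) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        seedv <- c(sample.int(dims[1], 1), sample.int(dims[2], 1),
                   sample.int(dims[3], 1))
        if (forbidden[seedv[1], seedv[2], seedv[3]]) next
        size <- sample(spec$blob_voxel_range[1]:spec$blob_voxel_range[2], 1)
        vox <- grow_blob(seedv, size, dims, forbidden)
        if (is.null(vox)) next
        # dilate by the separation distance and mark forbidden
        off <- as.matrix(expand.grid(-sep:sep, -sep:sep, -sep:sep))
        dil <- vox[rep(seq_len(nrow(vox)), each = nrow(off)), , drop = FALSE] +
          off[rep(seq_len(nrow(off)), times = nrow(vox)), , drop = FALSE]
        keep <- dil[, 1] >= 1 & dil[, 1] <= dims[1] &
                dil[, 2] >= 1 & dil[, 2] <= dims[2] &
                dil[, 3] >= 1 & dil[, 3] <= dims[3]
        forbidden[dil[keep, , drop = FALSE]] <- TRUE
        blobs[[b]] <- vox
        placed <- TRUE
        break
      }
      if (!placed)
        abort("infeasible packing: could not place all blobs")
    }
    for (vox in blobs)
      data[vox] <- clamp(rnorm(nrow(vox), spec$blob_gray_mean,
                               spec$blob_gray_sd))
    grid <- voxel_grid(data, spec$voxel_size)
    if (spec$n_junctions == 0L) {
      truth <- empty_junction_table()
    } else {
      cent <- t(vapply(blobs, function(m)
        colMeans(voxel_centers_um(m, spec$voxel_size)), numeric(3)))
      truth <- tibble::tibble(
        junction_id = seq_along(blobs),
        syn_type = ifelse(runif(length(blobs)) < spec$as_fraction,
                          "AS", "SS"),
        n_voxels = vapply(blobs, nrow, integer(1)),
        x_um = cent[, 1], y_um = cent[, 2], z_um = cent[, 3],
        voxels = lapply(blobs, function(m) {
          storage.mode(m) <- "integer"; dimnames(m) <- NULL; m
        }))
    }
    list(grid = grid, truth = truth)
  })
}

#' Fiber-network specification
#'
#' Study-condition parameters of the synthetic fiber network. Defaults are
#' the SR (stratum radiatum) magnitudes: the published per-class length
#' densities, per-micron synapse rates of 0.38 (excitatory) and 0.33
#' (inhibitory), an AS-on-spine fraction of ~93% of AS, ~60% of SS on
#' shafts, an 84.38/15.63 head/neck split for SS on spines, and ~5%
#' terminal boutons, in a 500 um^3 (corrected) region.
#'
#' Length densities and synapse rates refer to shrinkage-corrected
#' geometry; the generator builds fibers in measured (shrunken) space and
#' compensates through `factors`, so analysing its output with the same
#' factors recovers the targets.
#'
#' @param volume_um3 Corrected region volume in um^3.
#' @param length_density_m_per_mm3 Named per-class length densities.
#' @param axon_synapse_rate_per_um Named per-axon-class synapse rates
#'   (per corrected um of shaft).
#' @param spine_rate_per_um Spine branches per corrected um of spiny
#'   dendrite shaft.
#' @param as_spine_frac Fraction of AS placed on spines.
#' @param ss_shaft_frac Fraction of SS placed on shafts.
#' @param ss_spine_head_frac Fraction of SS-on-spine placed on the head.
#' @param smooth_shaft_weight Relative attractiveness per um of smooth-
#'   dendrite shaft vs spiny shaft for shaft-targeted synapses.
#' @param terminal_frac Fraction of synapses at terminal boutons.
#' @param multi_contact_prob Probability that an axon's later synapse
#'   reuses an already-contacted dendrite.
#' @param step_um Walk step in um (measured space).
#' @param straightness Persistence of the random walk in `[0, 1)`.
#' @param orientation_bias Bias of walk directions toward the z axis in
#'   `[0, 1]` (0 = isotropic, as in multidirectional neuropil).
#' @param factors A [shrinkage_factors()].
#' @return A `network_spec` object.
#' @export
network_spec <- function(volume_um3 = 500,
                         length_density_m_per_mm3 = c(
                           excitatory_axon = 6761.19,
                           inhibitory_axon = 195.14,
                           myelinated_axon = 17.72,
                           spiny_dendrite = 731.79,
                           smooth_dendrite = 87.89,
                           non_synaptic = 382.06),
                         axon_synapse_rate_per_um = c(
                           excitatory_axon = 0.38,
                           inhibitory_axon = 0.33,
                           myelinated_axon = 0.10),
                         spine_rate_per_um = 3,
                         as_spine_frac = 0.928,
                         ss_shaft_frac = 0.60,
                         ss_spine_head_frac = 0.8438,
                         smooth_shaft_weight = 7.4,
                         terminal_frac = 0.05,
                         multi_contact_prob = 0.08,
                         step_um = 0.5, straightness = 0.8,
                         orientation_bias = 0,
                         factors = shrinkage_factors()) {
  if (volume_um3 <= 0) abort("`volume_um3` must be > 0")
  if (any(length_density_m_per_mm3 < 0) || any(axon_synapse_rate_per_um < 0))
    abort("densities and rates must be >= 0")
  if (!all(names(length_density_m_per_mm3) %in% FIBER_CLASSES))
    abort("unknown fiber class in `length_density_m_per_mm3`")
  fr <- c(as_spine_frac, ss_shaft_frac, ss_spine_head_frac, terminal_frac,
          multi_contact_prob, orientation_bias)
  if (any(fr < 0) || any(fr > 1)) abort("fractions must lie in [0, 1]")
  structure(list(volume_um3 = volume_um3,
                 length_density_m_per_mm3 = length_density_m_per_mm3,
                 axon_synapse_rate_per_um = axon_synapse_rate_per_um,
                 spine_rate_per_um = spine_rate_per_um,
                 as_spine_frac = as_spine_frac, ss_shaft_frac = ss_shaft_frac,
                 ss_spine_head_frac = ss_spine_head_frac,
                 smooth_shaft_weight = smooth_shaft_weight,
                 terminal_frac = terminal_frac,
                 multi_contact_prob = multi_contact_prob,
                 step_um = step_um, straightness = straightness,
                 orientation_bias = orientation_bias, factors = factors),
            class = "network_spec")
}

runit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# Persistent random walk clipped at the box faces; returns an n x 3 matrix.
walk_fiber <- function(lo, hi, step, straightness, orientation_bias) {
  pos <- lo + runif(3) * (hi - lo)
  dir <- runit()
  if (orientation_bias > 0) {
    zax <- c(0, 0, sample(c(-1, 1), 1))
    dir <- dir * (1 - orientation_bias) + zax * orientation_bias
    dir <- dir / sqrt(sum(dir^2))
  }
  nodes <- matrix(pos, ncol = 3)
  for (i in seq_len(400L)) {
    dir <- dir * straightness + runit() * (1 - straightness)
    dir <- dir / sqrt(sum(dir^2))
    nxt <- pos + dir * step
    if (any(nxt < lo) || any(nxt > hi)) {
      # clip the final segment at the first face crossed
      t_ <- suppressWarnings(min(
        ifelse(dir < 0, (lo - pos) / (dir * step), Inf),
        ifelse(dir > 0, (hi - pos) / (dir * step), Inf)))
      if (is.finite(t_) && t_ > 1e-6)
        nodes <- rbind(nodes, pos + dir * step * t_)
      break
    }
    nodes <- rbind(nodes, nxt)
    pos <- nxt
  }
  nodes
}

# Trim a polyline so its total length is at most `max_len` (moving the
# final node along its segment); keeps at least 2 nodes.
trim_polyline <- function(nodes, max_len) {
  seg <- sqrt(rowSums(diff(nodes)^2))
  cum <- cumsum(seg)
  if (cum[length(cum)] <= max_len) return(nodes)
  k <- which(cum > max_len)[1]
  excess <- cum[k] - max_len
  frac <- 1 - excess / seg[k]
  frac <- max(frac, 1e-3)
  last <- nodes[k, ] + (nodes[k + 1, ] - nodes[k, ]) * frac
  rbind(nodes[seq_len(k), , drop = FALSE], last)
}

#' Generate a synthetic fiber network with ground truth
#'
#' Fills the region with persistent-random-walk fibers until every class
#' reaches its target length density (realized lengths land within 5% of
#' target; the last fiber is trimmed), grows spine branches on spiny
#' dendrites, places synapses as Poisson processes along axon shafts at the
#' class rates, and wires each synapse to a postsynaptic dendrite according
#' to the configured target mixing, multi-contact propensity and bouton
#' shape.
#'
#' Realized lengths per *generated* class land within 5% of target (the
#' last fiber of each class is trimmed); the fibers table keeps this
#' generated class in `intended_class`. As in real tracing, a fiber can
#' only be classified by the synapses it actually establishes, so fibers
#' that draw zero synapses are returned with `fiber_class = "non_synaptic"`
#' whatever their intent -- generated networks therefore always pass
#' [validate_fibers()] cleanly, and generator-recovery checks of synapse
#' rates pool over `intended_class` (the unbiased ensemble).
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed.
#' @return List with `network` (a [fiber_network()]) and `synapses` (a
#'   junction tibble with ground-truth `syn_type`, `target`, `bouton`,
#'   `axon_id`, `dendrite_id`).
#' @export
generate_fiber_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  with_seed(seed, generate_fiber_network_impl(spec))
}

generate_fiber_network_impl <- function(spec) {
  f <- spec$factors
  v_meas <- spec$volume_um3 * f$volume
  side <- v_meas^(1 / 3)
  lo <- c(0, 0, 0); hi <- rep(side, 3)
  dens <- spec$length_density_m_per_mm3
  fibers <- list(); nodes <- list()
  fid <- 0L
  for (cls in names(dens)) {
    if (dens[[cls]] <= 0) next
    target <- dens[[cls]] * 1e-3 * spec$volume_um3 * f$linear  # measured um
    got <- 0
    while (got < target) {
      nm <- walk_fiber(lo, hi, spec$step_um, spec$straightness,
                       spec$orientation_bias)
      if (nrow(nm) < 2L) next
      nm <- trim_polyline(nm, target - got)
      dimnames(nm) <- NULL
      len <- polyline_length(nm)
      if (len < 1e-6) next
      fid <- fid + 1L
      fibers[[fid]] <- tibble::tibble(fiber_id = fid, fiber_class = cls,
                                      intended_class = cls,
                                      myelinated = cls == "myelinated_axon")
      nodes[[fid]] <- tibble::tibble(
        fiber_id = fid, node_id = seq_len(nrow(nm)),
        parent_id = c(NA_integer_, seq_len(nrow(nm) - 1L)),
        x_um = nm[, 1], y_um = nm[, 2], z_um = nm[, 3], role = "shaft")
      got <- got + len
    }
  }
  fibers <- dplyr::bind_rows(fibers)
  nodes <- dplyr::bind_rows(nodes)
  if (nrow(fibers) == 0L) {
    net <- fiber_network(
      tibble::tibble(fiber_id = integer(), fiber_class = character(),
                     myelinated = logical()),
      tibble::tibble(fiber_id = integer(), node_id = integer(),
                     parent_id = integer(), x_um = numeric(),
                     y_um = numeric(), z_um = numeric(), role = character()))
    return(list(network = net, synapses = empty_synapse_table(), spec = spec))
  }

  # spine branches on spiny dendrites (neck + head node, ~0.7 um)
  spine_rows <- list(); spine_index <- list()
  for (dfid in fibers$fiber_id[fibers$fiber_class == "spiny_dendrite"]) {
    sh <- nodes[nodes$fiber_id == dfid, ]
    slen <- polyline_length(as.matrix(sh[, c("x_um", "y_um", "z_um")]))
    nsp <- max(1L, rpois(1, spec$spine_rate_per_um * slen / f$linear))
    next_id <- max(sh$node_id)
    for (s in seq_len(nsp)) {
      base <- sh[sample.int(nrow(sh), 1L), ]
      u <- runit()
      neck <- c(base$x_um, base$y_um, base$z_um) + 0.35 * u
      hdir <- u * 0.8 + runit() * 0.2
      hdir <- hdir / sqrt(sum(hdir^2))
      headp <- neck + 0.35 * hdir
      spine_rows[[length(spine_rows) + 1L]] <- tibble::tibble(
        fiber_id = dfid, node_id = next_id + c(1L, 2L),
        parent_id = c(base$node_id, next_id + 1L),
        x_um = c(neck[1], headp[1]), y_um = c(neck[2], headp[2]),
        z_um = c(neck[3], headp[3]), role = "spine")
      spine_index[[length(spine_index) + 1L]] <- tibble::tibble(
        fiber_id = dfid, head_id = next_id + 2L, neck_id = next_id + 1L)
      next_id <- next_id + 2L
    }
  }
  nodes <- dplyr::bind_rows(nodes, dplyr::bind_rows(spine_rows))
  spines <- dplyr::bind_rows(spine_index)
  if (nrow(spines)) spines$occupied <- FALSE

  # per-dendrite shaft weights for shaft-targeted synapses
  shaft_nodes <- nodes[nodes$role == "shaft", ]
  dend <- fibers[fibers$fiber_class %in% DENDRITE_CLASSES, ]
  dend_weight <- vapply(seq_len(nrow(dend)), function(i) {
    sh <- shaft_nodes[shaft_nodes$fiber_id == dend$fiber_id[i], ]
    w <- polyline_length(as.matrix(sh[, c("x_um", "y_um", "z_um")]))
    if (dend$fiber_class[i] == "smooth_dendrite") w * spec$smooth_shaft_weight
    else w
  }, numeric(1))

  syn <- list(); att <- list()
  sid <- 0L
  axons <- fibers[fibers$fiber_class %in% AXON_CLASSES, ]
  rates <- spec$axon_synapse_rate_per_um
  for (i in seq_len(nrow(axons))) {
    afid <- axons$fiber_id[i]
    acls <- axons$fiber_class[i]
    an <- nodes[nodes$fiber_id == afid, ]
    alen <- polyline_length(as.matrix(an[, c("x_um", "y_um", "z_um")])) /
      f$linear
    nsyn <- rpois(1, (rates[[acls]] %||% 0) * alen)
    if (acls == "myelinated_axon") nsyn <- max(1L, nsyn)
    if (nsyn == 0L) next
    ty <- if (acls == "inhibitory_axon") "SS" else "AS"
    contacted <- integer()
    for (s in seq_len(nsyn)) {
      terminal <- runif(1) < spec$terminal_frac
      pre_node <- if (terminal || nrow(an) <= 2L)
        an$node_id[sample(c(1L, nrow(an)), 1L)]
      else an$node_id[sample(2:(nrow(an) - 1L), 1L)]
      want_spine <- if (ty == "AS") runif(1) < spec$as_spine_frac
                    else runif(1) >= spec$ss_shaft_frac
      reuse <- length(contacted) > 0 && runif(1) < spec$multi_contact_prob
      d_id <- NA_integer_
      if (reuse) d_id <- contacted[sample.int(length(contacted), 1L)]
      d_cls <- if (!is.na(d_id))
        dend$fiber_class[match(d_id, dend$fiber_id)] else NA
      if (want_spine) {
        cand <- if (!is.na(d_id) && identical(d_cls, "spiny_dendrite"))
          which(spines$fiber_id == d_id) else seq_len(nrow(spines))
        if (!length(cand)) want_spine <- FALSE
        else {
          pref <- if (ty == "AS") cand[!spines$occupied[cand]]
                  else cand[spines$occupied[cand]]
          pick <- if (length(pref)) pref[sample.int(length(pref), 1L)]
                  else cand[sample.int(length(cand), 1L)]
          d_id <- spines$fiber_id[pick]
          on_head <- ty == "AS" || runif(1) < spec$ss_spine_head_frac
          post_node <- if (on_head) spines$head_id[pick]
                       else spines$neck_id[pick]
          target <- if (on_head) "spine_head" else "spine_neck"
          spines$occupied[pick] <- TRUE
        }
      }
      if (!want_spine) {
        if (is.na(d_id)) {
          if (!nrow(dend) || sum(dend_weight) == 0) next
          d_id <- dend$fiber_id[sample.int(nrow(dend), 1L,
                                           prob = dend_weight)]
        }
        dn <- shaft_nodes[shaft_nodes$fiber_id == d_id, ]
        post_node <- dn$node_id[sample.int(nrow(dn), 1L)]
        target <- "shaft"
      }
      contacted <- unique(c(contacted, d_id))
      sid <- sid + 1L
      pn <- nodes[nodes$fiber_id == d_id & nodes$node_id == post_node, ]
      syn[[sid]] <- tibble::tibble(
        synapse_id = sid, syn_type = ty, x_um = pn$x_um, y_um = pn$y_um,
        z_um = pn$z_um, target = target,
        bouton = if (pre_node %in% c(an$node_id[1], an$node_id[nrow(an)]))
          "terminal" else "en_passant",
        axon_id = afid, dendrite_id = d_id)
      att[[length(att) + 1L]] <- tibble::tibble(
        synapse_id = sid, fiber_id = c(afid, d_id),
        node_id = c(pre_node, post_node), side = c("pre", "post"))
    }
  }
  synapses <- if (length(syn)) dplyr::bind_rows(syn) else empty_synapse_table()
  attachments <- if (length(att)) dplyr::bind_rows(att) else NULL

  # fibers whose intended class got no attachments become non-synaptic
  with_att <- unique(if (is.null(attachments)) integer()
                     else attachments$fiber_id)
  fibers$fiber_class[!(fibers$fiber_id %in% with_att) &
                       fibers$fiber_class != "non_synaptic"] <- "non_synaptic"
  list(network = fiber_network(fibers, nodes, attachments),
       synapses = synapses, spec = spec)
}

empty_synapse_table <- function() {
  tibble::tibble(synapse_id = integer(), syn_type = character(),
                 x_um = numeric(), y_um = numeric(), z_um = numeric(),
                 target = character(), bouton = character(),
                 axon_id = integer(), dendrite_id = integer())
}

#' Simulate a uniform cloud of synaptic junction points
#'
#' Homogeneous Poisson point process of junction centroids in a box of
#' measured space, at a given shrinkage-corrected volumetric density
#' (the expected count is `density * measured_volume / volume_factor`).
#' Used to exercise counting-frame unbiasedness and density recovery.
#'
#' @param lo,hi Box corners in um (measured space).
#' @param density_per_um3 Corrected volumetric density (synapses/um^3).
#' @param as_fraction Probability of an AS label.
#' @param factors A [shrinkage_factors()].
#' @param seed Integer seed.
#' @return Junction tibble with centroid columns and `syn_type`.
#' @export
simulate_junction_points <- function(lo, hi, density_per_um3,
                                     as_fraction = 0.971,
                                     factors = shrinkage_factors(),
                                     seed = 1L) {
  if (any(hi <= lo)) abort("`hi` must exceed `lo`")
  if (density_per_um3 < 0) abort("density must be >= 0")
  with_seed(seed, {
    vol_corr <- corrected_volume(prod(hi - lo), factors)
    n <- rpois(1, density_per_um3 * vol_corr)
    tibble::tibble(
      junction_id = seq_len(n),
      syn_type = ifelse(runif(n) < as_fraction, "AS", "SS"),
      x_um = runif(n, lo[1], hi[1]),
      y_um = runif(n, lo[2], hi[2]),
      z_um = runif(n, lo[3], hi[3]))
  })
}

#' Published per-region summary values (fixture)
#'
#' The printed per-region quantities used by the acceptance checks: the
#' fiber-class length densities (m/mm^3) with their printed percentages
#' and totals for the stratum radiatum (SR) and layers 1 and 3 of the
#' somatosensory cortex (L1, L3), and the volumetric synapse densities
#' with the printed SS percentages. Values are immutable as printed;
#' note the L1 and L3 printed totals differ from their column sums by
#' 0.01 m/mm^3 (rounding in the source table).
#'
#' @return List with tibbles `lengths` (`region`, `fiber_class`,
#'   `length_m_per_mm3`, `printed_pct`), `totals` (`region`,
#'   `printed_total_m_per_mm3`, `printed_synaptic_m_per_mm3`) and
#'   `synapse_density` (`region`, densities and printed SS share).
#' @export
table1_fixture <- function() {
  cls <- c("non_synaptic", "excitatory_axon", "inhibitory_axon",
           "myelinated_axon", "spiny_dendrite", "smooth_dendrite")
  lengths <- tibble::tibble(
    region = rep(c("SR", "L1", "L3"), each = 6L),
    fiber_class = rep(cls, 3L),
    length_m_per_mm3 = c(382.06, 6761.19, 195.14, 17.72, 731.79, 87.89,
                         1387.28, 6371.80, 578.53, 42.68, 961.27, 37.22,
                         2376.22, 4237.03, 282.96, 21.16, 601.56, 27.30),
    printed_pct = c(4.67, 82.70, 2.39, 0.22, 8.95, 1.08,
                    14.79, 67.94, 6.17, 0.46, 10.25, 0.40,
                    31.49, 56.15, 3.75, 0.28, 7.97, 0.36))
  totals <- tibble::tibble(
    region = c("SR", "L1", "L3"),
    printed_total_m_per_mm3 = c(8175.79, 9378.79, 7546.22),
    printed_synaptic_m_per_mm3 = c(7793.73, 7991.50, 5170.00))
  synapse_density <- tibble::tibble(
    region = c("SR", "L1", "L3"),
    total_per_um3 = c(2.76, 1.80, 1.08),
    ss_per_um3 = c(0.08, 0.20, 0.07),
    printed_ss_pct = c(2.90, 11.11, 6.09))
  list(lengths = lengths, totals = totals, synapse_density = synapse_density)
}
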