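# Shared domain types: voxel grids, counting frames, shrinkage factors,
# fiber networks (skeletons + synapse attachments), and structural
# validation of the fiber classification rules.

FIBER_CLASSES <- c("spiny_dendrite", "smooth_dendrite", "excitatory_axon",
                   "inhibitory_axon", "myelinated_axon", "non_synaptic")
DENDRITE_CLASSES <- c("spiny_dendrite", "smooth_dendrite")
AXON_CLASSES <- c("excitatory_axon", "inhibitory_axon", "myelinated_axon")

#' Create a voxel grid
#'
#' A `voxel_grid` wraps a 3D array of gray levels together with its
#' (possibly anisotropic) voxel size. Darker voxels are more electron-dense;
#' FIB-SEM stacks are typically acquired at 5 x 5 nm in-plane with 20 nm
#' section thickness. Voxel `(i, j, k)` (1-based) has its center at
#' `origin + ((i - 0.5) * sx, (j - 0.5) * sy, (k - 0.5) * sz)` nm, reported
#' in micrometers, so all geometry is independent of grid resolution.
#'
#' @param data 3D numeric array of gray levels, indexed `[x, y, z]`.
#' @param voxel_size Numeric length-3, voxel pitch in nm `(sx, sy, sz)`.
#' @param origin Numeric length-3, position of the grid corner in um.
#' @param bit_depth Gray-level bit depth (8 or 16).
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(array(128, dim = c(4, 4, 2)))
#' dim(g$data)
#' @export
voxel_grid <- function(data, voxel_size = c(5, 5, 20), origin = c(0, 0, 0),
                       bit_depth = 8) {
  if (!is.array(data) || length(dim(data)) != 3L)
    abort("`data` must be a 3D array")
  if (any(dim(data) < 1L)) abort("all grid dimensions must be >= 1")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    abort("`voxel_size` must be 3 positive numbers (nm)")
  if (length(origin) != 3L) abort("`origin` must have length 3")
  if (!bit_depth %in% c(8L, 16L)) abort("`bit_depth` must be 8 or 16")
  rng <- range(data, finite = TRUE)
  if (rng[1] < 0 || rng[2] > 2^bit_depth - 1)
    abort(sprintf("gray levels outside the declared %d-bit range", bit_depth))
  structure(list(data = data, voxel_size = voxel_size,
                 origin = as.numeric(origin), bit_depth = as.integer(bit_depth)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, %g x %g x %g nm, %d-bit\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3], x$bit_depth))
  ext <- grid_extent_um(x)
  cat(sprintf("  extent: %.3f x %.3f x %.3f um\n",
              ext$hi[1] - ext$lo[1], ext$hi[2] - ext$lo[2],
              ext$hi[3] - ext$lo[3]))
  invisible(x)
}

# Physical extent of a grid in um: [lo, hi] per axis.
grid_extent_um <- function(grid) {
  hi <- grid$origin + dim(grid$data) * grid$voxel_size / 1000
  list(lo = grid$origin, hi = hi)
}

#' Convert 1-based voxel indices to voxel-center positions in micrometers
#'
#' @param idx Integer matrix with columns `(i, j, k)`, 1-based.
#' @param voxel_size Voxel pitch in nm.
#' @param origin Grid origin in um.
#' @return Numeric matrix of `(x, y, z)` positions in um.
#' @export
voxel_centers_um <- function(idx, voxel_size = c(5, 5, 20),
                             origin = c(0, 0, 0)) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(sweep(idx - 0.5, 2, voxel_size / 1000, `*`), 2, origin, `+`)
}

#' Tissue shrinkage correction factors
#'
#' Brain tissue shrinks during processing for electron microscopy. Each
#' factor is the post-processing / pre-processing ratio, so measured
#' quantities are *divided* by the factor to recover in-vivo values
#' (e.g. a measured volume of 87 um^3 with `volume = 0.87` corrects to
#' 100 um^3). Defaults are the values estimated for osmicated,
#' Araldite-embedded mouse cortex.
#'
#' @param volume,surface,linear Ratios in `(0, 1]`.
#' @return An object of class `shrinkage_factors`.
#' @export
shrinkage_factors <- function(volume = 0.87, surface = 0.91, linear = 0.96) {
  f <- c(volume = volume, surface = surface, linear = linear)
  if (any(!is.finite(f)) || any(f <= 0) || any(f > 1))
    abort("shrinkage factors must lie in (0, 1]")
  structure(as.list(f), class = "shrinkage_factors")
}

#' No-op shrinkage factors (disable correction)
#' @return `shrinkage_factors(1, 1, 1)`.
#' @export
no_shrinkage <- function() shrinkage_factors(1, 1, 1)

FRAME_FACES <- c("x-", "x+", "y-", "y+", "z-", "z+")

#' Create an unbiased 3D counting frame
#'
#' An axis-aligned brick bounded by three acceptance planes and three
#' exclusion planes (one exclusion face per axis, conventionally the low
#' faces). Objects touching an exclusion plane -- extended beyond the frame
#' bounds -- are discarded; objects inside the brick or touching only
#' acceptance planes are counted. Under tiling this counts each object
#' exactly once.
#'
#' @param lo,hi Numeric length-3 corners in um, `lo < hi` componentwise.
#' @param exclusion_faces Character vector of exactly three of
#'   `"x-", "x+", "y-", "y+", "z-", "z+"`, one per axis.
#' @return An object of class `counting_frame`.
#' @examples
#' counting_frame(c(0, 0, 0), c(5, 5, 5))
#' @export
counting_frame <- function(lo, hi, exclusion_faces = c("x-", "y-", "z-")) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  if (length(lo) != 3L || length(hi) != 3L) abort("`lo`/`hi` must be length 3")
  if (any(!is.finite(c(lo, hi))) || any(lo >= hi))
    abort("`lo` must be < `hi` componentwise")
  if (length(exclusion_faces) != 3L ||
      !all(exclusion_faces %in% FRAME_FACES) ||
      anyDuplicated(substr(exclusion_faces, 1, 1)))
    abort("`exclusion_faces` must name exactly one face per axis")
  structure(list(lo = lo, hi = hi,
                 exclusion_faces = sort(exclusion_faces)),
            class = "counting_frame")
}

#' @export
print.counting_frame <- function(x, ...) {
  cat(sprintf("<counting_frame> [%.3f, %.3f] x [%.3f, %.3f] x [%.3f, %.3f] um\n",
              x$lo[1], x$hi[1], x$lo[2], x$hi[2], x$lo[3], x$hi[3]))
  cat("  exclusion faces:", paste(x$exclusion_faces, collapse = ", "), "\n")
  invisible(x)
}

#' Assemble a fiber network from node, fiber and attachment tables
#'
#' A fiber network is the skeletonized representation of all traced nerve
#' fibers in a tissue volume: each fiber is a rooted tree of nodes (shaft
#' polyline plus spine branches), carries a fiber class, and is linked to
#' segmented synaptic junctions through pre-/postsynaptic attachments.
#'
#' @param fibers Tibble with columns `fiber_id`, `fiber_class` (one of
#'   `r paste(FIBER_CLASSES, collapse = ", ")`), `myelinated` (logical).
#' @param nodes Tibble with columns `fiber_id`, `node_id`, `parent_id`
#'   (`NA` for roots), `x_um`, `y_um`, `z_um`, `role` (`"shaft"` or
#'   `"spine"`). Coordinates are in measured (post-shrinkage) space.
#' @param attachments Tibble with columns `synapse_id`, `fiber_id`,
#'   `node_id`, `side` (`"pre"` or `"post"`).
#' @return An object of class `fiber_network`.
#' @export
fiber_network <- function(fibers, nodes, attachments = NULL) {
  fibers <- tibble::as_tibble(fibers)
  nodes <- tibble::as_tibble(nodes)
  if (is.null(attachments))
    attachments <- tibble::tibble(synapse_id = integer(), fiber_id = integer(),
                                  node_id = integer(), side = character())
  attachments <- tibble::as_tibble(attachments)
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      abort(sprintf("%s table lacks column(s): %s", what,
                    paste(miss, collapse = ", ")))
  }
  need(fibers, c("fiber_id", "fiber_class", "myelinated"), "fibers")
  need(nodes, c("fiber_id", "node_id", "parent_id", "x_um", "y_um", "z_um",
                "role"), "nodes")
  need(attachments, c("synapse_id", "fiber_id", "node_id", "side"),
       "attachments")
  if (anyDuplicated(fibers$fiber_id)) abort("duplicated fiber_id")
  bad <- setdiff(unique(fibers$fiber_class), c(FIBER_CLASSES, NA))
  if (length(bad))
    abort(sprintf("unknown fiber_class: %s", paste(bad, collapse = ", ")))
  if (!all(nodes$role %in% c("shaft", "spine")))
    abort("node role must be 'shaft' or 'spine'")
  if (!all(nodes$fiber_id %in% fibers$fiber_id))
    abort("node references a missing fiber (reference error)")
  key <- paste(nodes$fiber_id, nodes$node_id)
  if (anyDuplicated(key)) abort("duplicated (fiber_id, node_id)")
  pk <- paste(nodes$fiber_id, nodes$parent_id)
  dangling <- !is.na(nodes$parent_id) & !(pk %in% key)
  if (any(dangling))
    abort(sprintf("dangling parent_id for node(s) %s (reference error)",
                  paste(utils::head(nodes$node_id[dangling], 5), collapse = ", ")))
  if (nrow(attachments)) {
    if (!all(attachments$side %in% c("pre", "post")))
      abort("attachment side must be 'pre' or 'post'")
    if (!all(paste(attachments$fiber_id, attachments$node_id) %in% key))
      abort("attachment references a missing node (reference error)")
  }
  structure(list(fibers = fibers, nodes = nodes, attachments = attachments),
            class = "fiber_network")
}

#' @export
print.fiber_network <- function(x, ...) {
  cat(sprintf("<fiber_network> %d fibers, %d nodes, %d attachments\n",
              nrow(x$fibers), nrow(x$nodes), nrow(x$attachments)))
  if (nrow(x$fibers)) {
    tab <- table(x$fibers$fiber_class)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

# Spine-branch bookkeeping: assign each spine node to a branch whose root
# attaches to a shaft node. Returns nodes with a `branch_id` column
# (NA for shaft nodes) and, per branch, the arc-length position of every
# spine node measured from the shaft attachment point.
spine_branches <- function(network) {
  nodes <- network$nodes
  nodes$.row <- seq_len(nrow(nodes))
  key <- paste(nodes$fiber_id, nodes$node_id)
  parent_row <- match(paste(nodes$fiber_id, nodes$parent_id), key)
  branch_id <- rep(NA_integer_, nrow(nodes))
  arc_um <- rep(NA_real_, nrow(nodes))
  seg_len <- rep(NA_real_, nrow(nodes))
  has_par <- !is.na(parent_row)
  seg_len[has_par] <- sqrt((nodes$x_um[has_par] - nodes$x_um[parent_row[has_par]])^2 +
                           (nodes$y_um[has_par] - nodes$y_um[parent_row[has_par]])^2 +
                           (nodes$z_um[has_par] - nodes$z_um[parent_row[has_par]])^2)
  is_spine <- nodes$role == "spine"
  # branch roots: spine nodes whose parent is a shaft node (or missing)
  root_rows <- which(is_spine &
                     (is.na(parent_row) | nodes$role[parent_row] == "shaft"))
  nb <- 0L
  # children lookup restricted to spine nodes
  kids <- split(which(is_spine & has_par), parent_row[is_spine & has_par])
  for (r in root_rows) {
    nb <- nb + 1L
    stack <- r
    arc_um[r] <- seg_len[r] %||% 0
    if (is.na(arc_um[r])) arc_um[r] <- 0
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      branch_id[v] <- nb
      ch <- kids[[as.character(v)]]
      if (length(ch)) {
        arc_um[ch] <- arc_um[v] + seg_len[ch]
        stack <- c(stack, ch)
      }
    }
  }
  nodes$branch_id <- branch_id
  nodes$arc_um <- arc_um
  nodes$seg_len_um <- seg_len
  nodes$parent_row <- parent_row
  nodes
}

#' Validate fiber traces against the classification rules
#'
#' Checks every fiber against the structural rules implied by the
#' classification scheme: dendrites carry only postsynaptic attachments and
#' axons only presynaptic ones; excitatory axons establish only asymmetric
#' (AS) and inhibitory axons only symmetric (SS) junctions; spiny dendrites
#' have at least one spine branch while smooth dendrites have none;
#' non-synaptic fibers have no attachments; spine branches are rooted on
#' shaft nodes. An axon attaching both AS and SS junctions is reported as a
#' violation (mixed classes are never silently resolved).
#'
#' @param network A [fiber_network()].
#' @param synapses Tibble of synaptic junctions with at least `synapse_id`
#'   and `syn_type` (`"AS"`/`"SS"`); used to check axon-class/junction-type
#'   consistency. May be `NULL` to skip those checks.
#' @return A tibble of violations (`fiber_id`, `rule`, `detail`); zero rows
#'   when every invariant holds. The check is idempotent and side-effect
#'   free.
#' @export
validate_fibers <- function(network, synapses = NULL) {
  stopifnot(inherits(network, "fiber_network"))
  att <- network$attachments
  if (!is.null(synapses) && nrow(att) &&
      !all(att$synapse_id %in% synapses$synapse_id))
    abort("attachment references a missing synapse (reference error)")
  out <- list()
  bad <- function(fiber_id, rule, detail)
    out[[length(out) + 1L]] <<- tibble::tibble(fiber_id = fiber_id,
                                               rule = rule, detail = detail)
  nodes <- spine_branches(network)
  n_nodes <- table(factor(network$nodes$fiber_id,
                          levels = network$fibers$fiber_id))
  spine_counts <- tapply(!is.na(nodes$branch_id), nodes$fiber_id, sum)
  branch_counts <- tapply(nodes$branch_id, nodes$fiber_id,
                          function(b) length(unique(b[!is.na(b)])))
  # spine nodes not reachable from a shaft attachment (orphan spine chains)
  orphan <- nodes$role == "spine" & is.na(nodes$branch_id)
  for (f in unique(nodes$fiber_id[orphan]))
    bad(f, "spine_branch_root", "spine nodes not attached to a shaft node")

  for (i in seq_len(nrow(network$fibers))) {
    fid <- network$fibers$fiber_id[i]
    cls <- network$fibers$fiber_class[i]
    if (n_nodes[[as.character(fid)]] < 1L) {
      bad(fid, "nonempty", "fiber has no nodes")
      next
    }
    a <- att[att$fiber_id == fid, , drop = FALSE]
    sides <- unique(a$side)
    nb <- branch_counts[[as.character(fid)]] %||% 0L
    if (is.na(nb)) nb <- 0L
    if (all(c("pre", "post") %in% sides))
      bad(fid, "pre_post_exclusive",
          "fiber is both pre- and postsynaptic")
    if (cls %in% DENDRITE_CLASSES && "pre" %in% sides)
      bad(fid, "dendrite_postsynaptic_only",
          "dendrite carries presynaptic attachments")
    if (cls %in% AXON_CLASSES && "post" %in% sides)
      bad(fid, "axon_presynaptic_only",
          "axon carries postsynaptic attachments")
    if (cls == "non_synaptic" && nrow(a))
      bad(fid, "non_synaptic_no_attachments",
          sprintf("non-synaptic fiber has %d attachment(s)", nrow(a)))
    if (cls != "non_synaptic" && !is.na(cls) && nrow(a) == 0L)
      bad(fid, "synaptic_class_needs_attachment",
          sprintf("class %s requires at least one attachment", cls))
    if (cls == "smooth_dendrite" && nb > 0L)
      bad(fid, "smooth_no_spines",
          sprintf("smooth dendrite has %d spine branch(es)", nb))
    if (cls == "spiny_dendrite" && nb < 1L)
      bad(fid, "spiny_needs_spine", "spiny dendrite has no spine branch")
    if (!is.null(synapses) && cls %in% c("excitatory_axon", "inhibitory_axon") &&
        nrow(a)) {
      types <- synapses$syn_type[match(a$synapse_id, synapses$synapse_id)]
      want <- if (cls == "excitatory_axon") "AS" else "SS"
      nbadty <- sum(types != want, na.rm = TRUE)
      if (nbadty || length(unique(stats::na.omit(types))) > 1L)
        bad(fid, "axon_type_consistency",
            sprintf("%s attaches %d junction(s) of the wrong type",
                    cls, nbadty))
    }
  }
  if (length(out)) dplyr::bind_rows(out)
  else tibble::tibble(fiber_id = integer(), rule = character(),
                      detail = character())
}
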