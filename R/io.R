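# File formats: TIFF stacks, the skeleton JSON dialect, SWC-extended
# import, junction tables. All writes are atomic (temp file + rename).
# Coordinates in files are always um in measured space; shrinkage
# corrections are applied at metric computation, never persisted.

write_atomic <- function(lines, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) abort(sprintf("cannot write %s", path))
  invisible(path)
}

#' Read an image stack from TIFF
#'
#' Accepts a multipage TIFF or a directory of single-page serial TIFFs
#' (sorted lexicographically = z order). Gray levels are read as stored
#' integers.
#'
#' @param path TIFF file or directory.
#' @param voxel_size Voxel pitch in nm (TIFF rarely carries the z pitch).
#' @param origin Grid origin in um.
#' @param bit_depth Gray bit depth (8 or 16).
#' @return A [voxel_grid()] whose z order equals page/file order.
#' @export
read_stack <- function(path, voxel_size = c(5, 5, 20), origin = c(0, 0, 0),
                       bit_depth = 8) {
  pages <- if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (!length(files)) abort(sprintf("no TIFF files in %s", path))
    unlist(lapply(files, tiff::readTIFF, all = TRUE, as.is = TRUE),
           recursive = FALSE)
  } else {
    p <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (is.matrix(p)) list(p) else p
  }
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    abort("inconsistent page dimensions (format error)")
  # TIFF pages are (row = y, col = x); store as [x, y, z]
  data <- array(0L, dim = c(dims[2, 1], dims[1, 1], length(pages)))
  for (k in seq_along(pages)) data[, , k] <- t(pages[[k]])
  voxel_grid(data, voxel_size, origin, bit_depth)
}

#' Write an image stack as multipage TIFF
#'
#' @param grid A [voxel_grid()]; gray levels are written at the grid's bit
#'   depth (values are rounded and clamped to range).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  maxval <- 2^grid$bit_depth - 1
  pages <- lapply(seq_len(dim(grid$data)[3]), function(k) {
    m <- round(grid$data[, , k])
    m[m < 0] <- 0
    m[m > maxval] <- maxval
    t(m) / maxval
  })
  tmp <- paste0(path, ".tmp", Sys.getpid(), ".tif")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  tiff::writeTIFF(pages, tmp, bits.per.sample = grid$bit_depth)
  if (!file.rename(tmp, path)) abort(sprintf("cannot write %s", path))
  invisible(path)
}

#' Write fibers and synapses to the skeleton JSON dialect
#'
#' A versioned JSON schema with four arrays: `fibers` (id, class,
#' myelinated), `nodes` (fiber, id, parent, x, y, z um, role), `synapses`
#' and `attachments` (synapse, fiber, node, side). Numbers are written at
#' full precision so a read-back reproduces topology, classes and
#' positions exactly.
#'
#' @param network A [fiber_network()].
#' @param path Output path.
#' @param synapses Optional junction tibble stored alongside.
#' @return `path`, invisibly.
#' @export
write_skeletons <- function(network, path, synapses = NULL) {
  stopifnot(inherits(network, "fiber_network"))
  body <- list(format = "synaptometry/skeletons", version = 1L,
               fibers = as.data.frame(network$fibers),
               nodes = as.data.frame(network$nodes),
               attachments = as.data.frame(network$attachments))
  if (!is.null(synapses)) {
    s <- as.data.frame(synapses)
    s$voxels <- NULL
    body$synapses <- s
  }
  json <- jsonlite::toJSON(body, dataframe = "columns", auto_unbox = TRUE,
                           digits = NA, na = "null", pretty = TRUE)
  write_atomic(as.character(json), path)
}

json_tbl <- function(x, proto) {
  if (is.null(x) || !length(x)) return(proto)
  df <- tibble::as_tibble(lapply(x, unlist_nullable))
  for (nm in names(proto))
    if (!nm %in% names(df)) df[[nm]] <- proto[[nm]][0][NA]
  for (nm in names(proto))
    storage.mode(df[[nm]]) <- storage.mode(proto[[nm]])
  df[, names(proto)]
}

unlist_nullable <- function(v) {
  if (!is.list(v)) return(v)
  v[vapply(v, is.null, logical(1))] <- NA
  unlist(v)
}

#' Read fibers and synapses from the skeleton JSON dialect
#'
#' @param path A file written by [write_skeletons()].
#' @return List with `network` (a [fiber_network()]) and `synapses`
#'   (possibly empty tibble). Dangling references raise an error.
#' @export
read_skeletons <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  if (!identical(raw$format, "synaptometry/skeletons"))
    abort(sprintf("%s: not a skeleton file (format error)", path))
  fibers <- json_tbl(raw$fibers,
                     tibble::tibble(fiber_id = integer(),
                                    fiber_class = character(),
                                    myelinated = logical()))
  nodes <- json_tbl(raw$nodes,
                    tibble::tibble(fiber_id = integer(), node_id = integer(),
                                   parent_id = integer(), x_um = numeric(),
                                   y_um = numeric(), z_um = numeric(),
                                   role = character()))
  attachments <- json_tbl(raw$attachments,
                          tibble::tibble(synapse_id = integer(),
                                         fiber_id = integer(),
                                         node_id = integer(),
                                         side = character()))
  synapses <- json_tbl(raw$synapses, empty_synapse_table())
  list(network = fiber_network(fibers, nodes, attachments),
       synapses = synapses)
}

#' Import skeletons from SWC (extended)
#'
#' Standard SWC columns `id type x y z radius parent` (um; parent `-1` for
#' roots; comment lines start with `#`), with the extension that type code
#' 10 marks spine nodes (any other code is shaft). Each root starts one
#' fiber whose id is the root node id. Fiber classes and synapse
#' attachments arrive through sidecar tables because SWC carries neither.
#'
#' @param path SWC file.
#' @param classes Optional data frame (or CSV path) with `root_id`,
#'   `fiber_class`, `myelinated`.
#' @param attachments Optional data frame (or CSV path) with `synapse_id`,
#'   `node_id` (global SWC id), `side`.
#' @return A [fiber_network()]. Orphan parent references raise an error
#'   naming the offending line.
#' @export
read_swc <- function(path, classes = NULL, attachments = NULL) {
  df <- utils::read.table(path, comment.char = "#",
                          col.names = c("id", "type", "x", "y", "z",
                                        "radius", "parent"))
  if (anyDuplicated(df$id)) abort("duplicate SWC node id (format error)")
  pidx <- match(df$parent, df$id)
  orphan <- df$parent != -1 & is.na(pidx)
  if (any(orphan))
    abort(sprintf("SWC orphan parent %d at line %d (format error)",
                  df$parent[which(orphan)[1]], which(orphan)[1]))
  # root of every node by climbing the parent chain (memoized)
  root <- rep(NA_integer_, nrow(df))
  for (i in seq_len(nrow(df))) {
    chain <- i
    j <- i
    while (df$parent[j] != -1 && is.na(root[j])) {
      j <- pidx[j]
      chain <- c(chain, j)
    }
    root[chain] <- if (!is.na(root[j])) root[j] else df$id[j]
  }
  nodes <- tibble::tibble(
    fiber_id = root, node_id = df$id,
    parent_id = ifelse(df$parent == -1, NA_integer_, df$parent),
    x_um = df$x, y_um = df$y, z_um = df$z,
    role = ifelse(df$type == 10L, "spine", "shaft"))
  if (is.character(classes)) classes <- utils::read.csv(classes)
  if (is.character(attachments)) attachments <- utils::read.csv(attachments)
  roots <- sort(unique(root))
  fibers <- tibble::tibble(fiber_id = roots,
                           fiber_class = NA_character_, myelinated = FALSE)
  if (!is.null(classes)) {
    m <- match(fibers$fiber_id, classes$root_id)
    fibers$fiber_class <- as.character(classes$fiber_class[m])
    fibers$myelinated <- isTRUE_vec(classes$myelinated[m])
  }
  att <- NULL
  if (!is.null(attachments)) {
    att <- tibble::tibble(synapse_id = attachments$synapse_id,
                          fiber_id = root[match(attachments$node_id, df$id)],
                          node_id = attachments$node_id,
                          side = as.character(attachments$side))
    if (anyNA(att$fiber_id))
      abort("attachment references a missing SWC node (format error)")
  }
  fiber_network(fibers, nodes, att)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Export a network to SWC (extended) with a class sidecar
#'
#' Node ids are renumbered globally; spine nodes get type code 10, shaft
#' nodes 3 (dendrites), 2 (axons) or 0.
#'
#' @param network A [fiber_network()].
#' @param path Output SWC path.
#' @return Invisibly, the `classes` sidecar tibble (`root_id`,
#'   `fiber_class`, `myelinated`) for [read_swc()].
#' @export
write_swc <- function(network, path) {
  nodes <- network$nodes
  gid <- seq_len(nrow(nodes))
  key <- paste(nodes$fiber_id, nodes$node_id)
  pg <- gid[match(paste(nodes$fiber_id, nodes$parent_id), key)]
  cls <- network$fibers$fiber_class[match(nodes$fiber_id,
                                          network$fibers$fiber_id)]
  type <- ifelse(nodes$role == "spine", 10L,
                 ifelse(cls %in% DENDRITE_CLASSES, 3L,
                        ifelse(cls %in% AXON_CLASSES, 2L, 0L)))
  lines <- sprintf("%d %d %.9g %.9g %.9g %.3g %d", gid, type, nodes$x_um,
                   nodes$y_um, nodes$z_um, 0.1,
                   ifelse(is.na(pg), -1L, pg))
  write_atomic(c("# SWC export (type 10 = spine node)", lines), path)
  roots <- gid[is.na(nodes$parent_id)]
  sidecar <- tibble::tibble(
    root_id = roots,
    fiber_class = network$fibers$fiber_class[match(
      nodes$fiber_id[is.na(nodes$parent_id)], network$fibers$fiber_id)],
    myelinated = network$fibers$myelinated[match(
      nodes$fiber_id[is.na(nodes$parent_id)], network$fibers$fiber_id)])
  invisible(sidecar)
}

#' Write a junction table to CSV (+ sparse voxel sidecar)
#'
#' The CSV holds one row per junction (`junction_id`, `n_voxels`, centroid,
#' `syn_type`); voxel index sets, when present, go to a sparse JSON sidecar
#' keyed by junction id.
#'
#' @param junctions Junction tibble.
#' @param path CSV path.
#' @param voxel_path Optional JSON sidecar path.
#' @return `path`, invisibly.
#' @export
write_junctions <- function(junctions, path, voxel_path = NULL) {
  df <- as.data.frame(junctions[, intersect(
    c("junction_id", "syn_type", "n_voxels", "x_um", "y_um", "z_um"),
    names(junctions))])
  tmp <- paste0(path, ".tmp", Sys.getpid())
  utils::write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
  if (!is.null(voxel_path) && "voxels" %in% names(junctions)) {
    vox <- lapply(junctions$voxels, function(m) as.vector(t(m)))
    names(vox) <- as.character(junctions$junction_id)
    json <- jsonlite::toJSON(list(format = "synaptometry/voxels",
                                  version = 1L, triplets = vox),
                             auto_unbox = TRUE)
    write_atomic(as.character(json), voxel_path)
  }
  invisible(path)
}

#' Read a junction table written by [write_junctions()]
#' @param path CSV path.
#' @param voxel_path Optional JSON voxel sidecar.
#' @return Junction tibble.
#' @export
read_junctions <- function(path, voxel_path = NULL) {
  df <- tibble::as_tibble(utils::read.csv(path))
  df$syn_type <- as.character(df$syn_type)
  if (!is.null(voxel_path)) {
    raw <- jsonlite::fromJSON(voxel_path)
    vox <- lapply(raw$triplets[as.character(df$junction_id)], function(v)
      matrix(as.integer(v), ncol = 3, byrow = TRUE))
    df$voxels <- unname(vox)
  }
  df
}
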