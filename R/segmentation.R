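# Synaptic-junction segmentation: Gaussian pre-filter, gray-level
# threshold, 3D connected components, size filter.

# Discrete Gaussian kernel, truncated at 4 sigma and normalized.
gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian pre-filtering of an image stack
#'
#' Smooths a gray-level stack with a separable Gaussian to suppress pixel
#' noise before thresholding. The sigma may be anisotropic: with 5 nm
#' in-plane pixels and 20 nm sections the default smooths in-plane only
#' (`sigma_z = 0`). A sigma of zero along an axis leaves that axis
#' untouched; a zero sigma everywhere returns the input unchanged.
#' Boundaries are handled by mirror reflection.
#'
#' @param grid A [voxel_grid()].
#' @param sigma_xy Standard deviation in pixels for the x and y axes.
#' @param sigma_z Standard deviation in sections for the z axis.
#' @return A [voxel_grid()] with identical dimensions and voxel size.
#' @export
gaussian_preprocess <- function(grid, sigma_xy = 1, sigma_z = 0) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (sigma_xy < 0 || sigma_z < 0) abort("sigma must be >= 0")
  if (sigma_xy == 0 && sigma_z == 0) return(grid)
  kxy <- gaussian_kernel(sigma_xy)
  kz <- gaussian_kernel(sigma_z)
  sm <- cpp_convolve_separable(as.numeric(grid$data), dim(grid$data),
                               kxy, kxy, kz)
  out <- grid
  out$data <- array(sm, dim = dim(grid$data))
  out
}

#' Segment synaptic junctions by gray-level thresholding
#'
#' Extracts the pre- and postsynaptic densities -- the darkest,
#' electron-dense elements of each synaptic junction -- as the connected
#' components of the foreground `{gray <= gray_threshold}` (ties at the
#' threshold are foreground), discarding components smaller than
#' `min_voxels`. Segmentation is fully 3D, so a junction spanning many
#' serial sections forms a single object.
#'
#' AS/SS classification by PSD prominence is an expert judgement made
#' across serial sections; it is not automated here. Types are taken from
#' an optional label volume (codes 1 = AS, 2 = SS, majority vote over the
#' component) or left `NA`; see [estimate_syn_type()] for a rough,
#' non-validated heuristic.
#'
#' @param grid A [voxel_grid()], usually after [gaussian_preprocess()].
#' @param gray_threshold Gray level; voxels at or below it are foreground.
#' @param min_voxels Minimum component size in voxels.
#' @param connectivity 6, 18 or 26 (default 26: thin curved densities stay
#'   connected best under full 3D connectivity).
#' @param label_grid Optional integer array of the same dimensions with
#'   AS/SS codes (1/2, 0 elsewhere).
#' @return A tibble with one row per junction: `junction_id`, `syn_type`,
#'   `n_voxels`, centroid `x_um`/`y_um`/`z_um`, and a `voxels` list-column
#'   of 1-based `(i, j, k)` index matrices. Voxel sets are disjoint and
#'   jointly equal the surviving foreground.
#' @export
segment_junctions <- function(grid, gray_threshold, min_voxels = 1L,
                              connectivity = 26L, label_grid = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (length(grid$data) == 0L) abort("empty grid")
  if (gray_threshold < 0 || gray_threshold > 2^grid$bit_depth - 1)
    abort("threshold outside the grid's bit depth")
  if (min_voxels < 1L) abort("`min_voxels` must be >= 1")
  if (!connectivity %in% c(6L, 18L, 26L))
    abort("`connectivity` must be 6, 18 or 26")
  labels <- cpp_label_components(grid$data <= gray_threshold, dim(grid$data),
                                 as.integer(connectivity))
  fg <- which(labels > 0L)
  if (!length(fg)) return(empty_junction_table())
  lab <- labels[fg]
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_voxels)
  if (!length(keep)) return(empty_junction_table())
  sel <- lab %in% keep
  idx <- arrayInd(fg[sel], dim(grid$data))
  comp <- split.data.frame(idx, lab[sel])
  vox <- unname(lapply(comp, function(m) {
    storage.mode(m) <- "integer"
    dimnames(m) <- NULL
    m
  }))
  cent <- t(vapply(vox, function(m)
    colMeans(voxel_centers_um(m, grid$voxel_size, grid$origin)),
    numeric(3)))
  syn_type <- rep(NA_character_, length(vox))
  if (!is.null(label_grid)) {
    if (!identical(dim(label_grid), dim(grid$data)))
      abort("`label_grid` dimensions differ from the image grid")
    syn_type <- vapply(vox, function(m) {
      codes <- label_grid[m]
      codes <- codes[codes %in% c(1L, 2L)]
      if (!length(codes)) return(NA_character_)
      c("AS", "SS")[which.max(tabulate(codes, 2L))]
    }, character(1))
  }
  tibble::tibble(
    junction_id = seq_along(vox),
    syn_type = syn_type,
    n_voxels = vapply(vox, nrow, integer(1)),
    x_um = cent[, 1], y_um = cent[, 2], z_um = cent[, 3],
    voxels = vox
  )
}

empty_junction_table <- function() {
  tibble::tibble(junction_id = integer(), syn_type = character(),
                 n_voxels = integer(), x_um = numeric(), y_um = numeric(),
                 z_um = numeric(), voxels = list())
}

#' Centroid of a junction voxel set
#'
#' Arithmetic mean of the member voxel-center positions, in micrometers.
#'
#' @param voxels Integer matrix of 1-based `(i, j, k)` indices.
#' @inheritParams voxel_centers_um
#' @return Numeric length-3 `(x, y, z)` in um.
#' @export
junction_centroid <- function(voxels, voxel_size = c(5, 5, 20),
                              origin = c(0, 0, 0)) {
  if (is.null(dim(voxels))) voxels <- matrix(voxels, ncol = 3)
  if (nrow(voxels) == 0L) abort("empty voxel set")
  colMeans(voxel_centers_um(voxels, voxel_size, origin))
}

#' Match segmented junctions against a ground-truth set
#'
#' Compares two junction tables by voxel overlap. A truth junction is
#' *recovered* when it overlaps exactly one segmented component and that
#' component overlaps no other truth junction (a one-to-one match, neither
#' split nor merged).
#'
#' @param truth,segmented Junction tibbles with `voxels` list-columns.
#' @param dims Grid dimensions.
#' @return One-row tibble: `n_truth`, `n_segmented`, `n_recovered`,
#'   `n_split`, `n_merged`, `recovery_pct`.
#' @export
junction_recovery <- function(truth, segmented, dims) {
  flat <- function(m) (as.numeric(m[, 1]) - 1) + (m[, 2] - 1) * dims[1] +
    (m[, 3] - 1) * dims[1] * dims[2]
  seg_flat <- unlist(lapply(segmented$voxels, flat))
  seg_id <- rep(seq_len(nrow(segmented)),
                vapply(segmented$voxels, nrow, integer(1)))
  overlaps <- lapply(truth$voxels, function(m)
    unique(seg_id[stats::na.omit(match(flat(m), seg_flat))]))
  hit_counts <- table(factor(unlist(overlaps),
                             levels = seq_len(nrow(segmented))))
  recovered <- vapply(overlaps, function(o)
    length(o) == 1L && hit_counts[[o]] == 1L, logical(1))
  tibble::tibble(
    n_truth = nrow(truth), n_segmented = nrow(segmented),
    n_recovered = sum(recovered),
    n_split = sum(lengths(overlaps) > 1L),
    n_merged = sum(hit_counts > 1L),
    recovery_pct = if (nrow(truth)) 100 * sum(recovered) / nrow(truth)
                   else NA_real_)
}

#' Heuristic AS/SS guess from junction thickness (non-validated)
#'
#' Asymmetric junctions have a prominent postsynaptic density and so tend
#' to be thicker along their principal normal than symmetric ones. This
#' heuristic measures the slab-equivalent extent of each voxel set along
#' the principal axis of least variance (`sqrt(12) * RMS spread`, the
#' thickness of a uniform slab with the same variance) and calls a
#' junction `AS` when it meets `thickness_threshold_nm`. It is a rough
#' stand-in for the expert serial-section judgement and is **not
#' validated** against expert labels; prefer a label volume or curated
#' sidecar whenever available.
#'
#' @param junctions Junction tibble from [segment_junctions()].
#' @param voxel_size Voxel pitch in nm.
#' @param thickness_threshold_nm Thickness separating AS from SS.
#' @return The junction tibble with `syn_type` filled by the heuristic.
#' @export
estimate_syn_type <- function(junctions, voxel_size = c(5, 5, 20),
                              thickness_threshold_nm = 30) {
  thick <- vapply(junctions$voxels, function(m) {
    pts <- sweep(matrix(as.numeric(m), ncol = 3), 2, voxel_size, `*`)
    if (nrow(pts) < 4L) return(min(voxel_size))
    pts <- sweep(pts, 2, colMeans(pts))
    ev <- eigen(crossprod(pts) / nrow(pts), symmetric = TRUE)$values
    # slab-equivalent thickness along the least-variance axis, floored at
    # one voxel
    max(sqrt(12 * max(ev[3], 0)), min(voxel_size))
  }, numeric(1))
  junctions$syn_type <- ifelse(thick >= thickness_threshold_nm, "AS", "SS")
  junctions
}
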