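# Unbiased 3D counting frame and shrinkage-corrected volumetric densities.

#' Build a counting frame inset from a grid
#'
#' Creates a counting frame spanning the grid extent, inset by the given
#' margins on both sides of each axis.
#'
#' @param grid A [voxel_grid()].
#' @param margin_um Length-3 margins in um, each `>= 0` and smaller than the
#'   half-extent of its axis.
#' @param exclusion_faces Passed to [counting_frame()].
#' @return A [counting_frame()].
#' @export
frame_from_grid <- function(grid, margin_um = c(0, 0, 0),
                            exclusion_faces = c("x-", "y-", "z-")) {
  stopifnot(inherits(grid, "voxel_grid"))
  margin_um <- as.numeric(margin_um)
  if (length(margin_um) != 3L || any(margin_um < 0))
    abort("`margin_um` must be 3 non-negative numbers")
  ext <- grid_extent_um(grid)
  half <- (ext$hi - ext$lo) / 2
  if (any(margin_um >= half))
    abort("margin too large: frame would be empty")
  counting_frame(ext$lo + margin_um, ext$hi - margin_um, exclusion_faces)
}

#' Volume of a counting frame in cubic micrometers
#' @param frame A [counting_frame()].
#' @return Volume in um^3 (measured space; see [corrected_volume()]).
#' @export
frame_volume <- function(frame) {
  stopifnot(inherits(frame, "counting_frame"))
  prod(frame$hi - frame$lo)
}

# Does a point set touch an exclusion plane (extended beyond the frame)?
# "Touching" = point on or beyond the plane; sub-voxel geometry is ignored.
touches_exclusion <- function(points, frame, tol = 1e-9) {
  axis <- match(substr(frame$exclusion_faces, 1, 1), c("x", "y", "z"))
  side <- substr(frame$exclusion_faces, 2, 2)
  for (k in seq_along(axis)) {
    p <- points[, axis[k]]
    hit <- if (side[k] == "-") any(p <= frame$lo[axis[k]] + tol)
           else any(p >= frame$hi[axis[k]] - tol)
    if (hit) return(TRUE)
  }
  FALSE
}

#' Decide whether an object is counted by an unbiased frame
#'
#' An object is counted when it intersects the closed frame (touching an
#' acceptance face counts) and touches none of the three exclusion planes,
#' each extended beyond the frame bounds per the unbiased-brick rule. For
#' voxel objects "touching" means a voxel center on or beyond the plane.
#'
#' @param frame A [counting_frame()].
#' @param points Numeric matrix of object sample points in um -- typically
#'   voxel centers (see [voxel_centers_um()]) or a single centroid row.
#' @return `TRUE` if the object is counted.
#' @export
counts_object <- function(frame, points) {
  stopifnot(inherits(frame, "counting_frame"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  if (nrow(points) == 0L) abort("empty object")
  tol <- 1e-9
  inside <- points[, 1] >= frame$lo[1] - tol & points[, 1] <= frame$hi[1] + tol &
            points[, 2] >= frame$lo[2] - tol & points[, 2] <= frame$hi[2] + tol &
            points[, 3] >= frame$lo[3] - tol & points[, 3] <= frame$hi[3] + tol
  any(inside) && !touches_exclusion(points, frame, tol)
}

#' Count junctions inside an unbiased counting frame
#'
#' Applies [counts_object()] to every junction. Junctions carrying a
#' `voxels` list-column are tested on their voxel centers; otherwise the
#' centroid columns `x_um`/`y_um`/`z_um` are used (point objects).
#'
#' @param junctions Junction tibble ([segment_junctions()] or synthetic).
#' @param frame A [counting_frame()].
#' @param voxel_size,origin Geometry used to convert voxel indices to
#'   positions when `voxels` are present.
#' @return Integer count.
#' @export
count_in_frame <- function(junctions, frame, voxel_size = c(5, 5, 20),
                           origin = c(0, 0, 0)) {
  if (nrow(junctions) == 0L) return(0L)
  use_vox <- "voxels" %in% names(junctions) &&
    !all(vapply(junctions$voxels, is.null, logical(1)))
  hits <- vapply(seq_len(nrow(junctions)), function(i) {
    pts <- if (use_vox)
      voxel_centers_um(junctions$voxels[[i]], voxel_size, origin)
    else
      cbind(junctions$x_um[i], junctions$y_um[i], junctions$z_um[i])
    counts_object(frame, pts)
  }, logical(1))
  sum(hits)
}

#' Correct a measured volume for tissue shrinkage
#'
#' Measured (post-processing) volumes are divided by the volume shrinkage
#' factor to recover the pre-processing tissue volume; e.g. 87 um^3
#' measured with factor 0.87 corrects to 100 um^3.
#'
#' @param measured_volume Volume in um^3, `> 0`.
#' @param factors A [shrinkage_factors()].
#' @return Corrected volume in um^3.
#' @export
corrected_volume <- function(measured_volume, factors = shrinkage_factors()) {
  if (any(!is.finite(measured_volume)) || any(measured_volume <= 0))
    abort("`measured_volume` must be > 0")
  measured_volume / factors$volume
}

#' Correct a measured length for tissue shrinkage
#' @param measured_length Length in um, `>= 0`.
#' @param factors A [shrinkage_factors()].
#' @return Corrected length in um.
#' @export
corrected_length <- function(measured_length, factors = shrinkage_factors()) {
  if (any(!is.finite(measured_length)) || any(measured_length < 0))
    abort("`measured_length` must be >= 0")
  measured_length / factors$linear
}

#' Volumetric synapse density
#'
#' @param count Number of synapses counted (>= 0).
#' @param volume_um3 Shrinkage-corrected reference volume in um^3, `> 0`.
#' @return Synapses per cubic micrometer.
#' @export
volumetric_density <- function(count, volume_um3) {
  if (any(count < 0)) abort("`count` must be >= 0")
  if (any(!is.finite(volume_um3)) || any(volume_um3 <= 0))
    abort("`volume_um3` must be > 0")
  count / volume_um3
}
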