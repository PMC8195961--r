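#' Reference point in world coordinates
#'
#' @param world_mm Numeric length-3 vector of world coordinates (mm), in the
#'   cohort's common space (e.g. the centre of the third ventricle).
#' @param label Human-readable label for provenance.
#' @return An object of class `reference_point`.
#' @export
reference_point <- function(world_mm, label = "reference") {
  world_mm <- as.numeric(world_mm)
  stopifnot(length(world_mm) == 3L, all(is.finite(world_mm)))
  structure(list(world_mm = world_mm, label = label), class = "reference_point")
}

# world coordinates (rows) of the voxel centres at the given 0-based index
# triples, via the grid affine
voxel_centers_mm <- function(grid, ijk0) {
  h <- cbind(ijk0, 1)
  xyz <- h %*% t(grid$affine)
  xyz[, 1:3, drop = FALSE]
}

# 0-based voxel index nearest to a world point (may fall outside the grid)
world_to_voxel <- function(grid, world_mm) {
  inv <- solve(grid$affine)
  as.vector(inv %*% c(world_mm, 1))[1:3]
}

# mask voxels with at least one 6-connected neighbour outside the mask (the
# volume boundary counts as outside); operates on a 3D 0/1 array
border_voxels <- function(vox) {
  d <- dim(vox)
  pad <- array(0L, dim = d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- vox
  core <- function(sx, sy, sz)   # array() guards against dropped length-1 dims
    array(pad[(2:(d[1] + 1L)) + sx, (2:(d[2] + 1L)) + sy, (2:(d[3] + 1L)) + sz], dim = d)
  nb_all <- core(-1, 0, 0) & core(1, 0, 0) &
            core(0, -1, 0) & core(0, 1, 0) &
            core(0, 0, -1) & core(0, 0, 1)
  vox == 1L & !nb_all
}

#' Shortest distance from a reference point to the tumor border, in cm
#'
#' Computes the minimum Euclidean distance in world millimetres from the
#' reference point to the centre of any border voxel of the mask, divided by
#' 10. A border voxel is a mask voxel with at least one 6-connected
#' neighbour outside the mask (or on the volume boundary). If the reference
#' point falls inside the mask the distance is 0. With the reference at the
#' centre of the third ventricle this is the TVTB tumor-centrality metric.
#'
#' Distances are measured to voxel centres, not sub-voxel surfaces; the
#' discretisation error is bounded by half the voxel diagonal.
#'
#' @param mask A [tumor_mask].
#' @param ref A [reference_point] (or a length-3 numeric world coordinate).
#' @return Non-negative distance in centimetres.
#' @export
tvtb_cm <- function(mask, ref) {
  stopifnot(inherits(mask, "tumor_mask"))
  if (!inherits(ref, "reference_point")) ref <- reference_point(ref)
  if (sum(mask$voxels) == 0L) stop("mask is empty")
  # inside-the-mask check at the nearest voxel
  v <- round(world_to_voxel(mask$grid, ref$world_mm))
  if (all(v >= 0) && all(v < mask$grid$shape) &&
      mask$voxels[v[1] + 1L, v[2] + 1L, v[3] + 1L] == 1L)
    return(0)
  # restrict to the mask bounding box: border voxels of the crop are exact
  # because the mask has no voxels outside its own bounding box
  idx <- which(mask$voxels == 1L, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  crop <- mask$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  crop <- array(crop, dim = hi - lo + 1L)
  bord <- which(border_voxels(crop), arr.ind = TRUE)
  ijk0 <- sweep(bord, 2, lo - 1L, "+") - 1L   # back to 0-based full-grid indices
  xyz <- voxel_centers_mm(mask$grid, ijk0)
  diffs <- sweep(xyz, 2, ref$world_mm)
  min(sqrt(rowSums(diffs^2))) / 10
}

#' Append the centrality metric to a cohort registry
#'
#' Computes [tvtb_cm()] for every patient and fills the registry's
#' `tvtb_cm` column.
#'
#' @param registry A `cohort_registry`.
#' @param masks List of [tumor_mask] whose patient ids cover the registry.
#' @param ref A [reference_point].
#' @return The registry with `tvtb_cm` filled.
#' @export
append_tvtb <- function(registry, masks, ref) {
  ids <- vapply(masks, function(m) m$patient_id, character(1))
  missing <- setdiff(registry$patient_id, ids)
  if (length(missing))
    stop(sprintf("no mask for patient(s): %s", paste(missing, collapse = ", ")))
  by_id <- stats::setNames(masks, ids)
  registry$tvtb_cm <- vapply(registry$patient_id,
                             function(p) tvtb_cm(by_id[[p]], ref), numeric(1))
  registry
}
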