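#' Grid specification for a common reference space
#'
#' A `grid_spec` describes the shared voxel grid of a cohort: the array
#' dimensions, the voxel spacing in millimetres, and the 4x4 voxel-to-world
#' affine (0-based voxel indices, NIfTI convention). All masks and maps in an
#' analysis must live on one `grid_spec`; downstream functions refuse to mix
#' grids.
#'
#' @param shape Integer vector of length 3, voxels per axis.
#' @param spacing_mm Numeric vector of length 3, voxel edge lengths in mm.
#'   Defaults to the column norms of `affine`.
#' @param affine 4x4 voxel-to-world matrix. Defaults to a diagonal affine with
#'   the given spacing, centred so the world origin falls at the grid centre.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(shape, spacing_mm = NULL, affine = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  if (is.null(affine)) {
    if (is.null(spacing_mm)) spacing_mm <- c(1, 1, 1)
    stopifnot(length(spacing_mm) == 3L, all(spacing_mm > 0))
    affine <- diag(c(spacing_mm, 1))
    # centre the grid on the world origin
    affine[1:3, 4] <- -spacing_mm * (shape - 1L) / 2
  }
  affine <- unname(as.matrix(affine))
  stopifnot(all(dim(affine) == c(4L, 4L)))
  derived <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (is.null(spacing_mm)) {
    spacing_mm <- derived
  } else if (max(abs(derived - spacing_mm) / spacing_mm) > 1e-6) {
    stop("spacing_mm disagrees with the affine column norms")
  }
  structure(
    list(shape = shape, spacing_mm = as.numeric(spacing_mm), affine = affine),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %s voxels, %s mm spacing\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing_mm, trim = TRUE), collapse = "x")))
  invisible(x)
}

# Affines are compared entrywise; tol_mm absorbs header round-off across
# NIfTI writers.
grids_compatible <- function(a, b, tol_mm = 1e-4) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) <= tol_mm
}

assert_same_grid <- function(a, b, what = "objects") {
  if (!grids_compatible(a, b))
    stop(sprintf("grid mismatch: %s are not on the same grid", what))
  invisible(TRUE)
}

#' Construct a tumor mask
#'
#' @param patient_id Character scalar identifying the patient.
#' @param voxels 3D array coercible to 0/1.
#' @param grid A [grid_spec] the mask lives on.
#' @return An object of class `tumor_mask`.
#' @export
tumor_mask <- function(patient_id, voxels, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.integer(voxels) || !all(range(voxels) %in% c(0L, 1L)))
    voxels <- array(as.integer(voxels != 0), dim = dim(voxels))
  if (!identical(dim(voxels), as.integer(grid$shape)))
    stop(sprintf("mask for patient '%s' does not match the grid shape", patient_id))
  if (sum(voxels) == 0L)
    stop(sprintf("mask for patient '%s' is empty", patient_id))
  structure(
    list(patient_id = as.character(patient_id), grid = grid, voxels = voxels),
    class = "tumor_mask"
  )
}

#' @export
print.tumor_mask <- function(x, ...) {
  cat(sprintf("<tumor_mask> patient %s: %d voxels (%.2f mL)\n",
              x$patient_id, sum(x$voxels),
              sum(x$voxels) * prod(x$grid$spacing_mm) / 1000))
  invisible(x)
}

VOXEL_MAP_LABELS <- c("COUNT", "ODDS", "LOG_OR", "PVALUE", "ADJ_PVALUE", "SIGNIFICANCE")

#' Construct a labelled voxel map
#'
#' A `voxel_map` is a scalar field on the cohort grid carrying a semantic
#' label (count, odds, log odds ratio, p-value, adjusted p-value, or a 0/1
#' significance mask) plus free-form provenance metadata (groups compared,
#' group sizes, permutation count, seed). Voxels outside the analysis domain
#' are `NaN` for real-valued maps.
#'
#' @param label One of `"COUNT"`, `"ODDS"`, `"LOG_OR"`, `"PVALUE"`,
#'   `"ADJ_PVALUE"`, `"SIGNIFICANCE"`.
#' @param values 3D numeric array matching the grid shape.
#' @param grid A [grid_spec].
#' @param metadata Named list of provenance fields, serialised to a JSON
#'   sidecar by [write_map()].
#' @return An object of class `voxel_map`.
#' @export
voxel_map <- function(label, values, grid, metadata = list()) {
  label <- match.arg(label, VOXEL_MAP_LABELS)
  stopifnot(inherits(grid, "grid_spec"))
  values <- array(as.numeric(values), dim = dim(values))
  if (!identical(dim(values), as.integer(grid$shape)))
    stop("map values do not match the grid shape")
  finite <- values[is.finite(values)]
  if (label %in% c("PVALUE", "ADJ_PVALUE") && length(finite) &&
      (min(finite) < 0 || max(finite) > 1))
    stop(sprintf("%s map has values outside [0, 1]", label))
  if (label == "SIGNIFICANCE" && length(finite) && !all(finite %in% c(0, 1)))
    stop("SIGNIFICANCE map must be 0/1")
  if (label == "COUNT" && length(finite) &&
      (min(finite) < 0 || max(abs(finite - round(finite))) > 0))
    stop("COUNT map must hold non-negative integers")
  structure(
    list(label = label, grid = grid, values = values, metadata = metadata),
    class = "voxel_map"
  )
}

#' @export
print.voxel_map <- function(x, ...) {
  fin <- x$values[is.finite(x$values)]
  rng <- if (length(fin)) sprintf("range [%g, %g]", min(fin), max(fin)) else "no finite voxels"
  cat(sprintf("<voxel_map> %s on %s grid, %d finite voxels, %s\n",
              x$label, paste(x$grid$shape, collapse = "x"), length(fin), rng))
  invisible(x)
}

grid_from_nifti <- function(img) {
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  grid_spec(shape = dim(img)[1:3], affine = matrix(as.numeric(aff), 4, 4))
}

#' Load a binary tumor mask from NIfTI
#'
#' Reads a single-volume NIfTI file, binarises it at a strict `> 0.5`
#' threshold (robust to interpolation artifacts from registration), and
#' optionally checks the grid against a cohort reference grid.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param patient_id Identifier stored on the mask; defaults to the file stem.
#' @param reference_grid Optional [grid_spec]; a shape or affine mismatch
#'   (beyond 1e-4 mm) is a cohort-consistency error naming the patient.
#' @return A [tumor_mask].
#' @export
load_mask <- function(path, patient_id = NULL, reference_grid = NULL) {
  if (!file.exists(path)) stop(sprintf("mask file not found: %s", path))
  if (is.null(patient_id))
    patient_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  img <- RNifti::readNifti(path)
  if (length(dim(img)) > 3L) {
    if (any(dim(img)[-(1:3)] != 1L))
      stop(sprintf("mask for patient '%s' is not a single volume", patient_id))
    img_arr <- array(as.numeric(img), dim = dim(img)[1:3])
  } else img_arr <- as.array(img)
  grid <- grid_from_nifti(img)
  if (!is.null(reference_grid) && !grids_compatible(grid, reference_grid))
    stop(sprintf("mask for patient '%s' is not on the cohort reference grid", patient_id))
  tumor_mask(patient_id, img_arr > 0.5, if (is.null(reference_grid)) grid else reference_grid)
}

nifti_datatype <- function(label) {
  switch(label, COUNT = "int16", SIGNIFICANCE = "uint8", "float")
}

as_nifti_volume <- function(values, grid) {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- grid$spacing_mm
  RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
}

#' Write a voxel map (or mask) to NIfTI with a JSON provenance sidecar
#'
#' COUNT maps are stored as 16-bit integers, SIGNIFICANCE masks as 8-bit
#' integers, all other maps as 32-bit floats; non-finite masked voxels are
#' stored as NaN. Metadata is written next to the image as `<path>.json`.
#'
#' @param map A [voxel_map] or [tumor_mask].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param sidecar Write the JSON sidecar? Default `TRUE` for voxel maps.
#' @return The path, invisibly.
#' @export
write_map <- function(map, path, sidecar = TRUE) {
  if (!dir.exists(dirname(path)))
    stop(sprintf("parent directory does not exist: %s", dirname(path)))
  if (inherits(map, "tumor_mask")) {
    img <- as_nifti_volume(map$voxels, map$grid)
    RNifti::writeNifti(img, path, datatype = "uint8")
    return(invisible(path))
  }
  stopifnot(inherits(map, "voxel_map"))
  img <- as_nifti_volume(map$values, map$grid)
  RNifti::writeNifti(img, path, datatype = nifti_datatype(map$label))
  if (sidecar) {
    meta <- c(list(label = map$label), map$metadata)
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Load a voxel map written by [write_map()]
#'
#' @param path Path to the NIfTI file; the `<path>.json` sidecar is read when
#'   present.
#' @return A [voxel_map].
#' @export
load_map <- function(path) {
  if (!file.exists(path)) stop(sprintf("map file not found: %s", path))
  img <- RNifti::readNifti(path)
  grid <- grid_from_nifti(img)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
  label <- if (!is.null(meta$label)) meta$label else "LOG_OR"
  meta$label <- NULL
  voxel_map(label, array(as.numeric(img), dim = dim(img)[1:3]), grid, metadata = meta)
}
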