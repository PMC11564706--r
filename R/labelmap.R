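#' Read a label map from NIfTI, reorienting to the canonical frame
#'
#' Reads an integer NIfTI volume, reconciles its stored orientation to the
#' canonical LPS-like frame (i: right-to-left, j: anterior-to-posterior,
#' k: inferior-to-superior) using the affine direction cosines (nearest axis
#' codes), and validates all voxel values against the schema. Only
#' axis-permutation/flip orientations are accepted; oblique affines are
#' rejected rather than resampled, because every downstream metric assumes an
#' axis-aligned lattice.
#'
#' @param path path to a `.nii` or `.nii.gz` file with integer data.
#' @param schema a [TissueSchema-class]; defaults to [defaultSchema()].
#' @return A [LabelMap-class] in canonical orientation, with spacing taken
#'   from the file header.
#' @seealso [saveLabelMap()], [readSchema()]
#' @export
loadLabelMap <- function(path, schema = defaultSchema()) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("label map must be a 3D volume, got ", length(dim(img)), "D",
         call. = FALSE)
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  sc <- sqrt(colSums(rot^2))
  if (any(sc <= 0))
    stop("orientation error: degenerate affine direction cosines",
         call. = FALSE)
  dircos <- sweep(rot, 2, sc, "/")
  if (any(abs(dircos) > 1e-3 & abs(abs(dircos) - 1) > 1e-3))
    stop("orientation error: oblique affine; only axis-aligned ",
         "orientations are supported", call. = FALSE)
  RNifti::orientation(img) <- "LPS"
  vals <- as.vector(img)
  if (any(abs(vals - round(vals)) > 1e-6))
    stop("format error: label map data are not integers", call. = FALSE)
  arr <- array(as.integer(round(vals)), dim(img))
  sp <- RNifti::pixdim(img)[1:3]
  LabelMap(arr, spacing = sp, schema = schema)
}

#' Write a label map as NIfTI in the canonical orientation
#'
#' @param map a [LabelMap-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
saveLabelMap <- function(map, path) {
  aff <- diag(c(-map@spacing[1], -map@spacing[2], map@spacing[3], 1))
  img <- RNifti::asNifti(map@voxels)
  RNifti::pixdim(img) <- map@spacing
  RNifti::qform(img) <- structure(aff, code = 1L)
  RNifti::sform(img) <- structure(aff, code = 1L)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Read a tissue schema from JSON
#'
#' The JSON object maps class names to integer labels, e.g.
#' `{"air":0,"skin":1,...}`, covering all seven classes.
#'
#' @param path path to a JSON file.
#' @return A [TissueSchema-class].
#' @export
readSchema <- function(path) {
  TissueSchema(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Binary mask of one tissue class
#'
#' @param map a [LabelMap-class].
#' @param tissue one of the seven semantic class names.
#' @return A logical 3D array of the map's shape, TRUE where the voxel
#'   carries the tissue's label; the voxel spacing is attached as the
#'   `"spacing"` attribute.
#' @export
tissueMask <- function(map, tissue) {
  lab <- labelOf(map@schema, tissue)
  m <- map@voxels == lab
  attr(m, "spacing") <- map@spacing
  m
}

#' Split a bilateral label map at the mid-sagittal grid plane
#'
#' The default midline is the center grid plane `floor(Ni/2)` (0-based): the
#' patient-left half holds 0-based indices `>= midline`, the right half the
#' rest. Halves retain their global physical coordinates through the
#' `"offsetVoxels"` attribute (number of i-voxels cropped on the low side).
#'
#' @param map a [LabelMap-class].
#' @param midline optional 0-based midline i-index; `0` assigns the whole
#'   volume to the left side (useful for unilateral acquisitions).
#' @return list with elements `left` and `right` ([LabelMap-class] halves,
#'   possibly with zero extent) and `midline` (0-based index used).
#' @export
splitLaterality <- function(map, midline = NULL) {
  ni <- dim(map@voxels)[1]
  if (is.null(midline)) midline <- ni %/% 2L
  midline <- as.integer(midline)
  if (midline < 0L || midline > ni)
    stop("midline must be in [0, Ni]", call. = FALSE)
  half <- function(idx, off) {
    sub <- map@voxels[idx, , , drop = FALSE]
    m <- LabelMap(sub, spacing = map@spacing, schema = map@schema)
    attr(m@voxels, "offsetVoxels") <- off
    m
  }
  list(left = if (midline < ni) half((midline + 1L):ni, midline) else NULL,
       right = if (midline > 0L) half(seq_len(midline), 0L) else NULL,
       midline = midline)
}

#' 1-based i-indices of one laterality
#' @keywords internal
sideIndices <- function(map, side = c("left", "right"), midline = NULL) {
  side <- match.arg(side)
  ni <- dim(map@voxels)[1]
  if (is.null(midline)) midline <- ni %/% 2L
  midline <- as.integer(midline)
  if (side == "left") {
    if (midline >= ni) integer(0) else (midline + 1L):ni
  } else {
    if (midline <= 0L) integer(0) else seq_len(midline)
  }
}

# restrict a mask to one side (everything else FALSE)
maskOnSide <- function(mask, map, side, midline = NULL) {
  idx <- sideIndices(map, side, midline)
  out <- mask
  out[] <- FALSE
  if (length(idx)) out[idx, , ] <- mask[idx, , ]
  attr(out, "spacing") <- attr(mask, "spacing")
  out
}

#' Physical voxel-center coordinates of a mask
#'
#' @param mask logical 3D array.
#' @param spacing numeric(3) voxel spacing in mm.
#' @return numeric matrix (n x 3) of the centers of TRUE voxels, mm.
#' @export
maskCenters <- function(mask, spacing = attr(mask, "spacing")) {
  ind <- which(mask, arr.ind = TRUE)
  sweep(ind - 0.5, 2, as.numeric(spacing), "*")
}

#' Deduplicated voxel-corner coordinates of a mask
#'
#' Each occupied voxel contributes its 8 corners; shared corners are counted
#' once. Corners lie exactly on the integer spacing lattice.
#'
#' @inheritParams maskCenters
#' @return numeric matrix (n x 3) of unique corner coordinates, mm.
#' @export
maskCorners <- function(mask, spacing = attr(mask, "spacing")) {
  d <- dim(mask)
  ind <- which(mask, arr.ind = TRUE)
  if (nrow(ind) == 0L) return(matrix(numeric(0), ncol = 3))
  # corner lattice ids (0-based corners 0..d per axis)
  n1 <- d[1] + 1L
  n2 <- d[2] + 1L
  ids <- integer(0)
  base <- (ind[, 1] - 1L) + n1 * ((ind[, 2] - 1L) + n2 * (ind[, 3] - 1L))
  offs <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
  ids <- unlist(lapply(seq_len(8), function(r) {
    base + offs$a[r] + n1 * (offs$b[r] + n2 * offs$c[r])
  }), use.names = FALSE)
  ids <- unique(ids)
  a <- ids %% n1
  rest <- ids %/% n1
  b <- rest %% n2
  cc <- rest %/% n2
  sp <- as.numeric(spacing)
  cbind(a * sp[1], b * sp[2], cc * sp[3])
}
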