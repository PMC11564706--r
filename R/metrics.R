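#' Connected components of a binary mask
#'
#' Labels maximal connected sets under the chosen structure element.
#' Component ids are assigned in raster-scan order of each component's first
#' voxel (column-major, i fastest), so labelling is deterministic.
#'
#' @param mask logical 3D array.
#' @param connectivity `"face"` (6-neighbours), `"edge"` (18) or
#'   `"corner"` (26).
#' @return integer 3D array of component labels (0 = background) with
#'   attribute `"nComponents"`.
#' @export
connectedComponents <- function(mask,
                                connectivity = c("face", "edge", "corner")) {
  connectivity <- match.arg(connectivity)
  conn <- c(face = 6L, edge = 18L, corner = 26L)[[connectivity]]
  lab <- cc_label_cpp(as.logical(mask), dim(mask), conn)
  out <- array(lab, dim(mask))
  attr(out, "nComponents") <- attr(lab, "n_components")
  out
}

#' Largest connected tumor component (dominant mass)
#'
#' Returns the component with the most voxels; ties go to the component with
#' the smaller id (raster order of first voxel).
#'
#' @inheritParams connectedComponents
#' @return logical 3D array selecting the dominant component, with
#'   attributes `"componentId"` and `"nComponents"`.
#' @export
dominantMass <- function(mask, connectivity = c("face", "edge", "corner")) {
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  lab <- connectedComponents(mask, connectivity)
  ncomp <- attr(lab, "nComponents")
  sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
  id <- which.max(sizes)  # first maximum = smallest id
  out <- lab == id
  attr(out, "spacing") <- attr(mask, "spacing")
  attr(out, "componentId") <- id
  attr(out, "nComponents") <- ncomp
  out
}

#' Axis-aligned extents of a mask
#'
#' Per axis, the outer-edge-to-outer-edge span of occupied voxels:
#' `(max_index - min_index + 1) * spacing`. With this convention the maximum
#' over the three axes is the longest axis-aligned dimension and the product
#' is the bounding-box volume.
#'
#' @param mask non-empty logical 3D array.
#' @param spacing numeric(3) voxel spacing in mm.
#' @return named numeric(3) `(dx, dy, dz)` in mm.
#' @export
axisExtents <- function(mask, spacing = attr(mask, "spacing")) {
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  ind <- which(mask, arr.ind = TRUE)
  ext <- (apply(ind, 2, max) - apply(ind, 2, min) + 1) * as.numeric(spacing)
  names(ext) <- c("dx", "dy", "dz")
  ext
}

#' Tumor volume from voxel counting
#'
#' @param mask logical 3D array (may be empty).
#' @param spacing numeric(3) voxel spacing in mm.
#' @return volume in mm^3 (0 for an empty mask).
#' @export
tumorVolume <- function(mask, spacing = attr(mask, "spacing")) {
  sum(mask) * prod(as.numeric(spacing))
}

#' Breast volume within a breast box
#'
#' Sums voxel volumes of all valid breast tissues (skin, adipose,
#' fibroglandular, vessel, tumor) whose indices lie inside the box
#' (inclusive bounds). Chest and air voxels inside the box contribute
#' nothing.
#'
#' @param map a [LabelMap-class].
#' @param box a [BreastBox-class] built on the same map/side.
#' @return volume in mm^3, with attribute `"empty"` set TRUE when no
#'   qualifying voxel lies in the box.
#' @export
breastVolume <- function(map, box) {
  b <- box@bounds
  sub <- map@voxels[b[1, 1]:b[2, 1], b[1, 2]:b[2, 2], b[1, 3]:b[2, 3],
                    drop = FALSE]
  labs <- labelOf(map@schema, BREAST_TISSUES)
  cnt <- sum(sub %in% labs)
  structure(cnt * prod(map@spacing), empty = cnt == 0)
}

#' Shortest vertex-set distance from tumor to a landmark
#'
#' Vertex sets are the deduplicated voxel corners (8 per voxel) of the
#' occupied voxels, in mm. Returns the minimum Euclidean distance between
#' the tumor vertex set and the target vertex set (or a physical point),
#' computed with an exact KD-tree nearest-neighbour query; this equals the
#' brute-force pairwise minimum.
#'
#' @param tumorMask non-empty logical 3D array.
#' @param target non-empty logical 3D array on the same grid, or a numeric
#'   point `c(x, y, z)` in mm.
#' @param spacing numeric(3) voxel spacing in mm.
#' @return distance in mm (0 when the vertex sets share a corner).
#' @examples
#' m <- array(FALSE, c(6, 1, 1)); m[1] <- TRUE
#' t <- array(FALSE, c(6, 1, 1)); t[6] <- TRUE
#' tumorToLandmarkDistance(m, t, c(1, 1, 1))  # 4: corner x=1 to corner x=5
#' @export
tumorToLandmarkDistance <- function(tumorMask, target,
                                    spacing = attr(tumorMask, "spacing")) {
  if (!any(tumorMask)) stop("tumor mask is empty", call. = FALSE)
  A <- maskCorners(tumorMask, spacing)
  if (is.numeric(target) && is.null(dim(target))) {
    if (length(target) != 3L || any(!is.finite(target)))
      stop("target point must be a finite (x, y, z)", call. = FALSE)
    return(sqrt(min(colSums((t(A) - as.numeric(target))^2))))
  }
  if (!any(target)) stop("target mask is empty", call. = FALSE)
  B <- maskCorners(target, spacing)
  min(RANN::nn2(B, query = A, k = 1)$nn.dists)
}

#' Assemble the tumor metrics report for one breast
#'
#' Computes, for the whole tumor and for its dominant mass, the axis-aligned
#' extents, longest dimension and bounding-box volume; plus tumor volume,
#' breast volume within the box, their ratio, and the vertex-set distances
#' from the (whole) tumor to skin, chest and the nipple point.
#'
#' @param map a [LabelMap-class].
#' @param side `"left"` or `"right"`.
#' @param nipple nipple point `c(x, y, z)` in mm (e.g. from
#'   [locateNipple()]).
#' @param box a [BreastBox-class] for the same side (e.g. from
#'   [buildBreastBox()]).
#' @param midline optional 0-based laterality midline (see
#'   [splitLaterality()]).
#' @param connectivity connectivity for the dominant mass; default face.
#' @return a named list; see Details.
#' @details The returned list carries `wholeTumor` and `dominantMass`
#'   sub-lists (`extentsMM`, `longestDimensionMM`, `boundingBoxVolumeMM3`,
#'   `volumeMM3`), `nComponents`, `tumorVolumeMM3`, `breastVolumeMM3`,
#'   `tumorToBreastRatio`, and `distancesMM` (`toSkin`, `toChest`,
#'   `toNipple`). Distances are computed from the whole tumor. Dominant-mass
#'   metrics equal whole-tumor metrics exactly when `nComponents == 1`.
#' @export
tumorMetricsReport <- function(map, side = c("left", "right"), nipple, box,
                               midline = NULL,
                               connectivity = c("face", "edge", "corner")) {
  side <- match.arg(side)
  connectivity <- match.arg(connectivity)
  sp <- map@spacing
  tumor <- maskOnSide(tissueMask(map, "tumor"), map, side, midline)
  if (!any(tumor))
    stop("no tumor voxels on the ", side, " side", call. = FALSE)
  dom <- dominantMass(tumor, connectivity)

  scopeMetrics <- function(m) {
    ext <- axisExtents(m, sp)
    list(extentsMM = ext,
         longestDimensionMM = max(ext),
         boundingBoxVolumeMM3 = prod(ext),
         volumeMM3 = tumorVolume(m, sp))
  }

  skin <- maskOnSide(tissueMask(map, "skin"), map, side, midline)
  chest <- maskOnSide(tissueMask(map, "chest"), map, side, midline)
  dists <- list(
    toSkin = if (any(skin)) tumorToLandmarkDistance(tumor, skin, sp) else NA_real_,
    toChest = if (any(chest)) tumorToLandmarkDistance(tumor, chest, sp) else NA_real_,
    toNipple = tumorToLandmarkDistance(tumor, nipple, sp))

  bv <- breastVolume(map, box)
  tv <- tumorVolume(tumor, sp)
  ratio <- if (isTRUE(attr(bv, "empty")) || bv == 0) {
    warning("breast volume is zero; tumor-to-breast ratio undefined")
    NA_real_
  } else tv / as.numeric(bv)

  list(side = side,
       wholeTumor = scopeMetrics(tumor),
       dominantMass = scopeMetrics(dom),
       nComponents = attr(dom, "nComponents"),
       tumorVolumeMM3 = tv,
       breastVolumeMM3 = as.numeric(bv),
       tumorToBreastRatio = ratio,
       distancesMM = dists)
}
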