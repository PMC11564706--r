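#' Nipple localization parameters
#'
#' @param neighborhoodRadiusMM search radius for the air/skin/fibroglandular
#'   adjacency test (default 8 mm).
#' @param posteriorOffsetMM posterior translation applied to the candidate
#'   center of mass (default 6 mm).
#' @return named list of validated parameters.
#' @export
nippleParams <- function(neighborhoodRadiusMM = 8, posteriorOffsetMM = 6) {
  stopifnot(neighborhoodRadiusMM > 0, posteriorOffsetMM > 0)
  list(neighborhoodRadiusMM = neighborhoodRadiusMM,
       posteriorOffsetMM = posteriorOffsetMM)
}

#' Automated nipple localization
#'
#' Finds all voxels of one breast whose centers lie within the neighborhood
#' radius (Euclidean, mm) of the center of at least one air voxel AND one
#' skin voxel AND one fibroglandular voxel, takes the unweighted center of
#' mass of the candidate voxel centers, and offsets it posteriorly (+j) by
#' the posterior offset.
#'
#' @param map a [LabelMap-class].
#' @param side `"left"` or `"right"`.
#' @param params see [nippleParams()].
#' @param midline optional 0-based laterality midline (see
#'   [splitLaterality()]).
#' @return named numeric(3) nipple point `(x, y, z)` in mm, with the
#'   candidate count as attribute `"nCandidates"`.
#' @export
locateNipple <- function(map, side = c("left", "right"),
                         params = nippleParams(), midline = NULL) {
  side <- match.arg(side)
  sp <- map@spacing
  r <- params$neighborhoodRadiusMM
  air <- maskOnSide(tissueMask(map, "air"), map, side, midline)
  skin <- maskOnSide(tissueMask(map, "skin"), map, side, midline)
  fib <- maskOnSide(tissueMask(map, "fibroglandular"), map, side, midline)
  if (!any(air) || !any(skin) || !any(fib))
    stop("landmark-not-found: side lacks air, skin or fibroglandular ",
         "voxels", call. = FALSE)

  # candidates must be near all three tissues; start from the smallest
  # tissue's dilated bounding box and narrow with exact KD-tree queries
  idx <- sideIndices(map, side, midline)
  fibC <- maskCenters(fib, sp)
  d <- dim(map@voxels)
  lo <- pmax(c(min(idx), 1L, 1L),
             ceiling((apply(fibC, 2, min) - r) / sp + 0.5))
  hi <- pmin(c(max(idx), d[2], d[3]),
             floor((apply(fibC, 2, max) + r) / sp + 0.5))
  grid <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                                k = lo[3]:hi[3]))
  pts <- sweep(grid - 0.5, 2, sp, "*")

  near <- function(pts, tissueCenters) {
    RANN::nn2(tissueCenters, query = pts, k = 1)$nn.dists[, 1] <= r
  }
  keep <- near(pts, fibC)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts)) {
    keep <- near(pts, maskCenters(skin, sp))
    pts <- pts[keep, , drop = FALSE]
  }
  if (nrow(pts)) {
    keep <- near(pts, maskCenters(air, sp))
    pts <- pts[keep, , drop = FALSE]
  }
  if (nrow(pts) == 0L)
    stop("landmark-not-found: no voxel lies within ", r,
         " mm of air, skin and fibroglandular tissue", call. = FALSE)
  p <- colMeans(pts)
  p[2] <- p[2] + params$posteriorOffsetMM
  structure(c(x = p[1], y = p[2], z = p[3]), nCandidates = nrow(pts))
}

# skin-surface mask: skin voxels with >= 1 face-neighbour labelled air
skinSurfaceMask <- function(map) {
  skin <- tissueMask(map, "skin")
  air <- tissueMask(map, "air")
  d <- dim(skin)
  nb <- array(FALSE, d)
  pad <- function(axis, by) {
    out <- array(FALSE, d)
    n <- d[axis]
    idx <- lapply(d, seq_len)
    idxTo <- idx
    if (by >= 0) { idxTo[[axis]] <- seq_len(n - by) + by
                   idx[[axis]] <- seq_len(n - by) }
    else { idxTo[[axis]] <- seq_len(n + by)
           idx[[axis]] <- seq_len(n + by) - by }
    out[idxTo[[1]], idxTo[[2]], idxTo[[3]]] <-
      air[idx[[1]], idx[[2]], idx[[3]]]
    out
  }
  for (axis in 1:3) nb <- nb | pad(axis, 1L) | pad(axis, -1L)
  out <- skin & nb
  attr(out, "spacing") <- map@spacing
  out
}

#' Construct the breast box from five skin-anchored key points
#'
#' Implements the five-point procedure: (1) center of mass of all breast
#' tissues of the side; (2) most anterior skin-surface point on the side's
#' central sagittal plane (ties: smallest k, then i); (3) reference point
#' 6 mm posterior to (2), aligned with (1) in the medial-lateral direction;
#' (4a,b) skin-surface points nearest the reference in the transverse
#' projection, one on each medial/lateral side, defining the i extents;
#' (5a,b) the same in the sagittal projection, one inferior and one
#' superior, defining the k extents. The anterior extent is the most
#' anterior skin-surface point of the side; the posterior face is the
#' anterior face of the chest slab within the box footprint. A corrective
#' pass then pushes any face that excludes breast-tissue voxels outward, one
#' voxel at a time, until no breast tissue is excluded.
#'
#' @param map a [LabelMap-class].
#' @param side `"left"` or `"right"`.
#' @param midline optional 0-based laterality midline.
#' @param anteriorOffsetMM posterior offset of the reference point from the
#'   anterior midline point (default 6 mm).
#' @return A [BreastBox-class].
#' @export
buildBreastBox <- function(map, side = c("left", "right"), midline = NULL,
                           anteriorOffsetMM = 6) {
  side <- match.arg(side)
  sp <- map@spacing
  idx <- sideIndices(map, side, midline)
  if (!length(idx)) stop("empty side subvolume", call. = FALSE)

  labs <- labelOf(map@schema, BREAST_TISSUES)
  breast <- array(map@voxels %in% labs, dim(map@voxels))
  breast <- maskOnSide(breast, map, side, midline)
  if (!any(breast)) stop("no breast tissue on the ", side, " side",
                         call. = FALSE)
  surf <- maskOnSide(skinSurfaceMask(map), map, side, midline)
  if (!any(surf)) stop("no skin surface on the ", side, " side",
                       call. = FALSE)

  bInd <- which(breast, arr.ind = TRUE)
  com <- colMeans(sweep(bInd - 0.5, 2, sp, "*"))

  sInd <- which(surf, arr.ind = TRUE)
  sPts <- sweep(sInd - 0.5, 2, sp, "*")

  # (2) most anterior skin-surface point on the central sagittal plane
  iMid <- idx[ceiling(length(idx) / 2)]
  onMid <- sInd[, 1] == iMid
  midFallback <- FALSE
  if (!any(onMid)) {
    # nearest i-plane that carries skin surface
    iNear <- sInd[which.min(abs(sInd[, 1] - iMid)), 1]
    onMid <- sInd[, 1] == iNear
    midFallback <- TRUE
  }
  cand <- sInd[onMid, , drop = FALSE]
  ordc <- order(cand[, 2], cand[, 3], cand[, 1])
  antVox <- cand[ordc[1], ]
  antPt <- (antVox - 0.5) * sp

  # (3) reference point: 6 mm posterior, medial-lateral aligned with COM
  refPt <- c(com[1], antPt[2] + anteriorOffsetMM, antPt[3])

  nearestIn <- function(pts, rows, axes) {
    if (!any(rows)) return(NA_integer_)
    sub <- pts[rows, axes, drop = FALSE]
    d2 <- (sub[, 1] - refPt[axes[1]])^2 + (sub[, 2] - refPt[axes[2]])^2
    which(rows)[which.min(d2)]
  }
  # (4) transverse projection (x, y): medial and lateral extents
  iMedial <- nearestIn(sPts, sPts[, 1] < refPt[1], c(1, 2))
  iLateral <- nearestIn(sPts, sPts[, 1] >= refPt[1], c(1, 2))
  # (5) sagittal projection (y, z): inferior and superior extents
  iInferior <- nearestIn(sPts, sPts[, 3] < refPt[3], c(2, 3))
  iSuperior <- nearestIn(sPts, sPts[, 3] >= refPt[3], c(2, 3))
  flagged <- midFallback ||
    anyNA(c(iMedial, iLateral, iInferior, iSuperior))

  tight <- rbind(apply(bInd, 2, min), apply(bInd, 2, max))
  pick <- function(i, col, default) if (is.na(i)) default else sInd[i, col]
  iLo <- pick(iMedial, 1, tight[1, 1])
  iHi <- pick(iLateral, 1, tight[2, 1])
  if (side == "right") { # medial is +x on the right
    tmp <- iLo; iLo <- min(iLo, iHi); iHi <- max(tmp, iHi)
  }
  kLo <- pick(iInferior, 3, tight[1, 3])
  kHi <- pick(iSuperior, 3, tight[2, 3])
  jLo <- min(sInd[, 2])  # most anterior skin-surface point

  # posterior face: anterior face of the chest slab within the footprint
  chest <- maskOnSide(tissueMask(map, "chest"), map, side, midline)
  cInd <- which(chest, arr.ind = TRUE)
  inFoot <- cInd[, 1] >= min(iLo, iHi) & cInd[, 1] <= max(iLo, iHi) &
    cInd[, 3] >= min(kLo, kHi) & cInd[, 3] <= max(kLo, kHi)
  if (any(inFoot)) {
    jHi <- min(cInd[inFoot, 2])
  } else {
    jHi <- tight[2, 2]
    flagged <- TRUE
  }

  lo0 <- c(min(iLo, iHi), jLo, min(kLo, kHi))
  hi0 <- c(max(iLo, iHi), jHi, max(kLo, kHi))

  # corrective pass: walk each face outward one voxel at a time until no
  # breast tissue is excluded (the walk cannot leave the subvolume because
  # the tissue's tight bounds lie inside it)
  lo <- lo0; hi <- hi0
  corrected <- logical(6)
  for (ax in 1:3) {
    while (lo[ax] > tight[1, ax]) { lo[ax] <- lo[ax] - 1L
                                    corrected[2 * ax - 1] <- TRUE }
    while (hi[ax] < tight[2, ax]) { hi[ax] <- hi[ax] + 1L
                                    corrected[2 * ax] <- TRUE }
  }
  bounds <- rbind(lo = as.integer(lo), hi = as.integer(hi))
  colnames(bounds) <- c("i", "j", "k")
  boundsMM <- rbind(lo = (lo - 1) * sp, hi = hi * sp)

  keyPoints <- list(
    centerOfMass = com,
    anteriorMidlinePoint = antPt,
    referencePoint = refPt,
    medialPoint = if (!is.na(iMedial)) sPts[iMedial, ] else NULL,
    lateralPoint = if (!is.na(iLateral)) sPts[iLateral, ] else NULL,
    inferiorPoint = if (!is.na(iInferior)) sPts[iInferior, ] else NULL,
    superiorPoint = if (!is.na(iSuperior)) sPts[iSuperior, ] else NULL,
    anteriorSkinJ = (jLo - 0.5) * sp[2],
    initialBounds = rbind(lo = lo0, hi = hi0))

  new("BreastBox", side = side, bounds = bounds, boundsMM = boundsMM,
      keyPoints = keyPoints, corrected = corrected, fallback = flagged)
}
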