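#' Tissue-balancing quadrant plane for one breast
#'
#' The rotating quadrant plane contains the nipple and the superior-inferior
#' axis. Starting from the sagittal orientation, the rotation angle about
#' the superior-inferior axis is sought such that the breast-tissue volume
#' (within the breast box) on each side of the plane differs by less than
#' `tol` of the total, via bisection of the signed imbalance over
#' [-45, +45] degrees. Voxels are assigned by center position; centers
#' exactly on the plane count to the medial side.
#'
#' @param map a [LabelMap-class].
#' @param side `"left"` or `"right"`.
#' @param nipple nipple point `(x, y, z)` mm.
#' @param box a [BreastBox-class] for the side.
#' @param tol imbalance tolerance as a fraction of total tissue (default
#'   0.005, i.e. 0.5%).
#' @param maxIter bisection iteration cap.
#' @return list with `angleDeg` (rotation of the plane normal from the
#'   medial-lateral axis towards +j), `normal` (unit in-plane-normal, z
#'   component 0), `point` (the nipple), `residual` (achieved fractional
#'   imbalance) and `converged`.
#' @export
balancePlane <- function(map, side = c("left", "right"), nipple, box,
                         tol = 0.005, maxIter = 60L) {
  side <- match.arg(side)
  sp <- map@spacing
  b <- box@bounds
  labs <- labelOf(map@schema, BREAST_TISSUES)
  sub <- map@voxels[b[1, 1]:b[2, 1], b[1, 2]:b[2, 2], b[1, 3]:b[2, 3],
                    drop = FALSE]
  tInd <- which(array(sub %in% labs, dim(sub)), arr.ind = TRUE)
  if (nrow(tInd) == 0L) stop("no breast tissue within the box", call. = FALSE)
  tInd <- sweep(tInd, 2, b[1, ] - 1L, "+")
  pts <- sweep(tInd - 0.5, 2, sp, "*")
  if (nipple[1] < box@boundsMM[1, 1] || nipple[1] > box@boundsMM[2, 1] ||
      nipple[3] < box@boundsMM[1, 3] || nipple[3] > box@boundsMM[2, 3])
    warning("nipple point lies outside the box footprint")

  dx <- pts[, 1] - nipple[1]
  dy <- pts[, 2] - nipple[2]
  total <- nrow(pts)
  # signed imbalance (lateral minus medial) as a fraction of total tissue;
  # ties (centers exactly on the plane) count as medial
  imbalance <- function(angleDeg) {
    th <- angleDeg * pi / 180
    s <- dx * cos(th) + dy * sin(th)  # positive side = +x half-space
    if (side == "left") { nLat <- sum(s > 0); nMed <- total - nLat }
    else { nMed <- sum(s >= 0); nLat <- total - nMed }
    (nLat - nMed) / total
  }

  loA <- -45; hiA <- 45
  fLo <- imbalance(loA); fHi <- imbalance(hiA)
  best <- if (abs(fLo) < abs(fHi)) c(loA, fLo) else c(hiA, fHi)
  f0 <- imbalance(0)
  if (abs(f0) < abs(best[2])) best <- c(0, f0)
  converged <- FALSE
  if (abs(best[2]) < tol) {
    converged <- TRUE
  } else if (sign(fLo) != sign(fHi)) {
    for (it in seq_len(maxIter)) {
      mid <- (loA + hiA) / 2
      fm <- imbalance(mid)
      if (abs(fm) < abs(best[2])) best <- c(mid, fm)
      if (abs(fm) < tol) { converged <- TRUE; break }
      if (sign(fm) == sign(fLo)) { loA <- mid; fLo <- fm }
      else { hiA <- mid; fHi <- fm }
    }
  } else {
    # imbalance does not change sign on the range: grid-scan for minimum
    grid <- seq(-45, 45, by = 0.5)
    vals <- vapply(grid, imbalance, numeric(1))
    k <- which.min(abs(vals))
    best <- c(grid[k], vals[k])
    converged <- abs(best[2]) < tol
  }
  th <- best[1] * pi / 180
  list(angleDeg = best[1], normal = c(cos(th), sin(th), 0),
       point = as.numeric(nipple)[1:3], residual = abs(best[2]),
       converged = converged)
}

#' Quadrant localization of the tumor
#'
#' Quadrant boundaries are the balance plane and the transverse plane
#' through the nipple. The quadrant of the tumor's (unweighted) center of
#' mass names the localization; per-quadrant tumor volume fractions use
#' voxel-center membership. Outer/inner follow laterality (lateral = away
#' from the patient midline). Center-of-mass ties on a plane resolve to the
#' upper and/or outer quadrant (flagged); voxel-counting ties go to the
#' medial side of the balance plane and the lower side of the transverse
#' plane.
#'
#' @param map a [LabelMap-class].
#' @param side `"left"` or `"right"`.
#' @param nipple nipple point `(x, y, z)` mm.
#' @param plane result of [balancePlane()].
#' @param tumorMask non-empty logical 3D array (the side's tumor).
#' @return list with `rotationAngleDeg`, `quadrant`, `fractions` (named,
#'   summing to 1), `balanceResidual`, `centerOfMass` and `tieFlag`.
#' @export
assignQuadrants <- function(map, side = c("left", "right"), nipple, plane,
                            tumorMask) {
  side <- match.arg(side)
  if (!any(tumorMask)) stop("tumor mask is empty", call. = FALSE)
  sp <- map@spacing
  pts <- maskCenters(tumorMask, sp)
  n <- plane$normal

  sBal <- (pts[, 1] - nipple[1]) * n[1] + (pts[, 2] - nipple[2]) * n[2]
  lateral <- if (side == "left") sBal > 0 else sBal < 0
  upper <- pts[, 3] > nipple[3]

  quadName <- function(up, lat) {
    paste0(ifelse(up, "upper", "lower"), "-", ifelse(lat, "outer", "inner"))
  }
  counts <- table(factor(quadName(upper, lateral),
                         levels = c("upper-outer", "upper-inner",
                                    "lower-outer", "lower-inner")))
  fractions <- as.numeric(counts) / nrow(pts)
  names(fractions) <- names(counts)

  com <- colMeans(pts)
  sCom <- (com[1] - nipple[1]) * n[1] + (com[2] - nipple[2]) * n[2]
  tie <- sCom == 0 || com[3] == nipple[3]
  comLat <- if (side == "left") sCom >= 0 else sCom <= 0
  comUp <- com[3] >= nipple[3]

  list(rotationAngleDeg = plane$angleDeg,
       quadrant = quadName(comUp, comLat),
       fractions = fractions,
       balanceResidual = plane$residual,
       centerOfMass = com,
       tieFlag = tie)
}
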