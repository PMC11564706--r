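#' Corner-shifted tumor mask
#'
#' Builds a mask on the half-voxel-shifted grid whose voxel centers are the
#' corners of the original tumor voxels: the output grid has one extra voxel
#' per axis and its origin sits half a spacing below the input grid's; an
#' output voxel is TRUE exactly when its center coincides with a corner of at
#' least one occupied input voxel.
#'
#' @param mask non-empty logical 3D array.
#' @param spacing numeric(3) voxel spacing in mm.
#' @return list with `mask` (logical array of dim + 1) and `origin`
#'   (numeric(3), mm, equal to `-spacing/2`).
#' @export
cornerShiftedMask <- function(mask, spacing = attr(mask, "spacing")) {
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  d <- dim(mask)
  out <- array(FALSE, d + 1L)
  ind <- which(mask, arr.ind = TRUE)
  for (a in 0:1) for (b in 0:1) for (cc in 0:1)
    out[cbind(ind[, 1] + a, ind[, 2] + b, ind[, 3] + cc)] <- TRUE
  list(mask = out, origin = -as.numeric(spacing) / 2,
       spacing = as.numeric(spacing))
}

#' Extract a watertight triangulated surface from a binary sample grid
#'
#' Input values are treated as point samples at voxel centers. The surface
#' is the exact boundary of the union of dual-lattice cells whose eight
#' corner samples are all inside, with vertices placed exactly at sample
#' positions and outward-wound triangles; outward unit vertex normals are
#' the normalized area-weighted average of incident facet normals. Applied
#' to a [cornerShiftedMask()] this reproduces the tumor's voxel-corner
#' envelope exactly, so the enclosed volume equals the voxel volume and a
#' zero-margin hull coincides with the tumor's voxel region.
#'
#' @param mask logical 3D array of samples (non-empty, with a non-empty
#'   complement).
#' @param spacing numeric(3) sample spacing in mm.
#' @param origin numeric(3) grid origin in mm (default 0; use the origin
#'   returned by [cornerShiftedMask()] for shifted grids).
#' @return A [SurfaceMesh-class].
#' @export
extractSurface <- function(mask, spacing = attr(mask, "spacing"),
                           origin = c(0, 0, 0)) {
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  if (all(mask)) stop("mask has an empty complement: no surface", call. = FALSE)
  res <- voxel_surface_cpp(as.logical(mask), dim(mask),
                           as.numeric(spacing), as.numeric(origin))
  V <- res$vertices
  Fm <- res$faces
  # angle-weighted outward vertex normals: each incident triangle
  # contributes its unit normal weighted by the wedge angle at the vertex,
  # which is insensitive to how quads were split into triangles
  e1 <- V[Fm[, 2], , drop = FALSE] - V[Fm[, 1], , drop = FALSE]
  e2 <- V[Fm[, 3], , drop = FALSE] - V[Fm[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  fn <- fn / sqrt(rowSums(fn^2))
  wedgeAngle <- function(a, b) {
    # angle between edge vectors a, b (rows)
    num <- rowSums(a * b)
    den <- sqrt(rowSums(a^2) * rowSums(b^2))
    acos(pmin(1, pmax(-1, num / den)))
  }
  e3 <- V[Fm[, 3], , drop = FALSE] - V[Fm[, 2], , drop = FALSE]
  ang <- cbind(wedgeAngle(e1, e2),          # at vertex 1
               wedgeAngle(-e1, e3),         # at vertex 2
               wedgeAngle(-e2, -e3))        # at vertex 3
  vn <- matrix(0, nrow(V), 3)
  for (d in 1:3) {
    acc <- rowsum(as.vector(ang) * rep(fn[, d], 3L),
                  group = as.vector(Fm), reorder = TRUE)
    vn[as.integer(rownames(acc)), d] <- acc
  }
  len <- sqrt(rowSums(vn^2))
  deg <- len < 1e-12
  if (any(deg)) {
    # cancellation at pinch vertices: point away from the mesh centroid
    ctr <- colMeans(V)
    dir <- sweep(V[deg, , drop = FALSE], 2, ctr)
    dl <- sqrt(rowSums(dir^2))
    dl[dl < 1e-12] <- 1
    vn[deg, ] <- dir / dl
    len[deg] <- 1
  }
  vn <- vn / len
  new("SurfaceMesh", vertices = V, faces = Fm, normals = vn)
}

#' Enclosed volume of a closed surface mesh
#'
#' Divergence-theorem volume from outward-wound triangles.
#'
#' @param mesh a [SurfaceMesh-class].
#' @return volume in mm^3.
#' @export
meshVolume <- function(mesh) {
  V <- mesh@vertices
  Fm <- mesh@faces
  a <- V[Fm[, 1], , drop = FALSE]
  b <- V[Fm[, 2], , drop = FALSE]
  cc <- V[Fm[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

# convex hull of displaced surface vertices -> MarginHull
hullFromPoints <- function(pts, marginMM, components) {
  h <- quickhull3d_cpp(pts)
  keep <- h$vertexIndices
  remap <- integer(nrow(pts))
  remap[keep] <- seq_along(keep)
  faces <- matrix(remap[h$faces], ncol = 3)
  new("MarginHull", marginMM = marginMM,
      vertices = pts[keep, , drop = FALSE],
      faces = faces,
      facetNormals = h$normals,
      facetOffsets = as.numeric(h$offsets),
      components = as.integer(components),
      volume = h$volume)
}

# displaced surface vertex cloud for one tumor point set.
# Where the surface normal field is discontinuous (edges and corners of the
# voxel envelope), a single displaced copy per vertex under-supports the
# margin hull by m*(1 - cos(theta/2)); the vertex is therefore replicated
# along each incident facet normal and the normalized sums of their pairs
# and triples. Every copy lies exactly m from the vertex, i.e. within the
# true margin offset, so the hull stays conservative.
displacedSurfacePoints <- function(mask, spacing, marginMM) {
  sh <- cornerShiftedMask(mask, spacing)
  mesh <- extractSurface(sh$mask, spacing = sh$spacing, origin = sh$origin)
  V <- mesh@vertices
  if (marginMM == 0) return(V)
  Fm <- mesh@faces
  # incident axis-aligned facet directions per vertex (blocky envelope:
  # every facet normal is +-e_i); code 1..6 = -x,+x,-y,+y,-z,+z
  e1 <- V[Fm[, 2], , drop = FALSE] - V[Fm[, 1], , drop = FALSE]
  e2 <- V[Fm[, 3], , drop = FALSE] - V[Fm[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  ax <- max.col(abs(fn))
  sg <- sign(fn[cbind(seq_len(nrow(fn)), ax)])
  code <- 2L * ax - as.integer(sg < 0)
  vert <- as.vector(Fm)
  codes <- rep(code, times = 3L)
  key <- unique(cbind(vert, codes))
  axMat <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                 c(0, 0, -1), c(0, 0, 1))
  codeSets <- split(key[, 2], key[, 1])
  dirsOf <- function(cs) {
    ns <- axMat[cs, , drop = FALSE]
    k <- nrow(ns)
    if (k == 1) return(ns)
    if (k <= 3) {
      # graded conic combinations cover the normal cone to ~13 degrees
      W <- as.matrix(expand.grid(rep(list(0:2), k)))
      W <- W[rowSums(W) > 0, , drop = FALSE]
      s <- W %*% ns
    } else {
      # pinch vertices (rare, non-convex): axis sums of subsets up to 3
      s <- ns
      for (sz in 2:3) {
        cmb <- utils::combn(k, sz)
        s <- rbind(s, t(apply(cmb, 2, function(ix)
          colSums(ns[ix, , drop = FALSE]))))
      }
    }
    len <- sqrt(rowSums(s^2))
    keep <- len > 1e-9
    s <- s[keep, , drop = FALSE] / len[keep]
    unique(round(s, 9))
  }
  vids <- as.integer(names(codeSets))
  reps <- lapply(codeSets, dirsOf)
  nrep <- vapply(reps, nrow, integer(1))
  dirs <- do.call(rbind, reps)
  V[rep(vids, nrep), , drop = FALSE] + marginMM * dirs
}

#' Convex margin hull of one tumor point set
#'
#' Extracts the tumor surface from the corner-shifted mask, translates every
#' vertex along its outward normal by the surgical margin, and takes the
#' convex hull of the displaced vertices. At margin 0 the hull coincides
#' with the convex hull of the tumor's voxel corners, so every tumor voxel
#' corner lies inside the hull.
#'
#' @param mask non-empty logical 3D array (one component or a whole tumor
#'   treated as a single point set).
#' @param spacing numeric(3) voxel spacing in mm.
#' @param marginMM surgical margin in mm, in [0, 20].
#' @param components integer ids of the tumor components the hull encloses
#'   (bookkeeping; default 1).
#' @return A [MarginHull-class].
#' @export
buildHull <- function(mask, spacing = attr(mask, "spacing"), marginMM = 0,
                      components = 1L) {
  if (length(marginMM) != 1 || is.na(marginMM) || marginMM < 0 ||
      marginMM > 20)
    stop("marginMM must be a single value in [0, 20]", call. = FALSE)
  pts <- displacedSurfacePoints(mask, spacing, marginMM)
  hullFromPoints(pts, marginMM, components)
}

#' Unicentric margin hull
#'
#' A single convex hull around the entire tumor (all foci as one point set),
#' supporting en-bloc resection planning.
#'
#' @inheritParams buildHull
#' @param connectivity connectivity used to enumerate member component ids.
#' @return A [MarginHull-class] whose `components` lists all tumor
#'   components.
#' @export
unicentricHull <- function(mask, spacing = attr(mask, "spacing"),
                           marginMM = 0,
                           connectivity = c("face", "edge", "corner")) {
  lab <- connectedComponents(mask, match.arg(connectivity))
  ncomp <- attr(lab, "nComponents")
  buildHull(mask, spacing, marginMM, components = seq_len(ncomp))
}

#' Multicentric margin hulls with overlap merging
#'
#' Builds one margin hull per connected tumor component, then tests all hull
#' pairs for overlap by vertex-in-hull membership (facet half-space test
#' with 1e-9 mm slack). Overlapping hulls are merged transitively: each
#' merged group is rebuilt as one hull of the union of its members'
#' displaced surface vertex sets, and testing repeats until a fixed point.
#'
#' @inheritParams buildHull
#' @param connectivity component connectivity; default face (6).
#' @param tol overlap tolerance in mm.
#' @return list of [MarginHull-class] objects, ordered by smallest member
#'   component id.
#' @export
multicentricHulls <- function(mask, spacing = attr(mask, "spacing"),
                              marginMM = 0,
                              connectivity = c("face", "edge", "corner"),
                              tol = 1e-9) {
  if (length(marginMM) != 1 || is.na(marginMM) || marginMM < 0 ||
      marginMM > 20)
    stop("marginMM must be a single value in [0, 20]", call. = FALSE)
  lab <- connectedComponents(mask, match.arg(connectivity))
  ncomp <- attr(lab, "nComponents")
  if (ncomp == 0L) stop("mask is empty", call. = FALSE)
  sp <- as.numeric(spacing)
  clouds <- lapply(seq_len(ncomp), function(id)
    displacedSurfacePoints(lab == id, sp, marginMM))
  groups <- as.list(seq_len(ncomp))
  hulls <- lapply(seq_len(ncomp), function(id)
    hullFromPoints(clouds[[id]], marginMM, id))

  repeat {
    ng <- length(hulls)
    if (ng <= 1L) break
    # union-find over overlapping hull pairs
    parent <- seq_len(ng)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    merged <- FALSE
    for (i in seq_len(ng - 1L)) for (j in (i + 1L):ng) {
      if (hullsOverlap(hulls[[i]], hulls[[j]], tol)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) { parent[max(ri, rj)] <- min(ri, rj); merged <- TRUE }
      }
    }
    if (!merged) break
    roots <- vapply(seq_len(ng), find, integer(1))
    newGroups <- list(); newHulls <- list()
    for (r in unique(roots)) {
      members <- which(roots == r)
      comps <- sort(unlist(groups[members]))
      pts <- do.call(rbind, clouds[comps])
      newGroups[[length(newGroups) + 1L]] <- comps
      newHulls[[length(newHulls) + 1L]] <-
        hullFromPoints(pts, marginMM, comps)
    }
    groups <- newGroups
    hulls <- newHulls
  }
  ord <- order(vapply(hulls, function(h) min(h@components), integer(1)))
  hulls[ord]
}

# any vertex of one hull inside the other (symmetric)
hullsOverlap <- function(h1, h2, tol = 1e-9) {
  any(hullContains(h2, h1@vertices, tol)) ||
    any(hullContains(h1, h2@vertices, tol))
}

#' Test points for hull membership
#'
#' A point lies in the hull when it satisfies every facet half-space
#' inequality `x . n <= offset + tol`.
#'
#' @param hull a [MarginHull-class].
#' @param points numeric matrix (n x 3) or a single point `c(x, y, z)`, mm.
#' @param tol slack in mm (default 1e-9).
#' @return logical vector of length n.
#' @export
hullContains <- function(hull, points, tol = 1e-9) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  N <- hull@facetNormals
  off <- hull@facetOffsets
  ok <- rep(TRUE, nrow(points))
  for (f in seq_along(off)) {
    idx <- which(ok)
    if (!length(idx)) break
    s <- points[idx, , drop = FALSE] %*% N[f, ]
    ok[idx] <- s <= off[f] + tol
  }
  ok
}

#' Voxelize a margin hull onto a label-map grid
#'
#' A voxel is inside when its center satisfies all facet half-space
#' inequalities (1e-9 mm slack).
#'
#' @param hull a [MarginHull-class].
#' @param dim integer(3) grid dimensions, or a [LabelMap-class].
#' @param spacing numeric(3) voxel spacing in mm (taken from the map when a
#'   [LabelMap-class] is given).
#' @param tol half-space slack in mm.
#' @return logical 3D array.
#' @export
voxelizeHull <- function(hull, dim, spacing = NULL, tol = 1e-9) {
  if (is(dim, "LabelMap")) {
    spacing <- dim@spacing
    dim <- base::dim(dim@voxels)
  }
  sp <- as.numeric(spacing)
  out <- array(FALSE, dim)
  # crop to the hull's bounding box before the half-space test
  lo <- apply(hull@vertices, 2, min) - tol
  hi <- apply(hull@vertices, 2, max) + tol
  ilo <- pmax(1L, ceiling(lo / sp + 0.5))
  ihi <- pmin(dim, floor(hi / sp + 0.5))
  if (any(ilo > ihi)) return(out)
  idx <- as.matrix(expand.grid(i = ilo[1]:ihi[1], j = ilo[2]:ihi[2],
                               k = ilo[3]:ihi[3]))
  centers <- sweep(idx - 0.5, 2, sp, "*")
  inside <- hullContains(hull, centers, tol)
  out[idx[inside, , drop = FALSE]] <- TRUE
  attr(out, "spacing") <- sp
  out
}
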