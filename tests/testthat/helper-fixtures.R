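# shared fixtures and independent brute-force oracles

.phantomCache <- new.env(parent = emptyenv())

# cached preset phantom (deterministic, so caching is safe)
presetPhantom <- function(name, nippleTruth = TRUE) {
  key <- paste0(name, if (nippleTruth) "_t" else "")
  if (is.null(.phantomCache[[key]]))
    .phantomCache[[key]] <- generatePhantom(phantomSuite(name),
                                            nippleTruth = nippleTruth)
  .phantomCache[[key]]
}

# small single-breast phantom for focused tests
miniConfig <- function(spacing = 1,
                       tumors = list(list(center = c(32, 28.5, 34),
                                          semi = 6)),
                       lobes = list(), seed = 1L, jitterMM = 0) {
  sp <- rep(spacing, 3)
  phantomConfig(
    dim = round(c(64, 56, 64) / sp), spacing = sp, chestY = 42,
    breasts = list(breastSpec(
      side = "left", center = c(32, 42, 32), radius = 28,
      skinThickness = 1.5, nippleHeight = 3, nippleRadius = 4,
      fibroCenter = c(32, 28.5, 32), fibroSemi = c(9, 13, 9),
      tumors = tumors, lobes = lobes)),
    seed = seed, jitterMM = jitterMM, midlineIndex = 0L, name = "mini")
}

sphereMask <- function(r, dim = c(30, 30, 30), center = dim / 2,
                       spacing = c(1, 1, 1)) {
  xs <- ((seq_len(dim[1]) - 0.5) * spacing[1] - center[1])^2
  ys <- ((seq_len(dim[2]) - 0.5) * spacing[2] - center[2])^2
  zs <- ((seq_len(dim[3]) - 0.5) * spacing[3] - center[3])^2
  m <- outer(outer(xs, ys, "+"), zs, "+") <= r^2
  attr(m, "spacing") <- spacing
  m
}

randomMask <- function(dim, p, seed) {
  set.seed(seed)
  repeat {
    m <- array(runif(prod(dim)) < p, dim)
    if (any(m)) return(m)
  }
}

# all non-empty masks on a 2x2x2 grid
allTinyMasks <- function() {
  lapply(1:255, function(b) {
    array(as.logical(intToBits(b)[1:8]), c(2, 2, 2))
  })
}

# --- independent oracles ---------------------------------------------------

oracleDice <- function(a, b) {
  ia <- which(a); ib <- which(b)
  tp <- length(intersect(ia, ib))
  fp <- length(setdiff(ia, ib))
  fn <- length(setdiff(ib, ia))
  if (tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

# boundary voxel centers by explicit neighbour loops
oracleBoundaryCenters <- function(mask, sp) {
  d <- dim(mask)
  ind <- which(mask, arr.ind = TRUE)
  keep <- logical(nrow(ind))
  for (r in seq_len(nrow(ind))) {
    i <- ind[r, 1]; j <- ind[r, 2]; k <- ind[r, 3]
    nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    out <- FALSE
    for (q in seq_len(6)) {
      v <- nb[q, ]
      if (any(v < 1) || any(v > d) || !mask[v[1], v[2], v[3]]) {
        out <- TRUE; break
      }
    }
    keep[r] <- out
  }
  sweep(ind[keep, , drop = FALSE] - 0.5, 2, sp, "*")
}

oracleHausdorff <- function(a, b, sp) {
  X <- oracleBoundaryCenters(a, sp)
  Y <- oracleBoundaryCenters(b, sp)
  D2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
  D2[D2 < 0] <- 0
  max(max(sqrt(apply(D2, 1, min))), max(sqrt(apply(D2, 2, min))))
}

# deduplicated corner set from first principles
oracleCorners <- function(mask, sp) {
  ind <- which(mask, arr.ind = TRUE)
  out <- NULL
  for (r in seq_len(nrow(ind))) {
    v <- ind[r, ]
    cs <- as.matrix(expand.grid(c(v[1] - 1, v[1]), c(v[2] - 1, v[2]),
                                c(v[3] - 1, v[3])))
    out <- rbind(out, cs)
  }
  out <- out[!duplicated(paste(out[, 1], out[, 2], out[, 3])), ,
             drop = FALSE]
  sweep(out, 2, sp, "*")
}

oracleCornerDistance <- function(a, b, sp) {
  A <- oracleCorners(a, sp)
  B <- oracleCorners(b, sp)
  best <- Inf
  for (r in seq_len(nrow(A))) {
    d <- sqrt(min(colSums((t(B) - A[r, ])^2)))
    if (d < best) best <- d
  }
  best
}

# minimum distance from a set of points to a hull boundary (interior points)
minBoundaryDistance <- function(hull, pts) {
  M <- pts %*% t(hull@facetNormals)
  D <- sweep(-M, 2, hull@facetOffsets, "+")  # offsets - n.x per facet
  min(apply(D, 1, min))
}

breastTissueCount <- function(map) {
  labs <- labelOf(schema(map), c("skin", "adipose", "fibroglandular",
                                 "vessel", "tumor"))
  sum(voxels(map) %in% labs)
}
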