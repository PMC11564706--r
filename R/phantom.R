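#' Specify one phantom breast
#'
#' Geometry of a hemispherical breast attached anterior to the chest slab:
#' outer radius and skin shell, a paraboloidal nipple bump at the apex, a
#' fibroglandular ellipsoid behind the nipple, optional tubular vessels,
#' ellipsoidal tumor foci, and optional extra adipose lobes (for bulge /
#' asymmetry scenarios; lobes are excluded from analytic volume truth).
#'
#' @param side `"left"` or `"right"`.
#' @param center breast center `(x, y, z)` mm; `y` must equal the chest
#'   plane so the hemisphere attaches to the slab.
#' @param radius outer breast radius, mm.
#' @param skinThickness skin shell thickness, mm.
#' @param nippleHeight,nippleRadius paraboloidal bump height and base
#'   radius, mm.
#' @param fibroCenter,fibroSemi fibroglandular ellipsoid center (mm) and
#'   semi-axes (mm).
#' @param vessels list of `list(center, axis, radius, halfLength)` cylinders.
#' @param tumors list of `list(center, semi)` ellipsoids (`semi` may be a
#'   scalar radius for spheres).
#' @param lobes list of `list(center, radius)` extra adipose spheres.
#' @return named list describing the breast.
#' @export
breastSpec <- function(side, center, radius, skinThickness = 2,
                       nippleHeight = 5, nippleRadius = 5,
                       fibroCenter, fibroSemi, vessels = list(),
                       tumors = list(), lobes = list()) {
  tumors <- lapply(tumors, function(t) {
    t$semi <- rep(as.numeric(t$semi), length.out = 3)
    t$center <- as.numeric(t$center)
    t
  })
  list(side = match.arg(side, c("left", "right")),
       center = as.numeric(center), radius = radius,
       skinThickness = skinThickness, nippleHeight = nippleHeight,
       nippleRadius = nippleRadius, fibroCenter = as.numeric(fibroCenter),
       fibroSemi = rep(as.numeric(fibroSemi), length.out = 3),
       vessels = vessels, tumors = tumors, lobes = lobes)
}

#' Digital breast phantom configuration
#'
#' @slot dim grid shape (Ni, Nj, Nk).
#' @slot spacing voxel spacing, mm.
#' @slot chestY anterior face of the chest slab (chest occupies y >=
#'   chestY), mm.
#' @slot breasts list of [breastSpec()] descriptions.
#' @slot seed integer random seed (used only when `jitterMM > 0`).
#' @slot jitterMM amplitude of seeded Gaussian surface-radius jitter; 0
#'   gives purely analytic shapes.
#' @slot midlineIndex 0-based laterality midline for downstream analysis
#'   (0 = whole volume is the left side).
#' @slot name preset name (or "custom").
#' @export
setClass("PhantomConfig", representation(dim = "integer",
                                         spacing = "numeric",
                                         chestY = "numeric",
                                         breasts = "list",
                                         seed = "integer",
                                         jitterMM = "numeric",
                                         midlineIndex = "integer",
                                         name = "character"))

setValidity("PhantomConfig", function(object) {
  if (length(object@dim) != 3L || any(object@dim < 4L))
    return("dim must be three integers >= 4")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three positive numbers")
  for (br in object@breasts) {
    if (br$radius <= 0 || br$skinThickness <= 0 ||
        br$nippleHeight <= 0 || br$nippleRadius <= 0 ||
        any(br$fibroSemi <= 0))
      return("all radii and thicknesses must be positive")
    if (abs(br$center[2] - object@chestY) > 1e-9)
      return("breast center must lie on the chest plane")
    rIn <- br$radius - br$skinThickness
    if (rIn <= 0) return("skin thickness must be below the breast radius")
    for (tm in br$tumors) {
      if (any(tm$semi <= 0)) return("tumor semi-axes must be positive")
      if (ellipsoidMaxDist(tm$center, tm$semi, br$center) > rIn - 1e-9)
        return("config error: tumor not strictly inside the breast interior")
      if (tm$center[2] + max(tm$semi) >= object@chestY)
        return("config error: tumor overlaps the chest slab")
    }
  }
  TRUE
})

setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf(
    "PhantomConfig '%s': grid %s, spacing %s mm, %d breast(s), seed %d\n",
    object@name, paste(object@dim, collapse = "x"),
    paste(format(object@spacing), collapse = "x"),
    length(object@breasts), object@seed))
})

#' Construct a PhantomConfig
#'
#' @param dim,spacing,chestY,breasts,seed,jitterMM,midlineIndex,name see
#'   [PhantomConfig-class].
#' @return A validated [PhantomConfig-class].
#' @export
phantomConfig <- function(dim, spacing = c(1, 1, 1), chestY, breasts,
                          seed = 1L, jitterMM = 0, midlineIndex = 0L,
                          name = "custom") {
  new("PhantomConfig", dim = as.integer(dim),
      spacing = as.numeric(spacing), chestY = as.numeric(chestY),
      breasts = breasts, seed = as.integer(seed),
      jitterMM = as.numeric(jitterMM),
      midlineIndex = as.integer(midlineIndex), name = name)
}

#' Frozen phantom presets
#'
#' Six documented presets spanning the presentation spectrum: unifocal
#' small/large, multifocal with nearby foci (surface gap < 10 mm, so a 5 mm
#' margin forces hull merging), multifocal with distant foci (surface gap >
#' 40 mm, twice the maximum margin, so hulls never merge), bilateral disease,
#' and a dense fibroglandular breast with the tumor inside the
#' fibroglandular core. Unilateral presets model a single left breast
#' occupying the whole grid (`midlineIndex = 0`); the bilateral preset uses
#' the centered mid-sagittal split.
#'
#' @param name one of `"unifocal_small"`, `"unifocal_large"`,
#'   `"multifocal_near"`, `"multifocal_far"`, `"bilateral"`,
#'   `"dense_fibroglandular"`.
#' @param spacing voxel spacing in mm (default 1 mm isotropic); grid
#'   dimensions scale accordingly.
#' @return A [PhantomConfig-class].
#' @export
phantomSuite <- function(name = c("unifocal_small", "unifocal_large",
                                  "multifocal_near", "multifocal_far",
                                  "bilateral", "dense_fibroglandular"),
                         spacing = c(1, 1, 1)) {
  name <- match.arg(name)
  spacing <- rep(as.numeric(spacing), length.out = 3)
  sizeMM <- c(110, 96, 110)
  chestY <- 72
  std <- function(cx, tumors, fibroSemi = c(15, 23, 15),
                  fibroCenter = c(cx, 47, 55), side = "left") {
    breastSpec(side = side, center = c(cx, chestY, 55), radius = 50,
               skinThickness = 2, nippleHeight = 4, nippleRadius = 5,
               fibroCenter = fibroCenter, fibroSemi = fibroSemi,
               vessels = list(list(center = c(cx - 15, 60, 55),
                                   axis = c(0, 0, 1), radius = 2,
                                   halfLength = 25)),
               tumors = tumors)
  }
  cfg <- switch(name,
    unifocal_small = list(
      sizeMM = sizeMM,
      breasts = list(std(55, list(list(center = c(68, 48, 68), semi = 10))))),
    unifocal_large = list(
      sizeMM = sizeMM,
      breasts = list(std(55, list(list(center = c(64, 52, 62), semi = 16))))),
    multifocal_near = list(
      sizeMM = sizeMM,
      breasts = list(std(55, list(list(center = c(48, 45, 48), semi = 8),
                                  list(center = c(66, 45, 62), semi = 8))))),
    multifocal_far = list(
      sizeMM = sizeMM,
      breasts = list(std(55, list(list(center = c(30, 55, 55), semi = 6),
                                  list(center = c(80, 55, 80), semi = 6))))),
    bilateral = list(
      sizeMM = c(220, 96, 110),
      breasts = list(
        std(55, list(list(center = c(42, 48, 68), semi = 8)), side = "right"),
        std(165, list(list(center = c(178, 48, 68), semi = 10)),
            side = "left"))),
    dense_fibroglandular = list(
      sizeMM = sizeMM,
      breasts = list(std(55, list(list(center = c(58, 48, 63), semi = 8)),
                         fibroSemi = c(18, 24, 18),
                         fibroCenter = c(55, 48, 55)))))
  dim <- as.integer(round(cfg$sizeMM / spacing))
  midline <- if (name == "bilateral") dim[1] %/% 2L else 0L
  phantomConfig(dim = dim, spacing = spacing, chestY = chestY,
                breasts = cfg$breasts, seed = 1L, jitterMM = 0,
                midlineIndex = midline, name = name)
}

# --- continuous-geometry helpers -------------------------------------------

# distance from point q to the surface of an axis-aligned ellipsoid; 0 when
# q lies inside the solid
ellipsoidMinDist <- function(center, semi, q) {
  d <- as.numeric(q) - as.numeric(center)
  a <- rep(as.numeric(semi), length.out = 3)
  lev <- sum((d / a)^2)
  if (lev <= 1) return(0)
  f <- function(t) sum((a * d / (a^2 + t))^2) - 1
  up <- sqrt(sum((a * d)^2))
  t <- uniroot(f, c(0, up), tol = 1e-12)$root
  sqrt(sum((t * d / (a^2 + t))^2))
}

# maximum distance from point q to the surface of an axis-aligned ellipsoid
ellipsoidMaxDist <- function(center, semi, q) {
  d <- as.numeric(q) - as.numeric(center)
  a <- rep(as.numeric(semi), length.out = 3)
  if (sqrt(sum(d^2)) < 1e-12) return(max(a))
  amax2 <- max(a^2)
  onMax <- a^2 > amax2 - 1e-12
  g <- function(mu) sum((a * d / (a^2 - mu))^2)
  if (all(abs(a[onMax] * d[onMax]) < 1e-12)) {
    # the point is orthogonal to the longest axes; mass may sit there
    rest <- !onMax
    s <- if (any(rest)) sum((a[rest] * d[rest] / (a[rest]^2 - amax2))^2) else 0
    if (s <= 1) {
      u <- numeric(3)
      u[rest] <- a[rest] * d[rest] / (a[rest]^2 - amax2)
      # leftover on a longest axis
      u[which(onMax)[1]] <- sqrt(max(0, 1 - sum(u^2)))
      p <- a * u
      return(sqrt(sum((p - d)^2)))
    }
  }
  lo <- amax2 * (1 + 1e-12) + 1e-12
  hi <- amax2 + sqrt(sum((a * d)^2)) + max(a)
  while (g(lo) < 1) lo <- (lo + amax2) / 2  # safeguard
  mu <- uniroot(function(m) g(m) - 1, c(lo, hi), tol = 1e-12)$root
  u <- a * d / (a^2 - mu)
  sqrt(sum((a * u - d)^2))
}

# --- generation ------------------------------------------------------------

#' Generate a phantom label map with analytic ground truth
#'
#' Voxelizes the configured anatomy with stamping precedence air < chest <
#' adipose < fibroglandular < vessel < skin < tumor (every voxel labelled
#' exactly once). Ground truth is computed from the continuous geometry
#' (closed forms and 1D root-finding for sphere/ellipsoid/plane distances),
#' never from the voxel grid, so voxelization error remains measurable.
#'
#' @param config a [PhantomConfig-class].
#' @param nippleTruth compute the continuous-limit nipple landmark by fine
#'   quadrature (slower); needed for nipple and tumor-to-nipple truth.
#' @return list with `map` (a [LabelMap-class]) and `truth` (nested list;
#'   see Details).
#' @details `truth$sides[[side]]` carries `apexMM` (breast apex: the
#'   anterior pole of the hemisphere, where the nipple bump attaches),
#'   `nippleTipMM` (tip of the bump), `nippleMM` (continuous-limit detector
#'   landmark, when
#'   requested), per-tumor analytic volumes, extents and distances to skin /
#'   chest / nipple, whole-tumor aggregates, the intended quadrant, and
#'   analytic per-tissue volumes (NA when extra lobes or tumor/fibro
#'   overlap make them non-analytic).
#' @export
generatePhantom <- function(config, nippleTruth = TRUE) {
  validObject(config)
  set.seed(config@seed)
  d <- config@dim
  sp <- config@spacing
  xs <- (seq_len(d[1]) - 0.5) * sp[1]
  ys <- (seq_len(d[2]) - 0.5) * sp[2]
  zs <- (seq_len(d[3]) - 0.5) * sp[3]
  sch <- defaultSchema()
  lab <- array(labelOf(sch, "air"), d)

  chestJ <- ys >= config@chestY
  if (any(chestJ)) lab[, chestJ, ] <- labelOf(sch, "chest")

  # evaluate shape masks only within a bounding crop for speed
  cropOf <- function(loMM, hiMM) {
    lo <- pmax(1L, floor(loMM / sp + 0.5))
    hi <- pmin(d, ceiling(hiMM / sp + 0.5))
    if (any(lo > hi)) return(NULL)
    list(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3])
  }
  gridSq <- function(crop) {
    dd <- c(length(crop$i), length(crop$j), length(crop$k))
    list(d = dd,
         X = array(rep(xs[crop$i], times = dd[2] * dd[3]), dd),
         Y = array(rep(rep(ys[crop$j], each = dd[1]), times = dd[3]), dd),
         Z = array(rep(zs[crop$k], each = dd[1] * dd[2]), dd))
  }
  stamp <- function(lab, crop, maskSub, label) {
    sub <- lab[crop$i, crop$j, crop$k, drop = FALSE]
    sub[maskSub] <- label
    lab[crop$i, crop$j, crop$k] <- sub
    lab
  }

  truthSides <- list()
  for (br in config@breasts) {
    rIn <- br$radius - br$skinThickness
    tipY <- config@chestY - br$radius - br$nippleHeight
    pad <- 1 + 6 * config@jitterMM
    crop <- cropOf(c(br$center[1] - br$radius - pad, tipY - pad,
                     br$center[3] - br$radius - pad),
                   c(br$center[1] + br$radius + pad, config@chestY,
                     br$center[3] + br$radius + pad))
    g <- gridSq(crop)
    rr <- sqrt((g$X - br$center[1])^2 + (g$Y - br$center[2])^2 +
               (g$Z - br$center[3])^2)
    if (config@jitterMM > 0)
      rr <- rr + array(stats::rnorm(prod(g$d), 0, config@jitterMM), g$d)
    ant <- g$Y < config@chestY
    inBreast <- rr <= br$radius & ant
    interior <- rr <= rIn & ant

    lab <- stamp(lab, crop, interior, labelOf(sch, "adipose"))
    for (lb in br$lobes) {
      lc <- cropOf(lb$center - lb$radius - 1, lb$center + lb$radius + 1)
      gl <- gridSq(lc)
      lobeIn <- (gl$X - lb$center[1])^2 + (gl$Y - lb$center[2])^2 +
        (gl$Z - lb$center[3])^2 <= lb$radius^2 & gl$Y < config@chestY
      sub <- lab[lc$i, lc$j, lc$k, drop = FALSE]
      sub[lobeIn & sub == labelOf(sch, "air")] <- labelOf(sch, "adipose")
      lab[lc$i, lc$j, lc$k] <- sub
    }

    fib <- (g$X - br$fibroCenter[1])^2 / br$fibroSemi[1]^2 +
      (g$Y - br$fibroCenter[2])^2 / br$fibroSemi[2]^2 +
      (g$Z - br$fibroCenter[3])^2 / br$fibroSemi[3]^2 <= 1
    lab <- stamp(lab, crop, fib & interior, labelOf(sch, "fibroglandular"))

    for (vs in br$vessels) {
      u <- as.numeric(vs$axis); u <- u / sqrt(sum(u^2))
      proj <- (g$X - vs$center[1]) * u[1] + (g$Y - vs$center[2]) * u[2] +
        (g$Z - vs$center[3]) * u[3]
      perp2 <- (g$X - vs$center[1])^2 + (g$Y - vs$center[2])^2 +
        (g$Z - vs$center[3])^2 - proj^2
      vm <- perp2 <= vs$radius^2 & abs(proj) <= vs$halfLength
      lab <- stamp(lab, crop, vm & interior, labelOf(sch, "vessel"))
    }

    lab <- stamp(lab, crop, inBreast & !interior, labelOf(sch, "skin"))
    baseY <- config@chestY - br$radius
    frac <- pmax(0, (g$Y - tipY) / br$nippleHeight)
    bump <- g$Y >= tipY & g$Y <= baseY &
      (g$X - br$center[1])^2 + (g$Z - br$center[3])^2 <=
        br$nippleRadius^2 * frac
    lab <- stamp(lab, crop, bump & ant, labelOf(sch, "skin"))

    for (tm in br$tumors) {
      tmask <- (g$X - tm$center[1])^2 / tm$semi[1]^2 +
        (g$Y - tm$center[2])^2 / tm$semi[2]^2 +
        (g$Z - tm$center[3])^2 / tm$semi[3]^2 <= 1
      lab <- stamp(lab, crop, tmask & interior, labelOf(sch, "tumor"))
    }

    truthSides[[br$side]] <- breastTruth(br, config, nippleTruth)
  }

  map <- LabelMap(lab, spacing = sp, schema = sch)
  truth <- list(name = config@name, spacing = sp,
                midlineIndex = config@midlineIndex, sides = truthSides)
  list(map = map, truth = truth)
}

# analytic per-side ground truth
breastTruth <- function(br, config, nippleTruth) {
  chestY <- config@chestY
  rIn <- br$radius - br$skinThickness
  # breast apex: anterior pole of the hemisphere, where the bump attaches
  apex <- c(br$center[1], chestY - br$radius, br$center[3])
  nippleTip <- c(br$center[1], chestY - br$radius - br$nippleHeight,
                 br$center[3])
  nip <- if (nippleTruth) truthNipple(br, chestY) else NULL

  parabV <- 0.5 * pi * br$nippleRadius^2 * br$nippleHeight
  hemis <- function(r) (2 / 3) * pi * r^3
  vesselV <- sum(vapply(br$vessels, function(v)
    pi * v$radius^2 * 2 * v$halfLength, numeric(1)))
  tumorVols <- vapply(br$tumors, function(tm)
    (4 / 3) * pi * prod(tm$semi), numeric(1))

  # tumor/fibro overlap detection (sampled on the tumor surface)
  overlapsFibro <- vapply(br$tumors, function(tm) {
    u <- sphericalDirections(64)
    p <- sweep(u %*% diag(tm$semi), 2, tm$center, "+")
    lev <- colSums((t(p) - br$fibroCenter)^2 / br$fibroSemi^2)
    any(lev < 1) && !all(lev < 1)
  }, logical(1))
  insideFibro <- vapply(br$tumors, function(tm) {
    u <- sphericalDirections(64)
    p <- sweep(u %*% diag(tm$semi), 2, tm$center, "+")
    lev <- colSums((t(p) - br$fibroCenter)^2 / br$fibroSemi^2)
    all(lev < 1)
  }, logical(1))

  analyticOK <- length(br$lobes) == 0 && !any(overlapsFibro)
  fibroV <- (4 / 3) * pi * prod(br$fibroSemi) -
    sum(tumorVols[insideFibro])
  tissueVolumes <- if (analyticOK) list(
    breastTotal = hemis(br$radius) + parabV,
    skin = hemis(br$radius) - hemis(rIn) + parabV,
    fibroglandular = fibroV,
    adipose = hemis(rIn) - (4 / 3) * pi * prod(br$fibroSemi) - vesselV -
      sum(tumorVols[!insideFibro]),
    vessel = vesselV,
    tumor = sum(tumorVols)) else NULL

  tumors <- lapply(seq_along(br$tumors), function(ti) {
    tm <- br$tumors[[ti]]
    toSkin <- rIn - ellipsoidMaxDist(tm$center, tm$semi, br$center)
    toChest <- chestY - (tm$center[2] + tm$semi[2])
    toNip <- if (!is.null(nip))
      ellipsoidMinDist(tm$center, tm$semi, nip) else NA_real_
    ref <- if (!is.null(nip)) nip else apex
    lat <- if (br$side == "left") tm$center[1] > ref[1]
           else tm$center[1] < ref[1]
    up <- tm$center[3] > ref[3]
    list(centerMM = tm$center, semiMM = tm$semi,
         volumeMM3 = (4 / 3) * pi * prod(tm$semi),
         extentsMM = 2 * tm$semi,
         toSkinMM = toSkin, toChestMM = toChest, toNippleMM = toNip,
         quadrant = paste0(if (up) "upper" else "lower", "-",
                           if (lat) "outer" else "inner"))
  })

  whole <- if (length(tumors)) {
    ctrs <- do.call(rbind, lapply(br$tumors, `[[`, "center"))
    semis <- do.call(rbind, lapply(br$tumors, `[[`, "semi"))
    list(extentsMM = apply(ctrs + semis, 2, max) -
           apply(ctrs - semis, 2, min),
         volumeMM3 = sum(tumorVols),
         toSkinMM = min(vapply(tumors, `[[`, numeric(1), "toSkinMM")),
         toChestMM = min(vapply(tumors, `[[`, numeric(1), "toChestMM")),
         toNippleMM = min(vapply(tumors, `[[`, numeric(1), "toNippleMM")))
  } else NULL

  list(side = br$side, apexMM = apex, nippleTipMM = nippleTip,
       nippleMM = nip,
       breastCenter = br$center, radius = br$radius,
       skinThickness = br$skinThickness,
       tumors = tumors, wholeTumor = whole,
       tissueVolumesMM3 = tissueVolumes, hasLobes = length(br$lobes) > 0)
}

sphericalDirections <- function(n) {
  # deterministic quasi-uniform directions (Fibonacci sphere)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# continuous-limit nipple landmark: centroid of the region within the
# detector radius of the air, skin and fibroglandular regions, found by
# fine quadrature (step mm) of the continuous geometry, plus the posterior
# offset. Independent of the phantom's voxel grid.
truthNipple <- function(br, chestY, radiusMM = 8, offsetMM = 6,
                        step = 0.5) {
  twoPass <- function(stp, box) {
    gx <- seq(box[1, 1], box[2, 1], by = stp)
    gy <- seq(box[1, 2], box[2, 2], by = stp)
    gz <- seq(box[1, 3], box[2, 3], by = stp)
    G <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    rr <- sqrt((G[, 1] - br$center[1])^2 + (G[, 2] - br$center[2])^2 +
               (G[, 3] - br$center[3])^2)
    ant <- G[, 2] < chestY
    baseY <- chestY - br$radius
    tipY <- baseY - br$nippleHeight
    frac <- pmax(0, (G[, 2] - tipY) / br$nippleHeight)
    inBump <- G[, 2] >= tipY & G[, 2] <= baseY &
      ((G[, 1] - br$center[1])^2 + (G[, 3] - br$center[3])^2 <=
         br$nippleRadius^2 * frac)
    rIn <- br$radius - br$skinThickness
    skin <- ((rr <= br$radius & rr > rIn) | inBump) & ant
    air <- rr > br$radius & !inBump & ant
    lev <- (G[, 1] - br$fibroCenter[1])^2 / br$fibroSemi[1]^2 +
      (G[, 2] - br$fibroCenter[2])^2 / br$fibroSemi[2]^2 +
      (G[, 3] - br$fibroCenter[3])^2 / br$fibroSemi[3]^2
    fib <- lev <= 1 & rr <= rIn & ant
    # only the near-surface band around the apex can host candidates: a
    # candidate needs air (outside the breast), skin and fibroglandular
    # tissue all within reach, and the fibroglandular core approaches the
    # skin only near the apex. The restrictions below are supersets of the
    # reachable sets (ball bound around the fibro ellipsoid), hence exact.
    # distance lower bound from homothetic ellipsoids:
    # dist(p, fibro) >= (sqrt(lev) - 1) * min(semi) outside the ellipsoid
    aMin <- min(br$fibroSemi)
    levCap <- function(reach) (1 + reach / aMin)^2
    bumpish <- G[, 2] <= chestY - br$radius + 1 &
      (G[, 1] - br$center[1])^2 + (G[, 3] - br$center[3])^2 <=
        (br$nippleRadius + radiusMM + 1)^2
    band <- ((rr >= br$radius - radiusMM - 1 &
              rr <= br$radius + radiusMM + 1) | bumpish) &
      lev <= levCap(radiusMM + 1)
    air <- air & rr <= br$radius + radiusMM + 1 &
      lev <= levCap(2 * radiusMM + 2)
    fib <- fib & lev >= 0.7 &  # outer shell; interior points never nearest
      rr >= br$radius - 2 * radiusMM - 2
    skin <- skin & lev <= levCap(2 * radiusMM + 2)
    query <- which(band)
    near <- function(set) {
      out <- rep(FALSE, nrow(G))
      if (!any(set)) return(out)
      out[query] <- RANN::nn2(G[set, , drop = FALSE],
                              query = G[query, , drop = FALSE],
                              k = 1)$nn.dists[, 1] <= radiusMM
      out
    }
    cand <- near(fib) & near(skin) & near(air)
    list(G = G, cand = cand)
  }
  apexY <- chestY - br$radius - br$nippleHeight
  box1 <- rbind(c(br$center[1] - br$fibroSemi[1] - 18, apexY - 10,
                  br$center[3] - br$fibroSemi[3] - 18),
                c(br$center[1] + br$fibroSemi[1] + 18,
                  br$fibroCenter[2] - br$fibroSemi[2] + 20,
                  br$center[3] + br$fibroSemi[3] + 18))
  coarse <- twoPass(1.0, box1)
  if (!any(coarse$cand))
    stop("phantom geometry yields no nipple candidate region", call. = FALSE)
  cb <- coarse$G[coarse$cand, , drop = FALSE]
  box2 <- rbind(apply(cb, 2, min) - (radiusMM + 2),
                apply(cb, 2, max) + (radiusMM + 2))
  fine <- twoPass(step, box2)
  p <- colMeans(fine$G[fine$cand, , drop = FALSE])
  c(x = p[1], y = p[2] + offsetMM, z = p[3])
}
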