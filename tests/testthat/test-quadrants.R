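test_that("balance plane is sagittal for symmetric anatomy", {
  ph <- presetPhantom("unifocal_small")
  nip <- locateNipple(ph$map, "left", midline = 0)
  box <- buildBreastBox(ph$map, "left", midline = 0)
  pl <- balancePlane(ph$map, "left", nip, box)
  expect_true(pl$converged)
  expect_lt(abs(pl$angleDeg), 1)
  expect_lt(pl$residual, 0.005)
})

test_that("a lateral adipose lobe rotates the plane off sagittal", {
  cfg <- miniConfig(lobes = list(list(center = c(56, 34, 32), radius = 8)))
  ph <- generatePhantom(cfg)
  nip <- locateNipple(ph$map, "left", midline = 0)
  box <- buildBreastBox(ph$map, "left", midline = 0)
  pl <- balancePlane(ph$map, "left", nip, box)
  expect_true(pl$converged)
  expect_gt(abs(pl$angleDeg), 0.5)
  expect_lt(pl$residual, 0.005)
  # oracle bound: a 0.1-degree sweep finds no materially better angle
  b <- box@bounds
  labs <- labelOf(schema(ph$map), c("skin", "adipose", "fibroglandular",
                                    "vessel", "tumor"))
  sub <- voxels(ph$map)[b[1, 1]:b[2, 1], b[1, 2]:b[2, 2], b[1, 3]:b[2, 3]]
  ind <- which(array(sub %in% labs, dim(sub)), arr.ind = TRUE)
  ind <- sweep(ind, 2, b[1, ] - 1L, "+")
  pts <- sweep(ind, 2, c(0.5, 0.5, 0.5)) # spacing 1
  imb <- function(th) {
    s <- (pts[, 1] - nip[1]) * cos(th * pi / 180) +
      (pts[, 2] - nip[2]) * sin(th * pi / 180)
    abs(sum(s > 0) - sum(s <= 0)) / nrow(pts)
  }
  sweepMin <- min(vapply(seq(-45, 45, by = 0.1), imb, numeric(1)))
  expect_lte(pl$residual, sweepMin + 0.005)
})

test_that("quadrant assignment matches hand-checked geometry", {
  # 32^3 fixture: left breast, tumor strictly superior-lateral to the nipple
  arr <- array(0L, c(32, 32, 32))
  arr[4:28, 4:20, 4:28] <- 2L
  arr[20:24, 8:12, 20:24] <- 6L
  m <- LabelMap(arr)
  nip <- c(16, 6, 16)
  plane <- list(angleDeg = 0, normal = c(1, 0, 0), point = nip,
                residual = 0, converged = TRUE)
  tum <- tissueMask(m, "tumor")
  q <- assignQuadrants(m, "left", nip, plane, tum)
  expect_identical(q$quadrant, "upper-outer")
  expect_equal(unname(q$fractions["upper-outer"]), 1)
  expect_equal(sum(q$fractions), 1, tolerance = 1e-9)
  # mirrored to a right breast the quadrant name is preserved
  arrR <- arr[32:1, , ]
  mR <- LabelMap(arrR)
  nipR <- c(32 - 16, 6, 16)
  qR <- assignQuadrants(mR, "right", nipR, plane, tissueMask(mR, "tumor"))
  expect_identical(qR$quadrant, "upper-outer")
  expect_equal(unname(qR$fractions["upper-outer"]), 1)
})

test_that("mirroring the anatomy negates the balance angle", {
  cfg <- miniConfig(lobes = list(list(center = c(56, 34, 32), radius = 8)))
  ph <- generatePhantom(cfg, nippleTruth = FALSE)
  nip <- locateNipple(ph$map, "left", midline = 0)
  box <- buildBreastBox(ph$map, "left", midline = 0)
  pl <- balancePlane(ph$map, "left", nip, box)
  arrM <- voxels(ph$map)[dim(ph$map)[1]:1, , ]
  mM <- LabelMap(arrM, spacing = spacing(ph$map))
  ni <- dim(mM)[1]
  nipM <- c(ni * spacing(mM)[1] - nip[1], nip[2], nip[3])
  boxM <- buildBreastBox(mM, "right", midline = ni)
  plM <- balancePlane(mM, "right", nipM, boxM)
  expect_equal(plM$angleDeg, -pl$angleDeg, tolerance = 0.2)
})

test_that("tumor volume fractions partition across quadrants", {
  ph <- presetPhantom("multifocal_near")
  nip <- locateNipple(ph$map, "left", midline = 0)
  box <- buildBreastBox(ph$map, "left", midline = 0)
  pl <- balancePlane(ph$map, "left", nip, box)
  tum <- tissueMask(ph$map, "tumor")
  q <- assignQuadrants(ph$map, "left", nip, pl, tum)
  expect_equal(sum(q$fractions), 1, tolerance = 1e-9)
  expect_true(all(q$fractions >= 0))
  # the two foci straddle the nipple x: both inner and outer see volume
  expect_gt(q$fractions["lower-outer"] + q$fractions["upper-outer"], 0)
  expect_gt(q$fractions["lower-inner"] + q$fractions["upper-inner"], 0)
})

test_that("the intended phantom quadrant is recovered end to end", {
  for (nm in c("unifocal_small", "dense_fibroglandular")) {
    ph <- presetPhantom(nm)
    tr <- ph$truth$sides$left
    nip <- locateNipple(ph$map, "left", midline = 0)
    box <- buildBreastBox(ph$map, "left", midline = 0)
    pl <- balancePlane(ph$map, "left", nip, box)
    q <- assignQuadrants(ph$map, "left", nip, pl,
                         tissueMask(ph$map, "tumor"))
    expect_identical(q$quadrant, tr$tumors[[1]]$quadrant)
  }
})
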