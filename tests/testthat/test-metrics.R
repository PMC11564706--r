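test_that("connected components respect the structure element", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE  # shares only a corner with the first voxel
  lf <- connectedComponents(m, "face")
  expect_identical(attr(lf, "nComponents"), 2L)
  lc <- connectedComponents(m, "corner")
  expect_identical(attr(lc, "nComponents"), 1L)
  m2 <- array(FALSE, c(4, 4, 4))
  m2[1, 1, 1] <- TRUE
  m2[2, 2, 1] <- TRUE  # shares an edge
  expect_identical(attr(connectedComponents(m2, "face"), "nComponents"), 2L)
  expect_identical(attr(connectedComponents(m2, "edge"), "nComponents"), 1L)
  empty <- array(FALSE, c(3, 3, 3))
  expect_identical(attr(connectedComponents(empty), "nComponents"), 0L)
})

test_that("dominant mass picks the largest component with raster tie-break", {
  m <- array(FALSE, c(10, 3, 3))
  m[1:5, 1, 1] <- TRUE   # 5 voxels
  m[8:10, 1, 1] <- TRUE  # 3 voxels
  dm <- dominantMass(m)
  expect_identical(sum(dm), 5L)
  expect_true(all(dm[1:5, 1, 1]))
  # tie: two 4-voxel components -> earlier raster id wins
  t2 <- array(FALSE, c(10, 3, 3))
  t2[6:9, 1, 1] <- TRUE
  t2[1:4, 3, 3] <- TRUE
  dmt <- dominantMass(t2)
  expect_true(all(dmt[6:9, 1, 1]))  # first voxel in column-major order
  # unifocal: identity
  s <- sphereMask(5, c(14, 14, 14))
  expect_identical(unname(which(dominantMass(s))), which(s))
  expect_error(dominantMass(array(FALSE, c(2, 2, 2))), "empty")
})

test_that("axis extents use outer voxel edges", {
  rod <- array(FALSE, c(12, 3, 3)); rod[2:11, 2, 2] <- TRUE
  expect_equal(unname(axisExtents(rod, c(1, 1, 1))), c(10, 1, 1))
  expect_equal(unname(axisExtents(rod, c(0.5, 0.5, 2))), c(5, 0.5, 2))
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  expect_equal(unname(axisExtents(one, c(1, 1, 1))), c(1, 1, 1))
  expect_error(axisExtents(array(FALSE, c(2, 2, 2)), c(1, 1, 1)), "empty")
})

test_that("tumor volume is voxel count times voxel volume", {
  m <- array(FALSE, c(5, 5, 5)); m[1:10] <- TRUE
  expect_equal(tumorVolume(m, c(1, 1, 1)), 10)
  m8 <- array(FALSE, c(2, 2, 2)); m8[] <- TRUE
  expect_equal(tumorVolume(m8, c(0.5, 0.5, 2)), 4)
  expect_equal(tumorVolume(array(FALSE, c(2, 2, 2)), c(1, 1, 1)), 0)
})

test_that("vertex-set distances match hand-derived corner geometry", {
  sp <- c(1, 1, 1)
  a <- array(FALSE, c(6, 3, 3)); a[1, 2, 2] <- TRUE
  b <- array(FALSE, c(6, 3, 3)); b[6, 2, 2] <- TRUE
  expect_equal(tumorToLandmarkDistance(a, b, sp), 4)  # corner 1 to corner 5
  adj <- array(FALSE, c(6, 3, 3)); adj[2, 2, 2] <- TRUE
  expect_equal(tumorToLandmarkDistance(a, adj, sp), 0)  # shared corners
  # unit voxel [0,1]^3 against a point: nearest CORNER (1,0,0), not the
  # nearest face point (1,0.5,0.5) -> sqrt(2^2 + 0.5^2 + 0.5^2)
  u <- array(FALSE, c(4, 4, 4)); u[1, 1, 1] <- TRUE
  expect_equal(tumorToLandmarkDistance(u, c(3, 0.5, 0.5), sp), sqrt(4.5))
  expect_error(tumorToLandmarkDistance(array(FALSE, c(2, 2, 2)), a, sp),
               "empty")
  expect_error(tumorToLandmarkDistance(u, c(1, NA, 0), sp))
})

test_that("distances are invariant to whole-voxel translations", {
  sp <- c(1, 1, 1)
  a <- randomMask(c(6, 6, 6), 0.2, 11)
  b <- randomMask(c(6, 6, 6), 0.2, 12)
  d0 <- tumorToLandmarkDistance(a, b, sp)
  A <- array(FALSE, c(9, 9, 9)); A[3:8, 2:7, 4:9] <- a
  B <- array(FALSE, c(9, 9, 9)); B[3:8, 2:7, 4:9] <- b
  expect_equal(tumorToLandmarkDistance(A, B, sp), d0)
})

test_that("breast volume counts exactly the five breast tissues in the box", {
  ph <- generatePhantom(miniConfig(), nippleTruth = FALSE)
  box <- buildBreastBox(ph$map, "left", midline = 0)
  bv <- breastVolume(ph$map, box)
  b <- box@bounds
  sub <- voxels(ph$map)[b[1, 1]:b[2, 1], b[1, 2]:b[2, 2], b[1, 3]:b[2, 3]]
  brute <- sum(sub %in% c(1L, 2L, 3L, 4L, 6L)) * prod(spacing(ph$map))
  expect_equal(as.numeric(bv), brute)
  # a 1-voxel all-chest box yields zero with a flag
  cbox <- methods::new("BreastBox", side = "left",
                       bounds = rbind(lo = c(1L, dim(ph$map)[2], 1L),
                                      hi = c(1L, dim(ph$map)[2], 1L)),
                       boundsMM = rbind(lo = c(0, 0, 0), hi = c(1, 1, 1)),
                       keyPoints = list(), corrected = logical(6),
                       fallback = FALSE)
  bv0 <- breastVolume(ph$map, cbox)
  expect_equal(as.numeric(bv0), 0)
  expect_true(attr(bv0, "empty"))
})

test_that("the metrics report ties whole-tumor and dominant-mass scopes together", {
  ph <- presetPhantom("unifocal_small")
  nip <- locateNipple(ph$map, "left", midline = 0)
  box <- buildBreastBox(ph$map, "left", midline = 0)
  rep <- tumorMetricsReport(ph$map, "left", nip, box, midline = 0)
  expect_identical(rep$nComponents, 1L)
  expect_identical(rep$wholeTumor, rep$dominantMass)
  expect_equal(rep$wholeTumor$longestDimensionMM,
               max(rep$wholeTumor$extentsMM))
  expect_equal(rep$wholeTumor$boundingBoxVolumeMM3,
               prod(rep$wholeTumor$extentsMM))
  expect_gte(rep$wholeTumor$boundingBoxVolumeMM3, rep$tumorVolumeMM3)
  expect_true(rep$tumorToBreastRatio > 0 && rep$tumorToBreastRatio < 1)
  expect_true(all(unlist(rep$distancesMM) >= 0))

  phm <- presetPhantom("multifocal_far")
  nip2 <- locateNipple(phm$map, "left", midline = 0)
  box2 <- buildBreastBox(phm$map, "left", midline = 0)
  rep2 <- tumorMetricsReport(phm$map, "left", nip2, box2, midline = 0)
  expect_identical(rep2$nComponents, 2L)
  expect_lt(rep2$dominantMass$longestDimensionMM,
            rep2$wholeTumor$longestDimensionMM)
  # tumor volume is additive over components
  tum <- tissueMask(phm$map, "tumor")
  lab <- connectedComponents(tum)
  perComp <- vapply(seq_len(attr(lab, "nComponents")), function(id)
    tumorVolume(lab == id, spacing(phm$map)), numeric(1))
  expect_equal(sum(perComp), rep2$wholeTumor$volumeMM3)
})
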