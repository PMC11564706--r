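test_that("corner-shifted masks place voxel corners at sample centers", {
  sp <- c(1, 1, 1)
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  sh <- cornerShiftedMask(one, sp)
  expect_identical(dim(sh$mask), dim(one) + 1L)
  expect_identical(sum(sh$mask), 8L)
  expect_equal(sh$origin, c(-0.5, -0.5, -0.5))
  rod <- array(FALSE, c(3, 3, 4)); rod[2, 2, 2:3] <- TRUE
  expect_identical(sum(cornerShiftedMask(rod, sp)$mask), 12L)  # 2x2x3 block
  # corner-touching voxels share exactly one corner sample
  a <- array(FALSE, c(3, 3, 3)); a[1, 1, 1] <- TRUE
  b <- array(FALSE, c(3, 3, 3)); b[2, 2, 2] <- TRUE
  expect_identical(sum(cornerShiftedMask(a, sp)$mask &
                       cornerShiftedMask(b, sp)$mask), 1L)
  expect_error(cornerShiftedMask(array(FALSE, c(2, 2, 2)), sp), "empty")
})

test_that("extracted surfaces are watertight with exact enclosed volume", {
  sp <- c(1, 1, 1)
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  sh <- cornerShiftedMask(one, sp)
  mesh <- extractSurface(sh$mask, sp, sh$origin)
  expect_equal(meshVolume(mesh), 1)
  expect_equal(sort(unique(as.vector(mesh@vertices))), c(1, 2))
  sph <- sphereMask(10, c(26, 26, 26))
  shs <- cornerShiftedMask(sph, sp)
  ms <- extractSurface(shs$mask, sp, shs$origin)
  # enclosed volume equals the voxel volume exactly, within 5% of analytic
  expect_equal(meshVolume(ms), sum(sph))
  expect_lt(abs(meshVolume(ms) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000),
            0.05)
  # watertight: every undirected edge is shared by exactly two faces
  e <- rbind(ms@faces[, 1:2], ms@faces[, 2:3], ms@faces[, c(3, 1)])
  ek <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_true(all(table(ek) == 2L))
  # unit outward normals
  expect_equal(sqrt(rowSums(ms@normals^2)), rep(1, nrow(ms@normals)))
  ctr <- colMeans(ms@vertices)
  d0 <- sqrt(rowSums(sweep(ms@vertices, 2, ctr)^2))
  d1 <- sqrt(rowSums(sweep(ms@vertices + 0.1 * ms@normals, 2, ctr)^2))
  expect_true(all(d1 > d0))  # outward on a convex shape
  expect_error(extractSurface(array(TRUE, c(3, 3, 3)), sp), "complement")
})

test_that("margin hulls contain all tumor voxel corners exactly", {
  sp <- c(1, 1, 1)
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  h0 <- buildHull(one, sp, 0)
  expect_lt(abs(h0@volume - 1), 0.1)
  expect_true(all(hullContains(h0, maskCorners(one, sp))))
  cub <- array(FALSE, c(12, 12, 12)); cub[3:9, 4:8, 2:11] <- TRUE
  corners <- maskCorners(cub, sp)
  for (m in c(0, 5, 10, 20)) {
    h <- buildHull(cub, sp, m)
    expect_true(all(hullContains(h, corners)))
    expect_gte(minBoundaryDistance(h, corners), m - sqrt(3))
  }
  expect_error(buildHull(one, sp, 25), "marginMM")
  expect_error(buildHull(one, sp, -1), "marginMM")
})

test_that("hull volume grows strictly with the margin", {
  sph <- sphereMask(6, c(18, 18, 18))
  vols <- vapply(c(0, 2, 5, 10, 15, 20), function(m)
    buildHull(sph, c(1, 1, 1), m)@volume, numeric(1))
  expect_true(all(diff(vols) > 0))
})

test_that("offset-sphere hull volume matches the analytic ball", {
  sph <- sphereMask(10, c(30, 30, 30))
  h <- buildHull(sph, c(1, 1, 1), 10)
  target <- 4 / 3 * pi * 20^3
  expect_lt(abs(h@volume - target) / target, 0.1)
})

test_that("unicentric hulls treat all foci as one point set", {
  ph <- presetPhantom("multifocal_far", nippleTruth = FALSE)
  sp <- spacing(ph$map)
  tum <- tissueMask(ph$map, "tumor")
  uh <- unicentricHull(tum, sp, 5)
  expect_identical(uh@components, c(1L, 2L))
  mh <- multicentricHulls(tum, sp, 5)
  expect_identical(length(mh), 2L)
  # bridging hull is larger than the separate hulls combined
  expect_gt(uh@volume, sum(vapply(mh, function(h) h@volume, numeric(1))))
  # unifocal: multicentric output equals the unicentric hull
  ph1 <- presetPhantom("unifocal_small", nippleTruth = FALSE)
  t1 <- tissueMask(ph1$map, "tumor")
  m1 <- multicentricHulls(t1, sp, 5)
  u1 <- unicentricHull(t1, sp, 5)
  expect_identical(length(m1), 1L)
  expect_equal(sort(as.vector(m1[[1]]@vertices)),
               sort(as.vector(u1@vertices)))
})

test_that("overlapping multicentric hulls merge to a fixed point", {
  ph <- presetPhantom("multifocal_near", nippleTruth = FALSE)
  sp <- spacing(ph$map)
  tum <- tissueMask(ph$map, "tumor")
  sep <- multicentricHulls(tum, sp, 1)
  expect_identical(length(sep), 2L)
  expect_identical(lapply(sep, function(h) h@components),
                   list(1L, 2L))
  merged <- multicentricHulls(tum, sp, 5)
  expect_identical(length(merged), 1L)
  expect_identical(merged[[1]]@components, c(1L, 2L))
  # merged hull equals the unicentric hull of the union point set
  u <- unicentricHull(tum, sp, 5)
  expect_equal(merged[[1]]@volume, u@volume)
  expect_equal(sort(as.vector(merged[[1]]@vertices)),
               sort(as.vector(u@vertices)))
  # all corners of both foci inside the merged hull
  expect_true(all(hullContains(merged[[1]], maskCorners(tum, sp))))
})

test_that("hull voxelization recovers compact masks", {
  sp <- c(1, 1, 1)
  cub <- array(FALSE, c(10, 10, 10)); cub[3:8, 3:8, 3:8] <- TRUE
  attr(cub, "spacing") <- sp
  h <- buildHull(cub, sp, 0)
  vox <- voxelizeHull(h, dim(cub), sp)
  expect_gte(sum(vox & cub) / sum(cub), 0.99)
  expect_gte(as.numeric(diceCoefficient(vox, cub)), 0.9)
  # convex-hull corner bumps shrink with object size; a 20 mm ball is
  # representative of the tumors the pipeline targets
  s <- sphereMask(10, c(28, 28, 28))
  hs <- buildHull(s, sp, 0)
  vs <- voxelizeHull(hs, dim(s), sp)
  expect_gte(as.numeric(diceCoefficient(vs, s)), 0.9)
  # voxelization of a margin hull on the map grid stays inside the grid
  ph <- presetPhantom("unifocal_small", nippleTruth = FALSE)
  hp <- unicentricHull(tissueMask(ph$map, "tumor"), spacing(ph$map), 10)
  vp <- voxelizeHull(hp, ph$map)
  expect_identical(dim(vp), dim(ph$map))
  expect_gt(sum(vp), sum(tissueMask(ph$map, "tumor")))
})
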