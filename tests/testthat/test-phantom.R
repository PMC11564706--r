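test_that("phantom generation is deterministic", {
  cfg <- miniConfig(jitterMM = 0.5)
  a <- generatePhantom(cfg, nippleTruth = FALSE)
  b <- generatePhantom(cfg, nippleTruth = FALSE)
  expect_identical(voxels(a$map), voxels(b$map))
  # different seed changes a jittered surface
  cfg2 <- miniConfig(jitterMM = 0.5, seed = 2L)
  c2 <- generatePhantom(cfg2, nippleTruth = FALSE)
  expect_false(identical(voxels(a$map), voxels(c2$map)))
})

test_that("voxelized tumor volume approaches the analytic sphere volume", {
  ph <- generatePhantom(miniConfig(), nippleTruth = FALSE)
  v <- tumorVolume(tissueMask(ph$map, "tumor"), spacing(ph$map))
  truth <- ph$truth$sides$left$tumors[[1]]$volumeMM3
  expect_equal(truth, 4 / 3 * pi * 216)
  expect_lt(abs(v - truth) / truth, 0.05)
})

test_that("tissue volumes converge to analytic truth as spacing shrinks", {
  err <- sapply(c(2, 1, 0.5), function(s) {
    ph <- generatePhantom(miniConfig(spacing = s), nippleTruth = FALSE)
    tv <- ph$truth$sides$left$tissueVolumesMM3
    vol <- function(t) tumorVolume(tissueMask(ph$map, t), spacing(ph$map))
    c(total = abs(sum(voxels(ph$map) %in% c(1L, 2L, 3L, 4L, 6L)) *
        prod(spacing(ph$map)) - tv$breastTotal) / tv$breastTotal,
      tumor = abs(vol("tumor") - tv$tumor) / tv$tumor,
      skin = abs(vol("skin") - tv$skin) / tv$skin,
      fibro = abs(vol("fibroglandular") - tv$fibroglandular) /
        tv$fibroglandular)
  })
  # the large compound volume converges monotonically; individual small
  # tissues may benefit from lucky cancellation at a coarse grid, so they
  # are only required to improve from the coarsest to the finest grid
  expect_true(all(diff(err["total", ]) < 0))
  expect_true(all(err[, 3] < pmax(err[, 1], 0.005)))
  expect_true(all(err[, 3] < 0.01))
})

test_that("zero-tumor configurations give empty masks and empty truth", {
  ph <- generatePhantom(miniConfig(tumors = list()), nippleTruth = FALSE)
  expect_false(any(tissueMask(ph$map, "tumor")))
  expect_length(ph$truth$sides$left$tumors, 0)
  expect_null(ph$truth$sides$left$wholeTumor)
})

test_that("invalid tumor placements are config errors", {
  expect_error(miniConfig(tumors = list(list(center = c(10, 20, 10),
                                             semi = 12))),
               "inside the breast")
  expect_error(
    phantomConfig(dim = c(64, 56, 64), spacing = c(1, 1, 1), chestY = 42,
                  breasts = list(breastSpec(
                    side = "left", center = c(32, 42, 32), radius = 28,
                    fibroCenter = c(32, 28.5, 32), fibroSemi = c(9, 13, 9),
                    tumors = list(list(center = c(32, 41, 32), semi = 4))))),
    "config error")
})

test_that("presets encode their advertised multifocal geometry", {
  cfgNear <- phantomSuite("multifocal_near")
  tn <- cfgNear@breasts[[1]]$tumors
  gapNear <- sqrt(sum((tn[[1]]$center - tn[[2]]$center)^2)) -
    tn[[1]]$semi[1] - tn[[2]]$semi[1]
  expect_lt(gapNear, 10)
  cfgFar <- phantomSuite("multifocal_far")
  tf <- cfgFar@breasts[[1]]$tumors
  gapFar <- sqrt(sum((tf[[1]]$center - tf[[2]]$center)^2)) -
    tf[[1]]$semi[1] - tf[[2]]$semi[1]
  expect_gt(gapFar, 2 * 20)
  # bilateral: tumor voxels on both sides of the midline
  ph <- presetPhantom("bilateral", nippleTruth = FALSE)
  tum <- tissueMask(ph$map, "tumor")
  mid <- ph$truth$midlineIndex
  expect_gt(sum(tum[seq_len(mid), , ]), 0)
  expect_gt(sum(tum[(mid + 1):dim(tum)[1], , ]), 0)
})

test_that("analytic distances agree with voxel-corner measurements", {
  ph <- generatePhantom(miniConfig())
  tr <- ph$truth$sides$left
  sp <- spacing(ph$map)
  diag1 <- sqrt(sum(sp^2))
  tum <- tissueMask(ph$map, "tumor")
  dSkin <- tumorToLandmarkDistance(tum, tissueMask(ph$map, "skin"), sp)
  dChest <- tumorToLandmarkDistance(tum, tissueMask(ph$map, "chest"), sp)
  expect_lt(abs(dSkin - tr$tumors[[1]]$toSkinMM), diag1)
  expect_lt(abs(dChest - tr$tumors[[1]]$toChestMM), diag1)
})

test_that("every voxel carries exactly one label", {
  ph <- generatePhantom(miniConfig(), nippleTruth = FALSE)
  labs <- sort(unique(as.vector(voxels(ph$map))))
  expect_true(all(labs %in% schema(ph$map)@labels))
  counts <- table(voxels(ph$map))
  expect_equal(as.numeric(sum(counts)), prod(dim(ph$map)))
})
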