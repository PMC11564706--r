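test_that("Dice matches hand-computed overlap counts", {
  a <- array(FALSE, c(2, 2, 1)); a[1:2] <- TRUE
  b <- array(FALSE, c(2, 2, 1)); b[2:3] <- TRUE
  expect_equal(as.numeric(diceCoefficient(a, b)), 0.5)
  expect_equal(overlapCounts(a, b), c(TP = 1, FP = 1, FN = 1))
  expect_equal(as.numeric(diceCoefficient(a, a)), 1)
  c2 <- array(FALSE, c(2, 2, 1)); c2[4] <- TRUE
  expect_equal(as.numeric(diceCoefficient(a, c2)), 0)
  e <- array(FALSE, c(2, 2, 1))
  de <- diceCoefficient(e, e)
  expect_equal(as.numeric(de), 1)
  expect_true(attr(de, "bothEmpty"))
  expect_error(diceCoefficient(a, array(FALSE, c(3, 2, 1))), "grid")
})

test_that("boundary voxels follow the face-neighbour rule", {
  m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
  expect_equal(boundaryVoxels(m, c(1, 1, 1)),
               matrix(c(1.5, 1.5, 1.5), 1), ignore_attr = TRUE)
  solid <- array(TRUE, c(5, 5, 5))
  solid[1, 1, 1] <- TRUE
  block <- array(FALSE, c(5, 5, 5)); block[2:4, 2:4, 2:4] <- TRUE
  expect_identical(nrow(boundaryVoxels(block, c(1, 1, 1))), 26L)
  sheet <- array(FALSE, c(4, 4, 1)); sheet[, , 1] <- TRUE
  expect_identical(nrow(boundaryVoxels(sheet, c(1, 1, 1))), 16L)
  # image border counts as outside
  full <- array(TRUE, c(3, 3, 3))
  expect_identical(nrow(boundaryVoxels(full, c(1, 1, 1))), 26L)
})

test_that("Hausdorff distance matches its definition and is symmetric", {
  a <- array(FALSE, c(4, 4, 6)); a[1, 1, 1] <- TRUE
  b <- array(FALSE, c(4, 4, 6)); b[1, 1, 1] <- TRUE; b[1, 1, 4] <- TRUE
  expect_equal(hausdorffDistance(a, b, c(1, 1, 1)), 3)
  expect_equal(hausdorffDistance(a, a, c(1, 1, 1)), 0)
  for (s in 1:5) {
    x <- randomMask(c(8, 8, 8), 0.1, s)
    y <- randomMask(c(8, 8, 8), 0.1, s + 100)
    expect_identical(hausdorffDistance(x, y, c(1, 1, 1)),
                     hausdorffDistance(y, x, c(1, 1, 1)))
  }
})

test_that("evaluation metrics equal brute-force oracles on random grids", {
  sp <- c(1, 1, 1)
  for (s in 1:20) {
    a <- randomMask(c(6, 6, 6), 0.15, s)
    b <- randomMask(c(6, 6, 6), 0.15, s + 1000)
    expect_identical(as.numeric(diceCoefficient(a, b)), oracleDice(a, b))
    expect_identical(hausdorffDistance(a, b, sp), oracleHausdorff(a, b, sp))
    expect_identical(tumorToLandmarkDistance(a, b, sp),
                     oracleCornerDistance(a, b, sp))
  }
  # anisotropic spacing
  spA <- c(0.5, 1, 2)
  a <- randomMask(c(6, 6, 6), 0.2, 7)
  b <- randomMask(c(6, 6, 6), 0.2, 8)
  expect_identical(hausdorffDistance(a, b, spA), oracleHausdorff(a, b, spA))
  expect_identical(tumorToLandmarkDistance(a, b, spA),
                   oracleCornerDistance(a, b, spA))
})

test_that("Dice is symmetric and translation invariant", {
  for (s in 1:5) {
    a <- randomMask(c(8, 8, 8), 0.2, s)
    b <- randomMask(c(8, 8, 8), 0.2, s + 50)
    expect_identical(diceCoefficient(a, b), diceCoefficient(b, a))
    A <- array(FALSE, c(10, 10, 10)); A[2:9, 2:9, 2:9] <- a
    B <- array(FALSE, c(10, 10, 10)); B[2:9, 2:9, 2:9] <- b
    expect_identical(as.numeric(diceCoefficient(A, B)),
                     as.numeric(diceCoefficient(a, b)))
  }
})

test_that("reader-agreement statistics reproduce their closed forms", {
  t1 <- AgreementTable(a = 64, b = 10, c = 9, d = 7)
  expect_identical(attr(concordance(t1), "rounded"), 79)
  expect_equal(round(gwetAC1(t1), 2), 0.70)
  t2 <- AgreementTable(a = 80, b = 3, c = 3, d = 0)
  expect_identical(attr(concordance(t2), "rounded"), 93)
  expect_equal(round(gwetAC1(t2), 2), 0.93)
  # perfect agreement
  t3 <- AgreementTable(a = 10, b = 0, c = 0, d = 5)
  expect_equal(as.numeric(concordance(t3)), 100)
  expect_equal(gwetAC1(t3), 1)
  # AC1 depends on b + c only, not the split
  t4 <- AgreementTable(a = 64, b = 19, c = 0, d = 7)
  expect_equal(gwetAC1(t4), gwetAC1(t1))
  # monotone increasing in a with d, n - a - d fixed
  ac <- vapply(60:70, function(a)
    gwetAC1(AgreementTable(a = a, b = 90 - a - 7, c = 0, d = 7)),
    numeric(1))
  expect_true(all(diff(ac) > 0))
  expect_error(AgreementTable(a = -1, b = 0, c = 0, d = 1))
})

test_that("Clopper-Pearson lower bound matches an independent binomial oracle", {
  expect_identical(exactBinomialLowerBound(0, 50), 0)
  expect_equal(exactBinomialLowerBound(10, 10, 0.05), 0.05^(1 / 10))
  # oracle: bisect P(X >= x | p) = alpha using the binomial pmf directly
  oracleLower <- function(x, n, alpha) {
    f <- function(p) sum(dbinom(x:n, n, p)) - alpha
    uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  for (case in list(c(66, 88), c(5, 20), c(88, 88))) {
    x <- case[1]; n <- case[2]
    if (x < n)
      expect_equal(exactBinomialLowerBound(x, n, 0.05),
                   oracleLower(x, n, 0.05), tolerance = 1e-9)
  }
  # monotone in x, decreasing in alpha
  lows <- vapply(1:20, exactBinomialLowerBound, numeric(1), n = 20)
  expect_true(all(diff(lows) > 0))
  expect_gt(exactBinomialLowerBound(15, 20, 0.1),
            exactBinomialLowerBound(15, 20, 0.05))
  expect_error(exactBinomialLowerBound(5, 4))
})
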