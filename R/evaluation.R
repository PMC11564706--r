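#' Dice overlap coefficient of two binary masks
#'
#' `2TP / (2TP + FP + FN)` over voxels. Two empty masks are defined to have
#' Dice 1.0, flagged via the `"bothEmpty"` attribute.
#'
#' @param pred,ref logical 3D arrays on the same grid.
#' @return Dice coefficient in [0, 1].
#' @examples
#' a <- array(FALSE, c(2, 2, 1)); a[1:2] <- TRUE
#' b <- array(FALSE, c(2, 2, 1)); b[2:3] <- TRUE
#' diceCoefficient(a, b)  # overlap 1 of 2+2 -> 0.5
#' @export
diceCoefficient <- function(pred, ref) {
  if (!identical(dim(pred), dim(ref)))
    stop("masks must share the same grid", call. = FALSE)
  tp <- sum(pred & ref)
  fp <- sum(pred & !ref)
  fn <- sum(!pred & ref)
  if (tp + fp + fn == 0) return(structure(1.0, bothEmpty = TRUE))
  2 * tp / (2 * tp + fp + fn)
}

#' Overlap counts (TP/FP/FN) of two binary masks
#' @inheritParams diceCoefficient
#' @return named numeric vector with elements `TP`, `FP`, `FN`.
#' @export
overlapCounts <- function(pred, ref) {
  if (!identical(dim(pred), dim(ref)))
    stop("masks must share the same grid", call. = FALSE)
  c(TP = sum(pred & ref), FP = sum(pred & !ref), FN = sum(!pred & ref))
}

#' Boundary voxels of a binary mask
#'
#' A voxel is boundary when at least one of its six face neighbours is
#' outside the mask; the image border counts as outside.
#'
#' @param mask non-empty logical 3D array.
#' @param spacing numeric(3) voxel spacing in mm.
#' @return numeric matrix (n x 3) of boundary-voxel centers in mm.
#' @export
boundaryVoxels <- function(mask, spacing = attr(mask, "spacing")) {
  bm <- boundaryMask(mask)
  maskCenters(bm, spacing)
}

# logical mask of boundary voxels (face-neighbour rule, border = outside)
boundaryMask <- function(mask) {
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  d <- dim(mask)
  interior <- mask
  shift <- function(m, axis, by) {
    out <- array(FALSE, dim(m))
    n <- dim(m)[axis]
    if (abs(by) > n - 1) return(out)
    idx <- lapply(dim(m), seq_len)
    idxTo <- idx
    if (by >= 0) {
      idxTo[[axis]] <- seq_len(n - by) + by
      idx[[axis]] <- seq_len(n - by)
    } else {
      idxTo[[axis]] <- seq_len(n + by)
      idx[[axis]] <- seq_len(n + by) - by
    }
    out[idxTo[[1]], idxTo[[2]], idxTo[[3]]] <-
      m[idx[[1]], idx[[2]], idx[[3]]]
    out
  }
  for (axis in 1:3) {
    interior <- interior & shift(mask, axis, 1L) & shift(mask, axis, -1L)
  }
  mask & !interior
}

#' Hausdorff distance between two masks' boundaries
#'
#' The symmetric Hausdorff distance
#' `max(sup_x d(x, Y), sup_y d(X, y))` over the boundary-voxel centers
#' (Euclidean, mm) of the two masks, computed with exact KD-tree
#' nearest-neighbour queries.
#'
#' @param pred,ref non-empty logical 3D arrays on the same grid.
#' @param spacing numeric(3) voxel spacing in mm.
#' @return Hausdorff distance in mm.
#' @export
hausdorffDistance <- function(pred, ref, spacing = attr(pred, "spacing")) {
  if (!identical(dim(pred), dim(ref)))
    stop("masks must share the same grid", call. = FALSE)
  X <- boundaryVoxels(pred, spacing)
  Y <- boundaryVoxels(ref, spacing)
  dXY <- max(RANN::nn2(Y, query = X, k = 1)$nn.dists)
  dYX <- max(RANN::nn2(X, query = Y, k = 1)$nn.dists)
  max(dXY, dYX)
}

agreementN <- function(t) t@a + t@b + t@c + t@d

#' Percent agreement of two raters
#'
#' `100 (a + d) / n` for an [AgreementTable-class]; the value rounded to the
#' nearest integer percent is attached as attribute `"rounded"`.
#'
#' @param t an [AgreementTable-class].
#' @return exact concordance in percent.
#' @export
concordance <- function(t) {
  n <- agreementN(t)
  if (n <= 0) stop("empty agreement table", call. = FALSE)
  p <- 100 * (t@a + t@d) / n
  structure(p, rounded = round(p))
}

#' Gwet's AC1 chance-corrected agreement
#'
#' For two raters and two categories: `AC1 = (pa - pe) / (1 - pe)` with
#' `pa = (a + d)/n`, `pi = (2a + b + c)/(2n)` and `pe = 2 pi (1 - pi)`.
#' AC1 depends on the discordant total `b + c` only, not on its split, and
#' is robust to prevalence imbalance (unlike Cohen's kappa).
#'
#' @param t an [AgreementTable-class].
#' @return AC1 in [-1, 1].
#' @export
gwetAC1 <- function(t) {
  n <- agreementN(t)
  if (n <= 0) stop("empty agreement table", call. = FALSE)
  pa <- (t@a + t@d) / n
  pihat <- (2 * t@a + t@b + t@c) / (2 * n)
  pe <- 2 * pihat * (1 - pihat)
  if (abs(1 - pe) < .Machine$double.eps)
    stop("degenerate table: chance agreement is 1", call. = FALSE)
  (pa - pe) / (1 - pe)
}

#' One-sided Clopper-Pearson exact lower confidence bound
#'
#' Exact binomial lower bound via the beta-quantile formulation:
#' `qbeta(alpha, x, n - x + 1)`, with 0 when `x = 0`.
#'
#' @param x number of successes, `0 <= x <= n`.
#' @param n number of trials.
#' @param alpha one-sided level in (0, 1); default 0.05.
#' @return lower confidence bound on the success proportion.
#' @examples
#' exactBinomialLowerBound(10, 10, 0.05)  # 0.05^(1/10)
#' @export
exactBinomialLowerBound <- function(x, n, alpha = 0.05) {
  if (length(x) != 1 || length(n) != 1 || anyNA(c(x, n, alpha)) ||
      x < 0 || n < 1 || x > n || x != round(x) || n != round(n) ||
      alpha <= 0 || alpha >= 1)
    stop("need 0 <= x <= n (integers) and alpha in (0, 1)", call. = FALSE)
  if (x == 0) return(0)
  qbeta(alpha, x, n - x + 1)
}
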