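# Contour agreement metrics: Dice, Jaccard, percentile Hausdorff distance and
# mean distance to agreement, all computed in physical mm on anisotropic
# grids.  HD and MDA summarise the POOLED bidirectional multiset of boundary
# nearest-neighbour distances, which makes the two metrics mutually
# consistent; the 100th percentile coincides with the classical symmetric
# Hausdorff distance.

checkComparable <- function(a, b) {
  checkSameGeometry(a, b)
  na <- sum(a@voxels); nb <- sum(b@voxels)
  if (na == 0L && nb == 0L)
    .stopClassed("both masks are empty; overlap metrics are undefined",
                 "dilUndefinedMetricError")
  invisible(c(na, nb))
}

#' Dice coefficient of two masks
#'
#' `2 |A n B| / (|A| + |B|)` over voxel counts on a shared grid.  1 means
#' complete overlap; disjoint masks give 0; if exactly one mask is empty the
#' overlap is well-defined as 0.
#'
#' @param a,b [BinaryMask-class] objects on identical geometry
#' @return Dice coefficient in [0, 1]
#' @seealso [jaccardIndex()], [pairMetrics()]
#' @export
diceCoefficient <- function(a, b) {
  cnt <- checkComparable(a, b)
  2 * sum(a@voxels & b@voxels) / (cnt[1] + cnt[2])
}

#' Jaccard index of two masks
#'
#' `|A n B| / |A u B|`.  Related to Dice by `dice = 2 j / (1 + j)`.
#'
#' @inheritParams diceCoefficient
#' @return Jaccard index in [0, 1]
#' @export
jaccardIndex <- function(a, b) {
  checkComparable(a, b)
  sum(a@voxels & b@voxels) / sum(a@voxels | b@voxels)
}

#' Boundary voxel centres of a mask
#'
#' The boundary is the set of true voxels with at least one false
#' face-neighbour (6-connectivity); the grid edge counts as exposure.
#' Returned as physical mm coordinates of the voxel centres.
#'
#' @param a a non-empty [BinaryMask-class]
#' @return n x 3 matrix of mm points
#' @export
extractBoundary <- function(a) {
  v <- a@voxels
  if (!any(v))
    .stopClassed("cannot extract the boundary of an empty mask",
                 "dilUndefinedMetricError")
  sh <- dim(v)
  pad <- array(FALSE, dim = sh + 2L)
  pad[2:(sh[1] + 1), 2:(sh[2] + 1), 2:(sh[3] + 1)] <- v
  core <- function(di, dj, dk)
    pad[(2:(sh[1] + 1)) + di, (2:(sh[2] + 1)) + dj, (2:(sh[3] + 1)) + dk]
  interior <- core(-1, 0, 0) & core(1, 0, 0) &
              core(0, -1, 0) & core(0, 1, 0) &
              core(0, 0, -1) & core(0, 0, 1)
  boundary <- v & !interior
  idx <- which(boundary, arr.ind = TRUE)
  indexToPhysical(a@geometry, idx)
}

#' Bidirectional boundary nearest-neighbour distances
#'
#' Computes, for every boundary point of A, the Euclidean mm distance to the
#' nearest boundary point of B, and vice versa, respecting anisotropic voxel
#' spacing.  The search uses a compiled sorted-sweep nearest-neighbour kernel.
#'
#' @inheritParams diceCoefficient
#' @return a [SurfaceDistanceSet-class]
#' @export
surfaceDistances <- function(a, b) {
  checkSameGeometry(a, b)
  if (!any(a@voxels) || !any(b@voxels))
    .stopClassed("surface distances need two non-empty masks",
                 "dilUndefinedMetricError")
  pa <- extractBoundary(a)
  pb <- extractBoundary(b)
  new("SurfaceDistanceSet",
      ab = as.numeric(.nnDistances(pa, pb)),
      ba = as.numeric(.nnDistances(pb, pa)))
}

pooledDistances <- function(s) c(s@ab, s@ba)

#' Percentile Hausdorff distance
#'
#' The q-th percentile (linear interpolation between order statistics, the
#' position `q/100 * (n - 1)` convention) of the pooled bidirectional surface
#' distance multiset.  `q = 100` equals the classical symmetric Hausdorff
#' distance.
#'
#' @param s a [SurfaceDistanceSet-class]
#' @param q percentile in (0, 100]; default 95
#' @return distance in mm
#' @export
hausdorffPercentile <- function(s, q = 95) {
  stopifnot(is(s, "SurfaceDistanceSet"), q > 0, q <= 100)
  unname(quantile(pooledDistances(s), probs = q / 100, type = 7))
}

#' Mean distance to agreement
#'
#' Arithmetic mean of the pooled bidirectional surface distance multiset
#' (also known as the average symmetric surface distance).
#'
#' @param s a [SurfaceDistanceSet-class]
#' @return distance in mm
#' @export
meanDistanceToAgreement <- function(s) {
  stopifnot(is(s, "SurfaceDistanceSet"))
  mean(pooledDistances(s))
}

#' All four agreement metrics for one contour pair
#'
#' Bundles Dice, Jaccard, the q-percentile Hausdorff distance and the mean
#' distance to agreement for a pair of contours on a shared grid.
#'
#' @inheritParams diceCoefficient
#' @param q Hausdorff percentile, default 95
#' @return named list with elements `dice`, `jaccard`, `hd95` (mm), `mda` (mm)
#' @examples
#' g <- ImageGeometry(c(12, 12, 12), c(1, 1, 1))
#' cube <- function(lo, hi) {
#'   v <- array(FALSE, c(12, 12, 12)); v[lo:hi, lo:hi, lo:hi] <- TRUE
#'   BinaryMask(v, g)
#' }
#' pairMetrics(cube(1, 10), cube(2, 9))  # dice 1024/1512, jaccard 0.512
#' @export
pairMetrics <- function(a, b, q = 95) {
  d <- diceCoefficient(a, b)
  j <- jaccardIndex(a, b)
  if (!any(a@voxels) || !any(b@voxels)) {
    hd <- NA_real_; mda <- NA_real_
  } else {
    s <- surfaceDistances(a, b)
    hd <- hausdorffPercentile(s, q)
    mda <- meanDistanceToAgreement(s)
  }
  list(dice = d, jaccard = j, hd95 = hd, mda = mda)
}
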