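# Trilinear / nearest-neighbour resampling of axis-aligned volumes onto a
# reference grid, with an optional rigid transform mapping reference physical
# space into the moving volume's physical space.  Written vectorised over all
# reference voxels; no installed R package provides this for anisotropic 3D
# grids with a physical-space transform.

referenceVoxelCentres <- function(geom) {
  sh <- geom@shape
  idx <- as.matrix(expand.grid(seq_len(sh[1]), seq_len(sh[2]), seq_len(sh[3])))
  indexToPhysical(geom, idx)
}

# continuous 1-based indices -> interpolated values; points outside the moving
# grid receive `fill`
trilinearSample <- function(values, idx, fill) {
  sh <- dim(values)
  inside <- idx[, 1] >= 1 & idx[, 1] <= sh[1] &
            idx[, 2] >= 1 & idx[, 2] <= sh[2] &
            idx[, 3] >= 1 & idx[, 3] <= sh[3]
  out <- rep(fill, nrow(idx))
  if (!any(inside)) return(out)
  p <- idx[inside, , drop = FALSE]
  i0 <- pmin(pmax(floor(p[, 1]), 1), max(sh[1] - 1, 1))
  j0 <- pmin(pmax(floor(p[, 2]), 1), max(sh[2] - 1, 1))
  k0 <- pmin(pmax(floor(p[, 3]), 1), max(sh[3] - 1, 1))
  fx <- if (sh[1] > 1) p[, 1] - i0 else 0
  fy <- if (sh[2] > 1) p[, 2] - j0 else 0
  fz <- if (sh[3] > 1) p[, 3] - k0 else 0
  i1 <- pmin(i0 + 1, sh[1]); j1 <- pmin(j0 + 1, sh[2]); k1 <- pmin(k0 + 1, sh[3])
  nx <- sh[1]; nxy <- sh[1] * sh[2]
  lin <- function(i, j, k) i + (j - 1) * nx + (k - 1) * nxy
  v <- values[lin(i0, j0, k0)] * (1 - fx) * (1 - fy) * (1 - fz) +
       values[lin(i1, j0, k0)] * fx       * (1 - fy) * (1 - fz) +
       values[lin(i0, j1, k0)] * (1 - fx) * fy       * (1 - fz) +
       values[lin(i1, j1, k0)] * fx       * fy       * (1 - fz) +
       values[lin(i0, j0, k1)] * (1 - fx) * (1 - fy) * fz +
       values[lin(i1, j0, k1)] * fx       * (1 - fy) * fz +
       values[lin(i0, j1, k1)] * (1 - fx) * fy       * fz +
       values[lin(i1, j1, k1)] * fx       * fy       * fz
  out[inside] <- v
  out
}

nearestSample <- function(values, idx, fill) {
  sh <- dim(values)
  i <- round(idx[, 1]); j <- round(idx[, 2]); k <- round(idx[, 3])
  inside <- i >= 1 & i <= sh[1] & j >= 1 & j <= sh[2] & k >= 1 & k <= sh[3]
  out <- rep(fill, nrow(idx))
  out[inside] <- values[cbind(i[inside], j[inside], k[inside])]
  out
}

#' Resample a volume onto a reference grid
#'
#' Each output voxel takes the moving volume's interpolated value at the
#' transformed physical position of that voxel's centre: the rigid transform
#' maps reference physical space into the moving volume's physical space
#' (default identity, appropriate for already co-registered series).  Points
#' landing outside the moving grid receive `fill`.
#'
#' @param moving a [ScalarVolume-class]
#' @param reference target [ImageGeometry-class]
#' @param transform a [RigidTransform-class]; default identity
#' @param interpolation `"linear"` (trilinear) or `"nearest"`
#' @param fill value assigned outside the moving volume's support
#' @return a [ScalarVolume-class] on `reference`, keeping modality and units
#' @examples
#' g <- ImageGeometry(c(8, 8, 4), c(2, 2, 3))
#' v <- ScalarVolume(array(rnorm(256), c(8, 8, 4)), g)
#' fine <- ImageGeometry(c(32, 32, 4), c(0.5, 0.5, 3))
#' r <- resampleToReference(v, fine)
#' @export
resampleToReference <- function(moving, reference,
                                transform = RigidTransform(),
                                interpolation = c("linear", "nearest"),
                                fill = 0) {
  interpolation <- match.arg(interpolation)
  stopifnot(is(moving, "ScalarVolume"), is(reference, "ImageGeometry"),
            is(transform, "RigidTransform"))
  pts <- applyTransform(transform, referenceVoxelCentres(reference))
  idx <- physicalToIndex(moving@geometry, pts)
  vals <- if (interpolation == "linear")
    trilinearSample(moving@values, idx, fill)
  else
    nearestSample(moving@values, idx, fill)
  ScalarVolume(array(vals, dim = reference@shape), reference,
               modality = moving@modality, units = moving@units)
}

#' Resample a binary mask onto a reference grid
#'
#' The 0/1 field is interpolated trilinearly and thresholded at 0.5
#' (values >= 0.5 become true), the standard majority rule.
#'
#' @param moving a [BinaryMask-class]
#' @param reference target [ImageGeometry-class]
#' @param transform a [RigidTransform-class]; default identity
#' @return a [BinaryMask-class] on `reference`, keeping the label
#' @export
resampleMask <- function(moving, reference, transform = RigidTransform()) {
  stopifnot(is(moving, "BinaryMask"), is(reference, "ImageGeometry"))
  field <- ScalarVolume(array(as.numeric(moving@voxels), dim = dim(moving@voxels)),
                        moving@geometry)
  res <- resampleToReference(field, reference, transform,
                             interpolation = "linear", fill = 0)
  BinaryMask(array(res@values >= 0.5, dim = reference@shape), reference,
             label = moving@label)
}
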