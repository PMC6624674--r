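#' @rdname ImageGeometry-accessors
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))
#' @rdname ImageGeometry-accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))
#' @rdname ImageGeometry-accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname ImageGeometry-accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))
#' @rdname ImageGeometry-accessors
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))
#' @rdname ImageGeometry-accessors
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))
#' @rdname ImageGeometry-accessors
#' @export
setGeneric("maskVoxels", function(x) standardGeneric("maskVoxels"))
#' @rdname ImageGeometry-accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
#' @rdname ImageGeometry-accessors
#' @export
setGeneric("maskLabel", function(x) standardGeneric("maskLabel"))

#' Accessors for grids, volumes and masks
#'
#' `gridShape`, `gridSpacing` and `gridOrigin` return the grid descriptor
#' components; `geometry` extracts the [ImageGeometry-class] from a volume or
#' mask; `voxelVolume` returns the volume of one voxel in mm^3; `voxelValues`
#' and `maskVoxels` return the underlying arrays; `modality` and `maskLabel`
#' return the tags.
#'
#' @param x an ImageGeometry, ScalarVolume or BinaryMask
#' @return vectors, arrays or scalars as described above
#' @name ImageGeometry-accessors
NULL

#' @rdname ImageGeometry-accessors
setMethod("gridShape", "ImageGeometry", function(x) x@shape)
#' @rdname ImageGeometry-accessors
setMethod("gridSpacing", "ImageGeometry", function(x) x@spacing)
#' @rdname ImageGeometry-accessors
setMethod("gridOrigin", "ImageGeometry", function(x) x@origin)
#' @rdname ImageGeometry-accessors
setMethod("voxelVolume", "ImageGeometry", function(x) prod(x@spacing))

#' @rdname ImageGeometry-accessors
setMethod("geometry", "ScalarVolume", function(x) x@geometry)
#' @rdname ImageGeometry-accessors
setMethod("geometry", "BinaryMask", function(x) x@geometry)
#' @rdname ImageGeometry-accessors
setMethod("gridShape", "ScalarVolume", function(x) x@geometry@shape)
#' @rdname ImageGeometry-accessors
setMethod("gridShape", "BinaryMask", function(x) x@geometry@shape)
#' @rdname ImageGeometry-accessors
setMethod("gridSpacing", "ScalarVolume", function(x) x@geometry@spacing)
#' @rdname ImageGeometry-accessors
setMethod("gridSpacing", "BinaryMask", function(x) x@geometry@spacing)
#' @rdname ImageGeometry-accessors
setMethod("voxelValues", "ScalarVolume", function(x) x@values)
#' @rdname ImageGeometry-accessors
setMethod("maskVoxels", "BinaryMask", function(x) x@voxels)
#' @rdname ImageGeometry-accessors
setMethod("modality", "ScalarVolume", function(x) x@modality)
#' @rdname ImageGeometry-accessors
setMethod("maskLabel", "BinaryMask", function(x) x@label)

#' Map voxel indices to physical coordinates and back
#'
#' Voxel indices are 1-based (R convention); the physical coordinate of a
#' voxel is the position of its centre in mm.  `physicalToIndex` returns
#' continuous (fractional) 1-based indices; it does not round.
#'
#' @param geom an [ImageGeometry-class]
#' @param ijk n x 3 matrix (or length-3 vector) of 1-based voxel indices
#' @param xyz n x 3 matrix (or length-3 vector) of physical mm coordinates
#' @return an n x 3 numeric matrix
#' @examples
#' g <- ImageGeometry(c(10, 10, 4), c(0.5, 0.5, 3.0), origin = c(1, 2, 3))
#' indexToPhysical(g, c(1, 1, 1))   # equals the origin
#' @export
indexToPhysical <- function(geom, ijk) {
  ijk <- rbindAsMatrix(ijk)
  sweep(sweep(ijk - 1, 2, geom@spacing, "*"), 2, geom@origin, "+")
}

#' @rdname indexToPhysical
#' @export
physicalToIndex <- function(geom, xyz) {
  xyz <- rbindAsMatrix(xyz)
  sweep(sweep(xyz, 2, geom@origin, "-"), 2, geom@spacing, "/") + 1
}

rbindAsMatrix <- function(x) {
  if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 3)
}

sameGeometry <- function(a, b, tol = 1e-9) {
  identical(a@shape, b@shape) &&
    all(abs(a@spacing - b@spacing) <= tol) &&
    all(abs(a@origin - b@origin) <= tol)
}

checkSameGeometry <- function(a, b) {
  ga <- if (is(a, "ImageGeometry")) a else a@geometry
  gb <- if (is(b, "ImageGeometry")) b else b@geometry
  if (!sameGeometry(ga, gb))
    .stopClassed("inputs are on different image geometries", "dilGeometryError")
  invisible(TRUE)
}

#' Mask volume in millilitres
#'
#' True-voxel count times voxel volume (mm^3) divided by 1000.  An empty mask
#' has volume 0.
#'
#' @param x a [BinaryMask-class]
#' @return volume in mL
#' @export
setGeneric("volumeMl", function(x) standardGeneric("volumeMl"))

#' @rdname volumeMl
setMethod("volumeMl", "BinaryMask", function(x) {
  sum(x@voxels) * prod(x@geometry@spacing) / 1000
})

#' Rotation matrix of a rigid transform
#'
#' @param transform a [RigidTransform-class]
#' @return 3 x 3 rotation matrix (Rz Ry Rx Euler composition)
#' @export
rotationMatrix <- function(transform) {
  a <- transform@rotation
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Apply a rigid transform to physical points
#'
#' @param transform a [RigidTransform-class]
#' @param xyz n x 3 matrix (or length-3 vector) of mm points
#' @return n x 3 matrix of transformed points
#' @export
applyTransform <- function(transform, xyz) {
  xyz <- rbindAsMatrix(xyz)
  sweep(xyz %*% t(rotationMatrix(transform)), 2, transform@translation, "+")
}
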