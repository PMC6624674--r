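#' @useDynLib DILagree, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats cor quantile rnorm runif rlnorm rexp sd qnorm pnorm qexp
#' @importFrom utils read.csv write.csv
NULL

.stopClassed <- function(msg, class) {
  stop(structure(
    class = c(class, "dilError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Axis-aligned 3D image grid
#'
#' Describes the sampling grid shared by scalar volumes and binary masks:
#' the array dimensions, the physical voxel spacing in millimetres, and the
#' physical position (mm) of the centre of voxel index (1,1,1).  Physical
#' coordinates of voxel (i,j,k) are \code{origin + (i-1, j-1, k-1) * spacing},
#' i.e. voxel centres, with all distances in mm.  Only axis-aligned grids are
#' represented; oblique orientations are rejected at the I/O boundary.
#'
#' @slot shape integer vector of length 3, all entries >= 1
#' @slot spacing numeric vector of length 3, strictly positive, in mm
#' @slot origin numeric vector of length 3, in mm
#'
#' @seealso [ImageGeometry()], [indexToPhysical()], [voxelVolume()]
#' @export
setClass("ImageGeometry",
  representation(shape = "integer", spacing = "numeric", origin = "numeric"))

setValidity("ImageGeometry", function(object) {
  msgs <- character(0)
  if (length(object@shape) != 3L || any(is.na(object@shape)) || any(object@shape < 1L))
    msgs <- c(msgs, "'shape' must be 3 positive integers")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) || any(object@spacing <= 0))
    msgs <- c(msgs, "'spacing' must be 3 positive mm values")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msgs <- c(msgs, "'origin' must be 3 finite mm values")
  if (length(msgs)) msgs else TRUE
})

#' Construct an ImageGeometry
#'
#' @param shape integer triple (nx, ny, nz)
#' @param spacing positive mm triple
#' @param origin mm triple; physical position of the centre of the first voxel
#' @return an [ImageGeometry-class] object
#' @examples
#' ImageGeometry(c(72, 72, 16), c(0.5, 0.5, 3.0))
#' @export
ImageGeometry <- function(shape, spacing, origin = c(0, 0, 0)) {
  new("ImageGeometry", shape = as.integer(shape), spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' One MR sequence's voxel values on an image grid
#'
#' @slot geometry the [ImageGeometry-class] the values are sampled on
#' @slot values numeric 3D array matching \code{geometry} shape
#' @slot modality one of \code{"T2W"}, \code{"ADC"}, \code{"KTRANS"}, \code{"OTHER"}
#' @slot units free-text unit string (e.g. \code{"1e-6 mm^2/s"}, \code{"1/min"})
#' @export
setClass("ScalarVolume",
  representation(geometry = "ImageGeometry", values = "array",
                 modality = "character", units = "character"))

setValidity("ScalarVolume", function(object) {
  msgs <- character(0)
  if (!identical(dim(object@values), as.integer(object@geometry@shape)))
    msgs <- c(msgs, "value array shape must equal geometry shape")
  if (!object@modality %in% c("T2W", "ADC", "KTRANS", "OTHER"))
    msgs <- c(msgs, "modality must be one of T2W, ADC, KTRANS, OTHER")
  if (object@modality %in% c("ADC", "KTRANS") &&
      any(object@values < 0, na.rm = TRUE))
    msgs <- c(msgs, "ADC and Ktrans values must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ScalarVolume
#'
#' @param values numeric 3D array
#' @param geometry an [ImageGeometry-class]
#' @param modality sequence tag: \code{"T2W"}, \code{"ADC"}, \code{"KTRANS"} or
#'   \code{"OTHER"}
#' @param units free-text units
#' @return a [ScalarVolume-class]
#' @export
ScalarVolume <- function(values, geometry, modality = "OTHER", units = "") {
  storage.mode(values) <- "double"
  new("ScalarVolume", geometry = geometry, values = values,
      modality = modality, units = units)
}

#' A rasterized lesion contour
#'
#' A binary mask on an [ImageGeometry-class]; `label` records the sequence and
#' observer the contour came from (e.g. \code{"T2W/obs1"}).
#'
#' @slot geometry an [ImageGeometry-class]
#' @slot voxels logical 3D array matching the geometry shape
#' @slot label free text
#' @export
setClass("BinaryMask",
  representation(geometry = "ImageGeometry", voxels = "array", label = "character"))

setValidity("BinaryMask", function(object) {
  msgs <- character(0)
  if (!is.logical(object@voxels))
    msgs <- c(msgs, "voxels must be a logical array")
  if (!identical(dim(object@voxels), as.integer(object@geometry@shape)))
    msgs <- c(msgs, "voxel array shape must equal geometry shape")
  if (length(msgs)) msgs else TRUE
})

#' Construct a BinaryMask
#'
#' @param voxels logical (or 0/1 numeric) 3D array
#' @param geometry an [ImageGeometry-class]
#' @param label free-text label (sequence + observer id)
#' @return a [BinaryMask-class]
#' @export
BinaryMask <- function(voxels, geometry, label = "") {
  if (!is.logical(voxels)) {
    v <- array(voxels != 0, dim = dim(voxels))
    voxels <- v
  }
  new("BinaryMask", geometry = geometry, voxels = voxels, label = label)
}

#' Rigid transform between physical spaces
#'
#' Maps a physical point p (mm) to R p + t, where R is the rotation built from
#' three Euler angles applied in x, then y, then z order (R = Rz Ry Rx).  The
#' all-zero transform is the identity.  Used to map reference physical space
#' into the moving volume's physical space during resampling.
#'
#' @slot rotation numeric length-3, Euler angles in radians
#' @slot translation numeric length-3, mm
#' @export
setClass("RigidTransform",
  representation(rotation = "numeric", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  if (length(object@rotation) != 3L || length(object@translation) != 3L ||
      any(!is.finite(c(object@rotation, object@translation))))
    "rotation and translation must be finite numeric triples"
  else TRUE
})

#' Construct a RigidTransform
#'
#' @param rotation Euler angles (radians), length 3; default identity
#' @param translation mm triple; default zero
#' @return a [RigidTransform-class]
#' @examples
#' identityTransform <- RigidTransform()
#' @export
RigidTransform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = as.numeric(rotation),
      translation = as.numeric(translation))
}

#' Bidirectional boundary nearest-neighbour distances
#'
#' Holds the two directed multisets of surface distances between a pair of
#' contours: for every boundary point of A the Euclidean mm distance to the
#' nearest boundary point of B, and vice versa.  The percentile Hausdorff
#' distance and the mean distance to agreement are summaries of the pooled
#' multiset.
#'
#' @slot ab numeric vector, A-to-B nearest distances (mm)
#' @slot ba numeric vector, B-to-A nearest distances (mm)
#' @export
setClass("SurfaceDistanceSet", representation(ab = "numeric", ba = "numeric"))

setValidity("SurfaceDistanceSet", function(object) {
  if (any(object@ab < 0) || any(object@ba < 0))
    "surface distances must be non-negative"
  else if (length(object@ab) == 0L || length(object@ba) == 0L)
    "both directed distance sets must be non-empty"
  else TRUE
})

setMethod("show", "ImageGeometry", function(object) {
  cat(sprintf("ImageGeometry: %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              object@shape[1], object@shape[2], object@shape[3],
              object@spacing[1], object@spacing[2], object@spacing[3],
              object@origin[1], object@origin[2], object@origin[3]))
})

setMethod("show", "ScalarVolume", function(object) {
  rng <- range(object@values)
  cat(sprintf("ScalarVolume [%s]%s: %d x %d x %d voxels, values in [%.4g, %.4g]\n",
              object@modality,
              if (nzchar(object@units)) paste0(" (", object@units, ")") else "",
              dim(object@values)[1], dim(object@values)[2], dim(object@values)[3],
              rng[1], rng[2]))
  show(object@geometry)
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask%s: %d / %d voxels set (%.3f mL)\n",
              if (nzchar(object@label)) paste0(" [", object@label, "]") else "",
              sum(object@voxels), length(object@voxels), volumeMl(object)))
  show(object@geometry)
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform: Euler (%g, %g, %g) rad, translation (%g, %g, %g) mm\n",
              object@rotation[1], object@rotation[2], object@rotation[3],
              object@translation[1], object@translation[2], object@translation[3]))
})

setMethod("show", "SurfaceDistanceSet", function(object) {
  cat(sprintf("SurfaceDistanceSet: %d A->B + %d B->A distances, pooled mean %.3f mm\n",
              length(object@ab), length(object@ba),
              mean(c(object@ab, object@ba))))
})
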