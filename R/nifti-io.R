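#' Read a 3D NIfTI image as a volume or mask
#'
#' Reads a NIfTI-1 file and populates the grid descriptor from the header:
#' spacing from the diagonal of the xform affine, origin from its translation
#' column.  Only strictly axis-aligned affines (off-diagonal rotation below
#' `tol`) are accepted; oblique acquisitions must be resampled upstream.
#' When every stored value is 0 or 1 the image is returned as a
#' [BinaryMask-class] unless `as` forces the interpretation.
#'
#' @param path path to a .nii or .nii.gz file containing a 3D image
#' @param as `"auto"` (mask when values are restricted to \{0,1\}),
#'   `"volume"` or `"mask"`
#' @param modality modality tag attached when a ScalarVolume is returned
#' @param units units string attached when a ScalarVolume is returned
#' @param label label attached when a BinaryMask is returned
#' @param tol tolerance on off-diagonal affine entries
#' @return a [ScalarVolume-class] or [BinaryMask-class]
#' @seealso [writeNiftiVolume()]
#' @export
readNiftiVolume <- function(path, as = c("auto", "volume", "mask"),
                            modality = "OTHER", units = "", label = "",
                            tol = 1e-6) {
  as <- match.arg(as)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    .stopClassed(sprintf("expected a 3D NIfTI image, got %d dimensions: %s",
                         length(dim(arr)), path), "dilFormatError")
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > tol)
    .stopClassed(sprintf("non-axis-aligned affine in %s; only axis-aligned grids are supported",
                         path), "dilOrientationError")
  spacing <- abs(diag(rot))
  geom <- ImageGeometry(dim(arr), spacing, aff[1:3, 4])
  isBinary <- all(arr %in% c(0, 1))
  if (as == "mask" && !isBinary)
    .stopClassed(sprintf("requested a mask but %s has values outside {0,1}", path),
                 "dilFormatError")
  if (as == "mask" || (as == "auto" && isBinary))
    BinaryMask(array(arr != 0, dim = dim(arr)), geom, label = label)
  else
    ScalarVolume(array(as.numeric(arr), dim = dim(arr)), geom,
                 modality = modality, units = units)
}

#' Write a volume or mask to NIfTI
#'
#' Volumes are stored as float32 (the conventional parametric-map precision),
#' masks as uint8.  The geometry is written to both the qform and sform as an
#' axis-aligned affine.
#'
#' @param x a [ScalarVolume-class] or [BinaryMask-class]
#' @param path output .nii or .nii.gz path
#' @return `path`, invisibly
#' @export
writeNiftiVolume <- function(x, path) {
  if (is(x, "BinaryMask")) {
    arr <- array(as.integer(x@voxels), dim = dim(x@voxels))
    geom <- x@geometry
    dt <- "uint8"
  } else if (is(x, "ScalarVolume")) {
    arr <- x@values
    geom <- x@geometry
    dt <- "float"
  } else {
    .stopClassed("writeNiftiVolume needs a ScalarVolume or BinaryMask", "dilFormatError")
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- geom@spacing
  aff <- diag(c(geom@spacing, 1))
  aff[1:3, 4] <- geom@origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}
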