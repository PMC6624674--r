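test_that("index/physical round trip follows the voxel-centre convention", {
  g <- ImageGeometry(c(10, 8, 4), c(0.5, 0.5, 3.0), origin = c(1, -2, 5))
  expect_equal(as.numeric(indexToPhysical(g, c(1, 1, 1))), c(1, -2, 5))
  expect_equal(as.numeric(indexToPhysical(g, c(3, 2, 4))),
               c(1 + 2 * 0.5, -2 + 1 * 0.5, 5 + 3 * 3.0))
  set.seed(11)
  ijk <- cbind(runif(50, 1, 10), runif(50, 1, 8), runif(50, 1, 4))
  expect_equal(physicalToIndex(g, indexToPhysical(g, ijk)), ijk)
  expect_equal(voxelVolume(g), 0.5 * 0.5 * 3.0)
})

test_that("geometry validity rejects degenerate grids", {
  expect_error(ImageGeometry(c(0, 4, 4), c(1, 1, 1)), "shape")
  expect_error(ImageGeometry(c(4, 4, 4), c(1, -1, 1)), "spacing")
  expect_error(ScalarVolume(array(0, c(3, 3, 3)), ImageGeometry(c(4, 4, 4), c(1, 1, 1))),
               "shape")
  expect_error(ScalarVolume(array(-1, c(3, 3, 3)),
                            ImageGeometry(c(3, 3, 3), c(1, 1, 1)),
                            modality = "ADC"),
               "non-negative")
})

test_that("NIfTI write/read round trip preserves values and geometry", {
  tmp <- withr::local_tempdir()
  g <- ImageGeometry(c(4, 4, 4), c(0.5, 0.5, 3.0), origin = c(12, -3, 40))
  v <- ScalarVolume(array(7.0, c(4, 4, 4)), g, modality = "T2W")
  p <- file.path(tmp, "const.nii")
  writeNiftiVolume(v, p)
  r <- readNiftiVolume(p, as = "volume", modality = "T2W")
  expect_s4_class(r, "ScalarVolume")
  expect_equal(voxelValues(r), voxelValues(v))
  expect_equal(gridSpacing(r), c(0.5, 0.5, 3.0))
  expect_equal(gridOrigin(geometry(r)), c(12, -3, 40))

  set.seed(3)
  vals <- array(rnorm(4^3, sd = 100), c(4, 4, 4))
  writeNiftiVolume(ScalarVolume(vals, g), p)
  back <- voxelValues(readNiftiVolume(p, as = "volume"))
  # float32 storage precision
  expect_equal(back, vals, tolerance = 1e-6)
})

test_that("binary NIfTI files come back as masks, others as volumes", {
  tmp <- withr::local_tempdir()
  g <- ImageGeometry(c(5, 5, 3), c(1, 1, 2))
  m <- makeMask(c(5, 5, 3), cbind(2:4, 2:4, c(1, 2, 3)), spacing = c(1, 1, 2))
  p <- file.path(tmp, "mask.nii")
  writeNiftiVolume(m, p)
  r <- readNiftiVolume(p)
  expect_s4_class(r, "BinaryMask")
  expect_identical(maskVoxels(r), maskVoxels(m))
  expect_error(readNiftiVolume(p, as = "mask", tol = 1e-6), NA)
  v <- ScalarVolume(array(seq_len(75) / 10, c(5, 5, 3)), g)
  writeNiftiVolume(v, p)
  expect_s4_class(readNiftiVolume(p), "ScalarVolume")
  expect_error(readNiftiVolume(p, as = "mask"), class = "dilFormatError")
})

test_that("non-3D and oblique NIfTI inputs are rejected", {
  tmp <- withr::local_tempdir()
  p2d <- file.path(tmp, "flat.nii")
  RNifti::writeNifti(RNifti::asNifti(matrix(1:9, 3, 3)), p2d)
  expect_error(readNiftiVolume(p2d), class = "dilFormatError")

  pob <- file.path(tmp, "oblique.nii")
  img <- RNifti::asNifti(array(rnorm(27), c(3, 3, 3)))
  th <- 0.2
  aff <- diag(4)
  aff[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, pob)
  expect_error(readNiftiVolume(pob), class = "dilOrientationError")
})

test_that("rigid transforms compose rotation and translation correctly", {
  expect_equal(applyTransform(RigidTransform(), cbind(1.5, -2, 7)),
               cbind(1.5, -2, 7))
  t <- RigidTransform(rotation = c(0, 0, pi / 2), translation = c(1, 0, 0))
  expect_equal(as.numeric(applyTransform(t, c(1, 0, 0))), c(1, 1, 0),
               tolerance = 1e-12)
  R <- rotationMatrix(RigidTransform(rotation = c(0.3, -0.2, 0.9)))
  expect_equal(t(R) %*% R, diag(3), tolerance = 1e-12)
  expect_equal(det(R), 1, tolerance = 1e-12)
})

test_that("resampling a constant volume reproduces the constant", {
  mv <- ScalarVolume(array(4.2, c(10, 10, 6)),
                     ImageGeometry(c(10, 10, 6), c(2, 2, 3)))
  ref <- ImageGeometry(c(8, 8, 3), c(1.5, 1.5, 3), origin = c(2, 2, 3))
  out <- resampleToReference(mv, ref)
  expect_equal(gridSpacing(out), c(1.5, 1.5, 3))
  expect_true(all(abs(voxelValues(out) - 4.2) < 1e-12))
})

test_that("linear interpolation hits the analytic midpoint value", {
  g <- ImageGeometry(c(2, 1, 1), c(1, 1, 1))
  mv <- ScalarVolume(array(c(0, 10), c(2, 1, 1)), g)
  ref <- ImageGeometry(c(1, 1, 1), c(1, 1, 1), origin = c(0.5, 0, 0))
  expect_equal(as.numeric(voxelValues(resampleToReference(mv, ref))), 5.0)
})

test_that("identity resampling on an identical grid is exact", {
  set.seed(5)
  g <- ImageGeometry(c(7, 6, 4), c(0.5, 0.5, 3), origin = c(-1, 2, 0))
  mv <- ScalarVolume(array(rnorm(7 * 6 * 4), c(7, 6, 4)), g)
  out <- resampleToReference(mv, g)
  expect_identical(voxelValues(out), voxelValues(mv))
})

test_that("ADC-resolution grids resample onto the T2W grid spacing", {
  set.seed(6)
  adc <- ScalarVolume(array(abs(rnorm(12 * 12 * 4, 990, 150)), c(12, 12, 4)),
                      ImageGeometry(c(12, 12, 4), c(2, 2, 3)), modality = "ADC")
  ref <- ImageGeometry(c(40, 40, 4), c(0.5, 0.5, 3), origin = c(1, 1, 0))
  out <- resampleToReference(adc, ref)
  expect_equal(gridSpacing(out), c(0.5, 0.5, 3.0))
  expect_identical(gridShape(out), c(40L, 40L, 4L))
  expect_equal(modality(out), "ADC")
})

test_that("linear interpolation never overshoots the moving volume's range", {
  set.seed(7)
  for (rep in 1:10) {
    sh <- c(sample(4:9, 1), sample(4:9, 1), sample(3:5, 1))
    mv <- ScalarVolume(array(rnorm(prod(sh)), sh),
                       ImageGeometry(sh, runif(3, 0.4, 3)))
    ref <- ImageGeometry(c(12, 12, 6), runif(3, 0.3, 2),
                         origin = runif(3, -1, 1))
    tr <- RigidTransform(rotation = runif(3, -0.3, 0.3),
                         translation = runif(3, -2, 2))
    out <- voxelValues(resampleToReference(mv, ref, tr, fill = 0))
    rng <- range(c(voxelValues(mv), 0))
    expect_true(all(out >= rng[1] - 1e-12 & out <= rng[2] + 1e-12))
  }
})

test_that("mask resampling preserves identity and approximate volume", {
  m <- cubeMask(c(8, 8, 4), c(3, 3, 2), c(6, 6, 3), spacing = c(1, 1, 2))
  same <- resampleMask(m, geometry(m))
  expect_identical(maskVoxels(same), maskVoxels(m))

  allTrue <- BinaryMask(array(TRUE, c(6, 6, 4)),
                        ImageGeometry(c(6, 6, 4), c(2, 2, 3)))
  inner <- ImageGeometry(c(8, 8, 2), c(1, 1, 3), origin = c(1, 1, 3))
  expect_true(all(maskVoxels(resampleMask(allTrue, inner))))

  # single voxel onto a 2x finer in-plane grid: volume preserved within one
  # fine-voxel volume
  single <- makeMask(c(5, 5, 3), cbind(3, 3, 2), spacing = c(1, 1, 1))
  fine <- ImageGeometry(c(10, 10, 3), c(0.5, 0.5, 1), origin = c(-0.25, -0.25, 0))
  res <- resampleMask(single, fine)
  expect_lte(abs(volumeMl(res) - volumeMl(single)), 0.5 * 0.5 * 1 / 1000)
})
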