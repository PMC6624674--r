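refGeom <- ImageGeometry(c(72, 72, 16), c(0.5, 0.5, 3.0))

test_that("fixed-axis ellipsoids match the analytic volume", {
  m <- generateBaseLesion(refGeom, semiAxesMm = c(5, 5, 6))
  analytic <- 4 / 3 * pi * 5 * 5 * 6 / 1000
  # voxelization error bounded by one voxel shell: surface area x voxel diag
  shell <- 4 * pi * (5 * 5 * 6)^(2 / 3) * max(gridSpacing(refGeom)) / 1000
  expect_lte(abs(volumeMl(m) - analytic), shell)
  expect_true(any(maskVoxels(m)))
})

test_that("lesion generation is seed-deterministic and volume-calibrated", {
  set.seed(51); a <- generateBaseLesion(refGeom)
  set.seed(51); b <- generateBaseLesion(refGeom)
  expect_identical(maskVoxels(a), maskVoxels(b))

  set.seed(52)
  vols <- replicate(300, volumeMl(generateBaseLesion(refGeom)))
  expect_lte(abs(mean(vols) - 2.14) / 2.14, 0.15)
})

test_that("oversized lesions raise a generation error", {
  tiny <- ImageGeometry(c(10, 10, 4), c(0.5, 0.5, 3.0))
  set.seed(53)
  expect_error(generateBaseLesion(tiny, volumeMl = 50),
               class = "dilGenerationError")
})

test_that("zero-scale perturbation is the identity; Dice falls with scale", {
  set.seed(54)
  base <- generateBaseLesion(refGeom, volumeMl = 2.14)
  expect_identical(maskVoxels(perturbLesion(base, 0)), maskVoxels(base))
  expect_equal(diceCoefficient(perturbLesion(base, 0), base), 1.0)

  scales <- c(0.5, 1, 2, 4)
  meanDice <- vapply(scales, function(s) {
    set.seed(540 + round(10 * s))
    mean(replicate(30, diceCoefficient(perturbLesion(base, s), base)))
  }, numeric(1))
  expect_true(all(diff(meanDice) < 0))
  expect_true(all(meanDice > 0 & meanDice < 1))
})

test_that("perturbation calibration table is reproducible and monotone", {
  cfg <- syntheticConfig(nPatients = 1, refShape = c(48, 48, 12))
  cal1 <- calibratePerturbation(scalesMm = c(1, 3), reps = 10, config = cfg, seed = 2)
  cal2 <- calibratePerturbation(scalesMm = c(1, 3), reps = 10, config = cfg, seed = 2)
  expect_identical(cal1, cal2)
  expect_lt(cal1$mean_dice[2], cal1$mean_dice[1])
})

test_that("noiseless DWI round trip recovers the ADC exactly", {
  g <- ImageGeometry(c(6, 6, 2), c(2, 2, 3))
  truth <- array(seq(0.5e-3, 2e-3, length.out = 72), c(6, 6, 2))
  fit <- simulateDwiAndFitAdc(ScalarVolume(truth, g, "ADC", "mm^2/s"),
                              bValues = c(50, 400, 800), s0 = 1000, noiseSd = 0)
  expect_equal(voxelValues(fit$adc), truth, tolerance = 1e-12)
  expect_identical(fit$nClipped + fit$nExcluded, 0L)

  zero <- simulateDwiAndFitAdc(ScalarVolume(array(0, c(6, 6, 2)), g, "ADC"),
                               s0 = 500, noiseSd = 0)
  expect_true(all(voxelValues(zero$adc) == 0))
})

test_that("the ADC fit is scale-consistent in b", {
  g <- ImageGeometry(c(4, 4, 2), c(2, 2, 3))
  truth <- array(runif(32, 0.4e-3, 1.8e-3), c(4, 4, 2))
  b <- c(50, 400, 800); cc <- 3.7
  f1 <- simulateDwiAndFitAdc(ScalarVolume(truth, g, "ADC"), b, 1000, 0)
  f2 <- simulateDwiAndFitAdc(ScalarVolume(truth / cc, g, "ADC"), b * cc, 1000, 0)
  expect_equal(voxelValues(f2$adc) * cc, voxelValues(f1$adc), tolerance = 1e-12)
})

test_that("the noisy ADC fit stays within 2% in the median", {
  set.seed(55)
  g <- ImageGeometry(c(25, 25, 16), c(2, 2, 3))
  truth <- array(1.0e-3, c(25, 25, 16))  # 10^4 voxels
  fit <- simulateDwiAndFitAdc(ScalarVolume(truth, g, "ADC"),
                              bValues = c(50, 400, 800), s0 = 1000,
                              noiseSd = 10)
  expect_lte(abs(median(voxelValues(fit$adc)) - 1.0e-3) / 1.0e-3, 0.02)
})

test_that("non-positive noisy signals are excluded per voxel, not fatal", {
  g <- ImageGeometry(c(2, 1, 1), c(1, 1, 1))
  # enormous ADC drives high-b signals to ~0; huge noise forces negatives
  set.seed(56)
  truth <- array(c(5e-3, 1e-3), c(2, 1, 1))
  fit <- simulateDwiAndFitAdc(ScalarVolume(truth, g, "ADC"),
                              bValues = c(50, 400, 800), s0 = 10, noiseSd = 3)
  expect_true(all(voxelValues(fit$adc) >= 0))
  expect_true(is.finite(sum(voxelValues(fit$adc))))
})

test_that("copula targets are recovered through the full patient pipeline", {
  set.seed(57)
  v <- array(FALSE, c(24, 24, 8)); v[4:21, 4:21, 2:7] <- TRUE
  bsv <- BinaryMask(v, ImageGeometry(c(24, 24, 8), c(1, 1, 1)))
  n <- sum(v)
  pair <- generateCorrelatedPair(bsv, 0.20)
  est <- spearmanInBSV(pair[[1]], pair[[2]], bsv)
  expect_lte(abs(est$rho - 0.20), 3 / sqrt(n))
  expect_identical(est$n, n)
})

test_that("uninformative Ktrans maps are indistinguishable from background", {
  set.seed(58)
  v <- array(FALSE, c(20, 20, 6)); v[6:15, 6:15, 2:5] <- TRUE
  g <- ImageGeometry(c(20, 20, 6), c(1, 1, 1))
  bsv <- BinaryMask(v, g)
  nonSig <- 0L
  reps <- 40
  for (r in seq_len(reps)) {
    pair <- generateCorrelatedPair(bsv, 0.5)
    kt <- makeKtransUnusable(pair[[2]], bsv)
    inb <- voxelValues(kt)[maskVoxels(bsv)]
    outb <- voxelValues(kt)[!maskVoxels(bsv)]
    p <- suppressWarnings(wilcox.test(inb, outb)$p.value)
    if (p > 0.01) nonSig <- nonSig + 1L
    est <- spearmanInBSV(pair[[1]], kt, bsv)
    expect_true(!est$defined || abs(est$rho) < 0.5)
  }
  expect_gte(nonSig / reps, 0.95)
})

test_that("cohort generation is deterministic with the configured structure", {
  cfg <- syntheticConfig(nPatients = 6, seed = 9, refShape = c(48, 48, 12),
                         nInterobserver = 2)
  c1 <- generateCohort(cfg)
  c2 <- generateCohort(cfg)
  expect_identical(length(c1$cases), 6L)
  expect_identical(c1$meta, c2$meta)
  expect_identical(maskVoxels(c1$cases[[3]]$masks$ADC),
                   maskVoxels(c2$cases[[3]]$masks$ADC))
  expect_equal(voxelValues(c1$cases[[5]]$volumes$KTRANS),
               voxelValues(c2$cases[[5]]$volumes$KTRANS))
  # interobserver masks only for the configured subset
  expect_false(is.null(c1$cases[[1]]$masksObs2))
  expect_true(is.null(c1$cases[[3]]$masksObs2))
  # exact unusable count
  expect_identical(sum(!c1$meta$ktrans_usable), as.integer(round(19 / 90 * 6)))
})

makeRecords2 <- function(ids) {
  rbind(
    data.frame(patient_id = ids, pair = "T2W-ADC", metric = "Dice",
               value = 0.7, stringsAsFactors = FALSE),
    data.frame(patient_id = ids, pair = "T2W-KTRANS", metric = "Dice",
               value = 0.6, stringsAsFactors = FALSE))
}

test_that("the flagged Ktrans cases propagate into cohort exclusion", {
  cfg <- syntheticConfig(nPatients = 5, seed = 10, refShape = c(48, 48, 12),
                         ktransUnusableFraction = 0.4, nInterobserver = 0)
  co <- generateCohort(cfg)
  expect_identical(sum(!co$meta$ktrans_usable), 2L)
  rec <- makeRecords2(co$meta$patient_id)
  tab <- stratifiedTable(rec, co$meta, by = "grade_group")
  tot <- tab[tab$stratum == "Total" & tab$metric == "Dice", ]
  expect_identical(tot$n[tot$pair == "T2W-ADC"], 5L)
  expect_identical(tot$n[tot$pair == "T2W-KTRANS"], 3L)
})
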