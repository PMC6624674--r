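# Synthetic multiparametric prostate MRI cohort generator.  Emulates the
# post-registration state of a contouring study: per-sequence lesion contours
# with controllable boundary variation, parametric maps with controllable
# voxel-wise rank correlation (Gaussian copula), DWI signal synthesis with
# monoexponential ADC fitting, and cohort metadata (lesion zone, Gleason
# grade group, uninformative-Ktrans flag) with known ground truth throughout.

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the geometry and cohort structure of a 90-patient mpMRI
#' contouring study: a T2W reference grid of 0.5 x 0.5 x 3.0 mm, native ADC
#' (2.0 x 2.0 x 3.0 mm) and Ktrans (1.5 x 1.5 x 3.0 mm) grid descriptors,
#' lognormal lesion volumes with mean 2.14 mL and SD 2.1 mL, zone weights
#' 35.2 / 5.6 / 32.4 / 25.4 % (AFS / CZ / PZ / TZ, renormalised), grade-group
#' weights 30.3 / 39.4 / 17.2 / 13.1 % (1 / 2 / 3 / 4+5), a 19/90 fraction of
#' patients whose Ktrans map is uninformative, b-values 50 / 400 / 800
#' s/mm^2, and pairwise voxel-wise Spearman targets 0.20 (T2W-ADC), 0.13
#' (T2W-Ktrans) and 0.10 (ADC-Ktrans).  The per-sequence boundary
#' perturbation scales (0.8 / 1.6 / 2.6 mm RMS for T2W / ADC / Ktrans) are
#' calibrated by Monte-Carlo so the expected inter-sequence Dice sits at the
#' cohort level the study design anticipates (about 0.75 for T2W-ADC and
#' 0.61 for T2W-Ktrans); see [calibratePerturbation()].
#'
#' @slot nPatients number of patients
#' @slot seed master seed; every per-patient stream derives from it
#' @slot refShape,refSpacing reference (T2W) grid
#' @slot adcSpacing,ktransSpacing native grid spacings (mm), kept as
#'   descriptors for resampling workflows
#' @slot volumeMeanMl,volumeSdMl lognormal lesion-volume mean and SD (mL)
#' @slot perturbScaleMm named per-sequence boundary perturbation RMS (mm)
#' @slot targetRho named per-pair voxel-wise Spearman targets
#' @slot zoneWeights,gradeWeights sampling weights (sum to 1)
#' @slot ktransUnusableFraction fraction of patients with uninformative Ktrans
#' @slot bValues DWI b-values (s/mm^2), strictly increasing, >= 2
#' @slot dwiNoiseFrac additive Gaussian DWI noise SD as a fraction of s0
#' @slot s0 unweighted DWI signal
#' @slot adcMeanE6,adcSdE6 ADC marginal (units 1e-6 mm^2/s), normal truncated
#'   at 0
#' @slot ktransRateInvMin Ktrans exponential marginal rate (1 / mean, min)
#' @slot t2wMean,t2wSd T2W marginal (arbitrary units), normal truncated at 0
#' @slot nInterobserver patients also contoured by a second observer
#' @slot obs2PerturbScaleMm extra boundary perturbation of the second
#'   observer (mm)
#' @export
setClass("SyntheticConfig", representation(
  nPatients = "integer", seed = "integer",
  refShape = "integer", refSpacing = "numeric",
  adcSpacing = "numeric", ktransSpacing = "numeric",
  volumeMeanMl = "numeric", volumeSdMl = "numeric",
  perturbScaleMm = "numeric", targetRho = "numeric",
  zoneWeights = "numeric", gradeWeights = "numeric",
  ktransUnusableFraction = "numeric",
  bValues = "numeric", dwiNoiseFrac = "numeric", s0 = "numeric",
  adcMeanE6 = "numeric", adcSdE6 = "numeric",
  ktransRateInvMin = "numeric", t2wMean = "numeric", t2wSd = "numeric",
  nInterobserver = "integer", obs2PerturbScaleMm = "numeric"))

setValidity("SyntheticConfig", function(object) {
  msgs <- character(0)
  if (object@nPatients < 1L) msgs <- c(msgs, "nPatients must be >= 1")
  if (abs(sum(object@zoneWeights) - 1) > 1e-9 ||
      abs(sum(object@gradeWeights) - 1) > 1e-9)
    msgs <- c(msgs, "zone and grade weights must each sum to 1")
  if (any(object@perturbScaleMm < 0) || object@obs2PerturbScaleMm < 0)
    msgs <- c(msgs, "perturbation scales must be >= 0")
  if (length(object@bValues) < 2L || any(diff(object@bValues) <= 0))
    msgs <- c(msgs, "bValues must be >= 2 strictly increasing values")
  if (object@ktransUnusableFraction < 0 || object@ktransUnusableFraction > 1)
    msgs <- c(msgs, "ktransUnusableFraction must be in [0, 1]")
  if (any(abs(object@targetRho) > 1))
    msgs <- c(msgs, "targetRho entries must be in [-1, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Build a SyntheticConfig
#'
#' @param nPatients cohort size (default 90)
#' @param seed master seed
#' @param refShape,refSpacing reference (T2W) grid; defaults 72 x 72 x 16 at
#'   0.5 x 0.5 x 3.0 mm
#' @param adcSpacing,ktransSpacing native grid spacings
#' @param volumeMeanMl,volumeSdMl lesion volume distribution (mL)
#' @param perturbScaleMm named per-sequence boundary perturbation (mm)
#' @param targetRho named per-pair Spearman targets
#' @param zoneWeights,gradeWeights sampling weights (renormalised to 1)
#' @param ktransUnusableFraction fraction of uninformative-Ktrans patients
#' @param bValues DWI b-values (s/mm^2)
#' @param dwiNoiseFrac DWI noise SD as a fraction of s0
#' @param s0 unweighted DWI signal
#' @param adcMeanE6,adcSdE6 ADC marginal parameters (1e-6 mm^2/s)
#' @param ktransRateInvMin Ktrans exponential rate (default mean 4 / min)
#' @param t2wMean,t2wSd T2W marginal parameters
#' @param nInterobserver patients with a second observer (default 19)
#' @param obs2PerturbScaleMm second observer's extra perturbation (mm)
#' @return a [SyntheticConfig-class]
#' @export
syntheticConfig <- function(nPatients = 90, seed = 1,
                            refShape = c(72, 72, 16),
                            refSpacing = c(0.5, 0.5, 3.0),
                            adcSpacing = c(2.0, 2.0, 3.0),
                            ktransSpacing = c(1.5, 1.5, 3.0),
                            volumeMeanMl = 2.14, volumeSdMl = 2.1,
                            perturbScaleMm = c(T2W = 0.8, ADC = 1.6, KTRANS = 2.6),
                            targetRho = c("T2W-ADC" = 0.20,
                                          "T2W-KTRANS" = 0.13,
                                          "ADC-KTRANS" = 0.10),
                            zoneWeights = c(AFS = 35.2, CZ = 5.6,
                                            PZ = 32.4, TZ = 25.4),
                            gradeWeights = c("1" = 30.3, "2" = 39.4,
                                             "3" = 17.2, "4+5" = 13.1),
                            ktransUnusableFraction = 19 / 90,
                            bValues = c(50, 400, 800),
                            dwiNoiseFrac = 0.01, s0 = 1000,
                            adcMeanE6 = 990, adcSdE6 = 150,
                            ktransRateInvMin = 0.25,
                            t2wMean = 400, t2wSd = 80,
                            nInterobserver = 19,
                            obs2PerturbScaleMm = 2.8) {
  new("SyntheticConfig",
      nPatients = as.integer(nPatients), seed = as.integer(seed),
      refShape = as.integer(refShape), refSpacing = as.numeric(refSpacing),
      adcSpacing = as.numeric(adcSpacing),
      ktransSpacing = as.numeric(ktransSpacing),
      volumeMeanMl = volumeMeanMl, volumeSdMl = volumeSdMl,
      perturbScaleMm = perturbScaleMm, targetRho = targetRho,
      zoneWeights = zoneWeights / sum(zoneWeights),
      gradeWeights = gradeWeights / sum(gradeWeights),
      ktransUnusableFraction = ktransUnusableFraction,
      bValues = as.numeric(bValues), dwiNoiseFrac = dwiNoiseFrac, s0 = s0,
      adcMeanE6 = adcMeanE6, adcSdE6 = adcSdE6,
      ktransRateInvMin = ktransRateInvMin, t2wMean = t2wMean, t2wSd = t2wSd,
      nInterobserver = as.integer(min(nInterobserver, nPatients)),
      obs2PerturbScaleMm = obs2PerturbScaleMm)
}

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf("SyntheticConfig: %d patients, seed %d, reference %d x %d x %d @ (%g, %g, %g) mm\n",
              object@nPatients, object@seed,
              object@refShape[1], object@refShape[2], object@refShape[3],
              object@refSpacing[1], object@refSpacing[2], object@refSpacing[3]))
})

referenceGeometry <- function(config) {
  ImageGeometry(config@refShape, config@refSpacing)
}

# deterministic per-patient sub-seed, kept below 2^31
.seedFor <- function(seed, i, salt = 0L) {
  ((as.double(seed) * 1000003 + i * 9973 + salt * 104729) %% 2147483629) + 1
}

lognormalParams <- function(meanMl, sdMl) {
  s2 <- log(1 + (sdMl / meanMl)^2)
  c(meanlog = log(meanMl) - s2 / 2, sdlog = sqrt(s2))
}

randomRotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3, 3)))
}

#' Generate a base lesion mask
#'
#' Rasterises a randomly oriented ellipsoid (semi-axes drawn around the
#' target volume with mild anisotropy) placed near the grid centre with a
#' small jitter, wholly inside the grid.  The target volume is drawn from the
#' configured lognormal distribution unless `volumeMl` or `semiAxesMm` pins
#' it.  Draws that cannot fit inside the grid are rejected and retried; after
#' `maxTries` failures a generation error is raised.
#'
#' @param geometry the grid to rasterise on
#' @param meanVolumeMl,sdVolumeMl lognormal volume distribution (mL)
#' @param volumeMl optional fixed volume (mL)
#' @param semiAxesMm optional fixed semi-axes (mm, length 3); overrides the
#'   volume draw and disables rotation/jitter (useful for analytic checks)
#' @param maxTries rejection-sampling budget
#' @return a [BinaryMask-class] labelled `"base"`
#' @export
generateBaseLesion <- function(geometry, meanVolumeMl = 2.14, sdVolumeMl = 2.1,
                               volumeMl = NULL, semiAxesMm = NULL,
                               maxTries = 25) {
  centres <- referenceVoxelCentres(geometry)
  fov_lo <- geometry@origin
  fov_hi <- geometry@origin + (geometry@shape - 1) * geometry@spacing
  mid <- (fov_lo + fov_hi) / 2
  if (!is.null(semiAxesMm)) {
    return(rasterEllipsoid(centres, geometry, mid, semiAxesMm, diag(3)))
  }
  lp <- lognormalParams(meanVolumeMl, sdVolumeMl)
  for (try in seq_len(maxTries)) {
    v <- if (is.null(volumeMl)) rlnorm(1, lp["meanlog"], lp["sdlog"]) else volumeMl
    ratios <- runif(3, 0.7, 1.3)
    scale <- (v * 1000 / (4 / 3 * pi * prod(ratios)))^(1 / 3)
    axes <- ratios * scale
    rot <- randomRotation()
    jitter <- c(runif(2, -2, 2), runif(1, -1.5, 1.5))
    centre <- mid + jitter
    rmax <- max(axes)
    if (any(centre - rmax < fov_lo + geometry@spacing) ||
        any(centre + rmax > fov_hi - geometry@spacing)) next
    m <- rasterEllipsoid(centres, geometry, centre, axes, rot)
    if (any(m@voxels)) return(m)
  }
  .stopClassed("could not fit a lesion of the requested volume inside the grid",
               "dilGenerationError")
}

rasterEllipsoid <- function(centres, geometry, centre, axes, rot) {
  rel <- sweep(centres, 2, centre, "-") %*% rot
  q <- (rel[, 1] / axes[1])^2 + (rel[, 2] / axes[2])^2 + (rel[, 3] / axes[3])^2
  BinaryMask(array(q <= 1, dim = geometry@shape), geometry, label = "base")
}

# smooth random scalar field on the unit sphere: mixture of Gaussian-like
# bumps at random directions, rescaled to a requested RMS amplitude
sphereField <- function(scale, nBumps = 8, width = 0.35) {
  dirs <- matrix(rnorm(3 * nBumps), nBumps, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  g <- rnorm(nBumps)
  raw <- function(u) as.numeric(exp((u %*% t(dirs) - 1) / width) %*% g)
  probe <- matrix(rnorm(3 * 512), 512, 3)
  probe <- probe / sqrt(rowSums(probe^2))
  rms <- sqrt(mean(raw(probe)^2))
  if (rms < 1e-12) rms <- 1e-12
  function(u) raw(u) * (scale / rms)
}

#' Perturb a lesion contour
#'
#' Applies a smooth random radial displacement of the boundary with RMS
#' magnitude about `scaleMm`: the mask is radially warped about its centroid
#' by a smooth random field on the sphere of directions, emulating
#' inter-sequence and inter-observer contour variation.  `scaleMm = 0`
#' returns the input exactly.
#'
#' @param base a non-empty [BinaryMask-class]
#' @param scaleMm RMS boundary displacement (mm), >= 0
#' @param label label for the perturbed mask
#' @return a [BinaryMask-class]
#' @export
perturbLesion <- function(base, scaleMm, label = base@label) {
  stopifnot(scaleMm >= 0)
  if (!any(base@voxels))
    .stopClassed("cannot perturb an empty mask", "dilGenerationError")
  if (scaleMm == 0) {
    return(BinaryMask(base@voxels, base@geometry, label = label))
  }
  geom <- base@geometry
  idx <- which(base@voxels, arr.ind = TRUE)
  centroid <- colMeans(indexToPhysical(geom, idx))
  disp <- sphereField(scaleMm)
  # evaluate on a bounding box dilated by the displacement reach
  marginVox <- ceiling((3 * scaleMm) / geom@spacing) + 2L
  lo <- pmax(apply(idx, 2, min) - marginVox, 1L)
  hi <- pmin(apply(idx, 2, max) + marginVox, geom@shape)
  box <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
  pts <- indexToPhysical(geom, box)
  rel <- sweep(pts, 2, centroid, "-")
  r <- sqrt(rowSums(rel^2))
  ok <- r > 1e-9
  u <- rel[ok, , drop = FALSE] / r[ok]
  d <- disp(u)
  src <- pts
  src[ok, ] <- sweep(u * pmax(r[ok] - d, 0), 2, centroid, "+")
  field <- array(as.numeric(base@voxels), dim = geom@shape)
  vals <- trilinearSample(field, physicalToIndex(geom, src), fill = 0)
  out <- array(FALSE, dim = geom@shape)
  out[box] <- vals >= 0.5
  if (!any(out))
    .stopClassed("perturbation emptied the mask", "dilGenerationError")
  BinaryMask(out, geom, label = label)
}

#' Simulate DWI signals and fit a monoexponential ADC map
#'
#' Per voxel, signals `S(b) = s0 exp(-b ADC)` receive additive Gaussian
#' noise; the ADC is then re-fitted by least squares on the log-signals.
#' Non-positive noisy signals are excluded from a voxel's fit (the value
#' comes from the remaining b-values, or 0 if fewer than two remain);
#' negative fitted slopes are clipped to ADC 0.  Both cases are flagged.
#'
#' @param trueAdc a [ScalarVolume-class] of non-negative ADC values in
#'   mm^2/s
#' @param bValues >= 2 strictly increasing b-values (s/mm^2)
#' @param s0 unweighted signal, > 0
#' @param noiseSd additive Gaussian noise SD (signal units)
#' @return list: `adc` (fitted [ScalarVolume-class], mm^2/s), `flagged`
#'   (logical array: clipped or signal-excluded voxels), `nClipped`,
#'   `nExcluded`
#' @export
simulateDwiAndFitAdc <- function(trueAdc, bValues = c(50, 400, 800),
                                 s0 = 1000, noiseSd = 0) {
  stopifnot(is(trueAdc, "ScalarVolume"), s0 > 0,
            length(bValues) >= 2L, all(diff(bValues) > 0),
            all(trueAdc@values >= 0))
  adc <- as.numeric(trueAdc@values)
  nvox <- length(adc)
  nb <- length(bValues)
  signals <- s0 * exp(-outer(adc, bValues))
  if (noiseSd > 0)
    signals <- signals + matrix(rnorm(nvox * nb, sd = noiseSd), nvox, nb)
  pos <- signals > 0
  allPos <- rowSums(pos) == nb
  fitted <- numeric(nvox)
  excluded <- !allPos
  # fast path: every signal positive -> closed-form log-linear slope
  if (any(allPos)) {
    y <- log(signals[allPos, , drop = FALSE])
    y <- y - rowMeans(y)  # centring keeps constant signals at slope exactly 0
    bc <- bValues - mean(bValues)
    slope <- as.numeric(y %*% bc) / sum(bc^2)
    fitted[allPos] <- -slope
  }
  if (any(excluded)) {
    for (i in which(excluded)) {
      keep <- pos[i, ]
      if (sum(keep) < 2L) {
        fitted[i] <- 0
      } else {
        b <- bValues[keep]
        y <- log(signals[i, keep])
        y <- y - mean(y)
        bc <- b - mean(b)
        fitted[i] <- -sum(bc * y) / sum(bc^2)
      }
    }
  }
  clipped <- fitted < 0
  fitted[clipped] <- 0
  list(adc = ScalarVolume(array(fitted, dim = dim(trueAdc@values)),
                          trueAdc@geometry, modality = "ADC",
                          units = trueAdc@units),
       flagged = array(clipped | excluded, dim = dim(trueAdc@values)),
       nClipped = sum(clipped), nExcluded = sum(excluded))
}

#' Quantile functions for the default parametric-map marginals
#'
#' `adcMarginal` is a normal truncated at zero (defaults 990 +/- 150 in
#' 1e-6 mm^2/s); `ktransMarginal` is exponential (default mean 4 / min);
#' `t2wMarginal` is a truncated normal in arbitrary units.
#'
#' @param mean,sd,rate distribution parameters
#' @return a quantile function `function(p)`
#' @export
adcMarginal <- function(mean = 990, sd = 150) {
  p0 <- pnorm(0, mean, sd)
  function(p) qnorm(p0 + p * (1 - p0), mean, sd)
}

#' @rdname adcMarginal
#' @export
ktransMarginal <- function(rate = 0.25) function(p) qexp(p, rate)

#' @rdname adcMarginal
#' @export
t2wMarginal <- function(mean = 400, sd = 80) adcMarginal(mean, sd)

# Pearson parameter of the bivariate Gaussian copula achieving a Spearman
# target: r = 2 sin(pi rho_s / 6)
spearmanToPearson <- function(rhoS) 2 * sin(pi * rhoS / 6)

# Latent correlated standard normals (n x k) with pairwise Pearson matrix R
latentGaussian <- function(n, R) {
  L <- tryCatch(chol(R), error = function(e)
    .stopClassed("Spearman targets imply a non-positive-definite copula",
                 "dilParameterError"))
  matrix(rnorm(n * nrow(R)), n, nrow(R)) %*% L
}

#' Generate a pair of volumes with a known voxel-wise Spearman correlation
#'
#' Inside the Boolean sum volume, values are drawn from a Gaussian copula
#' with Pearson parameter `2 sin(pi rho_s / 6)` — the parameter whose
#' implied population Spearman equals `targetRhoS` — and transformed to the
#' requested marginals; outside the BSV, background values are drawn
#' independently from the same marginals.
#'
#' @param bsv a [BinaryMask-class] defining the coupled region
#' @param targetRhoS target Spearman correlation in [-1, 1]
#' @param marginalA,marginalB quantile functions (see [adcMarginal()])
#' @param modalities,units modality and unit tags for the two volumes
#' @return list of two [ScalarVolume-class] objects
#' @export
generateCorrelatedPair <- function(bsv, targetRhoS,
                                   marginalA = adcMarginal(),
                                   marginalB = ktransMarginal(),
                                   modalities = c("ADC", "KTRANS"),
                                   units = c("1e-6 mm^2/s", "1/min")) {
  if (!is.finite(targetRhoS) || abs(targetRhoS) > 1)
    .stopClassed("targetRhoS must lie in [-1, 1]", "dilParameterError")
  vols <- generateCorrelatedFields(
    bsv, matrix(c(1, targetRhoS, targetRhoS, 1), 2, 2),
    list(marginalA, marginalB), modalities, units)
  vols
}

# k correlated fields with pairwise Spearman target matrix rhoMat
generateCorrelatedFields <- function(bsv, rhoMat, marginals, modalities, units) {
  geom <- bsv@geometry
  sel <- as.logical(bsv@voxels)
  nIn <- sum(sel)
  nOut <- length(sel) - nIn
  k <- nrow(rhoMat)
  R <- spearmanToPearson(rhoMat)
  diag(R) <- 1
  # fields comonotone/antitone with the first share its uniforms directly;
  # zero their latent coupling so the factorisation stays positive definite
  degen <- abs(R) >= 1 & row(R) != col(R)
  Rsafe <- R
  Rsafe[degen] <- 0
  zIn <- if (nIn > 0) latentGaussian(nIn, Rsafe) else matrix(0, 0, k)
  lapply(seq_len(k), function(j) {
    vals <- numeric(length(sel))
    if (nIn > 0) {
      if (abs(rhoMat[1, j]) == 1 && j > 1) {
        # comonotone / antitone: share (or reverse) the first field's uniforms
        u <- pnorm(zIn[, 1])
        if (rhoMat[1, j] < 0) u <- 1 - u
        vals[sel] <- marginals[[j]](u)
      } else {
        vals[sel] <- marginals[[j]](pnorm(zIn[, j]))
      }
    }
    if (nOut > 0) vals[!sel] <- marginals[[j]](runif(nOut))
    ScalarVolume(array(vals, dim = geom@shape), geom,
                 modality = modalities[j], units = units[j])
  })
}

#' Make a Ktrans map uninformative inside the BSV
#'
#' Replaces in-BSV values with independent draws from the background
#' distribution, so lesion and background become statistically
#' indistinguishable; downstream voxel-wise correlation is expected near 0
#' and the patient is flagged `ktrans_usable = FALSE` in the metadata.
#'
#' @param vol a Ktrans [ScalarVolume-class]
#' @param bsv a [BinaryMask-class]
#' @param background quantile function of the background distribution
#' @return a [ScalarVolume-class]
#' @export
makeKtransUnusable <- function(vol, bsv, background = ktransMarginal()) {
  checkSameGeometry(vol, bsv)
  vals <- vol@values
  n <- sum(bsv@voxels)
  if (n > 0) vals[bsv@voxels] <- background(runif(n))
  ScalarVolume(vals, vol@geometry, modality = vol@modality, units = vol@units)
}

#' Generate a full synthetic cohort
#'
#' For each patient: a base lesion, per-sequence contours obtained by smooth
#' boundary perturbation, a Boolean sum volume, copula-coupled T2W / ADC /
#' Ktrans maps with the configured pairwise Spearman targets (the ADC map
#' additionally passes through DWI synthesis and monoexponential re-fitting),
#' an uninformative-Ktrans transformation for the flagged subset, metadata
#' sampled from the zone / grade-group weights, and — for the first
#' `nInterobserver` patients — a second observer's contours.  Exactly
#' `round(fraction * n)` patients are flagged Ktrans-unusable.  Every draw
#' derives from the master seed through per-patient streams, so regeneration
#' is fully deterministic and independent of evaluation order.
#'
#' @param config a [SyntheticConfig-class]
#' @return list with `cases` (per-patient list: `volumes`, `masks`,
#'   `masksObs2` or NULL, `meta`, `groundTruth`), `meta` (data.frame) and
#'   `config`
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  geom <- referenceGeometry(config)
  n <- config@nPatients
  set.seed(config@seed)
  nBad <- round(config@ktransUnusableFraction * n)
  badIds <- sort(sample.int(n, nBad))
  seqs <- c("T2W", "ADC", "KTRANS")
  cases <- vector("list", n)
  metaRows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(.seedFor(config@seed, i))
    pid <- sprintf("pt-%03d", i)
    base <- generateBaseLesion(geom, config@volumeMeanMl, config@volumeSdMl)
    masks <- lapply(seqs, function(s)
      perturbLesion(base, config@perturbScaleMm[[s]],
                    label = paste0(s, "/obs1")))
    names(masks) <- seqs
    bsv <- booleanSumVolume(masks)
    rhoMat <- matrix(c(
      1, config@targetRho[["T2W-ADC"]], config@targetRho[["T2W-KTRANS"]],
      config@targetRho[["T2W-ADC"]], 1, config@targetRho[["ADC-KTRANS"]],
      config@targetRho[["T2W-KTRANS"]], config@targetRho[["ADC-KTRANS"]], 1),
      3, 3)
    fields <- generateCorrelatedFields(
      bsv, rhoMat,
      list(t2wMarginal(config@t2wMean, config@t2wSd),
           adcMarginal(config@adcMeanE6, config@adcSdE6),
           ktransMarginal(config@ktransRateInvMin)),
      modalities = c("T2W", "ADC", "KTRANS"),
      units = c("a.u.", "1e-6 mm^2/s", "1/min"))
    names(fields) <- seqs
    trueAdc <- fields$ADC
    # DWI round trip: synthesise signals from the true ADC field and re-fit
    adcMm2s <- ScalarVolume(trueAdc@values * 1e-6, geom, "ADC", "mm^2/s")
    fit <- simulateDwiAndFitAdc(adcMm2s, config@bValues, config@s0,
                                noiseSd = config@dwiNoiseFrac * config@s0)
    fields$ADC <- ScalarVolume(fit$adc@values * 1e6, geom, "ADC",
                               "1e-6 mm^2/s")
    ktransUsable <- !(i %in% badIds)
    if (!ktransUsable)
      fields$KTRANS <- makeKtransUnusable(
        fields$KTRANS, bsv, ktransMarginal(config@ktransRateInvMin))
    zone <- sample(names(config@zoneWeights), 1, prob = config@zoneWeights)
    grade <- sample(names(config@gradeWeights), 1, prob = config@gradeWeights)
    masksObs2 <- NULL
    if (i <= config@nInterobserver) {
      masksObs2 <- lapply(seqs, function(s)
        perturbLesion(masks[[s]], config@obs2PerturbScaleMm,
                      label = paste0(s, "/obs2")))
      names(masksObs2) <- seqs
    }
    metaRows[[i]] <- data.frame(
      patient_id = pid, zone = zone, grade_group = grade,
      observer_id = "obs1", ktrans_usable = ktransUsable,
      stringsAsFactors = FALSE)
    cases[[i]] <- list(
      patientId = pid, volumes = fields, masks = masks,
      masksObs2 = masksObs2,
      meta = metaRows[[i]],
      groundTruth = list(
        baseMask = base, trueAdc = trueAdc,
        targetRho = config@targetRho,
        perturbScaleMm = config@perturbScaleMm,
        baseVolumeMl = volumeMl(base),
        adcFitFlagged = sum(fit$flagged)))
  }
  list(cases = cases, meta = do.call(rbind, metaRows), config = config)
}

#' Calibrate boundary perturbation against expected Dice
#'
#' Monte-Carlo mapping from perturbation scale to the expected Dice
#' coefficient between a perturbed contour and its base, for lesions drawn
#' from the configured volume distribution.  The calibration is itself
#' seeded and reproducible.
#'
#' @param scalesMm perturbation scales to probe (mm)
#' @param reps replicates per scale
#' @param config a [SyntheticConfig-class] supplying the grid and volume
#'   distribution
#' @param seed RNG seed
#' @return data.frame with `scale_mm`, `mean_dice`, `sd_dice`, `reps`
#' @export
calibratePerturbation <- function(scalesMm = c(0.5, 1, 2, 4), reps = 50,
                                  config = syntheticConfig(), seed = 1) {
  geom <- referenceGeometry(config)
  rows <- lapply(scalesMm, function(s) {
    set.seed(.seedFor(seed, 1L, salt = round(s * 1000)))
    d <- vapply(seq_len(reps), function(r) {
      base <- generateBaseLesion(geom, config@volumeMeanMl, config@volumeSdMl)
      diceCoefficient(perturbLesion(base, s), base)
    }, numeric(1))
    data.frame(scale_mm = s, mean_dice = mean(d), sd_dice = sd(d), reps = reps)
  })
  do.call(rbind, rows)
}
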