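# Voxel-wise rank correlation between parametric maps inside a Boolean sum
# volume (BSV): the union of the contours from all available sequences, used
# as a common sampling region so that every sequence contributes the same
# voxels to the correlation.

#' Boolean sum volume of a set of contours
#'
#' Voxel-wise union of masks on a shared grid; labelled `"BSV"`.
#'
#' @param masks list of [BinaryMask-class] objects, identical geometry
#' @return a [BinaryMask-class]
#' @export
booleanSumVolume <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 1L)
  g <- masks[[1]]@geometry
  acc <- masks[[1]]@voxels
  for (m in masks[-1]) {
    checkSameGeometry(masks[[1]], m)
    acc <- acc | m@voxels
  }
  BinaryMask(acc, g, label = "BSV")
}

#' Fractional ranks of a numeric sequence
#'
#' Average-tie ranks divided by the sequence length, so values lie in
#' (0, 1].  Spearman's rho is the Pearson correlation of fractional ranks.
#'
#' @param values numeric vector, length >= 1
#' @return numeric vector of fractional ranks
#' @examples
#' fractionalRanks(c(5, 1, 5))  # 0.8333, 0.3333, 0.8333
#' @export
fractionalRanks <- function(values) {
  if (length(values) == 0L)
    .stopClassed("fractional ranks of an empty sequence are undefined",
                 "dilUndefinedMetricError")
  rank(values, ties.method = "average") / length(values)
}

#' Spearman correlation of two volumes inside a BSV
#'
#' Samples both volumes at the BSV voxels, converts each sample to fractional
#' ranks and returns their Pearson correlation — Spearman's rho with
#' average-tie handling.  A volume that is constant inside the BSV (the
#' signature of an uninformative parametric map) yields a flagged undefined
#' result rather than a silent 0.
#'
#' @param volA,volB [ScalarVolume-class] objects
#' @param bsv a [BinaryMask-class]; all three on identical geometry
#' @return list with `rho` (NA when undefined), `n` (BSV voxel count),
#'   `defined` (logical)
#' @export
spearmanInBSV <- function(volA, volB, bsv) {
  checkSameGeometry(volA, bsv)
  checkSameGeometry(volB, bsv)
  sel <- bsv@voxels
  n <- sum(sel)
  if (n < 2L)
    .stopClassed("Spearman correlation needs at least 2 BSV voxels",
                 "dilUndefinedMetricError")
  xa <- volA@values[sel]
  xb <- volB@values[sel]
  if (length(unique(xa)) < 2L || length(unique(xb)) < 2L)
    return(list(rho = NA_real_, n = n, defined = FALSE))
  rho <- cor(fractionalRanks(xa), fractionalRanks(xb), method = "pearson")
  list(rho = rho, n = n, defined = TRUE)
}

#' Voxel-wise correlation for one patient and one sequence pair
#'
#' Builds the BSV from all three sequence contours (regardless of which pair
#' is being correlated, so every pair is evaluated over the same voxels) and
#' correlates the requested pair of volumes inside it.
#'
#' @param pair one of `"T2W-ADC"`, `"T2W-KTRANS"`, `"ADC-KTRANS"`
#' @param volumes named list of [ScalarVolume-class]: `T2W`, `ADC`, `KTRANS`
#' @param masks list of three [BinaryMask-class] contours (one per sequence)
#' @return list with `rho`, `n`, `defined` as in [spearmanInBSV()]
#' @export
patientVoxelwise <- function(pair = c("T2W-ADC", "T2W-KTRANS", "ADC-KTRANS"),
                             volumes, masks) {
  pair <- match.arg(pair)
  stopifnot(length(masks) == 3L)
  bsv <- booleanSumVolume(masks)
  mods <- strsplit(pair, "-", fixed = TRUE)[[1]]
  if (!all(mods %in% names(volumes)))
    .stopClassed(sprintf("volumes list is missing %s",
                         paste(setdiff(mods, names(volumes)), collapse = ", ")),
                 "dilIntegrityError")
  spearmanInBSV(volumes[[mods[1]]], volumes[[mods[2]]], bsv)
}
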