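# Cohort-level aggregation: per-stratum metric tables (lesion zone, Gleason
# grade group), within-contour intensity statistics, lesion volume summaries,
# interobserver comparison, and cohort composition.

metricLevels <- c("HD95", "MDA", "Dice", "Jaccard", "Spearman")
pairLevels <- c("T2W-ADC", "T2W-KTRANS", "ADC-KTRANS")
zoneLevels <- c("AFS", "CZ", "PZ", "TZ")
gradeLevels <- c("1", "2", "3", "4+5")

#' Normalise patient metadata
#'
#' Validates the closed vocabularies and pools Gleason grade groups 4 and 5
#' into a single `"4+5"` level at ingest (they are never reported
#' separately).  Zones are `AFS`, `CZ`, `PZ`, `TZ`; unknown labels become NA.
#'
#' @param meta data.frame with columns `patient_id`, `zone`, `grade_group`,
#'   and optionally `observer_id`, `ktrans_usable`
#' @return the normalised data.frame
#' @export
normalizeMeta <- function(meta) {
  stopifnot(all(c("patient_id", "zone", "grade_group") %in% names(meta)))
  meta$patient_id <- as.character(meta$patient_id)
  gg <- as.character(meta$grade_group)
  gg[gg %in% c("4", "5", "4+5", "4,5")] <- "4+5"
  gg[!gg %in% gradeLevels] <- NA_character_
  meta$grade_group <- gg
  z <- as.character(meta$zone)
  z[!z %in% zoneLevels] <- NA_character_
  meta$zone <- z
  if (is.null(meta$ktrans_usable)) meta$ktrans_usable <- TRUE
  meta$ktrans_usable <- as.logical(meta$ktrans_usable)
  meta
}

#' Within-contour intensity statistics
#'
#' Mean, minimum, maximum and sample standard deviation (n - 1 denominator;
#' a single-voxel contour reports sd = 0) of a parametric map's values inside
#' a contour, in the map's units.
#'
#' @param vol a [ScalarVolume-class]
#' @param mask a non-empty [BinaryMask-class] on the same geometry
#' @return named list `mean`, `min`, `max`, `sd`
#' @export
contourIntensityStats <- function(vol, mask) {
  checkSameGeometry(vol, mask)
  x <- vol@values[mask@voxels]
  if (length(x) == 0L)
    .stopClassed("intensity statistics over an empty contour are undefined",
                 "dilUndefinedMetricError")
  list(mean = mean(x), min = min(x), max = max(x),
       sd = if (length(x) > 1L) sd(x) else 0)
}

#' Lesion volume in millilitres
#'
#' @param mask a [BinaryMask-class]; an empty mask has volume 0
#' @return volume in mL
#' @export
lesionVolumeMl <- function(mask) volumeMl(mask)

#' Combine agreement and voxel-wise records into one long table
#'
#' @param metrics data.frame with columns `patient_id`, `pair`, `dice`,
#'   `jaccard`, `hd95_mm`, `mda_mm`
#' @param voxelwise optional data.frame with columns `patient_id`, `pair`,
#'   `rho`, `defined`
#' @return long data.frame with columns `patient_id`, `pair`, `metric`,
#'   `value`
#' @export
combineRecords <- function(metrics, voxelwise = NULL) {
  long <- do.call(rbind, lapply(
    list(c("Dice", "dice"), c("Jaccard", "jaccard"),
         c("HD95", "hd95_mm"), c("MDA", "mda_mm")),
    function(m) data.frame(patient_id = as.character(metrics$patient_id),
                           pair = metrics$pair, metric = m[1],
                           value = metrics[[m[2]]],
                           stringsAsFactors = FALSE)))
  if (!is.null(voxelwise)) {
    v <- voxelwise
    v$rho[!as.logical(v$defined)] <- NA_real_
    long <- rbind(long, data.frame(patient_id = as.character(v$patient_id),
                                   pair = v$pair, metric = "Spearman",
                                   value = v$rho, stringsAsFactors = FALSE))
  }
  long
}

dropKtransUnusable <- function(records, meta) {
  bad <- meta$patient_id[!meta$ktrans_usable]
  involvesK <- grepl("KTRANS", records$pair, fixed = TRUE)
  records[!(involvesK & records$patient_id %in% bad), , drop = FALSE]
}

strataFor <- function(meta, by) {
  if (by == "zone") {
    s <- ifelse(meta$zone == "AFS", "AFS",
         ifelse(meta$zone == "PZ", "Peripheral",
         ifelse(meta$zone %in% c("CZ", "TZ"), "Cent/Tran", NA_character_)))
  } else {
    s <- meta$grade_group
  }
  stats::setNames(s, meta$patient_id)
}

summariseCell <- function(v) {
  v <- v[!is.na(v)]
  n <- length(v)
  c(mean = if (n) mean(v) else NA_real_,
    sd = if (n >= 2) sd(v) else NA_real_, n = n)
}

#' Stratified cohort metric table
#'
#' Mean, sample SD and contributing-patient count per stratum x sequence pair
#' x metric, plus a `"Total"` stratum over all patients with a known stratum
#' label.  Zone strata mirror the reporting convention: `AFS`, `Peripheral`
#' (PZ) and pooled `Cent/Tran` (CZ + TZ).  Patients whose Ktrans map is
#' flagged unusable are excluded from Ktrans-involved pairs only.  Undefined
#' (NA) metric values never contribute to a cell.
#'
#' @param records long records from [combineRecords()]
#' @param meta metadata from [normalizeMeta()]
#' @param by `"zone"` or `"grade_group"`
#' @return data.frame with columns `stratum`, `pair`, `metric`, `mean`, `sd`,
#'   `n`
#' @export
stratifiedTable <- function(records, meta, by = c("zone", "grade_group")) {
  by <- match.arg(by)
  meta <- normalizeMeta(meta)
  if (!all(records$patient_id %in% meta$patient_id))
    .stopClassed(sprintf(
      "records reference patients absent from the metadata: %s",
      paste(unique(setdiff(records$patient_id, meta$patient_id)), collapse = ", ")),
      "dilIntegrityError")
  records <- dropKtransUnusable(records, meta)
  stratum <- strataFor(meta, by)
  records$stratum <- unname(stratum[records$patient_id])
  records <- records[!is.na(records$stratum), , drop = FALSE]
  strata <- if (by == "zone") c("AFS", "Peripheral", "Cent/Tran") else gradeLevels
  rows <- list()
  for (st in c(strata, "Total")) {
    sub <- if (st == "Total") records else records[records$stratum == st, , drop = FALSE]
    for (p in intersect(pairLevels, unique(records$pair))) {
      for (m in intersect(metricLevels, unique(records$metric))) {
        v <- sub$value[sub$pair == p & sub$metric == m]
        cell <- summariseCell(v)
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = st, pair = p, metric = m,
          mean = cell["mean"], sd = cell["sd"], n = as.integer(cell["n"]),
          stringsAsFactors = FALSE, row.names = NULL)
      }
    }
  }
  do.call(rbind, rows)
}

#' Interobserver comparison report
#'
#' Joins two observers' per-patient agreement records into a side-by-side
#' long table (one row per patient x pair x observer x metric) plus
#' per-observer per-pair means, suitable for a grouped bar chart.
#'
#' @param recordsObs1,recordsObs2 long records from [combineRecords()] for
#'   each observer; both must cover the same patient ids
#' @return list with `perPatient` and `observerMeans` data.frames
#' @export
interobserverReport <- function(recordsObs1, recordsObs2) {
  ids1 <- sort(unique(recordsObs1$patient_id))
  ids2 <- sort(unique(recordsObs2$patient_id))
  if (!identical(ids1, ids2))
    .stopClassed(sprintf(
      "observers cover different patients (only one observer: %s)",
      paste(union(setdiff(ids1, ids2), setdiff(ids2, ids1)), collapse = ", ")),
      "dilIntegrityError")
  recordsObs1$observer <- "obs1"
  recordsObs2$observer <- "obs2"
  perPatient <- rbind(recordsObs1, recordsObs2)
  agg <- stats::aggregate(value ~ observer + pair + metric, data = perPatient,
                          FUN = mean, na.rm = TRUE, na.action = stats::na.pass)
  names(agg)[names(agg) == "value"] <- "mean"
  list(perPatient = perPatient, observerMeans = agg)
}

#' Cohort composition percentages
#'
#' Percentage of patients per lesion zone and per Gleason grade group,
#' computed over patients with a known label; unlabeled counts are reported
#' alongside.
#'
#' @param meta metadata data.frame (normalised internally)
#' @return list with `zone` and `grade` percentage data.frames and
#'   `nUnlabeledZone` / `nUnlabeledGrade` counts
#' @export
cohortComposition <- function(meta) {
  meta <- normalizeMeta(meta)
  if (nrow(meta) == 0L)
    .stopClassed("cohort composition of an empty cohort is undefined",
                 "dilUndefinedMetricError")
  pct <- function(x, levels) {
    known <- x[!is.na(x)]
    tab <- table(factor(known, levels = levels))
    data.frame(level = levels,
               n = as.integer(tab),
               percent = if (length(known)) 100 * as.numeric(tab) / length(known)
                         else rep(NA_real_, length(levels)),
               stringsAsFactors = FALSE)
  }
  list(zone = pct(meta$zone, zoneLevels),
       grade = pct(meta$grade_group, gradeLevels),
       nUnlabeledZone = sum(is.na(meta$zone)),
       nUnlabeledGrade = sum(is.na(meta$grade_group)))
}
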