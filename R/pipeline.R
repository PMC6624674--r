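# Pipeline drivers tying the stages together on disk: simulate a cohort
# directory, compute agreement metrics and voxel-wise correlations into CSVs,
# and aggregate cohort tables.  Every stage writes a manifest (config + seed
# + package version) next to its outputs, and skipped patients are logged,
# never silently dropped.

pkgVersion <- function() as.character(utils::packageVersion("DILagree"))

configAsList <- function(config) {
  slots <- methods::slotNames(class(config))
  out <- lapply(slots, function(s) slot(config, s))
  names(out) <- slots
  out
}

writeManifest <- function(dir, stage, fields, path = NULL) {
  manifest <- c(list(stage = stage, package_version = pkgVersion()), fields)
  if (is.null(path)) path <- file.path(dir, paste0("manifest_", stage, ".json"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  # config hash ties outputs to the exact run configuration
  invisible(path)
}

logLine <- function(verbose, stage, pid, outcome) {
  if (verbose) message(sprintf("[%s] %s: %s", stage, pid, outcome))
}

#' Simulate a synthetic cohort to disk
#'
#' Writes one directory per patient (uncompressed NIfTI volumes `t2w.nii`,
#' `adc.nii`, `ktrans.nii` and masks `mask_<SEQ>_<obs>.nii`), plus
#' `metadata.csv`, `ground_truth.csv` and a manifest recording the seed and
#' configuration.  Re-running with the same configuration reproduces the
#' directory byte for byte.
#'
#' @param config a [SyntheticConfig-class]
#' @param outDir output directory (created if needed)
#' @param verbose log one line per patient
#' @return `outDir`, invisibly
#' @export
runSimulate <- function(config, outDir, verbose = FALSE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generateCohort(config)
  gtRows <- list()
  for (case in cohort$cases) {
    pid <- case$patientId
    pdir <- file.path(outDir, pid)
    dir.create(pdir, showWarnings = FALSE)
    writeNiftiVolume(case$volumes$T2W, file.path(pdir, "t2w.nii"))
    writeNiftiVolume(case$volumes$ADC, file.path(pdir, "adc.nii"))
    writeNiftiVolume(case$volumes$KTRANS, file.path(pdir, "ktrans.nii"))
    for (s in names(case$masks))
      writeNiftiVolume(case$masks[[s]],
                       file.path(pdir, sprintf("mask_%s_obs1.nii", s)))
    if (!is.null(case$masksObs2))
      for (s in names(case$masksObs2))
        writeNiftiVolume(case$masksObs2[[s]],
                         file.path(pdir, sprintf("mask_%s_obs2.nii", s)))
    gt <- case$groundTruth
    gtRows[[pid]] <- data.frame(
      patient_id = pid, base_volume_ml = gt$baseVolumeMl,
      target_rho_t2w_adc = gt$targetRho[["T2W-ADC"]],
      target_rho_t2w_ktrans = gt$targetRho[["T2W-KTRANS"]],
      target_rho_adc_ktrans = gt$targetRho[["ADC-KTRANS"]],
      adc_fit_flagged = gt$adcFitFlagged,
      stringsAsFactors = FALSE)
    logLine(verbose, "simulate", pid, "written")
  }
  write.csv(cohort$meta, file.path(outDir, "metadata.csv"), row.names = FALSE)
  write.csv(do.call(rbind, c(gtRows, list(make.row.names = FALSE))),
            file.path(outDir, "ground_truth.csv"), row.names = FALSE)
  writeManifest(outDir, "simulate",
                list(seed = config@seed, config = configAsList(config)))
  invisible(outDir)
}

patientDirs <- function(cohortDir) {
  dirs <- list.dirs(cohortDir, recursive = FALSE)
  dirs[grepl("^pt-", basename(dirs))]
}

readMaskSet <- function(pdir, observer) {
  seqs <- c("T2W", "ADC", "KTRANS")
  paths <- file.path(pdir, sprintf("mask_%s_%s.nii", seqs, observer))
  if (!all(file.exists(paths))) return(NULL)
  masks <- lapply(seq_along(seqs), function(j)
    readNiftiVolume(paths[j], as = "mask",
                    label = paste0(seqs[j], "/", observer)))
  names(masks) <- seqs
  masks
}

pairSequences <- list("T2W-ADC" = c("T2W", "ADC"),
                      "T2W-KTRANS" = c("T2W", "KTRANS"),
                      "ADC-KTRANS" = c("ADC", "KTRANS"))

#' Compute agreement metrics for a cohort directory
#'
#' One row per patient and sequence pair with Dice, Jaccard, HD95 and MDA,
#' plus a per-sequence lesion-volume table.  Patients with missing mask
#' files are logged and skipped; the run fails only if no patient succeeds.
#'
#' @param cohortDir directory produced by [runSimulate()] (or with the same
#'   layout)
#' @param outCsv metrics CSV path
#' @param observer observer id suffix of the mask files (default `"obs1"`)
#' @param q Hausdorff percentile
#' @param verbose log per-patient lines
#' @return data.frame of metric rows, invisibly; a per-sequence lesion
#'   volume table is written alongside as `<outCsv>_volumes.csv`
#' @export
runMetrics <- function(cohortDir, outCsv, observer = "obs1", q = 95,
                       verbose = FALSE) {
  rows <- list(); vrows <- list(); nFail <- 0L
  pdirs <- patientDirs(cohortDir)
  for (pdir in pdirs) {
    pid <- basename(pdir)
    masks <- readMaskSet(pdir, observer)
    if (is.null(masks)) {
      logLine(TRUE, "metrics", pid, "missing mask files; skipped")
      nFail <- nFail + 1L
      next
    }
    for (pair in names(pairSequences)) {
      ab <- pairSequences[[pair]]
      pm <- pairMetrics(masks[[ab[1]]], masks[[ab[2]]], q = q)
      rows[[paste(pid, pair)]] <- data.frame(
        patient_id = pid, pair = pair, dice = pm$dice, jaccard = pm$jaccard,
        hd95_mm = pm$hd95, mda_mm = pm$mda, stringsAsFactors = FALSE)
    }
    for (s in names(masks))
      vrows[[paste(pid, s)]] <- data.frame(
        patient_id = pid, sequence = s,
        volume_ml = lesionVolumeMl(masks[[s]]), stringsAsFactors = FALSE)
    logLine(verbose, "metrics", pid, "ok")
  }
  if (length(rows) == 0L)
    .stopClassed("no patient produced agreement metrics", "dilIntegrityError")
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  write.csv(df, outCsv, row.names = FALSE)
  base <- tools::file_path_sans_ext(outCsv)
  write.csv(do.call(rbind, c(vrows, list(make.row.names = FALSE))),
            paste0(base, "_volumes.csv"), row.names = FALSE)
  writeManifest(dirname(outCsv), "metrics",
                list(cohort_dir = cohortDir, observer = observer, q = q,
                     n_failed = nFail),
                path = paste0(base, "_manifest.json"))
  invisible(df)
}

#' Compute voxel-wise correlations for a cohort directory
#'
#' One row per patient and sequence pair: Spearman rho inside the
#' three-sequence Boolean sum volume, the BSV voxel count and the
#' defined flag (FALSE when a map is constant inside the BSV).
#'
#' @inheritParams runMetrics
#' @return data.frame of rows, invisibly
#' @export
runVoxelwise <- function(cohortDir, outCsv, observer = "obs1",
                         verbose = FALSE) {
  rows <- list(); nFail <- 0L
  for (pdir in patientDirs(cohortDir)) {
    pid <- basename(pdir)
    masks <- readMaskSet(pdir, observer)
    vpaths <- file.path(pdir, c("t2w.nii", "adc.nii", "ktrans.nii"))
    if (is.null(masks) || !all(file.exists(vpaths))) {
      logLine(TRUE, "voxelwise", pid, "missing files; skipped")
      nFail <- nFail + 1L
      next
    }
    volumes <- list(
      T2W = readNiftiVolume(vpaths[1], as = "volume", modality = "T2W"),
      ADC = readNiftiVolume(vpaths[2], as = "volume", modality = "ADC"),
      KTRANS = readNiftiVolume(vpaths[3], as = "volume", modality = "KTRANS"))
    for (pair in names(pairSequences)) {
      res <- patientVoxelwise(pair, volumes, masks)
      rows[[paste(pid, pair)]] <- data.frame(
        patient_id = pid, pair = pair, rho = res$rho, n_voxels = res$n,
        defined = res$defined, stringsAsFactors = FALSE)
    }
    logLine(verbose, "voxelwise", pid, "ok")
  }
  if (length(rows) == 0L)
    .stopClassed("no patient produced voxel-wise rows", "dilIntegrityError")
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  write.csv(df, outCsv, row.names = FALSE)
  writeManifest(dirname(outCsv), "voxelwise",
                list(cohort_dir = cohortDir, observer = observer,
                     n_failed = nFail),
                path = paste0(tools::file_path_sans_ext(outCsv),
                              "_manifest.json"))
  invisible(df)
}

pivotWide <- function(tab) {
  strata <- unique(tab$stratum)
  keys <- unique(tab[, c("pair", "metric")])
  out <- keys
  for (st in strata) {
    cell <- vapply(seq_len(nrow(keys)), function(i) {
      r <- tab[tab$stratum == st & tab$pair == keys$pair[i] &
               tab$metric == keys$metric[i], ]
      if (nrow(r) == 0L || is.na(r$mean[1])) return(NA_character_)
      if (is.na(r$sd[1])) sprintf("%.2f (n=%d)", r$mean[1], r$n[1])
      else sprintf("%.2f ± %.2f (n=%d)", r$mean[1], r$sd[1], r$n[1])
    }, character(1))
    out[[st]] <- cell
  }
  out
}

#' Aggregate cohort tables from stage CSVs
#'
#' Joins the agreement and voxel-wise CSVs with the patient metadata and
#' writes: long stratified tables by lesion zone and grade group, wide
#' mean +/- SD versions of both, the cohort composition, a lesion volume
#' summary, and (when second-observer CSVs are given) the interobserver
#' report.
#'
#' @param metricsCsv,voxelwiseCsv,metaCsv stage outputs
#' @param outDir output directory
#' @param metricsObs2Csv,voxelwiseObs2Csv optional second-observer CSVs; the
#'   interobserver report compares the patients both observers covered
#' @param volumesCsv optional per-sequence lesion volume CSV (written by
#'   [runMetrics()])
#' @return list of the data.frames written, invisibly
#' @export
runCohort <- function(metricsCsv, voxelwiseCsv, metaCsv, outDir,
                      metricsObs2Csv = NULL, voxelwiseObs2Csv = NULL,
                      volumesCsv = NULL) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  metrics <- read.csv(metricsCsv, stringsAsFactors = FALSE)
  voxelwise <- read.csv(voxelwiseCsv, stringsAsFactors = FALSE)
  meta <- normalizeMeta(read.csv(metaCsv, stringsAsFactors = FALSE))
  records <- combineRecords(metrics, voxelwise)
  zoneTab <- stratifiedTable(records, meta, by = "zone")
  gradeTab <- stratifiedTable(records, meta, by = "grade_group")
  comp <- cohortComposition(meta)
  out <- list(zone = zoneTab, grade = gradeTab, composition = comp)
  write.csv(zoneTab, file.path(outDir, "table_zone_long.csv"), row.names = FALSE)
  write.csv(gradeTab, file.path(outDir, "table_grade_long.csv"), row.names = FALSE)
  write.csv(pivotWide(zoneTab), file.path(outDir, "table_zone_wide.csv"),
            row.names = FALSE)
  write.csv(pivotWide(gradeTab), file.path(outDir, "table_grade_wide.csv"),
            row.names = FALSE)
  write.csv(comp$zone, file.path(outDir, "composition_zone.csv"),
            row.names = FALSE)
  write.csv(comp$grade, file.path(outDir, "composition_grade.csv"),
            row.names = FALSE)
  if (!is.null(volumesCsv) && file.exists(volumesCsv)) {
    vols <- read.csv(volumesCsv, stringsAsFactors = FALSE)
    vsum <- do.call(rbind, lapply(split(vols, vols$sequence), function(d)
      data.frame(sequence = d$sequence[1], mean_ml = mean(d$volume_ml),
                 sd_ml = sd(d$volume_ml), n = nrow(d))))
    write.csv(vsum, file.path(outDir, "volume_summary.csv"), row.names = FALSE)
    out$volumes <- vsum
  }
  if (!is.null(metricsObs2Csv)) {
    m2 <- read.csv(metricsObs2Csv, stringsAsFactors = FALSE)
    v2 <- if (!is.null(voxelwiseObs2Csv))
      read.csv(voxelwiseObs2Csv, stringsAsFactors = FALSE) else NULL
    ids2 <- unique(m2$patient_id)
    r1 <- records[records$patient_id %in% ids2, , drop = FALSE]
    rep2 <- interobserverReport(r1, combineRecords(m2, v2))
    write.csv(rep2$perPatient, file.path(outDir, "interobserver_per_patient.csv"),
              row.names = FALSE)
    write.csv(rep2$observerMeans, file.path(outDir, "interobserver_means.csv"),
              row.names = FALSE)
    out$interobserver <- rep2
  }
  writeManifest(outDir, "cohort",
                list(metrics_csv = metricsCsv, voxelwise_csv = voxelwiseCsv,
                     meta_csv = metaCsv))
  invisible(out)
}
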