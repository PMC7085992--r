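# Stage orchestration with YAML configs and reproducible artifacts. Each
# run writes its outputs plus a manifest (inputs with checksums, config,
# package version, seed) sufficient for an exact re-run.

.manifest <- function(outDir, command, inputs, config, seed = NA) {
  mf <- list(command = command, package = "psoasPET",
             version = as.character(utils::packageVersion("psoasPET")),
             seed = seed,
             inputs = lapply(inputs, function(p)
               list(path = p, md5 = unname(tools::md5sum(p)))),
             config = config)
  jsonlite::write_json(mf, file.path(outDir, paste0("manifest_", command,
                                                    ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(mf)
}

.needField <- function(x, field, where) {
  if (is.null(x[[field]]))
    stop("validation error: missing field '", field, "' in ", where)
  x[[field]]
}

#' Read a segmentation config from YAML
#'
#' Required fields: \code{slice_start}, \code{slice_stop}, \code{seeds}
#' (two \code{[row, col]} pairs). Optional: \code{alpha},
#' \code{canny_sigma}, \code{canny_low}, \code{canny_high},
#' \code{body_window}, \code{area_ratio_bounds}, \code{k_missing},
#' \code{capture_radius}. Validation failures name the offending field.
#'
#' @param path YAML file.
#' @return a [SegmentationConfig-class].
#' @export
readSegmentationConfig <- function(path) {
  if (!file.exists(path)) stop("validation error: config file not found: ",
                               path)
  y <- yaml::read_yaml(path)
  seeds <- .needField(y, "seeds", path)
  seeds <- do.call(rbind, lapply(seeds, as.numeric))
  if (!all(dim(seeds) == c(2, 2)))
    stop("validation error: field 'seeds' must be two [row, col] pairs")
  args <- list(sliceStart = .needField(y, "slice_start", path),
               sliceStop = .needField(y, "slice_stop", path),
               seeds = seeds)
  opt <- c(alpha = "alpha", cannySigma = "canny_sigma",
           cannyLow = "canny_low", cannyHigh = "canny_high",
           bodyWindow = "body_window",
           areaRatioBounds = "area_ratio_bounds", kMissing = "k_missing",
           captureRadius = "capture_radius")
  for (nm in names(opt))
    if (!is.null(y[[opt[[nm]]]])) args[[nm]] <- y[[opt[[nm]]]]
  do.call(SegmentationConfig, args)
}

#' @noRd
.writeSegmentationConfig <- function(config, path) {
  yaml::write_yaml(list(
    slice_start = config@sliceStart, slice_stop = config@sliceStop,
    seeds = list(as.numeric(config@seeds[1, ]),
                 as.numeric(config@seeds[2, ])),
    alpha = if (is.na(config@alpha)) NULL else config@alpha,
    canny_sigma = config@cannySigma, canny_low = config@cannyLow,
    canny_high = config@cannyHigh,
    body_window = as.numeric(config@bodyWindow),
    area_ratio_bounds = as.numeric(config@areaRatioBounds),
    k_missing = config@kMissing,
    capture_radius = config@captureRadius), path)
  invisible(path)
}

.readMeta <- function(path) {
  y <- yaml::read_yaml(path)
  ScanMeta(bodyWeightKg = .needField(y, "body_weight_kg", path),
           injectedDoseMBq = .needField(y, "injected_dose_MBq", path),
           sex = .needField(y, "sex", path),
           heightCm = .needField(y, "height_cm", path),
           liverSuvMean = if (is.null(y$liver_suv_mean)) NA_real_ else
             y$liver_suv_mean)
}

#' Write a phantom bundle to disk
#'
#' Writes \code{ct.nii.gz}, \code{pet.nii.gz} (concentration), the two
#' ground-truth masks, \code{meta.yaml}, a default segmentation config,
#' a simulated \code{cohort.csv} and a manifest.
#'
#' @param outDir output directory (created if needed).
#' @param seed RNG seed for phantom and cohort.
#' @param specArgs named list of overrides passed to [phantomSpec()].
#' @param cohortArgs named list of overrides passed to [generateCohort()].
#' @return invisibly, the list of written paths.
#' @export
runSimulate <- function(outDir, seed = 1L, specArgs = list(),
                        cohortArgs = list()) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  spec <- do.call(phantomSpec, c(specArgs, list(seed = seed)))
  ph <- generatePhantom(spec)
  paths <- c(ct = file.path(outDir, "ct.nii.gz"),
             pet = file.path(outDir, "pet.nii.gz"),
             truthCt = file.path(outDir, "truth_mask_ct.nii.gz"),
             truthPet = file.path(outDir, "truth_mask_pet.nii.gz"),
             meta = file.path(outDir, "meta.yaml"),
             config = file.path(outDir, "segmentation.yaml"),
             cohort = file.path(outDir, "cohort.csv"))
  writeVolume(ph$ct, paths["ct"])
  writeVolume(ph$pet, paths["pet"])
  writeMask(ph$truth@ctMask, paths["truthCt"])
  writeMask(ph$truth@petMask, paths["truthPet"])
  yaml::write_yaml(list(body_weight_kg = spec$bodyWeightKg,
                        injected_dose_MBq = spec$injectedDoseMBq,
                        sex = spec$sex, height_cm = spec$heightCm),
                   paths["meta"])
  .writeSegmentationConfig(phantomSegmentationConfig(spec), paths["config"])
  cohort <- do.call(generateCohort,
                    c(cohortArgs, list(seed = seed)))
  utils::write.csv(cohort, paths["cohort"], row.names = FALSE)
  .manifest(outDir, "simulate", as.list(paths), unclass(spec), seed)
  invisible(paths)
}

#' Segment a CT volume and write the label mask
#'
#' @param ctPath CT NIfTI path.
#' @param configPath segmentation YAML (see [readSegmentationConfig()]).
#' @param outDir output directory.
#' @return invisibly, list(mask = path, qc = path).
#' @export
runSegment <- function(ctPath, configPath, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  ct <- readVolume(ctPath, "CT_HU")
  config <- readSegmentationConfig(configPath)
  mask <- buildMask(ct, config)
  maskPath <- file.path(outDir, "psoas_mask_ct.nii.gz")
  qcPath <- file.path(outDir, "segmentation_qc.csv")
  writeMask(mask, maskPath)
  utils::write.csv(attr(mask, "qc"), qcPath, row.names = FALSE)
  .manifest(outDir, "segment", list(ct = ctPath, config = configPath),
            list(config = configPath))
  invisible(list(mask = maskPath, qc = qcPath))
}

#' Compute per-subject ROI metrics and write them
#'
#' @param ctPath,petPath,maskPath NIfTI inputs (PET as concentration,
#'   kBq/mL).
#' @param metaPath YAML with \code{body_weight_kg},
#'   \code{injected_dose_MBq}, \code{sex}, \code{height_cm}, optional
#'   \code{liver_suv_mean}.
#' @param outDir output directory.
#' @param liverMaskPath optional liver mask NIfTI (PET grid).
#' @param liverSphere optional numeric(4): centre (z, y, x) mm + diameter.
#' @param subjectId row label for the CSV (default "subject").
#' @param fracThreshold PET-voxel inclusion threshold (default 0.5).
#' @return the [RoiMetrics-class], invisibly.
#' @export
runMetrics <- function(ctPath, petPath, maskPath, metaPath, outDir,
                       liverMaskPath = NULL, liverSphere = NULL,
                       subjectId = "subject", fracThreshold = 0.5) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  ct <- readVolume(ctPath, "CT_HU")
  pet <- readVolume(petPath, "PET_KBQ_ML")
  mask <- readMask(maskPath, "ct")
  meta <- .readMeta(metaPath)
  suv <- computeSUV(pet, meta)
  liverMask <- if (!is.null(liverMaskPath)) readMask(liverMaskPath, "pet")
  metrics <- extractRoiMetrics(
    ct, suv, mask, meta, liverMask = liverMask,
    liverCenter = if (!is.null(liverSphere)) liverSphere[1:3],
    liverDiameterMm = if (!is.null(liverSphere)) liverSphere[4] else 30,
    fracThreshold = fracThreshold)
  df <- as.data.frame(metrics, row.names = subjectId)
  df <- cbind(subject_id = subjectId, df)
  utils::write.csv(df, file.path(outDir, "metrics.csv"), row.names = FALSE)
  jsonlite::write_json(as.list(df), file.path(outDir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  .manifest(outDir, "metrics",
            list(ct = ctPath, pet = petPath, mask = maskPath,
                 meta = metaPath),
            list(frac_threshold = fracThreshold))
  invisible(metrics)
}

#' Run the cohort survival analysis and write its tables
#'
#' @param cohortPath cohort CSV with the subject-record columns.
#' @param outDir output directory.
#' @param variables stratification variables (default
#'   [strataVariables()]).
#' @param removalP multivariate removal threshold (default 0.1).
#' @return the [outcomeTable()] result, invisibly.
#' @export
runSurvival <- function(cohortPath, outDir,
                        variables = strataVariables(), removalP = 0.1) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  records <- utils::read.csv(cohortPath)
  tab <- outcomeTable(records, variables, removalP)
  utils::write.csv(tab$univariate,
                   file.path(outDir, "outcome_univariate.csv"),
                   row.names = FALSE)
  for (v in variables) {
    ms <- medianSplit(records, v)
    km <- lapply(list(low = ms$low, high = ms$high), function(g)
      kmEstimate(g$followup_months, g$event))
    kmdf <- do.call(rbind, lapply(names(km), function(nm)
      data.frame(group = nm, time = km[[nm]]$time, surv = km[[nm]]$surv,
                 n_risk = km[[nm]]$nRisk, n_event = km[[nm]]$nEvent)))
    utils::write.csv(kmdf, file.path(outDir, paste0("km_", v, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(retained = tab$multivariate$retained,
         model = tab$multivariate$result,
         steps = tab$multivariate$steps,
         log_likelihood = tab$multivariate$logLik),
    file.path(outDir, "cox_multivariate.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  .manifest(outDir, "survival", list(cohort = cohortPath),
            list(variables = variables, removal_p = removalP))
  invisible(tab)
}

#' End-to-end pipeline on a phantom bundle
#'
#' Simulates a phantom bundle, segments the CT, extracts the ROI metrics
#' (liver reference: 30-mm sphere at the phantom's liver centre), and runs
#' the cohort survival analysis on the simulated cohort.
#'
#' @param outDir output directory.
#' @param seed RNG seed.
#' @param specArgs,cohortArgs overrides for [phantomSpec()] /
#'   [generateCohort()].
#' @return list with \code{metrics} ([RoiMetrics-class]) and
#'   \code{survival} (the [outcomeTable()] result), invisibly.
#' @export
runPipeline <- function(outDir, seed = 1L, specArgs = list(),
                        cohortArgs = list()) {
  paths <- runSimulate(outDir, seed, specArgs, cohortArgs)
  seg <- runSegment(paths["ct"], paths["config"], outDir)
  spec <- do.call(phantomSpec, c(specArgs, list(seed = seed)))
  metrics <- runMetrics(paths["ct"], paths["pet"], seg$mask,
                        paths["meta"], outDir,
                        liverSphere = c(spec$liverCenter, 30))
  surv <- runSurvival(paths["cohort"], outDir)
  invisible(list(metrics = metrics, survival = surv))
}
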