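## Orchestration: run the whole study design in silico (phantoms ->
## rescans -> segmentation -> histomorphometry + micro-FE -> statistical
## report tables) and recompute the report tables from any per-specimen
## table (e.g. the original study's raw-data sheet) with a configurable
## column mapping.

structureParams <- c("Tb.Nd", "Tb.Tm", "Tb.Sp", "Tb.Sc", "Tb.N", "Tb.Th",
                     "BVTV")

#' Study configuration
#'
#' Defaults define a scaled in-silico replica of the cadaver-study
#' design: phantoms at 0.05 mm voxels with volume fractions spanning
#' 0.05-0.45, a 4 mm trabecular analysis cube and a 2.4 mm FE cube
#' (preserving the ~8:5.3 analysis-to-FE ratio of the emulated
#' protocol), micro-CT-grade segmentation by histogram threshold and
#' clinical-grade segmentation by ARG.
#'
#' @param nSpecimens number of specimens.
#' @param phantom template [PhantomSpec-class].
#' @param fineImaging,clinicalImaging imaging specs passed to
#'   [makeSpecimenSet] (NULL = its defaults).
#' @param analysisCubeMm trabecular analysis cube side (mm).
#' @param feCubeMm FE cube side (mm); must not exceed `analysisCubeMm`.
#' @param argConfig an [ARGConfig-class].
#' @param pEnter,pRemove stepwise thresholds.
#' @param bvtvRange range of target volume fractions across specimens.
#' @param outputDir optional directory for CSV/JSON reports.
#' @param masterSeed master seed; every random stream derives from it.
#' @return a `trabeculaStudyConfig` list.
#' @export
studyConfig <- function(nSpecimens = 14L, phantom = PhantomSpec(),
                        fineImaging = NULL, clinicalImaging = NULL,
                        analysisCubeMm = 4.0, feCubeMm = 2.4,
                        argConfig = ARGConfig(), pEnter = 0.05,
                        pRemove = 0.10, bvtvRange = c(0.05, 0.45),
                        outputDir = NULL, masterSeed = 20160811L) {
  if (feCubeMm > analysisCubeMm)
    stop("feCubeMm must not exceed analysisCubeMm")
  structure(list(nSpecimens = as.integer(nSpecimens), phantom = phantom,
                 fineImaging = fineImaging,
                 clinicalImaging = clinicalImaging,
                 analysisCubeMm = analysisCubeMm, feCubeMm = feCubeMm,
                 argConfig = argConfig, pEnter = pEnter, pRemove = pRemove,
                 bvtvRange = bvtvRange, outputDir = outputDir,
                 masterSeed = as.integer(masterSeed)),
            class = "trabeculaStudyConfig")
}

metricsAsRow <- function(metrics, modality) {
  df <- as.data.frame(metrics)
  names(df) <- paste0(modality, "_", names(df))
  df
}

# CNR of a simulated scan measured against pure-phase ROIs derived from
# the ground truth at the scan's resolution
scanCnr <- function(scan, truth) {
  f <- max(1L, as.integer(round(voxelSize(scan) / voxelSize(truth))))
  frac <- blockAverage(array(as.numeric(truth@voxels), dim(truth)), f)
  d <- dim(scan@voxels)
  frac <- frac[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]
  bone <- BinaryVolume(frac == 1, voxelSize(scan))
  bg <- BinaryVolume(frac == 0, voxelSize(scan))
  if (!any(bone@voxels) || !any(bg@voxels)) return(NA_real_)
  cnr(scan, bone, bg)
}

#' Run the full in-silico study
#'
#' For every specimen: generate the ground truth and its rescans; segment
#' the fine rescan with the histogram threshold and every clinical rescan
#' with ARG; compute the seven structure parameters per modality; run
#' micro-FE homogenization on the FE cube of the fine segmentation; then
#' assemble the per-specimen table and the statistical reports
#' (correlations against the fine reference, simple regressions of E3 and
#' Gmin on every parameter, stepwise regressions, descriptive statistics,
#' and Bland-Altman agreement between repeated scans of the same
#' modality, recognized by the `_repeat` name suffix).
#'
#' @param config a [studyConfig] list.
#' @return list with `table` (wide per-specimen data.frame), `reports`
#'   (correlations, regressionE3, regressionGmin, stepwise, descriptives,
#'   blandAltman), and `manifest`. Reports are byte-identical across runs
#'   with the same config and seed.
#' @export
runStudy <- function(config = studyConfig()) {
  stopifnot(inherits(config, "trabeculaStudyConfig"))
  specimens <- makeSpecimenSet(config$nSpecimens, config$masterSeed,
                               phantom = config$phantom,
                               fineImaging = config$fineImaging,
                               clinicalImaging = config$clinicalImaging,
                               bvtvRange = config$bvtvRange)
  set.seed(config$masterSeed + 1L)
  bmd <- runif(config$nSpecimens, 0.004, 0.018)  # areal BMD analog, g/cm^2

  clinicalNames <- setdiff(names(specimens[[1]]$scans), "fine")
  rows <- vector("list", length(specimens))
  cnrLog <- list()
  for (i in seq_along(specimens)) {
    sp <- specimens[[i]]
    fineCube <- extractCube(sp$scans$fine, config$analysisCubeMm)
    microMask <- otsuSegment(fineCube)
    row <- data.frame(specimen_id = sp$id)
    row <- cbind(row, metricsAsRow(computeMetrics(microMask), "micro"))

    feMask <- extractCube(microMask, config$feCubeMm)
    stiff <- tryCatch(homogenize(buildModel(feMask)), error = function(e) e)
    if (inherits(stiff, "error")) {
      # a sparse specimen can lack a load-bearing path through the FE
      # cube; record missing mechanics rather than aborting the study
      warning(sprintf("specimen %s: micro-FE failed (%s); recording NA",
                      sp$id, conditionMessage(stiff)))
      row$fe_E3_gpa <- NA_real_
      row$fe_Gmin_gpa <- NA_real_
    } else {
      row$fe_E3_gpa <- youngsModuli(stiff)[["E3"]]
      row$fe_Gmin_gpa <- shearMin(stiff)
    }

    for (mod in clinicalNames) {
      cube <- extractCube(sp$scans[[mod]], config$analysisCubeMm)
      seg <- argSegment(cube, config$argConfig)
      row <- cbind(row, metricsAsRow(computeMetrics(seg@selectedMask), mod))
      cnrLog[[paste(sp$id, mod, sep = ":")]] <-
        scanCnr(sp$scans[[mod]], sp$truth)
    }
    row$bmd <- bmd[i]
    rows[[i]] <- row
  }
  table <- do.call(rbind, rows)

  reports <- studyReportTables(table, modalities = clinicalNames,
                               refModality = "micro",
                               e3Col = "fe_E3_gpa", gminCol = "fe_Gmin_gpa",
                               bmdCol = "bmd", pEnter = config$pEnter,
                               pRemove = config$pRemove)

  manifest <- list(
    package = "trabecula",
    version = as.character(utils::packageVersion("trabecula")),
    masterSeed = config$masterSeed,
    nSpecimens = config$nSpecimens,
    phantom = list(sideMm = config$phantom@sideMm,
                   fineVoxelMm = config$phantom@fineVoxelMm,
                   thicknessScaleMm = config$phantom@thicknessScaleMm,
                   anisotropy = config$phantom@anisotropy),
    analysisCubeMm = config$analysisCubeMm, feCubeMm = config$feCubeMm,
    specimenSeeds = vapply(specimens, function(s) s$spec@seed, integer(1)),
    targetBvtv = vapply(specimens, function(s) s$spec@targetBvtv, numeric(1)),
    cnr = unlist(cnrLog),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(table, file.path(config$outputDir, "specimen_table.csv"),
              row.names = FALSE)
    for (nm in names(reports))
      if (is.data.frame(reports[[nm]]))
        write.csv(reports[[nm]],
                  file.path(config$outputDir, paste0(nm, ".csv")),
                  row.names = FALSE)
    jsonlite::write_json(manifest,
                         file.path(config$outputDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(table = table, reports = reports, manifest = manifest,
       specimens = specimens)
}

# the statistical report tables shared by runStudy and
# reproduceStudyTables
studyReportTables <- function(table, modalities, refModality, e3Col,
                              gminCol, bmdCol = NULL, pEnter = 0.05,
                              pRemove = 0.10, params = structureParams) {
  colOf <- function(mod, par) table[[paste0(mod, "_", par)]]

  corr <- do.call(rbind, lapply(modalities, function(mod) {
    do.call(rbind, lapply(params, function(par) {
      pc <- pearsonCi(colOf(mod, par), colOf(refModality, par))
      data.frame(modality = mod, parameter = par, r = pc$r,
                 ci_low = pc$ciLow, ci_high = pc$ciHigh, n = pc$n)
    }))
  }))

  regTable <- function(yCol) {
    mods <- c(modalities, refModality)
    do.call(rbind, lapply(mods, function(mod) {
      do.call(rbind, lapply(params, function(par) {
        sr <- simpleRegression(colOf(mod, par), table[[yCol]])
        data.frame(modality = mod, parameter = par, r2 = sr$r2, p = sr$p,
                   n = sr$n)
      }))
    }))
  }
  regE3 <- regTable(e3Col)
  regGmin <- regTable(gminCol)

  stepTable <- do.call(rbind, lapply(c(modalities, refModality),
                                     function(mod) {
    X <- as.data.frame(lapply(params, function(par) colOf(mod, par)))
    names(X) <- params
    do.call(rbind, lapply(c(e3Col, gminCol), function(yCol) {
      st <- stepwiseRegression(X, table[[yCol]], pEnter, pRemove)
      data.frame(modality = mod,
                 outcome = if (yCol == e3Col) "E3" else "Gmin",
                 single_predictor = if (st$empty) NA_character_ else
                   st$selected[1],
                 r2_single = st$r2Single,
                 two_predictors = if (length(st$selected) >= 2)
                   paste(st$selected[1:2], collapse = "+") else NA_character_,
                 adj_r2_two = st$adjR2Two, n = st$n)
    }))
  }))
  if (!is.null(bmdCol) && bmdCol %in% names(table)) {
    bmdRows <- do.call(rbind, lapply(c(e3Col, gminCol), function(yCol) {
      sr <- simpleRegression(table[[bmdCol]], table[[yCol]])
      data.frame(modality = "DXA",
                 outcome = if (yCol == e3Col) "E3" else "Gmin",
                 single_predictor = "BMD", r2_single = sr$r2,
                 two_predictors = NA_character_, adj_r2_two = NA_real_,
                 n = sr$n)
    }))
    stepTable <- rbind(stepTable, bmdRows)
  }

  desc <- do.call(rbind, lapply(c(modalities, refModality), function(mod) {
    do.call(rbind, lapply(params, function(par) {
      v <- colOf(mod, par)
      data.frame(modality = mod, parameter = par, mean = mean(v),
                 sd = sd(v), n = length(v))
    }))
  }))

  ba <- NULL
  repeats <- grep("_repeat$", modalities, value = TRUE)
  for (rep in repeats) {
    base <- sub("_repeat$", "", rep)
    if (!base %in% modalities) next
    ba <- rbind(ba, do.call(rbind, lapply(params, function(par) {
      b <- blandAltman(colOf(rep, par), colOf(base, par))
      data.frame(modality = base, parameter = par, bias = b$bias,
                 loa_low = b$loa[["lower"]], loa_high = b$loa[["upper"]],
                 systematic = b$systematic, n = b$n)
    })))
  }

  list(correlations = corr, regressionE3 = regE3, regressionGmin = regGmin,
       stepwise = stepTable, descriptives = desc, blandAltman = ba)
}

#' Recompute the study's report tables from a per-specimen table
#'
#' Takes a per-specimen table of structure parameters (one column per
#' modality x parameter), FE outcomes and optionally BMD -- either a
#' data.frame or a CSV/XLSX path -- and recomputes the four report
#' tables: Pearson correlations of every clinical modality against the
#' reference modality, simple regressions of stiffness (E3) and minimum
#' shear on every parameter, stepwise multiple regressions, and
#' descriptive statistics. When a reference table of printed values is
#' supplied, a side-by-side comparison with two-decimal pass/fail is
#' appended.
#'
#' @param table data.frame, or path to a CSV or XLSX file (XLSX needs the
#'   readxl package).
#' @param modalities clinical modality column prefixes.
#' @param refModality reference modality prefix (default "micro").
#' @param e3Col,gminCol,bmdCol outcome/BMD column names.
#' @param columnMap optional named character vector renaming input
#'   columns (`c(new = old, ...)`) before the prefixes are applied, so
#'   arbitrary sheet layouts can be mapped.
#' @param reference optional data.frame of printed values with columns
#'   `table`, `modality`, `parameter`, `statistic`, `printed` (see
#'   `system.file("extdata", "reference_study_tables.csv", package =
#'   "trabecula")` for the layout).
#' @param pEnter,pRemove stepwise thresholds.
#' @return list of report data.frames; with `reference`, also
#'   `comparison` (recomputed vs printed, `pass` at two-decimal
#'   rounding).
#' @export
reproduceStudyTables <- function(table, modalities, refModality = "micro",
                                 e3Col = "fe_E3_gpa",
                                 gminCol = "fe_Gmin_gpa", bmdCol = NULL,
                                 columnMap = NULL, reference = NULL,
                                 pEnter = 0.05, pRemove = 0.10) {
  if (is.character(table)) {
    path <- table
    if (grepl("\\.xlsx$", path)) {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop("reading XLSX requires the readxl package")
      table <- as.data.frame(readxl::read_excel(path))
    } else {
      table <- read.csv(path, check.names = FALSE)
    }
  }
  if (!is.null(columnMap)) {
    missing <- setdiff(unname(columnMap), names(table))
    if (length(missing) > 0)
      stop("column mapping refers to absent columns: ",
           paste(missing, collapse = ", "))
    for (new in names(columnMap))
      names(table)[names(table) == columnMap[[new]]] <- new
  }
  needed <- c(paste0(rep(c(modalities, refModality),
                         each = length(structureParams)), "_",
                     structureParams), e3Col, gminCol)
  missing <- setdiff(needed, names(table))
  if (length(missing) > 0)
    stop("missing columns (supply a columnMap): ",
         paste(missing, collapse = ", "))

  reports <- studyReportTables(table, modalities, refModality, e3Col,
                               gminCol, bmdCol, pEnter, pRemove)
  if (!is.null(reference))
    reports$comparison <- compareToReference(reports, reference)
  reports
}

# side-by-side recomputed vs printed values, pass/fail at two decimals
compareToReference <- function(reports, reference) {
  lookup <- function(tab, mod, par, stat) {
    val <- switch(tab,
      correlations = {
        r <- reports$correlations
        r[[stat]][r$modality == mod & r$parameter == par]
      },
      regressionE3 = {
        r <- reports$regressionE3
        r[[stat]][r$modality == mod & r$parameter == par]
      },
      regressionGmin = {
        r <- reports$regressionGmin
        r[[stat]][r$modality == mod & r$parameter == par]
      },
      stepwise = {
        r <- reports$stepwise
        r[[stat]][r$modality == mod & r$outcome == par]
      },
      descriptives = {
        r <- reports$descriptives
        r[[stat]][r$modality == mod & r$parameter == par]
      },
      NA_real_)
    if (length(val) != 1) NA_real_ else val
  }
  reference$recomputed <- mapply(lookup, reference$table,
                                 reference$modality, reference$parameter,
                                 reference$statistic)
  reference$pass <- !is.na(reference$recomputed) &
    abs(round(reference$recomputed, 2) - reference$printed) < 0.005 + 1e-9
  reference
}
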