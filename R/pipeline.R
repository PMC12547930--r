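#' Extract scan-level features for a whole cohort
#'
#' Runs [scanFeatures] over every scan of an in-memory cohort (from
#' [generateCohort]) or of a cohort loaded from a manifest directory.
#'
#' @param cohort in-memory cohort list, or a manifest CSV path.
#' @param ng grey level count for discretisation.
#' @return list with `features` (scans x 118 matrix), `info` (data.frame:
#'   patient_id, modality, fraction_index, n_subimages) and `records`.
#' @export
extractCohortFeatures <- function(cohort, ng = 8L) {
  if (is.character(cohort)) {
    man <- readCohortManifest(cohort)
    reg <- man$registry
    rows <- vector("list", nrow(reg))
    info <- reg[, c("patient_id", "modality", "fraction_index")]
    info$n_subimages <- 0L
    contourCache <- new.env()
    for (i in seq_len(nrow(reg))) {
      scan <- readScan(reg$path[i], patientId = reg$patient_id[i],
                       modality = reg$modality[i],
                       fractionIndex = reg$fraction_index[i])
      cf <- reg$contour_file[i]
      if (is.null(contourCache[[cf]])) contourCache[[cf]] <- readContours(cf)
      v <- scanFeatures(scan, contourCache[[cf]], ng)
      rows[[i]] <- v
      info$n_subimages[i] <- attr(v, "nSubimages")
    }
    records <- man$records
  } else {
    rows <- list(); infoRows <- list()
    for (p in cohort$patients) {
      for (key in names(p$scans)) {
        scan <- p$scans[[key]]
        v <- scanFeatures(scan, p$contours[[key]], ng)
        rows[[length(rows) + 1]] <- v
        infoRows[[length(infoRows) + 1]] <- data.frame(
          patient_id = scan@patientId, modality = scan@modality,
          fraction_index = scan@fractionIndex,
          n_subimages = attr(v, "nSubimages"), stringsAsFactors = FALSE)
      }
    }
    info <- do.call(rbind, infoRows)
    records <- cohort$records
  }
  list(features = do.call(rbind, rows), info = info, records = records)
}

#' Default pipeline configuration
#'
#' All modelling defaults follow the reference analysis settings: 75:25
#' stratified split, z-scoring with training parameters, |rho| >= 0.8
#' Spearman pruning, elastic net with L1 ratio 0.5 and C tuned over
#' 10^-4..10^3 (500 log-spaced points) by 5-fold CV, 100 bootstrap samples,
#' alpha = 0.05 for time-point comparisons. Every value can be overridden.
#'
#' @param ... overrides of the default entries.
#' @return named list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    ng = 8L,
    trainFraction = 0.75,
    cGridRange = c(1e-4, 1e3),
    cGridPoints = 500L,
    l1Ratio = 0.5,
    folds = 5L,
    bootB = 100L,
    rhoThreshold = 0.8,
    alpha = 0.05,
    modes = c("separate", "cumulative"),
    simulate = list(),   # syntheticCohortSpec() overrides; NULL = no simulate
    inputDir = NULL,     # manifest.csv directory when not simulating
    makePlots = TRUE)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

configHash <- function(cfg) {
  f <- tempfile()
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = I(10),
                              null = "null", force = TRUE), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> extract -> aggregate -> model ->
#' report. Patients are stratified by prescription regimen; within each
#' regimen, a separate-mode sweep across time points is run and (if
#' requested) a cumulative-mode sweep built on its pruned selections, the
#' optimal re-planning week is selected, and per-regimen report tables are
#' written. All randomness derives from the single master seed in the
#' config, so a rerun with identical config is identical in all tables.
#'
#' @param config list from [pipelineConfig] or a YAML/JSON config file path.
#' @param outDir run directory for artefacts (created).
#' @param cohort optionally a pre-built in-memory cohort (skips
#'   simulate/load).
#' @return invisible list: per-regimen list of sweeps (`separate`,
#'   `cumulative`), `optimal` selections per regimen and mode, paths of
#'   written artefacts.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir, cohort = NULL) {
  if (is.character(config)) {
    cfg <- pipelineConfig()
    over <- yaml::read_yaml(config)
    cfg[names(over)] <- over
    config <- cfg
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  failed <- file.path(outDir, "FAILED")
  on.exit(if (!file.exists(file.path(outDir, "run_manifest.json")))
    writeLines("pipeline did not complete", failed))

  # simulate or load
  if (is.null(cohort)) {
    if (!is.null(config$inputDir)) {
      cohort <- file.path(config$inputDir, "manifest.csv")
    } else {
      simArgs <- config$simulate
      simArgs$seed <- deriveSeed(config$seed, 1)
      spec <- do.call(syntheticCohortSpec, simArgs)
      cohort <- generateCohort(spec)
    }
  }

  ex <- extractCohortFeatures(cohort, ng = config$ng)
  records <- ex$records

  # persist feature tables (tidy + wide)
  tidy <- data.frame(
    patient_id = rep(ex$info$patient_id, each = ncol(ex$features)),
    modality = rep(ex$info$modality, each = ncol(ex$features)),
    fraction_index = rep(ex$info$fraction_index, each = ncol(ex$features)),
    feature = rep(colnames(ex$features), nrow(ex$features)),
    value = as.vector(t(ex$features)))
  write.csv(tidy, file.path(outDir, "scan_features_tidy.csv"),
            row.names = FALSE)
  write.csv(cbind(ex$info, ex$features),
            file.path(outDir, "scan_features_wide.csv"), row.names = FALSE)

  cGrid <- 10^seq(log10(config$cGridRange[1]), log10(config$cGridRange[2]),
                  length.out = config$cGridPoints)
  sweeps <- list(); optimal <- list()
  for (regimen in unique(records$regimen)) {
    recs <- records[records$regimen == regimen, , drop = FALSE]
    keep <- ex$info$patient_id %in% recs$patient_id
    table <- buildWeekTable(ex$features[keep, , drop = FALSE],
                            ex$info[keep, , drop = FALSE], recs)
    split <- splitCohort(recs, config$trainFraction,
                         seed = deriveSeed(config$seed, 2))
    sw <- list()
    if ("separate" %in% config$modes || "cumulative" %in% config$modes) {
      sw$separate <- sweepTimepoints(table, recs, split, "separate",
        cGrid = cGrid, l1Ratio = config$l1Ratio, folds = config$folds,
        bootB = config$bootB, rhoThreshold = config$rhoThreshold,
        seed = deriveSeed(config$seed, 3))
    }
    if ("cumulative" %in% config$modes) {
      sw$cumulative <- sweepTimepoints(table, recs, split, "cumulative",
        selections = sw$separate@selections, cGrid = cGrid,
        l1Ratio = config$l1Ratio, folds = config$folds,
        bootB = config$bootB, rhoThreshold = config$rhoThreshold,
        seed = deriveSeed(config$seed, 4))
    }
    sweeps[[regimen]] <- sw
    for (mode in names(sw)) {
      if (!mode %in% config$modes) next
      opt <- selectOptimalWeek(sw[[mode]], alpha = config$alpha)
      optimal[[paste(regimen, mode, sep = ".")]] <- opt
      writeSweepReport(sw[[mode]], records = recs,
        file.path(outDir, sprintf("models_%s_%s", regimen, mode)),
        optimal = opt)
      if (isTRUE(config$makePlots))
        plotSweepAuc(sw[[mode]],
          file.path(outDir, sprintf("auc_%s_%s.png", regimen, mode)))
    }
  }

  manifest <- list(config = config[setdiff(names(config), "simulate")],
                   simulate = config$simulate,
                   config_hash = configHash(config),
                   seed = config$seed,
                   n_patients = nrow(records),
                   catalogue_version = "118-feature IBSI-style v1",
                   optimal = lapply(optimal, function(o)
                     o[c("timePoint", "weekIndex", "annotation")]))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = I(10), null = "null", force = TRUE),
             file.path(outDir, "run_manifest.json"))
  if (file.exists(failed)) file.remove(failed)
  invisible(list(sweeps = sweeps, optimal = optimal, outDir = outDir))
}

#' Write the report tables for one sweep
#'
#' Produces `<stem>.csv` (per-time-point metrics), `<stem>_coefficients.csv`
#' (non-zero coefficients with Wald p-values from an unpenalised refit on
#' the selected support) and `<stem>.md` (a Markdown summary table with
#' train/test AUC, 95% CIs, sensitivity/specificity at the Youden threshold
#' and the highest comparison p-value against other time points).
#'
#' @param sweep a [TimepointSweep].
#' @param records cohort records for the regimen (used for the refit).
#' @param stem output path stem (no extension).
#' @param optimal optional [selectOptimalWeek] result to annotate.
#' @return invisible character vector of written paths.
#' @export
writeSweepReport <- function(sweep, records, stem, optimal = NULL) {
  ok <- sweep@timePoints[vapply(sweep@timePoints, function(tp)
    !is.null(sweep@models[[tp]]), logical(1))]
  rows <- lapply(ok, function(tp) {
    m <- sweep@models[[tp]]
    cmp <- sweep@comparisons
    highTrain <- suppressWarnings(max(cmp$train_p[cmp$b == tp], na.rm = TRUE))
    highTest <- suppressWarnings(max(cmp$test_p[cmp$b == tp], na.rm = TRUE))
    data.frame(time_point = tp, n_features = length(m@features),
               n_nonzero = sum(m@coefficients[-1] != 0),
               C = m@cSelected,
               train_auc = m@train$auc, train_lo = m@train$ci[1],
               train_hi = m@train$ci[2], train_sen = m@train$sensitivity,
               train_spe = m@train$specificity,
               test_auc = m@test$auc, test_lo = m@test$ci[1],
               test_hi = m@test$ci[2], test_sen = m@test$sensitivity,
               test_spe = m@test$specificity,
               highest_p_train = highTrain, highest_p_test = highTest)
  })
  tab <- do.call(rbind, rows)
  csv <- paste0(stem, ".csv")
  write.csv(tab, csv, row.names = FALSE)
  coefTab <- do.call(rbind, lapply(ok, function(tp)
    cbind(time_point = tp, sweep@models[[tp]]@train$wald)))
  coefCsv <- paste0(stem, "_coefficients.csv")
  write.csv(coefTab, coefCsv, row.names = FALSE)
  md <- paste0(stem, ".md")
  lines <- c(sprintf("# %s analysis", sweep@mode), "",
    "| Time point | Train AUC (95% CI) | Train SEN | Train SPE | Test AUC (95% CI) | Test SEN | Test SPE | Highest p (train) |",
    "|---|---|---|---|---|---|---|---|")
  for (i in seq_len(nrow(tab)))
    lines <- c(lines, sprintf(
      "| %s | %.3f (%.3f-%.3f) | %.3f | %.3f | %.3f (%.3f-%.3f) | %.3f | %.3f | %.3g |",
      tab$time_point[i], tab$train_auc[i], tab$train_lo[i], tab$train_hi[i],
      tab$train_sen[i], tab$train_spe[i], tab$test_auc[i], tab$test_lo[i],
      tab$test_hi[i], tab$test_sen[i], tab$test_spe[i],
      tab$highest_p_train[i]))
  if (!is.null(optimal))
    lines <- c(lines, "", sprintf(
      "Optimal re-planning time point: **%s**%s", optimal$timePoint,
      if (!is.na(optimal$annotation))
        paste0(" (", optimal$annotation, ")") else ""))
  writeLines(lines, md)
  invisible(c(csv, md))
}

#' Plot training/test AUC across time points
#'
#' @param sweep a [TimepointSweep].
#' @param path PNG output path.
#' @return invisibly `path`.
#' @export
plotSweepAuc <- function(sweep, path) {
  ok <- sweep@timePoints[vapply(sweep@timePoints, function(tp)
    !is.null(sweep@models[[tp]]), logical(1))]
  tr <- vapply(ok, function(tp) sweep@models[[tp]]@train$auc, numeric(1))
  te <- vapply(ok, function(tp) sweep@models[[tp]]@test$auc, numeric(1))
  lo <- vapply(ok, function(tp) sweep@models[[tp]]@train$ci[1], numeric(1))
  hi <- vapply(ok, function(tp) sweep@models[[tp]]@train$ci[2], numeric(1))
  grDevices::png(path, width = 900, height = 600, res = 120)
  on.exit(grDevices::dev.off())
  x <- seq_along(ok)
  graphics::plot(x, tr, type = "b", pch = 19, ylim = c(0.3, 1),
                 xaxt = "n", xlab = "time point", ylab = "AUC",
                 main = sprintf("%s analysis", sweep@mode))
  graphics::axis(1, at = x, labels = ok)
  graphics::arrows(x, lo, x, hi, angle = 90, code = 3, length = 0.03)
  graphics::lines(x, te, type = "b", pch = 1, lty = 2, col = "grey40")
  graphics::legend("bottomright", c("train", "test"), pch = c(19, 1),
                   lty = c(1, 2), col = c("black", "grey40"), bty = "n")
  graphics::abline(h = 0.5, lty = 3)
  invisible(path)
}
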