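#' Average feature vectors over subimages or scans
#'
#' Element-wise arithmetic mean of a set of feature vectors (rows of a
#' matrix or a list of equal-length named vectors).
#'
#' @param features an n x p matrix of feature vectors, or a list of vectors.
#' @return the mean feature vector (named as the input columns).
#' @export
aggregateScan <- function(features) {
  if (is.list(features) && !is.data.frame(features))
    features <- do.call(rbind, features)
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (nrow(features) == 0) stop("cannot aggregate an empty feature set")
  colMeans(features)
}

#' Map a fraction index to its treatment week
#'
#' 37-fraction courses run over 7 weeks (weeks 1-6 cover fractions
#' 5(k-1)+1..5k, week 7 covers fractions 31-37); 20-fraction courses run
#' over 4 weeks of 5 fractions each.
#'
#' @param fraction integer fraction index (vectorised).
#' @param regimen `"74Gy_37F"` or `"60Gy_20F"`.
#' @return integer week index.
#' @export
fractionToWeek <- function(fraction, regimen) {
  nf <- regimenFractions(regimen)
  if (any(fraction < 1 | fraction > nf))
    stop("fraction index out of range 1..", nf, " for ", regimen)
  fraction <- as.integer(fraction)
  pmin((fraction - 1L) %/% 5L + 1L, nWeeks(regimen))
}

#' @rdname fractionToWeek
#' @export
regimenFractions <- function(regimen) {
  switch(regimen, "74Gy_37F" = 37L, "60Gy_20F" = 20L,
         stop("unknown regimen: ", regimen))
}

#' @rdname fractionToWeek
#' @export
nWeeks <- function(regimen) {
  switch(regimen, "74Gy_37F" = 7L, "60Gy_20F" = 4L,
         stop("unknown regimen: ", regimen))
}

#' Build the patient x time-point feature table
#'
#' Aggregates scan-level feature vectors to weekly time points: the week
#' value is the mean of the patient's scan vectors whose fractions map to
#' that week; the `CT` column is the planning-scan vector. Returned as a
#' `SummarizedExperiment` with features as rows and one column per available
#' (patient, time point) cell; cells with no scans are simply absent and
#' listed in `metadata(x)$roster`.
#'
#' @param scanFeatures numeric matrix, scans x features.
#' @param scanInfo data.frame aligned with `scanFeatures` rows, columns
#'   `patient_id`, `modality`, `fraction_index`.
#' @param records cohort records data.frame (`patient_id`, `regimen`).
#' @return a [SummarizedExperiment::SummarizedExperiment].
#' @export
buildWeekTable <- function(scanFeatures, scanInfo, records) {
  stopifnot(nrow(scanFeatures) == nrow(scanInfo))
  regimen <- records$regimen[match(scanInfo$patient_id, records$patient_id)]
  tp <- rep("CT", nrow(scanInfo))
  mv <- scanInfo$modality == "mvct"
  tp[mv] <- paste0("W", mapply(fractionToWeek, scanInfo$fraction_index[mv],
                               regimen[mv]))
  key <- paste(scanInfo$patient_id, tp, sep = "|")
  groups <- split(seq_len(nrow(scanFeatures)), key)
  vals <- vapply(groups, function(ix)
    aggregateScan(scanFeatures[ix, , drop = FALSE]),
    numeric(ncol(scanFeatures)))
  parts <- do.call(rbind, strsplit(names(groups), "|", fixed = TRUE))
  cd <- S4Vectors::DataFrame(
    patient_id = parts[, 1], time_point = parts[, 2],
    n_scans = vapply(groups, length, integer(1)))
  # roster of missing (patient, week) cells
  allTp <- lapply(seq_len(nrow(records)), function(i)
    c("CT", paste0("W", seq_len(nWeeks(records$regimen[i])))))
  expected <- data.frame(
    patient_id = rep(records$patient_id, lengths(allTp)),
    time_point = unlist(allTp), stringsAsFactors = FALSE)
  haveKey <- paste(cd$patient_id, cd$time_point)
  roster <- expected[!paste(expected$patient_id, expected$time_point)
                     %in% haveKey, , drop = FALSE]
  if (nrow(roster) > 0)
    message(nrow(roster), " missing (patient, time point) cell(s); ",
            "affected patients are dropped from models at those time points")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = vals), colData = cd)
  S4Vectors::metadata(se)$roster <- roster
  se
}

tpOrder <- function(tp) {
  out <- integer(length(tp))
  w <- tp != "CT"
  out[w] <- as.integer(sub("W", "", tp[w]))
  out
}

#' Assemble a model design matrix for one time point
#'
#' Separate mode returns the full feature block of the requested time point
#' (columns named `"TP:FEATURE"`). Cumulative mode at week w returns the
#' union of the separate-analysis pruned selections at CT and weeks 1..w,
#' which must be supplied via `selections`; the cumulative column set is
#' therefore monotone non-decreasing in w. Patients lacking any required
#' cell are dropped (with a message).
#'
#' @param table `SummarizedExperiment` from [buildWeekTable].
#' @param timePoint e.g. `"CT"`, `"W1"`.
#' @param mode `"separate"` or `"cumulative"`.
#' @param selections named list of prefixed feature names per time point
#'   (cumulative mode only), as produced by the separate-mode sweep.
#' @return numeric matrix, patients x features, rownames = patient ids.
#' @export
assembleDesign <- function(table, timePoint, mode = c("separate", "cumulative"),
                           selections = NULL) {
  mode <- match.arg(mode)
  cd <- SummarizedExperiment::colData(table)
  av <- SummarizedExperiment::assay(table, "features")
  if (mode == "separate") {
    need <- timePoint
    cols <- lapply(need, function(tp) {
      m <- t(av[, cd$time_point == tp, drop = FALSE])
      rownames(m) <- cd$patient_id[cd$time_point == tp]
      colnames(m) <- paste0(tp, ":", rownames(av))
      m
    })
  } else {
    if (is.null(selections))
      stop("cumulative mode requires the separate-analysis selections; ",
           "run the separate sweep first")
    need <- names(selections)[tpOrder(names(selections)) <=
                                tpOrder(timePoint)]
    if (!timePoint %in% need)
      stop("no separate-analysis selection available for ", timePoint)
    cols <- lapply(need, function(tp) {
      feats <- sub("^[^:]+:", "", selections[[tp]])
      m <- t(av[feats, cd$time_point == tp, drop = FALSE])
      rownames(m) <- cd$patient_id[cd$time_point == tp]
      colnames(m) <- paste0(tp, ":", feats)
      m
    })
  }
  ids <- Reduce(intersect, lapply(cols, rownames))
  full <- unique(unlist(lapply(cols, rownames)))
  if (length(ids) < length(full))
    message(length(full) - length(ids), " patient(s) dropped at ",
            timePoint, " (", mode, "): missing time-point cells")
  do.call(cbind, lapply(cols, function(m) m[ids, , drop = FALSE]))
}
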