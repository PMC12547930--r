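#' Specification of a synthetic phantom cohort
#'
#' Defines the statistical structure of a simulated prostate-radiotherapy
#' cohort: the regimen mix and endpoint prevalence mirror a two-regimen
#' cohort (59% receiving 74 Gy / 37 fractions, 41% receiving 60 Gy / 20
#' fractions, 33% grade >= 1 rectal bleeding), while the imaging model is a
#' stylised pelvic slice: a uniform background, an annular rectal wall whose
#' texture is a spatially correlated Gaussian field, and a darker lumen.
#' Daily (MVCT-like) images carry more acquisition noise than the planning
#' image. In endpoint-positive patients the wall-texture variance is
#' multiplied by `1 + delta * ramp(week)` with
#' `ramp(w) = min(1, max(0, (w - onsetWeek + 1) / 2))`: the effect appears
#' at `onsetWeek` and saturates one week later. The planning CT uses week-0
#' texture (no effect).
#'
#' @param nPatients cohort size.
#' @param regimenMix proportion on the 37-fraction regimen (default 0.59).
#' @param prevalence endpoint prevalence (default 0.33).
#' @param shape slice grid (rows, cols), default 64 x 64.
#' @param nSlices slices per scan (default 5).
#' @param radiusRange per-patient outer rectum radius range in px.
#' @param muWall,muBg,muLumen mean intensities (HU-like) of wall band,
#'   background and lumen.
#' @param sigmaCt,sigmaMvct acquisition noise SD of planning and daily
#'   images (sigmaMvct >= sigmaCt).
#' @param sigmaTexture cohort-median baseline SD of the wall texture field.
#' @param texturePatientSdLog between-patient biological variability of the
#'   baseline texture SD: each patient's SD is
#'   `sigmaTexture * exp(N(0, texturePatientSdLog))`.
#' @param corLength texture correlation length in px (Gaussian smoothing).
#' @param delta effect size: relative wall-texture variance shift (in units
#'   of the baseline variance) separating outcome classes at full ramp.
#' @param onsetWeek first week at which the effect appears.
#' @param maxFractions optionally truncate each regimen's fraction count
#'   (problem-size control for small studies); `NULL` = full course.
#' @param seed master seed.
#' @return a `SyntheticCohortSpec` (validated list).
#' @export
syntheticCohortSpec <- function(nPatients = 120, regimenMix = 0.59,
                                prevalence = 0.33, shape = c(64L, 64L),
                                nSlices = 5L, radiusRange = c(8, 14),
                                muWall = 60, muBg = 0, muLumen = 20,
                                sigmaCt = 5, sigmaMvct = 15,
                                sigmaTexture = 35,
                                texturePatientSdLog = 0.15, corLength = 2,
                                delta = 1, onsetWeek = 1,
                                maxFractions = NULL, seed = 1L) {
  spec <- list(nPatients = as.integer(nPatients), regimenMix = regimenMix,
               prevalence = prevalence, shape = as.integer(shape),
               nSlices = as.integer(nSlices), radiusRange = radiusRange,
               muWall = muWall, muBg = muBg, muLumen = muLumen,
               sigmaCt = sigmaCt, sigmaMvct = sigmaMvct,
               sigmaTexture = sigmaTexture,
               texturePatientSdLog = texturePatientSdLog,
               corLength = corLength,
               delta = delta, onsetWeek = onsetWeek,
               maxFractions = maxFractions, seed = as.integer(seed))
  if (spec$prevalence <= 0 || spec$prevalence >= 1)
    stop("prevalence must be in (0, 1)")
  if (spec$sigmaMvct < spec$sigmaCt) stop("sigmaMvct must be >= sigmaCt")
  if (spec$delta < 0) stop("delta must be >= 0")
  if (spec$onsetWeek < 1) stop("onsetWeek must be >= 1")
  class(spec) <- "SyntheticCohortSpec"
  spec
}

rampEffect <- function(week, onsetWeek) {
  pmin(1, pmax(0, (week - onsetWeek + 1) / 2))
}

# spatially correlated Gaussian field (white noise smoothed with a Gaussian
# kernel of SD corLength)
correlatedField <- function(nr, nc, corLength) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  if (corLength <= 0) return(z)
  EBImage::gblur(z, sigma = corLength)
}

# one elliptical rectum contour, 0-based (row, col) pixel coordinates
rectumContour <- function(centre, radiusRow, radiusCol, sliceIndex,
                          nVertices = 48) {
  th <- seq(0, 2 * pi, length.out = nVertices + 1)[-(nVertices + 1)]
  ContourPolygon(cbind(centre[1] + radiusRow * sin(th),
                       centre[2] + radiusCol * cos(th)), sliceIndex)
}

# paint one slice: background + lumen + wall band with correlated texture
paintSlice <- function(spec, mask, varMult, sigmaMod, sigmaTexture) {
  nr <- nrow(mask); nc <- ncol(mask)
  wall <- suppressWarnings(buildWallRing(mask))
  img <- matrix(spec$muBg, nr, nc)
  img[mask] <- spec$muLumen
  # standardise the correlated field over the wall band so the realised
  # wall-texture variance equals the design value exactly (the smoothed
  # field has few effective degrees of freedom, so its raw variance would
  # fluctuate strongly from scan to scan)
  tex <- correlatedField(nr, nc, spec$corLength)
  tw <- tex[wall@wallMask]
  if (length(tw) > 1 && stats::sd(tw) > 0)
    tex <- (tex - mean(tw)) / stats::sd(tw)
  img[wall@wallMask] <- spec$muWall +
    tex[wall@wallMask] * sigmaTexture * sqrt(varMult)
  img + matrix(rnorm(nr * nc, 0, sigmaMod), nr, nc)
}

#' Generate one synthetic patient
#'
#' Builds the planning CT, the per-fraction MVCT-like scans, the per-slice
#' rectum contours, and the outcome record for a single patient. The rectum
#' is an ellipse with a per-patient outer radius, mild per-fraction centre
#' and radius jitter, and per-slice radius variation. Deterministic given
#' `patientSeed`.
#'
#' @param spec a [syntheticCohortSpec].
#' @param patientSeed integer seed for this patient's random stream.
#' @param patientId patient identifier.
#' @param regimen `"74Gy_37F"` or `"60Gy_20F"`.
#' @param label binary endpoint (1 = grade >= 1 bleeding).
#' @return list with `record` (1-row data.frame), `scans` (list of
#'   [ScanSeries]: planning first, then fractions), `contours` (named list
#'   of per-scan contour lists).
#' @export
generatePatient <- function(spec, patientSeed, patientId, regimen, label) {
  set.seed(patientSeed)
  nr <- spec$shape[1]; nc <- spec$shape[2]
  centre0 <- c(nr, nc) / 2 - 0.5
  rPat <- runif(1, spec$radiusRange[1], spec$radiusRange[2])
  # per-patient baseline texture SD (biological between-patient variability)
  sigmaPat <- spec$sigmaTexture * exp(rnorm(1, 0, spec$texturePatientSdLog))
  # keep the full window band inside the slice; shrink if needed (logged)
  maxR <- min(nr, nc) / 2 - 9
  if (rPat > maxR) {
    message("patient ", patientId, ": radius shrunk to fit the slice")
    rPat <- maxR
  }
  nf <- regimenFractions(regimen)
  if (!is.null(spec$maxFractions)) nf <- min(nf, spec$maxFractions)

  makeScan <- function(modality, fractionIndex, week) {
    varMult <- if (label == 1)
      1 + spec$delta * rampEffect(week, spec$onsetWeek) else 1
    sigmaMod <- if (modality == "planning_ct") spec$sigmaCt else
      spec$sigmaMvct
    jitter <- if (modality == "planning_ct") c(0, 0) else rnorm(2, 0, 0.7)
    rFrac <- rPat + if (modality == "planning_ct") 0 else rnorm(1, 0, 0.4)
    rFrac <- max(3, min(rFrac, maxR))
    ecc <- runif(1, 0.9, 1.1)
    sl <- list(); ct <- list()
    for (k in seq_len(spec$nSlices)) {
      rSlice <- max(3, rFrac * (1 + rnorm(1, 0, 0.03)))
      poly <- rectumContour(centre0 + jitter, rSlice * ecc, rSlice / ecc, k)
      mask <- rasteriseContour(poly, c(nr, nc))
      sl[[k]] <- SliceImage(paintSlice(spec, mask, varMult, sigmaMod,
                                       sigmaPat), sliceIndex = k)
      ct[[k]] <- poly
    }
    list(scan = ScanSeries(patientId, modality, sl, fractionIndex),
         contours = ct)
  }

  scans <- list(); contours <- list()
  p <- makeScan("planning_ct", NA_integer_, 0)
  scans[["planning"]] <- p$scan; contours[["planning"]] <- p$contours
  for (f in seq_len(nf)) {
    wk <- fractionToWeek(f, regimen)
    m <- makeScan("mvct", f, wk)
    key <- paste0("f", f)
    scans[[key]] <- m$scan; contours[[key]] <- m$contours
  }
  grade <- if (label == 1) sample(1:3, 1, prob = c(0.66, 0.29, 0.05)) else 0L
  list(record = data.frame(patient_id = patientId, regimen = regimen,
                           endpoint_grade = as.integer(grade),
                           endpoint_binary = as.integer(label),
                           stringsAsFactors = FALSE),
       scans = scans, contours = contours)
}

#' Generate a synthetic cohort
#'
#' Assigns regimens (`round(regimenMix * n)` patients on the 37-fraction
#' course, shuffled), draws Bernoulli(prevalence) endpoint labels, and
#' generates every patient from an independent derived seed. With `dir`
#' given, all scans are written as NIfTI files, contours as JSON and the
#' manifest as CSV, in exactly the formats [readCohortManifest] and
#' [readScan] consume; otherwise the cohort is returned in memory.
#'
#' @param spec a [syntheticCohortSpec].
#' @param dir output directory (created), or `NULL` for an in-memory cohort.
#' @return in-memory: list with `records`, `patients` (per-patient lists
#'   from [generatePatient]); on disk: the manifest path (invisibly), with
#'   the same list returned invisibly in `attr(, "cohort")` omitted.
#' @export
generateCohort <- function(spec, dir = NULL) {
  set.seed(spec$seed)
  n <- spec$nPatients
  n74 <- roundHalfUp(spec$regimenMix * n)
  regimen <- sample(c(rep("74Gy_37F", n74), rep("60Gy_20F", n - n74)))
  labels <- rbinom(n, 1, spec$prevalence)
  seeds <- sample.int(2147483600L, n)
  ids <- sprintf("P%03d", seq_len(n))
  patients <- lapply(seq_len(n), function(i)
    generatePatient(spec, seeds[i], ids[i], regimen[i], labels[i]))
  records <- do.call(rbind, lapply(patients, `[[`, "record"))
  message("synthetic cohort: ", n, " patients, ", sum(labels),
          " endpoint-positive, ", n74, " on 74Gy_37F")
  cohort <- list(records = records, patients = patients)
  if (is.null(dir)) return(cohort)

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(patients, function(p) {
    pid <- p$record$patient_id
    pdir <- file.path(dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    writeScan(p$scans$planning, file.path(pdir, "planning.nii.gz"))
    mv <- character(0)
    for (key in names(p$scans)) {
      if (key == "planning") next
      f <- p$scans[[key]]@fractionIndex
      writeScan(p$scans[[key]], file.path(pdir, sprintf("mvct_%02d.nii.gz", f)))
      mv <- c(mv, sprintf("%d:%s/mvct_%02d.nii.gz", f, pid, f))
    }
    # contours are drawn per scan (the rectum deforms between fractions)
    writeContours(p$contours$planning, file.path(pdir, "rectum.json"))
    mc <- character(0)
    for (key in setdiff(names(p$contours), "planning")) {
      f <- p$scans[[key]]@fractionIndex
      writeContours(p$contours[[key]],
                    file.path(pdir, paste0("rectum_", key, ".json")))
      mc <- c(mc, sprintf("%d:%s/rectum_%s.json", f, pid, key))
    }
    data.frame(patient_id = pid, regimen = p$record$regimen,
               endpoint_grade = p$record$endpoint_grade,
               contour_file = paste0(pid, "/rectum.json"),
               planning_scan = paste0(pid, "/planning.nii.gz"),
               mvct_scans = paste(mv, collapse = ";"),
               mvct_contours = paste(mc, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "manifest.csv")
  write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
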