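#' Read a scan from disk
#'
#' Reads an image series into a [ScanSeries]. Two formats are supported:
#' NIfTI (`.nii` / `.nii.gz`, via RNifti) and the package's plain-text
#' raw-array JSON container (see [writeScan]). Scan-level metadata (patient,
#' modality, fraction) is stored inside the raw-array container; for NIfTI it
#' must be supplied by the caller (normally from the cohort manifest).
#'
#' @param path file path.
#' @param format `"auto"`, `"nifti"` or `"rarray"`.
#' @param patientId,modality,fractionIndex metadata used for NIfTI input.
#' @return a [ScanSeries].
#' @export
readScan <- function(path, format = "auto", patientId = "unknown",
                     modality = "planning_ct", fractionIndex = NA_integer_) {
  if (!file.exists(path))
    stop("cannot read scan: file does not exist: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
    else if (grepl("\\.json$", path)) "rarray"
    else if (grepl("\\.dcm$", path) || dir.exists(path)) "dicom"
    else stop("cannot infer format of ", path)
  }
  if (format == "dicom")
    stop("DICOM reading is not supported; convert to NIfTI or the ",
         "raw-array JSON container")
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1))
    if (length(dim(arr)) != 3)
      stop("format error: expected a 2D/3D image in ", path)
    pd <- RNifti::pixdim(img)
    sl <- lapply(seq_len(dim(arr)[3]), function(k)
      SliceImage(arr[, , k], rowSpacing = pd[1], colSpacing = pd[2],
                 sliceIndex = k))
    return(ScanSeries(patientId, modality, sl, fractionIndex))
  }
  if (format == "rarray") {
    obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    sl <- lapply(seq_along(obj$slices), function(k) {
      px <- do.call(rbind, lapply(obj$slices[[k]],
                                  function(r) as.numeric(unlist(r))))
      SliceImage(px, obj$row_spacing, obj$col_spacing, k)
    })
    d <- vapply(sl, function(s) dim(s@pixels), integer(2))
    if (any(d != d[, 1])) stop("format error: mixed slice dimensions in ", path)
    return(ScanSeries(obj$patient_id, obj$modality, sl,
                      if (is.null(obj$fraction_index)) NA_integer_
                      else obj$fraction_index))
  }
  stop("unknown scan format: ", format)
}

#' Write a scan to disk
#'
#' NIfTI output preserves pixel values bit-exactly (float64 data). The
#' raw-array container is a plain-text JSON file holding metadata plus the
#' per-slice pixel grids printed with 17 significant digits (also lossless
#' for doubles).
#'
#' @param scan a [ScanSeries].
#' @param path output path (`.nii`/`.nii.gz` or `.json`).
#' @param format `"auto"`, `"nifti"` or `"rarray"`.
#' @return `path`, invisibly.
#' @export
writeScan <- function(scan, path, format = "auto") {
  if (format == "auto")
    format <- if (grepl("\\.json$", path)) "rarray" else "nifti"
  s1 <- scan@slices[[1]]
  if (format == "nifti") {
    arr <- vapply(scan@slices, function(s) s@pixels, s1@pixels)
    if (length(scan@slices) == 1) arr <- array(arr, c(dim(s1@pixels), 1))
    img <- RNifti::asNifti(arr, list(
      pixdim = c(1, s1@rowSpacing, s1@colSpacing, 1, 0, 0, 0, 0),
      datatype = "double"))
    RNifti::writeNifti(img, path)
  } else {
    obj <- list(
      patient_id = scan@patientId, modality = scan@modality,
      fraction_index = if (is.na(scan@fractionIndex)) NULL
                       else scan@fractionIndex,
      row_spacing = s1@rowSpacing, col_spacing = s1@colSpacing,
      slices = lapply(scan@slices, function(s) s@pixels))
    writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE),
               path)
  }
  invisible(path)
}

#' Rasterise a planar contour into a binary mask
#'
#' A pixel belongs to the mask iff its centre lies inside the polygon or on
#' its boundary. Pixel centres sit at integer (row, col) coordinates,
#' 0-based; the mask element `[r + 1, c + 1]` corresponds to centre (r, c).
#'
#' @param polygon a [ContourPolygon].
#' @param gridShape integer length-2, (rows, cols) of the target grid.
#' @return logical matrix of dimension `gridShape`.
#' @export
rasteriseContour <- function(polygon, gridShape) {
  v <- polygon@vertices
  n <- nrow(v)
  area2 <- sum(v[, 1] * v[c(2:n, 1), 2] - v[c(2:n, 1), 1] * v[, 2])
  if (abs(area2) < 1e-12)
    stop("degenerate polygon: zero area")
  nr <- gridShape[1]; nc <- gridShape[2]
  pr <- rep(0:(nr - 1), times = nc)   # pixel-centre rows
  pc <- rep(0:(nc - 1), each = nr)    # pixel-centre cols
  inside <- rep(FALSE, nr * nc)
  onEdge <- rep(FALSE, nr * nc)
  eps <- 1e-9
  for (i in seq_len(n)) {
    a <- v[i, ]; b <- v[if (i == n) 1 else i + 1, ]
    # even-odd crossing rule on the (col = x, row = y) plane
    crosses <- ((a[1] > pr) != (b[1] > pr)) &
      (pc < (b[2] - a[2]) * (pr - a[1]) / (b[1] - a[1]) + a[2])
    inside <- xor(inside, crosses & !is.na(crosses))
    # boundary inclusion: point within eps of segment ab
    abr <- b[1] - a[1]; abc <- b[2] - a[2]
    len2 <- abr^2 + abc^2
    t <- if (len2 > 0) pmin(1, pmax(0, ((pr - a[1]) * abr +
                                        (pc - a[2]) * abc) / len2)) else 0
    d2 <- (pr - (a[1] + t * abr))^2 + (pc - (a[2] + t * abc))^2
    onEdge <- onEdge | (d2 < eps)
  }
  mask <- matrix(inside | onEdge, nr, nc)
  if (!any(mask))
    warning("contour covers no pixel centre on slice ", polygon@sliceIndex)
  mask
}

#' Write / read rectum contours as JSON
#'
#' One JSON object per structure: a structure name plus a list of per-slice
#' vertex lists (0-based (row, col) pixel coordinates, fractional allowed).
#'
#' @param contours list of [ContourPolygon].
#' @param path JSON file path.
#' @param structure structure name stored in the file.
#' @return `path` invisibly (write); list of [ContourPolygon] (read).
#' @export
writeContours <- function(contours, path, structure = "rectum") {
  obj <- list(structure = structure,
              slices = lapply(contours, function(p)
                list(slice_index = p@sliceIndex,
                     vertices = unname(p@vertices))))
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname writeContours
#' @export
readContours <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(obj$slices, function(s) {
    v <- s$vertices
    if (!is.matrix(v)) v <- do.call(rbind, lapply(v, unlist))
    ContourPolygon(v, s$slice_index)
  })
}

#' Read a cohort manifest
#'
#' The manifest is a CSV with one row per patient and columns `patient_id`,
#' `regimen` (`74Gy_37F` or `60Gy_20F`), `endpoint_grade` (0-3),
#' `contour_file`, `planning_scan` and `mvct_scans`
#' (semicolon-separated `fraction:path` entries). Relative paths are resolved
#' against the manifest's directory. The binary endpoint is derived as
#' grade >= 1 rectal bleeding. Fraction counts are checked against the
#' regimen (37 or 20); missing fractions are tolerated with a warning and
#' recorded in the `gaps` element.
#'
#' @param path manifest CSV path.
#' @param checkFiles verify that all referenced files exist.
#' @return list with `records` (data.frame: patient_id, regimen,
#'   endpoint_grade, endpoint_binary), `registry` (data.frame: patient_id,
#'   modality, fraction_index, path, contour_file) and `gaps` (data.frame of
#'   missing fractions).
#' @export
readCohortManifest <- function(path, checkFiles = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "regimen", "endpoint_grade")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (any(!man$regimen %in% c("74Gy_37F", "60Gy_20F")))
    stop("unknown regimen in manifest")
  if (any(man$endpoint_grade < 0 | man$endpoint_grade > 3))
    stop("endpoint_grade outside 0-3 in manifest")
  base <- dirname(path)
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  records <- data.frame(
    patient_id = as.character(man$patient_id),
    regimen = man$regimen,
    endpoint_grade = as.integer(man$endpoint_grade),
    endpoint_binary = as.integer(man$endpoint_grade >= 1),
    stringsAsFactors = FALSE)

  registry <- NULL; gaps <- NULL
  hasScans <- all(c("planning_scan", "mvct_scans", "contour_file")
                  %in% names(man))
  if (hasScans) {
    rows <- lapply(seq_len(nrow(man)), function(i) {
      mv <- strsplit(man$mvct_scans[i], ";", fixed = TRUE)[[1]]
      mv <- mv[nzchar(mv)]
      fr <- as.integer(sub(":.*", "", mv))
      mp <- resolve(sub("^[0-9]+:", "", mv))
      # optional per-fraction contours; default to the planning contour
      mc <- rep(resolve(man$contour_file[i]), length(mv))
      if ("mvct_contours" %in% names(man) && nzchar(man$mvct_contours[i])) {
        cc <- strsplit(man$mvct_contours[i], ";", fixed = TRUE)[[1]]
        cfr <- as.integer(sub(":.*", "", cc))
        mc[match(cfr, fr)] <- resolve(sub("^[0-9]+:", "", cc))
      }
      rbind(
        data.frame(patient_id = man$patient_id[i], modality = "planning_ct",
                   fraction_index = NA_integer_,
                   path = resolve(man$planning_scan[i]),
                   contour_file = resolve(man$contour_file[i]),
                   stringsAsFactors = FALSE),
        if (length(mv)) data.frame(patient_id = man$patient_id[i],
                   modality = "mvct", fraction_index = fr, path = mp,
                   contour_file = mc,
                   stringsAsFactors = FALSE))
    })
    registry <- do.call(rbind, rows)
    if (checkFiles) {
      miss <- !file.exists(unique(c(registry$path, registry$contour_file)))
      if (any(miss))
        stop("manifest references missing files: ",
             paste(head(unique(c(registry$path,
                                 registry$contour_file))[miss], 3),
                   collapse = ", "))
    }
    expected <- ifelse(records$regimen == "74Gy_37F", 37L, 20L)
    gapRows <- list()
    for (i in seq_len(nrow(records))) {
      have <- registry$fraction_index[
        registry$patient_id == records$patient_id[i] &
          registry$modality == "mvct"]
      missing <- setdiff(seq_len(expected[i]), have)
      if (length(missing)) {
        warning("patient ", records$patient_id[i], " is missing ",
                length(missing), " MVCT fraction(s): ",
                paste(head(missing, 5), collapse = ","),
                "; week averages will use available fractions")
        gapRows[[length(gapRows) + 1]] <- data.frame(
          patient_id = records$patient_id[i], fraction_index = missing,
          stringsAsFactors = FALSE)
      }
    }
    gaps <- if (length(gapRows)) do.call(rbind, gapRows) else
      data.frame(patient_id = character(), fraction_index = integer())
  }
  list(records = records, registry = registry, gaps = gaps)
}

#' Summarise toxicity outcomes of a cohort
#'
#' Tabulates the endpoint grades and the binary grade >= 1 rectal-bleeding
#' endpoint, overall and per regimen.
#'
#' @param records data.frame with `patient_id`, `regimen`,
#'   `endpoint_grade` (and optionally `endpoint_binary`).
#' @return list with `n`, `byGrade` (named counts for grades 0-3),
#'   `geG1` (count with grade >= 1), `prevalence`, and `byRegimen`
#'   (data.frame regimen / n / geG1).
#' @export
summariseOutcomes <- function(records) {
  g <- factor(records$endpoint_grade, levels = 0:3)
  byGrade <- table(g)
  geG1 <- sum(records$endpoint_grade >= 1)
  byRegimen <- do.call(rbind, lapply(split(records, records$regimen),
    function(d) data.frame(regimen = d$regimen[1], n = nrow(d),
                           geG1 = sum(d$endpoint_grade >= 1))))
  rownames(byRegimen) <- NULL
  list(n = nrow(records), byGrade = byGrade, geG1 = geG1,
       prevalence = geG1 / nrow(records), byRegimen = byRegimen)
}
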