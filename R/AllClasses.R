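#' @import methods
#' @importFrom stats median quantile sd cor wilcox.test rnorm runif rbinom
#' @importFrom utils read.csv write.csv head
NULL

#' SliceImage: one 2D axial image
#'
#' A single axial slice: a rectangular grid of HU-like intensities together
#' with the in-plane pixel spacing (mm) and its index within the scan.
#' Pixel coordinates are (row, col), 0-based, with pixel centres at integer
#' coordinates.
#'
#' @slot pixels numeric matrix of intensities.
#' @slot rowSpacing,colSpacing pixel spacing in mm (> 0).
#' @slot sliceIndex integer slice index (1-based).
#' @export
setClass("SliceImage",
  representation(pixels = "matrix", rowSpacing = "numeric",
                 colSpacing = "numeric", sliceIndex = "integer"),
  validity = function(object) {
    if (length(object@pixels) == 0) return("pixel grid is empty")
    if (!is.numeric(object@pixels)) return("pixels must be numeric")
    if (object@rowSpacing <= 0 || object@colSpacing <= 0)
      return("pixel spacings must be > 0")
    TRUE
  })

#' ScanSeries: an ordered stack of slices from one scan
#'
#' Groups the slices of a single acquisition (planning CT or a daily MVCT
#' fraction) for one patient. All slices must share dimensions and spacing.
#'
#' @slot patientId character scalar.
#' @slot modality `"planning_ct"` or `"mvct"`.
#' @slot fractionIndex integer >= 1 for MVCT; `NA` for the planning CT.
#' @slot slices list of [SliceImage] objects ordered by slice index.
#' @export
setClass("ScanSeries",
  representation(patientId = "character", modality = "character",
                 fractionIndex = "integer", slices = "list"),
  validity = function(object) {
    if (!object@modality %in% c("planning_ct", "mvct"))
      return("modality must be 'planning_ct' or 'mvct'")
    if (object@modality == "mvct" &&
        (is.na(object@fractionIndex) || object@fractionIndex < 1))
      return("mvct scans need fractionIndex >= 1")
    if (length(object@slices) == 0) return("scan has no slices")
    if (!all(vapply(object@slices, is, logical(1), "SliceImage")))
      return("slices must be SliceImage objects")
    dims <- vapply(object@slices, function(s) dim(s@pixels), integer(2))
    if (any(dims != dims[, 1])) return("mixed slice dimensions in scan")
    sp <- vapply(object@slices, function(s) c(s@rowSpacing, s@colSpacing),
                 numeric(2))
    if (any(abs(sp - sp[, 1]) > 1e-9)) return("mixed slice spacings in scan")
    TRUE
  })

#' ContourPolygon: a planar rectum contour on one slice
#'
#' Vertices in pixel units (fractional allowed), (row, col) order, closed by
#' convention (last vertex connects back to the first).
#'
#' @slot sliceIndex integer slice index.
#' @slot vertices numeric matrix with >= 3 rows and columns (row, col).
#' @export
setClass("ContourPolygon",
  representation(sliceIndex = "integer", vertices = "matrix"),
  validity = function(object) {
    if (nrow(object@vertices) < 3) return("polygon needs >= 3 vertices")
    if (ncol(object@vertices) != 2) return("vertices must be (row, col) pairs")
    TRUE
  })

#' WallROI: the 2-pixel rectal-wall ring on one slice
#'
#' @slot wallMask logical matrix, the 2-pixel ring.
#' @slot sourceMask logical matrix, the filled rectum it was derived from.
#' @slot sliceIndex integer slice index.
#' @export
setClass("WallROI",
  representation(wallMask = "matrix", sourceMask = "matrix",
                 sliceIndex = "integer"),
  validity = function(object) {
    if (!identical(dim(object@wallMask), dim(object@sourceMask)))
      return("wall and source masks must share dimensions")
    if (any(object@wallMask & !object@sourceMask))
      return("wall mask must be a subset of the source mask")
    TRUE
  })

#' SubimageSet: 8x8 windows tiled along a wall ring
#'
#' Compact container for the windows extracted from one slice: an
#' 8 x 8 x n array of pixel values plus the (row, col) top-left anchor of
#' each window in 0-based slice coordinates, in row-major anchor order.
#'
#' @slot pixels numeric array, side x side x n.
#' @slot anchors integer matrix n x 2 (row, col), 0-based.
#' @slot sliceIndex integer slice index.
#' @slot nClipped integer, windows dropped because they crossed the border.
#' @export
setClass("SubimageSet",
  representation(pixels = "array", anchors = "matrix",
                 sliceIndex = "integer", nClipped = "integer"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3 || d[1] != d[2]) return("pixels must be side x side x n")
    if (nrow(object@anchors) != d[3]) return("anchor count != window count")
    TRUE
  })

#' ModelResult: one fitted elastic-net toxicity model
#'
#' Fitted penalised logistic regression for one time point, with bootstrap
#' AUC evaluation on the training and test sets and the Youden operating
#' point.
#'
#' @slot timePoint character, e.g. `"CT"` or `"W1"`.
#' @slot features character, the features offered to the model.
#' @slot coefficients named numeric, intercept + non-zero coefficients.
#' @slot cSelected numeric, inverse regularisation strength chosen by CV.
#' @slot train,test lists with elements `auc`, `ci` (length 2), `boot`
#'   (bootstrap AUC samples), `sensitivity`, `specificity`, `n`.
#' @slot threshold numeric, Youden threshold on the training scores.
#' @export
setClass("ModelResult",
  representation(timePoint = "character", features = "character",
                 coefficients = "numeric", cSelected = "numeric",
                 train = "list", test = "list", threshold = "numeric"))

#' TimepointSweep: models and comparisons across treatment time points
#'
#' @slot mode `"separate"` or `"cumulative"`.
#' @slot timePoints character vector, e.g. `c("CT","W1",...)`.
#' @slot models named list of [ModelResult] (or NULL where a time point
#'   failed, with the reason in `failures`).
#' @slot selections named list: the pruned feature set used at each time
#'   point (separate mode) or accumulated set (cumulative mode).
#' @slot comparisons data.frame of one-sided Mann-Whitney p-values between
#'   time points' bootstrap AUC samples (columns a, b, basis, p).
#' @slot failures named character, reasons for aborted time points.
#' @export
setClass("TimepointSweep",
  representation(mode = "character", timePoints = "character",
                 models = "list", selections = "list",
                 comparisons = "data.frame", failures = "character"))

setMethod("show", "SliceImage", function(object) {
  cat(sprintf("SliceImage %dx%d px, %.2fx%.2f mm, slice %d\n",
              nrow(object@pixels), ncol(object@pixels),
              object@rowSpacing, object@colSpacing, object@sliceIndex))
})

setMethod("show", "ScanSeries", function(object) {
  fi <- if (is.na(object@fractionIndex)) "" else
    sprintf(", fraction %d", object@fractionIndex)
  d <- dim(object@slices[[1]]@pixels)
  cat(sprintf("ScanSeries: patient %s, %s%s, %d slice(s) of %dx%d\n",
              object@patientId, object@modality, fi,
              length(object@slices), d[1], d[2]))
})

setMethod("show", "WallROI", function(object) {
  cat(sprintf("WallROI: slice %d, %d wall px (of %d rectum px)\n",
              object@sliceIndex, sum(object@wallMask),
              sum(object@sourceMask)))
})

setMethod("show", "SubimageSet", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("SubimageSet: %d window(s) of %dx%d on slice %d (%d clipped)\n",
              d[3], d[1], d[2], object@sliceIndex, object@nClipped))
})

setMethod("show", "ModelResult", function(object) {
  nz <- sum(object@coefficients[-1] != 0)
  cat(sprintf("ModelResult [%s]: %d/%d non-zero features, C = %.4g\n",
              object@timePoint, nz, length(object@features),
              object@cSelected))
  cat(sprintf("  train AUC %.3f (%.3f-%.3f)  test AUC %.3f (%.3f-%.3f)\n",
              object@train$auc, object@train$ci[1], object@train$ci[2],
              object@test$auc, object@test$ci[1], object@test$ci[2]))
})

setMethod("show", "TimepointSweep", function(object) {
  cat(sprintf("TimepointSweep (%s mode): %s\n", object@mode,
              paste(object@timePoints, collapse = ", ")))
  for (tp in object@timePoints) {
    m <- object@models[[tp]]
    if (is.null(m)) {
      cat(sprintf("  %-3s FAILED: %s\n", tp, object@failures[[tp]]))
    } else {
      cat(sprintf("  %-3s train AUC %.3f, test AUC %.3f (%d features)\n",
                  tp, m@train$auc, m@test$auc,
                  sum(m@coefficients[-1] != 0)))
    }
  }
})
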