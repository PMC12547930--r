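#' @rdname accessors
#' @export
setGeneric("pixels", function(x, ...) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("slices", function(x) standardGeneric("slices"))

#' @rdname accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname accessors
#' @export
setGeneric("fractionIndex", function(x) standardGeneric("fractionIndex"))

#' @rdname accessors
#' @export
setGeneric("wallMask", function(x) standardGeneric("wallMask"))

#' @rdname accessors
#' @export
setGeneric("sourceMask", function(x) standardGeneric("sourceMask"))

#' @rdname accessors
#' @export
setGeneric("anchors", function(x) standardGeneric("anchors"))

#' @rdname accessors
#' @export
setGeneric("modelCoefficients", function(x) standardGeneric("modelCoefficients"))

#' @rdname accessors
#' @export
setGeneric("trainMetrics", function(x) standardGeneric("trainMetrics"))

#' @rdname accessors
#' @export
setGeneric("testMetrics", function(x) standardGeneric("testMetrics"))

#' @rdname accessors
#' @export
setGeneric("sweepModels", function(x) standardGeneric("sweepModels"))

#' @rdname accessors
#' @export
setGeneric("sweepComparisons", function(x) standardGeneric("sweepComparisons"))

#' @rdname accessors
#' @export
setGeneric("sweepSelections", function(x) standardGeneric("sweepSelections"))

#' Accessors for rectomics S4 classes
#'
#' Getters for the slots of [SliceImage], [ScanSeries], [WallROI],
#' [SubimageSet], [ModelResult] and [TimepointSweep] objects.
#'
#' @param x an object of the relevant class.
#' @param ... unused.
#' @return the slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("pixels", "SliceImage", function(x, ...) x@pixels)

#' @rdname accessors
#' @export
setMethod("pixels", "SubimageSet", function(x, ...) x@pixels)

#' @rdname accessors
#' @export
setMethod("slices", "ScanSeries", function(x) x@slices)

#' @rdname accessors
#' @export
setMethod("patientId", "ScanSeries", function(x) x@patientId)

#' @rdname accessors
#' @export
setMethod("modality", "ScanSeries", function(x) x@modality)

#' @rdname accessors
#' @export
setMethod("fractionIndex", "ScanSeries", function(x) x@fractionIndex)

#' @rdname accessors
#' @export
setMethod("wallMask", "WallROI", function(x) x@wallMask)

#' @rdname accessors
#' @export
setMethod("sourceMask", "WallROI", function(x) x@sourceMask)

#' @rdname accessors
#' @export
setMethod("anchors", "SubimageSet", function(x) x@anchors)

#' @rdname accessors
#' @export
setMethod("modelCoefficients", "ModelResult", function(x) x@coefficients)

#' @rdname accessors
#' @export
setMethod("trainMetrics", "ModelResult", function(x) x@train)

#' @rdname accessors
#' @export
setMethod("testMetrics", "ModelResult", function(x) x@test)

#' @rdname accessors
#' @export
setMethod("sweepModels", "TimepointSweep", function(x) x@models)

#' @rdname accessors
#' @export
setMethod("sweepComparisons", "TimepointSweep", function(x) x@comparisons)

#' @rdname accessors
#' @export
setMethod("sweepSelections", "TimepointSweep", function(x) x@selections)
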