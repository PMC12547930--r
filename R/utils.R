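# internal helpers

# round-half-up, used for the 75:25 split arithmetic (round() would round
# half to even and not reproduce the published split sizes)
roundHalfUp <- function(x) floor(x + 0.5)

# derive a per-stage / per-unit seed from one master seed; keeps results
# reproducible under a single seed while decoupling the random streams of
# different pipeline stages and patients
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(offset)) %%
               2147483629L)
}

# constructor helpers ---------------------------------------------------------

#' Construct a SliceImage
#'
#' @param pixels numeric matrix of intensities.
#' @param rowSpacing,colSpacing pixel spacing in mm.
#' @param sliceIndex 1-based slice index.
#' @return a [SliceImage].
#' @export
SliceImage <- function(pixels, rowSpacing = 1, colSpacing = 1, sliceIndex = 1L) {
  new("SliceImage", pixels = pixels, rowSpacing = as.numeric(rowSpacing),
      colSpacing = as.numeric(colSpacing), sliceIndex = as.integer(sliceIndex))
}

#' Construct a ScanSeries
#'
#' @param patientId character scalar.
#' @param modality `"planning_ct"` or `"mvct"`.
#' @param slices list of [SliceImage], ordered by slice index.
#' @param fractionIndex integer fraction index (MVCT only).
#' @return a [ScanSeries].
#' @export
ScanSeries <- function(patientId, modality, slices, fractionIndex = NA_integer_) {
  new("ScanSeries", patientId = as.character(patientId),
      modality = modality, fractionIndex = as.integer(fractionIndex),
      slices = slices)
}

#' Construct a ContourPolygon
#'
#' @param vertices numeric matrix (row, col) with >= 3 rows, pixel units,
#'   0-based, fractional coordinates allowed.
#' @param sliceIndex 1-based slice index.
#' @return a [ContourPolygon].
#' @export
ContourPolygon <- function(vertices, sliceIndex = 1L) {
  new("ContourPolygon", sliceIndex = as.integer(sliceIndex),
      vertices = as.matrix(vertices))
}
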