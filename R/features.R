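#' The 118-feature catalogue
#'
#' Name, family and definition of every feature the extractor emits, in
#' output order: 23 first-order (FOS), 25 co-occurrence (GLCM), 16
#' run-length (GLRLM), 16 size-zone (GLSZM), 16 distance-zone (GLDZM), 5
#' neighbourhood grey-tone difference (NGTDM) and 17 neighbouring grey-level
#' dependence (NGLDM) features, following the IBSI reference definitions.
#' FOS intensity statistics use raw window intensities; all other families
#' (and the FOS histogram features) use fixed-bin-number discretised levels.
#'
#' @return data.frame with columns `index`, `name`, `family`, `definition`.
#' @export
featureCatalogue <- function() {
  fam <- c(rep("FOS", 23), rep("GLCM", 25), rep("GLRLM", 16),
           rep("GLSZM", 16), rep("GLDZM", 16), rep("NGTDM", 5),
           rep("NGLDM", 17))
  within <- unlist(lapply(c(23, 25, 16, 16, 16, 5, 17), seq_len))
  defs <- c(
    # FOS
    "mean intensity", "intensity variance (population)", "skewness",
    "excess kurtosis", "median", "minimum", "10th percentile",
    "90th percentile", "maximum", "histogram mode (grey level)",
    "interquartile range", "range", "mean absolute deviation",
    "robust mean absolute deviation (10-90 percentile)",
    "median absolute deviation (mean |x - median|)",
    "coefficient of variation", "quartile coefficient of dispersion",
    "histogram entropy (bits)", "histogram uniformity",
    "maximum histogram gradient", "maximum histogram gradient grey level",
    "minimum histogram gradient", "minimum histogram gradient grey level",
    # GLCM
    "joint maximum", "joint average", "joint variance", "joint entropy",
    "difference average", "difference variance", "difference entropy",
    "sum average", "sum variance", "sum entropy", "angular second moment",
    "contrast", "dissimilarity", "inverse difference",
    "inverse difference normalised", "inverse difference moment",
    "inverse difference moment normalised", "inverse variance",
    "correlation", "autocorrelation", "cluster tendency", "cluster shade",
    "cluster prominence", "information correlation 1",
    "information correlation 2",
    # GLRLM
    "short runs emphasis", "long runs emphasis",
    "low grey level run emphasis", "high grey level run emphasis",
    "short run low grey level emphasis", "short run high grey level emphasis",
    "long run low grey level emphasis", "long run high grey level emphasis",
    "grey level non-uniformity", "grey level non-uniformity normalised",
    "run length non-uniformity", "run length non-uniformity normalised",
    "run percentage", "grey level variance", "run length variance",
    "run entropy",
    # GLSZM
    "small zone emphasis", "large zone emphasis",
    "low grey level zone emphasis", "high grey level zone emphasis",
    "small zone low grey level emphasis",
    "small zone high grey level emphasis",
    "large zone low grey level emphasis",
    "large zone high grey level emphasis", "grey level non-uniformity",
    "grey level non-uniformity normalised", "zone size non-uniformity",
    "zone size non-uniformity normalised", "zone percentage",
    "grey level variance", "zone size variance", "zone size entropy",
    # GLDZM
    "small distance emphasis", "large distance emphasis",
    "low grey level zone emphasis", "high grey level zone emphasis",
    "small distance low grey level emphasis",
    "small distance high grey level emphasis",
    "large distance low grey level emphasis",
    "large distance high grey level emphasis", "grey level non-uniformity",
    "grey level non-uniformity normalised", "zone distance non-uniformity",
    "zone distance non-uniformity normalised", "zone percentage",
    "grey level variance", "zone distance variance", "zone distance entropy",
    # NGTDM
    "coarseness", "contrast", "busyness", "complexity", "strength",
    # NGLDM
    "low dependence emphasis", "high dependence emphasis",
    "low grey level count emphasis", "high grey level count emphasis",
    "low dependence low grey level emphasis",
    "low dependence high grey level emphasis",
    "high dependence low grey level emphasis",
    "high dependence high grey level emphasis", "grey level non-uniformity",
    "grey level non-uniformity normalised",
    "dependence count non-uniformity",
    "dependence count non-uniformity normalised",
    "dependence count percentage", "grey level variance",
    "dependence count variance", "dependence count entropy",
    "dependence count energy")
  data.frame(index = seq_along(fam), name = paste0(fam, within),
             family = fam, definition = defs, stringsAsFactors = FALSE)
}

#' Feature name vector in catalogue order
#' @return character vector of length 118.
#' @export
featureNames <- local({
  nm <- NULL
  function() {
    if (is.null(nm)) nm <<- featureCatalogue()$name
    nm
  }
})

#' Discretise a subimage to integer grey levels
#'
#' Fixed-bin-number discretisation over the window's own min-max intensity
#' range; a constant window maps to a single level 1. Discretisation is
#' invariant under affine rescaling of the input intensities.
#'
#' @param x numeric matrix of raw intensities.
#' @param ng number of grey levels (>= 2).
#' @return integer matrix of levels in 1..`ng`, with attribute `ng`.
#' @export
discretiseSubimage <- function(x, ng = 8L) {
  if (ng < 2) stop("ng must be >= 2")
  lv <- .cpp_discretise(x, as.integer(ng))
  attr(lv, "ng") <- as.integer(ng)
  lv
}

#' First-order features of a subimage
#'
#' The 23 FOS features: intensity statistics on raw values plus histogram
#' mode / entropy / uniformity / gradient features on the discretised
#' levels. Zero-variance conventions: skewness = kurtosis = 0, CoV = 0.
#'
#' @param x numeric matrix of raw intensities.
#' @param levels discretised levels from [discretiseSubimage] (computed if
#'   missing).
#' @param ng grey level count.
#' @return named numeric vector FOS1..FOS23.
#' @export
fosFeatures <- function(x, levels = NULL, ng = 8L) {
  if (is.null(levels)) levels <- discretiseSubimage(x, ng)
  v <- .cpp_fos(x, levels, as.integer(ng))
  names(v) <- paste0("FOS", 1:23)
  v
}

#' Build a texture matrix structure
#'
#' Returns the intermediate matrix representation used by each texture
#' family: GLCM - four symmetric normalised distance-1 matrices (0, 45, 90,
#' 135 degrees); GLRLM - four run-count matrices (level x run length);
#' GLSZM / GLDZM - zone-count matrices (level x zone size, level x zone
#' distance) over 8-connected equal-level zones, with zone distance the
#' minimum chessboard distance of a zone pixel to outside the window (border
#' pixels = 1); NGTDM - per-level grey-tone difference sums `s` and counts
#' `n` over the 8-neighbourhood; NGLDM - dependence-count matrix (level x
#' (count + 1)) with coarseness parameter alpha = 0.
#'
#' @param levels integer level matrix from [discretiseSubimage].
#' @param family one of `"GLCM"`, `"GLRLM"`, `"GLSZM"`, `"GLDZM"`,
#'   `"NGTDM"`, `"NGLDM"`.
#' @param ng grey level count (defaults to the attribute on `levels`).
#' @return family-specific matrix structure (see Details).
#' @export
textureMatrix <- function(levels, family, ng = attr(levels, "ng")) {
  if (is.null(ng)) ng <- max(levels)
  ng <- as.integer(ng)
  storage.mode(levels) <- "integer"
  switch(family,
    GLCM = .cpp_glcm_matrices(levels, ng),
    GLRLM = .cpp_glrlm_matrices(levels, ng),
    GLSZM = {
      z <- .cpp_zones(levels)
      m <- matrix(0, ng, max(z[, "size"]))
      for (i in seq_len(nrow(z)))
        m[z[i, "level"], z[i, "size"]] <- m[z[i, "level"], z[i, "size"]] + 1
      m
    },
    GLDZM = {
      z <- .cpp_zones(levels)
      m <- matrix(0, ng, max(z[, "distance"]))
      for (i in seq_len(nrow(z)))
        m[z[i, "level"], z[i, "distance"]] <-
          m[z[i, "level"], z[i, "distance"]] + 1
      m
    },
    NGTDM = .cpp_ngtdm(levels, ng),
    NGLDM = .cpp_ngldm_matrix(levels, ng, 0L),
    stop("unknown texture family: ", family))
}

# R-side feature formulas operating on matrix structures. These mirror the
# compiled fast path and are the reference implementation for tests and for
# inspecting individual families.

glcmFeaturesFromMatrix <- function(p) {
  ng <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  d <- abs(i - j)
  pdiff <- vapply(0:(ng - 1), function(k) sum(p[d == k]), numeric(1))
  psum <- vapply(2:(2 * ng), function(k) sum(p[(i + j) == k]), numeric(1))
  javg <- sum(i * p)
  da <- sum((0:(ng - 1)) * pdiff)
  sa <- sum((2:(2 * ng)) * psum)
  mu <- sum(seq_len(ng) * px)
  s2 <- sum((seq_len(ng) - mu)^2 * px)
  autoc <- sum(i * j * p)
  hx <- ent(px)
  q <- outer(px, px)
  hxy1 <- -sum((p * log2(q))[q > 0 & p > 0])
  hxy2 <- ent(q)
  jent <- ent(p)
  ic2arg <- 1 - exp(-2 * (hxy2 - jent))
  c(jointMaximum = max(p),
    jointAverage = javg,
    jointVariance = sum((i - javg)^2 * p),
    jointEntropy = jent,
    differenceAverage = da,
    differenceVariance = sum(((0:(ng - 1)) - da)^2 * pdiff),
    differenceEntropy = ent(pdiff),
    sumAverage = sa,
    sumVariance = sum(((2:(2 * ng)) - sa)^2 * psum),
    sumEntropy = ent(psum),
    angularSecondMoment = sum(p^2),
    contrast = sum(d^2 * p),
    dissimilarity = sum(d * p),
    inverseDifference = sum(p / (1 + d)),
    inverseDifferenceNorm = sum(p / (1 + d / ng)),
    inverseDifferenceMoment = sum(p / (1 + d^2)),
    inverseDifferenceMomentNorm = sum(p / (1 + d^2 / ng^2)),
    inverseVariance = sum((p / d^2)[d > 0]),
    correlation = if (s2 > 0) (autoc - mu^2) / s2 else 0,
    autocorrelation = autoc,
    clusterTendency = sum((i + j - 2 * mu)^2 * p),
    clusterShade = sum((i + j - 2 * mu)^3 * p),
    clusterProminence = sum((i + j - 2 * mu)^4 * p),
    informationCorrelation1 = if (hx > 0) (jent - hxy1) / hx else 0,
    informationCorrelation2 = if (ic2arg > 0) sqrt(ic2arg) else 0)
}

# shared 16-feature block for run-length / size-zone / distance-zone counts
rlszmFeaturesFromMatrix <- function(m, nVoxels) {
  ns <- sum(m)
  p <- m / ns
  g <- row(p); l <- col(p)
  mug <- sum(g * p); mul <- sum(l * p)
  pp <- p[p > 0]
  c(sum(p / l^2), sum(p * l^2), sum(p / g^2), sum(p * g^2),
    sum(p / (g^2 * l^2)), sum(p * g^2 / l^2), sum(p * l^2 / g^2),
    sum(p * g^2 * l^2),
    sum(rowSums(m)^2) / ns, sum(rowSums(m)^2) / ns^2,
    sum(colSums(m)^2) / ns, sum(colSums(m)^2) / ns^2,
    ns / nVoxels,
    sum(p * (g - mug)^2), sum(p * (l - mul)^2),
    -sum(pp * log2(pp)))
}

ngtdmFeaturesFromMatrix <- function(td, nVoxels) {
  s <- td$s; cnt <- td$n
  p <- cnt / nVoxels
  keep <- p > 0
  ngp <- sum(keep)
  lev <- seq_along(p)
  sumps <- sum(p * s); sums <- sum(s)
  coarse <- if (sumps > 0) 1 / sumps else 1e6
  pi <- p[keep]; si <- s[keep]; gi <- lev[keep]
  dif <- outer(gi, gi, "-")
  contrast <- if (ngp > 1)
    sum(outer(pi, pi) * dif^2) / (ngp * (ngp - 1)) * sums / nVoxels else 0
  busyDen <- sum(abs(outer(gi * pi, gi * pi, "-")))
  busy <- if (busyDen > 0) sumps / busyDen else 0
  complexity <- sum(abs(dif) * (outer(pi * si, pi * si, "+")) /
                      outer(pi, pi, "+")) / nVoxels
  strength <- if (sums > 0) sum(outer(pi, pi, "+") * dif^2) / sums else 0
  c(coarseness = coarse, contrast = contrast, busyness = busy,
    complexity = complexity, strength = strength)
}

ngldmFeaturesFromMatrix <- function(m, nVoxels) {
  ns <- sum(m)
  p <- m / ns
  g <- row(p); j <- col(p)
  mug <- sum(g * p); muj <- sum(j * p)
  pp <- p[p > 0]
  c(sum(p / j^2), sum(p * j^2), sum(p / g^2), sum(p * g^2),
    sum(p / (g^2 * j^2)), sum(p * g^2 / j^2), sum(p * j^2 / g^2),
    sum(p * g^2 * j^2),
    sum(rowSums(m)^2) / ns, sum(rowSums(m)^2) / ns^2,
    sum(colSums(m)^2) / ns, sum(colSums(m)^2) / ns^2,
    ns / nVoxels,
    sum(p * (g - mug)^2), sum(p * (j - muj)^2),
    -sum(pp * log2(pp)), sum(p^2))
}

#' Compute a texture family's features from its matrix structure
#'
#' GLCM and GLRLM structures (lists of four per-direction matrices) are
#' evaluated per direction and averaged at the feature level. The remaining
#' families are evaluated on their single matrix.
#'
#' @param mat structure returned by [textureMatrix].
#' @param family the texture family name.
#' @param nVoxels number of pixels in the window (needed for the
#'   run/zone/dependence percentage and NGTDM normalisations).
#' @return named numeric vector (25/16/16/16/5/17 values by family).
#' @export
textureFeatures <- function(mat, family, nVoxels = 64L) {
  cat118 <- featureCatalogue()
  nm <- cat118$name[cat118$family == family]
  v <- switch(family,
    GLCM = rowMeans(vapply(mat, glcmFeaturesFromMatrix, numeric(25))),
    GLRLM = rowMeans(vapply(mat, rlszmFeaturesFromMatrix, numeric(16),
                            nVoxels = nVoxels)),
    GLSZM = rlszmFeaturesFromMatrix(mat, nVoxels),
    GLDZM = rlszmFeaturesFromMatrix(mat, nVoxels),
    NGTDM = ngtdmFeaturesFromMatrix(mat, nVoxels),
    NGLDM = ngldmFeaturesFromMatrix(mat, nVoxels),
    stop("unknown texture family: ", family))
  names(v) <- nm
  v
}

#' Extract the 118-feature vector(s)
#'
#' Fast path over a [SubimageSet] (or a single window matrix): discretises
#' each window with `ng` fixed bins and computes the full catalogue in
#' compiled code.
#'
#' @param x a [SubimageSet], a numeric matrix (one window), or an
#'   side x side x n array of windows.
#' @param ng grey level count for discretisation.
#' @return for a single window, a named numeric vector of length 118; for a
#'   window set, an n x 118 matrix with catalogue column names.
#' @export
extractFeatures <- function(x, ng = 8L) {
  ng <- as.integer(ng)
  if (is(x, "SubimageSet")) x <- x@pixels
  if (is.matrix(x)) {
    v <- .cpp_extract_one(x, ng)
    names(v) <- featureNames()
    return(v)
  }
  d <- dim(x)
  if (length(d) != 3 || d[1] != d[2])
    stop("expected a square window or a side x side x n array")
  out <- .cpp_extract_many(as.numeric(x), d[1], ng)
  colnames(out) <- featureNames()
  out
}

#' Scan-level feature vector
#'
#' Runs the per-slice chain (rasterise contour, build the wall ring, tile
#' 8x8 windows, extract the catalogue) over all slices of a scan and
#' averages the per-window vectors across all subimages and slices.
#'
#' @param scan a [ScanSeries].
#' @param contours list of [ContourPolygon], one per slice (matched on
#'   slice index).
#' @param ng grey level count.
#' @return named numeric vector of 118 scan-level features, with attribute
#'   `nSubimages`.
#' @export
scanFeatures <- function(scan, contours, ng = 8L) {
  cIdx <- vapply(contours, function(p) p@sliceIndex, integer(1))
  rows <- list()
  total <- 0L
  for (s in scan@slices) {
    k <- match(s@sliceIndex, cIdx)
    if (is.na(k)) next
    mask <- rasteriseContour(contours[[k]], dim(s@pixels))
    if (!any(mask)) next
    wall <- buildWallRing(mask, s@sliceIndex)
    subs <- tileSubimages(wall, s)
    if (dim(subs@pixels)[3] == 0) next
    rows[[length(rows) + 1]] <- extractFeatures(subs, ng)
    total <- total + dim(subs@pixels)[3]
  }
  if (total == 0)
    stop("no subimages could be extracted for patient ", scan@patientId)
  v <- aggregateScan(do.call(rbind, rows))
  attr(v, "nSubimages") <- total
  v
}
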