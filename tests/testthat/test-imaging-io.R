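test_that("scan round trips are lossless for both on-disk formats", {
  set.seed(1)
  sl <- lapply(1:5, function(k)
    SliceImage(matrix(rnorm(64 * 64, 0, 100), 64, 64),
               rowSpacing = 0.754, colSpacing = 0.754, sliceIndex = k))
  scan <- ScanSeries("P001", "mvct", sl, 3L)

  nii <- tempfile(fileext = ".nii.gz")
  writeScan(scan, nii)
  back <- readScan(nii, patientId = "P001", modality = "mvct",
                   fractionIndex = 3L)
  expect_length(slices(back), 5)
  expect_identical(dim(pixels(slices(back)[[1]])), c(64L, 64L))
  for (k in 1:5)
    expect_identical(pixels(slices(back)[[k]]), pixels(sl[[k]]))
  expect_equal(slices(back)[[1]]@rowSpacing, 0.754, tolerance = 1e-6)

  js <- tempfile(fileext = ".json")
  writeScan(scan, js)
  back2 <- readScan(js)
  expect_identical(patientId(back2), "P001")
  expect_identical(fractionIndex(back2), 3L)
  for (k in 1:5)
    expect_identical(pixels(slices(back2)[[k]]), pixels(sl[[k]]))
})

test_that("unreadable and unsupported inputs produce clear errors", {
  expect_error(readScan("/nonexistent/scan.nii"), "does not exist")
  d <- tempfile(); dir.create(d)
  expect_error(readScan(d), "DICOM")
})

test_that("contour JSON round trip preserves vertices exactly", {
  polys <- list(ContourPolygon(cbind(c(10.25, 10.25, 20.75),
                                     c(10.5, 20.5, 15.1)), 1L),
                circleContour(c(32, 32), 9.33, sliceIndex = 2L))
  f <- tempfile(fileext = ".json")
  writeContours(polys, f)
  back <- readContours(f)
  expect_length(back, 2)
  expect_identical(back[[1]]@vertices, unname(polys[[1]]@vertices))
  expect_identical(back[[2]]@sliceIndex, 2L)
  expect_identical(back[[2]]@vertices, unname(polys[[2]]@vertices))
})

test_that("axis-aligned square rasterises to the centre-inclusive count", {
  sq <- ContourPolygon(rbind(c(10, 10), c(10, 20), c(20, 20), c(20, 10)))
  m <- rasteriseContour(sq, c(64, 64))
  expect_identical(dim(m), c(64L, 64L))
  expect_identical(sum(m), 121L)   # 11 x 11 inclusive boundary
  # exactly rows/cols 10..20 (0-based)
  expect_true(all(which(m, arr.ind = TRUE) >= 11 &
                    which(m, arr.ind = TRUE) <= 21))
})

test_that("degenerate contours error; centre-free triangles warn empty", {
  expect_error(ContourPolygon(rbind(c(0, 0), c(1, 1))), "3 vertices")
  flat <- ContourPolygon(rbind(c(5, 5), c(5, 9), c(5, 7)))
  expect_error(rasteriseContour(flat, c(16, 16)), "zero area")
  tiny <- ContourPolygon(rbind(c(4.2, 4.2), c(4.2, 4.4), c(4.4, 4.3)))
  expect_warning(m <- rasteriseContour(tiny, c(16, 16)), "no pixel centre")
  expect_identical(sum(m), 0L)
})

test_that("rasterisation agrees with an independent point-in-polygon oracle", {
  set.seed(7)
  for (i in 1:12) {
    # random convex-ish polygon with fractional vertices (centres stay off
    # the boundary with probability 1)
    centre <- runif(2, 24, 40)
    radius <- runif(1, 4, 14)
    th <- sort(runif(10, 0, 2 * pi))
    v <- cbind(centre[1] + radius * sin(th), centre[2] + radius * cos(th))
    got <- rasteriseContour(ContourPolygon(v), c(64, 64))
    ref <- oracleInOut(v, c(64, 64))
    expect_identical(unname(which(got)), unname(which(ref)))
  }
  # circle of radius 12: area within 4 px^2 of the exhaustive oracle
  circ <- circleContour(c(32, 32), 12)
  got <- rasteriseContour(circ, c(64, 64))
  ref <- oracleInOut(circ@vertices, c(64, 64))
  expect_lte(abs(sum(got) - sum(ref)), 4)
})

test_that("cohort manifest loads, derives the binary endpoint, and flags gaps", {
  dir <- tempfile(); dir.create(dir)
  # minimal manifest without scan columns: records only
  man <- data.frame(patient_id = sprintf("P%02d", 1:12),
                    regimen = rep(c("74Gy_37F", "60Gy_20F"), 6),
                    endpoint_grade = c(0, 1, 2, 3, 0, 0, 1, 0, 2, 0, 0, 1))
  f <- file.path(dir, "manifest.csv")
  write.csv(man, f, row.names = FALSE)
  got <- readCohortManifest(f)
  expect_identical(nrow(got$records), 12L)
  expect_identical(got$records$endpoint_binary,
                   as.integer(man$endpoint_grade >= 1))

  bad <- man; bad$endpoint_grade[1] <- 5
  write.csv(bad, f, row.names = FALSE)
  expect_error(readCohortManifest(f), "0-3")
})

test_that("a written synthetic cohort reads back with a missing-fraction warning", {
  dir <- tempfile()
  spec <- syntheticCohortSpec(nPatients = 2, shape = c(24L, 24L),
                              nSlices = 1, radiusRange = c(5, 6),
                              maxFractions = 3, seed = 3)
  suppressMessages(generateCohort(spec, dir))
  # 3 of the expected fractions present -> warning about the gap
  expect_warning(got <- readCohortManifest(file.path(dir, "manifest.csv")),
                 "missing")
  expect_identical(nrow(got$records), 2L)
  expect_identical(sum(got$registry$modality == "planning_ct"), 2L)
  expect_identical(sum(got$registry$modality == "mvct"), 6L)
  expect_gt(nrow(got$gaps), 0)
  # scans referenced by the registry are readable and consistent
  s <- readScan(got$registry$path[1])
  expect_identical(dim(pixels(slices(s)[[1]])), c(24L, 24L))
})

test_that("outcome summariser reproduces grade tabulations", {
  rec <- data.frame(
    patient_id = sprintf("P%03d", 1:10),
    regimen = rep("74Gy_37F", 10),
    endpoint_grade = c(0, 0, 0, 1, 1, 2, 0, 3, 0, 0))
  s <- summariseOutcomes(rec)
  expect_identical(s$geG1, 4L)
  expect_equal(unname(c(s$byGrade)), c(6, 2, 1, 1))
  expect_equal(s$prevalence, 0.4)
})
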