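# scan-level W1 feature matrix + labels for a small cohort, cached across
# tests (generation + extraction is the expensive part)
w1Features <- local({
  cache <- list()
  function(delta, seed, n = 40) {
    key <- paste(delta, seed, n)
    if (is.null(cache[[key]])) {
      spec <- syntheticCohortSpec(nPatients = n, shape = c(32L, 32L),
                                  nSlices = 1, radiusRange = c(5, 6.5),
                                  delta = delta, maxFractions = 5,
                                  seed = seed)
      co <- suppressMessages(generateCohort(spec))
      ex <- suppressMessages(extractCohortFeatures(co))
      tab <- suppressMessages(buildWeekTable(ex$features, ex$info,
                                             ex$records))
      cd <- SummarizedExperiment::colData(tab)
      w1 <- cd$time_point == "W1"
      X <- t(SummarizedExperiment::assay(tab)[, w1])
      rownames(X) <- cd$patient_id[w1]
      y <- ex$records$endpoint_binary[match(rownames(X),
                                            ex$records$patient_id)]
      cache[[key]] <<- list(X = X, y = y, records = ex$records)
    }
    cache[[key]]
  }
})

test_that("generation is bit-identical under a fixed seed", {
  spec <- syntheticCohortSpec(nPatients = 3, shape = c(24L, 24L),
                              nSlices = 2, radiusRange = c(5, 6),
                              maxFractions = 2, seed = 99)
  c1 <- suppressMessages(generateCohort(spec))
  c2 <- suppressMessages(generateCohort(spec))
  expect_identical(c1$records, c2$records)
  for (i in seq_along(c1$patients)) {
    p1 <- c1$patients[[i]]; p2 <- c2$patients[[i]]
    for (key in names(p1$scans))
      expect_identical(pixels(slices(p1$scans[[key]])[[1]]),
                       pixels(slices(p2$scans[[key]])[[1]]))
    expect_identical(p1$contours$planning[[1]]@vertices,
                     p2$contours$planning[[1]]@vertices)
  }
})

test_that("regimen mix and label prevalence follow the cohort spec", {
  spec <- syntheticCohortSpec(nPatients = 120, shape = c(24L, 24L),
                              nSlices = 1, radiusRange = c(5, 6),
                              maxFractions = 0, seed = 42)
  co <- suppressMessages(generateCohort(spec))
  expect_identical(sum(co$records$regimen == "74Gy_37F"), 71L)  # round(.59*120)
  expect_identical(nrow(co$records), 120L)
  npos <- sum(co$records$endpoint_binary)
  # binomial(120, 0.33) 99.9% range
  expect_true(npos > 20 && npos < 60)
  expect_true(all(co$records$endpoint_binary ==
                    (co$records$endpoint_grade >= 1)))

  # 12-patient cohort: positives within the binomial 99% range, reproducible
  spec12 <- syntheticCohortSpec(nPatients = 12, shape = c(24L, 24L),
                                nSlices = 1, radiusRange = c(5, 6),
                                maxFractions = 0, seed = 7)
  n1 <- sum(suppressMessages(generateCohort(spec12))$records$endpoint_binary)
  n2 <- sum(suppressMessages(generateCohort(spec12))$records$endpoint_binary)
  expect_identical(n1, n2)
  expect_true(n1 >= qbinom(0.005, 12, 0.33) && n1 <= qbinom(0.995, 12, 0.33))
})

test_that("daily images carry more within-wall variance than the planning scan", {
  spec <- syntheticCohortSpec(nPatients = 20, shape = c(32L, 32L),
                              nSlices = 3, radiusRange = c(5, 6.5),
                              delta = 0, maxFractions = 5, seed = 13)
  co <- suppressMessages(generateCohort(spec))
  wallVar <- function(scan, contours) {
    # intensity variance pooled over the wall pixels of all slices
    px <- unlist(lapply(seq_along(slices(scan)), function(k) {
      s <- slices(scan)[[k]]
      mask <- rasteriseContour(contours[[k]], dim(pixels(s)))
      pixels(s)[wallMask(buildWallRing(mask))]
    }))
    var(px)
  }
  worse <- 0L
  for (p in co$patients) {
    vCt <- wallVar(p$scans$planning, p$contours$planning)
    vMv <- mean(vapply(paste0("f", 1:5), function(k)
      wallVar(p$scans[[k]], p$contours[[k]]), numeric(1)))
    if (vMv > vCt) worse <- worse + 1L
  }
  expect_identical(worse, 20L)
})

test_that("with no injected effect, class feature distributions are exchangeable", {
  # Features within one cohort share the per-patient texture latent factor,
  # so their 118 screen p-values rise and fall together: a within-cohort
  # uniformity test has ~1 effective degree of freedom and is miscalibrated
  # by construction. The exchangeability property is therefore checked
  # across independent cohorts: under delta = 0 the screen p-value of the
  # effect-carrying feature (FOS2) is one independent Uniform(0,1) draw per
  # cohort.
  pv <- vapply(201:212, function(s) {
    fx <- w1Features(delta = 0, seed = s, n = 30)
    scr <- mwuScreen(fx$X[, "FOS2", drop = FALSE], fx$y)
    scr$p.value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
  # no systematic enrichment of small p-values
  expect_lte(sum(pv < 0.05), 2)
})

test_that("wall-texture effect injection separates classes monotonically in delta", {
  seeds <- c(5, 6, 7)
  medAuc <- vapply(c(0, 0.5, 1), function(delta) {
    median(vapply(seeds, function(s) {
      fx <- w1Features(delta = delta, seed = s)
      aucRank(fx$X[, "FOS2"], fx$y)
    }, numeric(1)))
  }, numeric(1))
  expect_lt(medAuc[1], medAuc[3])
  expect_lte(medAuc[1], medAuc[2] + 0.05)
  expect_lte(medAuc[2], medAuc[3] + 0.05)
  # at the default effect size the separation is strong
  expect_gt(medAuc[3], 0.7)
})

test_that("the default effect is detectable in week-1 scan variance", {
  # delta = 1, onset week 1: FOS2 at W1 differs between classes (MWU p < .05)
  pvals <- vapply(c(5, 6, 7), function(s) {
    fx <- w1Features(delta = 1, seed = s)
    suppressWarnings(wilcox.test(fx$X[fx$y == 1, "FOS2"],
                                 fx$X[fx$y == 0, "FOS2"])$p.value)
  }, numeric(1))
  expect_true(all(pvals < 0.05))
})
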