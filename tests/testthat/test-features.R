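test_that("fixed-bin discretisation follows the closed-form bin edges", {
  lv <- discretiseSubimage(matrix(0:63, 8, 8), 8)
  expect_identical(sort(unique(as.vector(lv))), 1:8)
  expect_true(all(table(lv) == 8))
  expect_true(all(discretiseSubimage(matrix(7, 4, 4), 8) == 1L))
  # affine intensity rescaling leaves levels unchanged
  x <- matrix(rnorm(64), 8, 8)
  expect_identical(discretiseSubimage(x, 8),
                   discretiseSubimage(3.2 * x - 41, 8))
  expect_error(discretiseSubimage(x, 1), "ng")
})

test_that("first-order features match closed forms and a sort-based oracle", {
  # constant grid: degenerate conventions
  f <- fosFeatures(matrix(5, 8, 8), ng = 8)
  expect_equal(unname(f[c("FOS2", "FOS3", "FOS4", "FOS16", "FOS18")]),
               rep(0, 5))
  expect_equal(unname(f["FOS19"]), 1)

  # four equally frequent values: uniformity 1/4, entropy 2 bits
  g <- matrix(rep(1:4, 16), 8, 8)
  fg <- fosFeatures(g, ng = 4)
  expect_equal(unname(fg["FOS19"]), 0.25)
  expect_equal(unname(fg["FOS18"]), 2)

  set.seed(11)
  for (i in 1:20) {
    x <- matrix(rnorm(64, 50, 20), 8, 8)
    f <- fosFeatures(x, ng = 8)
    v <- as.vector(x)
    expect_equal(unname(f["FOS1"]), mean(v))
    expect_equal(unname(f["FOS2"]), mean((v - mean(v))^2))
    expect_equal(unname(f["FOS5"]), median(v))
    expect_equal(unname(f["FOS6"]), min(v))
    expect_equal(unname(f["FOS7"]), unname(quantile(v, 0.1, type = 7)))
    expect_equal(unname(f["FOS8"]), unname(quantile(v, 0.9, type = 7)))
    expect_equal(unname(f["FOS9"]), max(v))
    expect_equal(unname(f["FOS11"]),
                 unname(diff(quantile(v, c(0.25, 0.75), type = 7))))
    expect_equal(unname(f["FOS12"]), diff(range(v)))
    expect_equal(unname(f["FOS13"]), mean(abs(v - mean(v))))
    expect_equal(unname(f["FOS15"]), mean(abs(v - median(v))))
    expect_equal(unname(f["FOS16"]), sd(v) * sqrt(63 / 64) / mean(v))
  }
})

test_that("texture matrices match exhaustive enumeration on random images", {
  dirs <- rbind(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  set.seed(23)
  for (i in 1:50) {
    nr <- sample(2:5, 1); nc <- sample(2:5, 1)
    ng <- sample(2:4, 1)
    lv <- randomLevels(nr, nc, ng)
    lvA <- structure(lv, ng = as.integer(ng))

    glcm <- textureMatrix(lvA, "GLCM")
    glrlm <- textureMatrix(lvA, "GLRLM")
    for (d in 1:4) {
      expect_equal(unname(glcm[[d]]), oracleGlcm(lv, ng, dirs[d, 1], dirs[d, 2]))
      ref <- oracleGlrlm(lv, ng, dirs[d, 1], dirs[d, 2])
      expect_equal(unname(glrlm[[d]]), ref)
    }
    expect_equal(unname(textureMatrix(lvA, "GLSZM")),
                 oracleZoneMatrix(lv, ng, "size"))
    expect_equal(unname(textureMatrix(lvA, "GLDZM")),
                 oracleZoneMatrix(lv, ng, "distance"))
    nt <- textureMatrix(lvA, "NGTDM")
    ref <- oracleNgtdm(lv, ng)
    expect_equal(unname(as.numeric(nt$s)), ref$s)
    expect_equal(unname(as.numeric(nt$n)), ref$n)
    expect_equal(unname(textureMatrix(lvA, "NGLDM")), oracleNgldm(lv, ng))
  }
})

test_that("GLCM matrices are symmetric and normalised", {
  set.seed(5)
  lv <- structure(randomLevels(8, 8, 6), ng = 6L)
  for (m in textureMatrix(lv, "GLCM")) {
    expect_equal(m, t(m))
    expect_equal(sum(m), 1)
  }
})

test_that("hand-computed texture feature values are reproduced", {
  two <- structure(matrix(c(1L, 2L, 1L, 2L), 2, 2), ng = 2L)  # [[1,1],[2,2]]
  g0 <- glcmFeaturesFromMatrix(textureMatrix(two, "GLCM")[[1]])
  expect_equal(unname(g0["jointMaximum"]), 0.5)
  expect_equal(unname(g0["contrast"]), 0)           # 0-degree pairs only
  sz <- textureFeatures(textureMatrix(two, "GLSZM"), "GLSZM", nVoxels = 4)
  expect_equal(unname(sz["GLSZM1"]), 0.25)          # (1/2)(1/4 + 1/4)
  expect_equal(unname(sz["GLSZM13"]), 0.5)          # 2 zones / 4 px

  const <- discretiseSubimage(matrix(3, 8, 8), 8)
  gc <- textureFeatures(textureMatrix(const, "GLCM"), "GLCM")
  expect_equal(unname(gc[c("GLCM12", "GLCM13")]), c(0, 0))
  expect_equal(unname(gc["GLCM11"]), 1)
  szc <- textureFeatures(textureMatrix(const, "GLSZM"), "GLSZM", 64)
  expect_equal(unname(szc["GLSZM2"]), 64^2)          # one zone of size 64
  nt <- textureFeatures(textureMatrix(const, "NGTDM"), "NGTDM", 64)
  expect_equal(unname(nt["NGTDM2"]), 0)
  # constant window NGLDM: corner/edge/interior dependence counts 3/5/8
  nl <- textureFeatures(textureMatrix(const, "NGLDM"), "NGLDM", 64)
  expect_equal(unname(nl["NGLDM17"]), (4^2 + 24^2 + 36^2) / 64^2)
})

test_that("compiled extractor agrees with the R formula implementations", {
  set.seed(31)
  for (i in 1:10) {
    x <- matrix(rnorm(64, 0, 30), 8, 8)
    lv <- discretiseSubimage(x, 8)
    got <- extractFeatures(x, 8)
    ref <- c(fosFeatures(x, lv, 8),
             textureFeatures(textureMatrix(lv, "GLCM"), "GLCM"),
             textureFeatures(textureMatrix(lv, "GLRLM"), "GLRLM", 64),
             textureFeatures(textureMatrix(lv, "GLSZM"), "GLSZM", 64),
             textureFeatures(textureMatrix(lv, "GLDZM"), "GLDZM", 64),
             textureFeatures(textureMatrix(lv, "NGTDM"), "NGTDM", 64),
             textureFeatures(textureMatrix(lv, "NGLDM"), "NGLDM", 64))
    expect_equal(unname(got), unname(ref), tolerance = 1e-12)
  }
})

test_that("every input yields 118 finite features in stable catalogue order", {
  cat118 <- featureCatalogue()
  expect_identical(nrow(cat118), 118L)
  expect_identical(cat118$name[1], "FOS1")
  counts <- c(c(table(cat118$family))[c("FOS", "GLCM", "GLRLM", "GLSZM",
                                        "GLDZM", "NGTDM", "NGLDM")])
  expect_equal(unname(counts), c(23, 25, 16, 16, 16, 5, 17))
  # indices cited in published coefficient tables all exist
  for (nm in c("FOS1", "FOS11", "FOS13", "FOS22", "FOS23", "GLCM6", "GLCM7",
               "GLCM25", "GLRLM7", "GLSZM3", "GLSZM5", "GLSZM6", "GLSZM8",
               "GLSZM16", "GLDZM3", "GLDZM4", "GLDZM5", "GLDZM7", "GLDZM10",
               "GLDZM14", "NGTDM3", "NGTDM5", "NGLDM3", "NGLDM7", "NGLDM15",
               "NGLDM16", "NGLDM17"))
    expect_true(nm %in% cat118$name)

  set.seed(4)
  inputs <- list(matrix(rnorm(64), 8, 8), matrix(0, 8, 8),
                 matrix(rep(c(1, 2), 32), 8, 8))
  for (x in inputs) {
    v <- extractFeatures(x)
    expect_length(v, 118)
    expect_true(all(is.finite(v)))
    expect_identical(names(v), cat118$name)
  }
})

test_that("90-degree rotation leaves direction-averaged GLCM/GLRLM unchanged", {
  set.seed(9)
  x <- matrix(rnorm(64), 8, 8)
  rot <- t(x)[, nrow(x):1]   # 90-degree rotation
  v1 <- extractFeatures(x); v2 <- extractFeatures(rot)
  fam <- featureCatalogue()$family
  expect_equal(v1[fam == "GLCM"], v2[fam == "GLCM"], tolerance = 1e-12)
  expect_equal(v1[fam == "GLRLM"], v2[fam == "GLRLM"], tolerance = 1e-12)
})

test_that("affine intensity rescaling changes only the raw-intensity features", {
  set.seed(14)
  x <- matrix(rnorm(64, 100, 25), 8, 8)
  y <- 2 * x + 10
  v1 <- extractFeatures(x); v2 <- extractFeatures(y)
  fam <- featureCatalogue()$family
  # discretised families are invariant
  expect_equal(v1[fam != "FOS"], v2[fam != "FOS"], tolerance = 1e-12)
  # raw-intensity statistics transform as expected
  expect_equal(unname(v2["FOS1"]), 2 * unname(v1["FOS1"]) + 10)
  expect_equal(unname(v2["FOS2"]), 4 * unname(v1["FOS2"]))
  expect_equal(unname(v2["FOS12"]), 2 * unname(v1["FOS12"]))
})
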