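fakeRecords <- function(n, nPos, seed = 1) {
  set.seed(seed)
  data.frame(patient_id = sprintf("P%03d", seq_len(n)),
             endpoint_binary = sample(c(rep(1L, nPos), rep(0L, n - nPos))))
}

test_that("cohort split reproduces the published 75:25 sizes and strata", {
  # 110 patients, 32 positive -> 82 train / 28 test with 8 positive test
  rec <- fakeRecords(110, 32)
  sp <- splitCohort(rec, seed = 4)
  expect_length(sp$train, 82)
  expect_length(sp$test, 28)
  y <- setNames(rec$endpoint_binary, rec$patient_id)
  expect_identical(sum(y[sp$test]), 8L)
  expect_identical(sum(y[sp$train]), 24L)

  # 77 patients, 30 positive -> 58 train / 19 test with 8 positive test
  rec2 <- fakeRecords(77, 30)
  sp2 <- splitCohort(rec2, seed = 4)
  expect_length(sp2$train, 58)
  expect_length(sp2$test, 19)
  y2 <- setNames(rec2$endpoint_binary, rec2$patient_id)
  expect_identical(sum(y2[sp2$test]), 8L)

  # determinism and disjointness
  sp3 <- splitCohort(rec, seed = 4)
  expect_identical(sort(sp$test), sort(sp3$test))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_error(splitCohort(fakeRecords(10, 1)), "2 patients per")
})

test_that("z-scoring uses training-set population parameters", {
  tr <- cbind(a = c(1, 2, 3), b = c(10, 10, 10), c = rnorm(3))
  te <- cbind(a = c(2, 4), b = c(10, 11), c = rnorm(2))
  expect_message(z <- zscoreStandardise(tr, te), "constant")
  expect_identical(z$dropped, "b")
  expect_equal(unname(z$train[, "a"]), c(-1, 0, 1) * sqrt(3 / 2))
  expect_equal(colMeans(z$train), c(a = 0, c = 0), tolerance = 1e-10)
  expect_equal(sqrt(colMeans(z$train^2)), c(a = 1, c = 1), tolerance = 1e-10)
  # test value equal to the training mean maps to 0
  expect_equal(unname(z$newdata[1, "a"]), 0)
})

test_that("Mann-Whitney screen matches exact and degenerate cases", {
  X <- cbind(f1 = c(1, 6, 3, 2, 5, 4),
             f2 = c(1, 1, 2, 1, 1, 2),
             f3 = c(4, 5, 6, 1, 2, 3))
  y <- c(1, 1, 1, 0, 0, 0)
  scr <- mwuScreen(X, y)
  # f2 identical distributions across groups -> p = 1
  expect_equal(scr$p.value[scr$feature == "f2"], 1)
  # complete separation of two groups of 3: exact two-sided p = 0.1
  expect_equal(scr$p.value[scr$feature == "f3"], 0.1)
  expect_equal(scr$statistic[scr$feature == "f3"], 9)  # U for the positives
  # top-10 listing ranks ascending p
  top <- attr(scr, "top10")
  expect_identical(top$feature[1], "f3")
  expect_true(!is.unsorted(top$p.value))
})

test_that("Spearman pruning keeps the more significant of correlated pairs", {
  set.seed(6)
  base <- rnorm(40)
  X <- cbind(u = base, v = base,                     # rho = 1 duplicate
             w = rnorm(40), x = rnorm(40))
  y <- rep(c(0, 1), 20)
  # force a p-value ordering: u more significant than v
  scr <- mwuScreen(X, y)
  scr$p.value <- c(0.01, 0.5, 0.3, 0.7)
  pr <- spearmanPrune(X, scr)
  expect_true("u" %in% pr$retained)
  expect_false("v" %in% pr$retained)
  expect_identical(pr$dropped$removed, "v")

  # three pairwise-collinear features -> a single survivor
  X3 <- cbind(a = base, b = 2 * base + 1, c = -base, d = rnorm(40))
  scr3 <- mwuScreen(X3, y)
  scr3$p.value <- c(0.2, 0.05, 0.4, 0.9)
  pr3 <- spearmanPrune(X3, scr3)
  expect_setequal(pr3$retained, c("b", "d"))

  # independent features at n = 200 survive untouched
  set.seed(12)
  Xi <- matrix(rnorm(200 * 20), 200, 20,
               dimnames = list(NULL, paste0("g", 1:20)))
  yi <- rep(c(0, 1), 100)
  pri <- spearmanPrune(Xi, mwuScreen(Xi, yi))
  expect_length(pri$retained, 20)

  # post-hoc guarantee on the survivors
  rho <- abs(cor(X3[, pr3$retained], method = "spearman"))
  diag(rho) <- 0
  expect_lt(max(rho), 0.8)
})

test_that("rank AUC equals the exhaustive pair-counting oracle", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(6:25, 1)
    y <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    s <- sample(seq_len(8), n, replace = TRUE) / 2   # ties likely
    expect_equal(aucRank(s, y), oracleAuc(s, y))
  }
  expect_equal(aucRank(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(aucRank(c(1, 1, 1, 1), c(0, 1, 0, 1)), 0.5)
})

test_that("elastic net: shrinkage limit, separable case, C grid mapping", {
  set.seed(10)
  n <- 60
  y <- rep(c(0L, 1L), n / 2)
  X <- cbind(s = as.numeric(scale(y + rnorm(n, 0, 0.1))),
             n1 = rnorm(n), n2 = rnorm(n))
  # strongest penalty forced: all coefficients zero, intercept = log-odds
  fit <- fitElasticNetCV(X, y, cGrid = 1e-4, seed = 2)
  expect_true(all(fit$coefficients[-1] == 0))
  expect_equal(unname(fit$coefficients[1]), log(mean(y) / (1 - mean(y))),
               tolerance = 1e-6)

  # single perfectly ordered feature at large C: training AUC 1
  Xp <- cbind(s = seq_len(n))
  yp <- as.integer(seq_len(n) > n / 2)
  fitp <- fitElasticNetCV(Xp, yp, cGrid = 1e3, seed = 2)
  expect_equal(aucRank(predictScores(fitp, Xp), yp), 1)

  # CV over the full grid selects a model that separates better than null
  fitcv <- fitElasticNetCV(X, y, seed = 2)
  expect_gt(aucRank(predictScores(fitcv, X), y), 0.9)
  expect_true(fitcv$cSelected >= 1e-4 && fitcv$cSelected <= 1e3)
})

test_that("elastic net recovers informative features from noise", {
  # 3 informative features (1 SD shift) + 20 noise, n = 200
  hits <- 0
  reps <- 20
  for (r in seq_len(reps)) {
    set.seed(1000 + r)
    y <- rep(c(0L, 1L), 100)
    X <- cbind(matrix(rnorm(200 * 3) + outer(y, rep(1, 3)), 200, 3),
               matrix(rnorm(200 * 20), 200, 20))
    colnames(X) <- c(paste0("inf", 1:3), paste0("noise", 1:20))
    z <- zscoreStandardise(X)
    fit <- fitElasticNetCV(z$train, y, seed = r)
    nz <- names(fit$coefficients[-1])[fit$coefficients[-1] != 0]
    if (sum(startsWith(nz, "inf")) >= 2) hits <- hits + 1
  }
  # >= 80% expected; 13/20 is the one-sided binomial 95% bound for 0.8
  expect_gte(hits, 13)
})

test_that("bootstrap AUC summarises resampled uncertainty correctly", {
  y <- rep(c(0L, 1L), 20)
  sPerfect <- y + rnorm(40, 0, 1e-4)
  b <- bootstrapAuc(sPerfect, y, seed = 1)
  expect_equal(b$auc, 1)
  expect_equal(unname(b$ci), c(1, 1))
  expect_length(b$boot, 100)

  # null scores, n = 200: AUC within [0.4, 0.6] in nearly all seeded runs
  inBand <- 0
  for (r in 1:20) {
    set.seed(300 + r)
    yn <- rep(c(0L, 1L), 100)
    sn <- rnorm(200)
    b <- bootstrapAuc(sn, yn, seed = r)
    if (b$auc >= 0.4 && b$auc <= 0.6) inBand <- inBand + 1
    expect_true(all(b$ci >= 0 & b$ci <= 1))
    expect_lte(b$ci[1], b$auc + 1e-12)
  }
  expect_gte(inBand, 18)   # one-sided binomial 95% bound for a 0.95 rate
})

test_that("Youden operating point matches the all-cut-points oracle", {
  yp <- c(0, 0, 0, 1, 1, 1)
  sp <- c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9)
  got <- youdenThreshold(sp, yp)
  expect_equal(got$sensitivity, 1)
  expect_equal(got$specificity, 1)
  # all-identical scores: J = 0 at the degenerate cut
  same <- youdenThreshold(rep(2, 6), yp)
  expect_equal(same$J, 0)
  set.seed(21)
  for (i in 1:20) {
    y <- c(0, 1, sample(0:1, 18, replace = TRUE))
    s <- sample(seq_len(10), 20, replace = TRUE) / 3
    got <- youdenThreshold(s, y)
    ref <- oracleYouden(s, y)
    expect_equal(got$J, ref$J)
    expect_equal(got$threshold, ref$threshold)   # ties -> lowest threshold
  }
})

test_that("one-sided bootstrap-AUC comparisons behave symmetrically", {
  set.seed(17)
  a <- runif(100, 0.6, 0.8)
  expect_equal(compareAucSamples(a, a), 0.5)
  b <- a - 0.2
  expect_lt(compareAucSamples(a, b), 0.001)
  expect_gt(compareAucSamples(b, a), 0.999)
  # antisymmetry under the tie-corrected approximation
  c1 <- runif(100, 0.5, 0.9)
  expect_equal(compareAucSamples(a, c1) + compareAucSamples(c1, a), 1,
               tolerance = 1e-9)
})
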