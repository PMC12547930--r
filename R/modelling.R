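#' Stratified 75:25 cohort split
#'
#' Splits patient ids into training and test sets stratified by the binary
#' endpoint. The test-set size is round-half-up(0.25 N) overall, with
#' round-half-up(0.25 n_pos) positive patients and the remainder negatives -
#' the rounding scheme that reproduces published split tables for cohorts of
#' 110 (82/28, 8 positive test patients) and 77 (58/19, 8 positive test
#' patients). Deterministic given `seed`.
#'
#' @param records data.frame with `patient_id` and `endpoint_binary`.
#' @param trainFraction training proportion (default 0.75).
#' @param seed integer seed.
#' @return list with `train` and `test` character vectors of patient ids.
#' @export
splitCohort <- function(records, trainFraction = 0.75, seed = 1L) {
  pos <- records$patient_id[records$endpoint_binary == 1]
  neg <- records$patient_id[records$endpoint_binary == 0]
  if (length(pos) < 2 || length(neg) < 2)
    stop("need at least 2 patients per endpoint class to split")
  n <- nrow(records)
  testN <- roundHalfUp((1 - trainFraction) * n)
  testPos <- min(roundHalfUp((1 - trainFraction) * length(pos)),
                 length(pos) - 1L, testN)
  testNeg <- testN - testPos
  set.seed(seed)
  tpos <- sample(pos, testPos)
  tneg <- sample(neg, testNeg)
  test <- c(tpos, tneg)
  list(train = setdiff(records$patient_id, test), test = test)
}

#' Z-score standardisation with training-set parameters
#'
#' Column means and population standard deviations (divisor n) are estimated
#' on the training matrix and applied to both the training matrix and any
#' new data. Constant training columns (sd = 0) are dropped with a message.
#'
#' @param train numeric matrix (training rows x features).
#' @param newdata optional matrix with the same columns to transform with
#'   the training parameters.
#' @return list with `train`, `newdata` (or NULL), `center`, `scale`,
#'   `dropped` (names of constant columns).
#' @export
zscoreStandardise <- function(train, newdata = NULL) {
  mu <- colMeans(train)
  sdev <- sqrt(colMeans(sweep(train, 2, mu)^2))
  keep <- sdev > 0
  if (any(!keep))
    message("dropping ", sum(!keep), " constant feature(s): ",
            paste(head(colnames(train)[!keep], 5), collapse = ", "))
  tr <- sweep(sweep(train[, keep, drop = FALSE], 2, mu[keep]), 2,
              sdev[keep], "/")
  nd <- if (!is.null(newdata))
    sweep(sweep(newdata[, keep, drop = FALSE], 2, mu[keep]), 2,
          sdev[keep], "/")
  list(train = tr, newdata = nd, center = mu[keep], scale = sdev[keep],
       dropped = colnames(train)[!keep])
}

#' Mann-Whitney univariate screen
#'
#' Two-sided Mann-Whitney U test of every feature against the binary
#' endpoint: exact enumeration when both groups have <= 8 members and there
#' are no ties, normal approximation with tie correction otherwise. The
#' screen ranks features but does not drop any - it feeds the correlation
#' pruning step, where significance decides which member of a correlated
#' pair is kept.
#'
#' @param design numeric matrix, patients x features.
#' @param labels binary 0/1 vector aligned with rows.
#' @return data.frame (`feature`, `statistic`, `p.value`) in design column
#'   order, with the top-10 smallest-p listing in `attr(x, "top10")`.
#' @export
mwuScreen <- function(design, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) != 2) stop("both endpoint classes required")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  res <- vapply(seq_len(ncol(design)), function(j) {
    x <- design[labels == 1, j]; y <- design[labels == 0, j]
    if (length(unique(c(x, y))) == 1)        # constant feature: no evidence
      return(c(n1 * n0 / 2, 1))
    exact <- n1 <= 8 && n0 <= 8 && !any(duplicated(c(x, y)))
    w <- suppressWarnings(wilcox.test(x, y, exact = exact))
    c(w$statistic, w$p.value)
  }, numeric(2))
  out <- data.frame(feature = colnames(design), statistic = res[1, ],
                    p.value = res[2, ], stringsAsFactors = FALSE)
  attr(out, "top10") <- out[order(out$p.value), ][
    seq_len(min(10, nrow(out))), ]
  out
}

#' Spearman redundancy pruning
#'
#' Iterates over feature pairs whose training-set Spearman correlation has
#' absolute value >= `threshold`, in descending |rho| (ties broken
#' lexicographically by name pair). Within a pair the feature with the
#' larger screen p-value is removed (ties: the lexicographically later
#' name); pairs involving already-removed features are skipped. The returned
#' set is guaranteed (and asserted) to contain no pair with training |rho|
#' >= `threshold`.
#'
#' @param design numeric matrix, patients x features (training set).
#' @param screen the [mwuScreen] result for the same design.
#' @param threshold absolute Spearman correlation cut-off (default 0.8).
#' @return list with `retained` (character), `dropped` (data.frame: a, b,
#'   rho, removed).
#' @export
spearmanPrune <- function(design, screen, threshold = 0.8) {
  stopifnot(identical(colnames(design), screen$feature))
  rho <- suppressWarnings(cor(design, method = "spearman"))
  rho[is.na(rho)] <- 0
  p <- ncol(design)
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  ut <- ut[abs(rho[ut]) >= threshold, , drop = FALSE]
  pv <- setNames(screen$p.value, screen$feature)
  nm <- colnames(design)
  dropped <- character(0)
  log <- list()
  if (nrow(ut) > 0) {
    a <- nm[ut[, 1]]; b <- nm[ut[, 2]]
    r <- abs(rho[ut])
    swap <- a > b   # canonical (lexicographically ordered) pair names
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    o <- order(-r, a, b)
    a <- a[o]; b <- b[o]; r <- r[o]
    for (k in seq_along(a)) {
      if (a[k] %in% dropped || b[k] %in% dropped) next
      pa <- pv[a[k]]; pb <- pv[b[k]]
      rm <- if (pa > pb) a[k]
            else if (pb > pa) b[k]
            else max(a[k], b[k])   # tie: lexicographically later name
      dropped <- c(dropped, rm)
      log[[length(log) + 1]] <- data.frame(a = a[k], b = b[k], rho = r[k],
                                           removed = rm,
                                           stringsAsFactors = FALSE)
    }
  }
  retained <- setdiff(nm, dropped)
  # post-hoc guarantee
  rr <- abs(rho[retained, retained, drop = FALSE])
  diag(rr) <- 0
  if (length(rr) && max(rr) >= threshold)
    stop("internal error: pruned set still contains |rho| >= ", threshold)
  list(retained = retained,
       dropped = if (length(log)) do.call(rbind, log) else
         data.frame(a = character(), b = character(), rho = numeric(),
                    removed = character()))
}

#' Rank-based AUC
#'
#' Area under the ROC curve via the rank (Mann-Whitney) formulation; tied
#' scores contribute 1/2.
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 vector.
#' @return AUC in `[0, 1]`.
#' @export
aucRank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified fold assignment, deterministic given seed
stratifiedFolds <- function(labels, folds, seed) {
  set.seed(seed)
  id <- integer(length(labels))
  for (cl in unique(labels)) {
    ix <- sample(which(labels == cl))
    id[ix] <- rep_len(seq_len(folds), length(ix))
  }
  id
}

#' Elastic-net logistic regression with cross-validated strength
#'
#' Penalised logistic regression (glmnet) with the elastic-net mixing
#' parameter fixed at `l1Ratio` and the inverse regularisation strength C
#' tuned over a 500-point log-spaced grid from 1e-4 to 1e3 by stratified
#' 5-fold cross-validation maximising mean fold AUC. C maps onto the glmnet
#' penalty as lambda = 1 / (n C). Ties in mean CV AUC resolve toward the
#' stronger penalty (smaller C). Features are assumed standardised upstream
#' (no internal standardisation).
#'
#' @param design standardised numeric matrix, patients x features.
#' @param labels binary 0/1 vector.
#' @param cGrid grid of C values.
#' @param l1Ratio elastic-net mixing parameter (default 0.5).
#' @param folds number of CV folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @return list with `coefficients` (named, intercept first, all features),
#'   `cSelected`, `lambda`, `cvAuc` (per-C mean fold AUC), `fit` (the
#'   full-data glmnet object) and `features`.
#' @export
fitElasticNetCV <- function(design, labels,
                            cGrid = 10^seq(-4, 3, length.out = 500),
                            l1Ratio = 0.5, folds = 5, seed = 1L) {
  labels <- as.integer(labels)
  n <- nrow(design)
  if (min(table(labels)) < folds)
    stop("need at least ", folds, " members per class for ", folds,
         "-fold CV")
  featNames <- colnames(design)
  if (ncol(design) == 1) {
    # glmnet needs >= 2 columns; pad with an all-zero dummy (coefficient is
    # identically 0 and is stripped from the result)
    design <- cbind(design, `..dummy` = 0)
  }
  cGrid <- sort(cGrid)                       # ascending C
  lambda <- 1 / (n * cGrid)                  # descending lambda for glmnet
  foldid <- stratifiedFolds(labels, folds, seed)
  cvAuc <- matrix(NA_real_, folds, length(lambda))
  for (f in seq_len(folds)) {
    inF <- foldid == f
    fit <- glmnet::glmnet(design[!inF, , drop = FALSE], labels[!inF],
                          family = "binomial", alpha = l1Ratio,
                          lambda = lambda, standardize = FALSE)
    pr <- predict(fit, design[inF, , drop = FALSE], s = lambda,
                  type = "link")
    cvAuc[f, ] <- apply(pr, 2, function(s) {
      if (length(unique(s)) == 1) 0.5 else aucRank(s, labels[inF])
    })
  }
  meanAuc <- colMeans(cvAuc)
  best <- which(meanAuc == max(meanAuc))[1]  # first = largest lambda
  fit <- glmnet::glmnet(design, labels, family = "binomial",
                        alpha = l1Ratio, lambda = lambda,
                        standardize = FALSE)
  co <- as.numeric(predict(fit, s = lambda[best], type = "coefficients"))
  names(co) <- c("(Intercept)", colnames(design))
  co <- co[names(co) != "..dummy"]
  list(coefficients = co, cSelected = cGrid[best], lambda = lambda[best],
       cvAuc = setNames(meanAuc, signif(cGrid, 6)), fit = fit,
       features = featNames)
}

#' Linear predictor scores from a fitted elastic-net model
#'
#' @param model result of [fitElasticNetCV].
#' @param design matrix with the model's feature columns.
#' @return numeric score vector (log-odds scale).
#' @export
predictScores <- function(model, design) {
  x <- design[, model$features, drop = FALSE]
  if (ncol(x) == 1) x <- cbind(x, `..dummy` = 0)
  as.numeric(predict(model$fit, x, s = model$lambda, type = "link"))
}

#' Bootstrap AUC with percentile confidence interval
#'
#' Point AUC on the full score set plus `B` class-stratified bootstrap
#' resamples (with replacement), summarised by the 2.5/97.5 empirical
#' percentiles. Stratification guarantees both classes in every resample.
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 vector.
#' @param B number of bootstrap resamples (default 100).
#' @param seed integer seed.
#' @return list with `auc`, `ci` (length 2), `boot` (the B resampled AUCs).
#' @export
bootstrapAuc <- function(scores, labels, B = 100, seed = 1L) {
  labels <- as.integer(labels)
  ixPos <- which(labels == 1); ixNeg <- which(labels == 0)
  set.seed(seed)
  boot <- vapply(seq_len(B), function(b) {
    ix <- c(sample(ixPos, replace = TRUE), sample(ixNeg, replace = TRUE))
    aucRank(scores[ix], labels[ix])
  }, numeric(1))
  list(auc = aucRank(scores, labels),
       ci = unname(quantile(boot, c(0.025, 0.975), type = 7)),
       boot = boot)
}

#' Youden-index operating point
#'
#' Scans all observed score cut-points (classify positive when
#' score >= threshold) and returns the threshold maximising
#' J = sensitivity + specificity - 1; ties resolve to the lowest threshold
#' (highest sensitivity).
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 vector.
#' @return list with `threshold`, `sensitivity`, `specificity`, `J`.
#' @export
youdenThreshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) != 2) stop("both classes required")
  cand <- sort(unique(scores))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  best <- list(J = -Inf)
  for (t in cand) {
    sens <- sum(scores >= t & labels == 1) / n1
    spec <- sum(scores < t & labels == 0) / n0
    J <- sens + spec - 1
    if (J > best$J)
      best <- list(threshold = t, sensitivity = sens, specificity = spec,
                   J = J)
  }
  best
}

#' Sensitivity and specificity at a fixed threshold
#'
#' @param scores numeric scores; positive classification when
#'   `scores >= threshold`.
#' @param labels binary 0/1 vector.
#' @param threshold the operating threshold.
#' @return named numeric (`sensitivity`, `specificity`).
#' @export
sensSpecAt <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  c(sensitivity = sum(scores >= threshold & labels == 1) / sum(labels == 1),
    specificity = sum(scores < threshold & labels == 0) / sum(labels == 0))
}

#' One-sided comparison of two bootstrap AUC samples
#'
#' One-sided Mann-Whitney U test (normal approximation with tie correction,
#' no continuity correction) of the hypothesis that sample `a` is
#' stochastically greater than sample `b`. Identical samples give p = 0.5;
#' p(a > b) + p(b > a) = 1.
#'
#' @param a,b numeric bootstrap AUC samples.
#' @return one-sided p-value.
#' @export
compareAucSamples <- function(a, b) {
  if (length(unique(c(a, b))) == 1) return(0.5)   # fully tied: no evidence
  suppressWarnings(wilcox.test(a, b, alternative = "greater",
                               exact = FALSE, correct = FALSE))$p.value
}
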