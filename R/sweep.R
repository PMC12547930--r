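#' Sweep toxicity models across treatment time points
#'
#' Runs the full modelling chain at every time point present in the feature
#' table: assemble the design, z-score with training-set parameters,
#' Mann-Whitney screen, Spearman redundancy pruning (separate mode) or
#' accumulation of the separate-mode selections (cumulative mode),
#' elastic-net logistic regression with 5-fold cross-validated strength,
#' bootstrap AUC evaluation of the training and test sets, the Youden
#' operating point, and all pairwise one-sided Mann-Whitney comparisons of
#' the bootstrap AUC distributions. A failure at one time point is recorded
#' and does not abort the sweep.
#'
#' @param table `SummarizedExperiment` from [buildWeekTable].
#' @param records cohort records (`patient_id`, `endpoint_binary`).
#' @param split list with `train`/`test` ids from [splitCohort].
#' @param mode `"separate"` or `"cumulative"`.
#' @param selections separate-mode pruned selections (required for
#'   cumulative mode); the `selections` slot of a separate-mode sweep.
#' @param cGrid,l1Ratio,folds elastic-net tuning parameters (see
#'   [fitElasticNetCV]).
#' @param bootB bootstrap resample count (default 100).
#' @param rhoThreshold Spearman pruning threshold (default 0.8).
#' @param seed integer master seed for folds and bootstrap.
#' @return a [TimepointSweep].
#' @export
sweepTimepoints <- function(table, records, split,
                            mode = c("separate", "cumulative"),
                            selections = NULL,
                            cGrid = 10^seq(-4, 3, length.out = 500),
                            l1Ratio = 0.5, folds = 5, bootB = 100,
                            rhoThreshold = 0.8, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "cumulative" && is.null(selections))
    stop("cumulative mode requires the separate-analysis selections")
  cd <- SummarizedExperiment::colData(table)
  tps <- unique(cd$time_point)
  tps <- tps[order(tpOrder(tps))]
  y <- setNames(records$endpoint_binary, records$patient_id)
  models <- list(); sel <- list(); failures <- character(0)

  for (k in seq_along(tps)) {
    tp <- tps[k]
    res <- tryCatch({
      X <- assembleDesign(table, tp, mode, selections)
      trainIds <- intersect(split$train, rownames(X))
      testIds <- intersect(split$test, rownames(X))
      z <- zscoreStandardise(X[trainIds, , drop = FALSE],
                             X[testIds, , drop = FALSE])
      scr <- mwuScreen(z$train, y[trainIds])
      if (mode == "separate") {
        pr <- spearmanPrune(z$train, scr, rhoThreshold)
        feats <- pr$retained
      } else {
        feats <- colnames(z$train)
      }
      Xtr <- z$train[, feats, drop = FALSE]
      Xte <- z$newdata[, feats, drop = FALSE]
      fit <- fitElasticNetCV(Xtr, y[trainIds], cGrid = cGrid,
                             l1Ratio = l1Ratio, folds = folds,
                             seed = deriveSeed(seed, 10 + k))
      str <- predictScores(fit, Xtr)
      ste <- predictScores(fit, Xte)
      btr <- bootstrapAuc(str, y[trainIds], B = bootB,
                          seed = deriveSeed(seed, 100 + k))
      bte <- bootstrapAuc(ste, y[testIds], B = bootB,
                          seed = deriveSeed(seed, 200 + k))
      yj <- youdenThreshold(str, y[trainIds])
      sste <- sensSpecAt(ste, y[testIds], yj$threshold)
      coefAll <- fit$coefficients
      nz <- coefAll[c(TRUE, coefAll[-1] != 0)]
      wald <- waldRefit(nz, Xtr, y[trainIds])
      list(sel = feats, model = new("ModelResult",
        timePoint = tp, features = feats, coefficients = nz,
        cSelected = fit$cSelected,
        train = list(auc = btr$auc, ci = btr$ci, boot = btr$boot,
                     sensitivity = yj$sensitivity,
                     specificity = yj$specificity, n = length(trainIds),
                     wald = wald),
        test = list(auc = bte$auc, ci = bte$ci, boot = bte$boot,
                    sensitivity = unname(sste["sensitivity"]),
                    specificity = unname(sste["specificity"]),
                    n = length(testIds)),
        threshold = yj$threshold))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[tp] <- conditionMessage(res)
      message("time point ", tp, " aborted: ", conditionMessage(res))
      models[tp] <- list(NULL)
    } else {
      models[[tp]] <- res$model
      sel[[tp]] <- if (mode == "separate")
        res$sel else res$sel   # accumulated set in cumulative mode
    }
  }

  ok <- names(models)[!vapply(models, is.null, logical(1))]
  comp <- list()
  for (a in ok) for (b in ok) {
    if (a == b) next
    comp[[length(comp) + 1]] <- data.frame(
      a = a, b = b,
      train_p = compareAucSamples(models[[a]]@train$boot,
                                  models[[b]]@train$boot),
      test_p = compareAucSamples(models[[a]]@test$boot,
                                 models[[b]]@test$boot),
      stringsAsFactors = FALSE)
  }
  new("TimepointSweep", mode = mode, timePoints = tps, models = models,
      selections = sel,
      comparisons = if (length(comp)) do.call(rbind, comp) else
        data.frame(a = character(), b = character(), train_p = numeric(),
                   test_p = numeric()),
      failures = failures)
}

# per-coefficient Wald p-values from an unpenalised logistic refit on the
# non-zero support (the penalised fit itself provides no standard errors;
# the refit choice is stated in the report docs)
waldRefit <- function(nzCoefs, design, labels) {
  feats <- names(nzCoefs)[-1]
  out <- data.frame(parameter = names(nzCoefs),
                    coefficient = unname(nzCoefs),
                    p.value = NA_real_, stringsAsFactors = FALSE)
  if (length(feats) == 0) return(out)
  df <- data.frame(y = labels, design[, feats, drop = FALSE],
                   check.names = FALSE)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = "binomial"))
  sm <- summary(fit)$coefficients
  rownames(sm) <- sub("^`|`$", "", rownames(sm))
  out$p.value <- sm[match(out$parameter, rownames(sm)), 4]
  out
}

#' Select the optimal re-planning week
#'
#' Applies the plateau rule: the optimal time point is the earliest t such
#' that no later time point's training-AUC bootstrap distribution
#' significantly exceeds t's (one-sided Mann-Whitney p < `alpha`). If every
#' pair is indistinguishable the earliest time point (CT) is returned. A
#' selection falling on the final treatment week is annotated as having
#' limited practical utility (no fractions remain to adapt).
#'
#' @param sweep a [TimepointSweep].
#' @param alpha significance level for "significant improvement"
#'   (default 0.05).
#' @return list with `timePoint`, `weekIndex` (0 = CT), `annotation`
#'   (`NA` or `"limited practical utility"`), and `rationale` (data.frame of
#'   all later-vs-candidate comparisons with p-values).
#' @export
selectOptimalWeek <- function(sweep, alpha = 0.05) {
  ok <- sweep@timePoints[vapply(sweep@timePoints, function(tp)
    !is.null(sweep@models[[tp]]), logical(1))]
  if (length(ok) == 0) stop("sweep contains no successful time points")
  rationale <- list()
  chosen <- ok[length(ok)]
  for (k in seq_along(ok)) {
    tp <- ok[k]
    later <- ok[seq_along(ok) > k]
    ps <- vapply(later, function(l) compareAucSamples(
      sweep@models[[l]]@train$boot, sweep@models[[tp]]@train$boot),
      numeric(1))
    if (length(later))
      rationale[[tp]] <- data.frame(candidate = tp, later = later,
                                    p_later_better = unname(ps),
                                    stringsAsFactors = FALSE)
    if (all(ps >= alpha)) { chosen <- tp; break }
  }
  isFinal <- chosen == ok[length(ok)] && length(ok) > 1
  list(timePoint = chosen, weekIndex = tpOrder(chosen),
       annotation = if (isFinal) "limited practical utility" else
         NA_character_,
       rationale = do.call(rbind, rationale))
}
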