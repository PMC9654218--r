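#' Subject-dependent k-fold cross-validation plan
#'
#' Five-fold subject-dependent evaluation: per subject (and per class when
#' stratified) the epochs are shuffled and dealt round-robin into k test
#' folds, so test sets partition the data with ~20% per fold at k = 5.
#' Within each fold, a random 30% of the remaining 80% is held out for
#' validation and the other 70% trains the model.
#'
#' @param es an [EEGEpochSet-class].
#' @param k number of folds (default 5).
#' @param valFrac validation fraction of the non-test pool (default 0.3).
#' @param seed shuffling seed.
#' @param stratify stratify fold assignment by subject and class.
#' @return a [CVPlan-class].
#' @export
planSubjectDependent <- function(es, k = 5L, valFrac = 0.3, seed = 1L,
                                 stratify = TRUE) {
  stopifnot(is(es, "EEGEpochSet"))
  if (k < 2L) stop("k must be at least 2")
  n <- nEpochs(es)
  if (n < k) stop("fewer epochs than folds")
  set.seed(seed)
  foldOf <- integer(n)
  groups <- if (stratify)
    split(seq_len(n), list(es@subjectIds, as.character(es@labels)),
          drop = TRUE)
  else split(seq_len(n), es@subjectIds)
  for (g in groups) {
    g <- g[sample.int(length(g))]
    foldOf[g] <- rep(seq_len(k), length.out = length(g))
  }
  folds <- lapply(seq_len(k), function(f) {
    test <- which(foldOf == f)
    pool <- setdiff(seq_len(n), test)
    nVal <- round(valFrac * length(pool))
    # stratify the validation draw by subject, topping up by largest
    # remainder so the total is exact
    bySubj <- split(pool, es@subjectIds[pool])
    targets <- vapply(bySubj, function(p) valFrac * length(p), numeric(1))
    base <- floor(targets)
    extra <- nVal - sum(base)
    orderRem <- order(targets - base, decreasing = TRUE)
    addTo <- names(bySubj)[orderRem[seq_len(max(0L, extra))]]
    val <- unlist(lapply(names(bySubj), function(s) {
      take <- base[[s]] + as.integer(s %in% addTo)
      p <- bySubj[[s]]
      p[sample.int(length(p))][seq_len(min(take, length(p)))]
    }), use.names = FALSE)
    list(train = sort(setdiff(pool, val)), val = sort(val),
         test = sort(test))
  })
  new("CVPlan", scheme = "subject_dependent_kfold", folds = folds,
      seed = as.integer(seed))
}

#' Leave-one-subject-out cross-validation plan
#'
#' One fold per subject: the held-out subject's epochs form the test set;
#' a random 30% of the remaining epochs (not balanced across subjects)
#' forms the validation set and the rest trains the model.
#'
#' @param es an [EEGEpochSet-class] with at least two subjects.
#' @param valFrac validation fraction of the training pool.
#' @param seed shuffling seed.
#' @return a [CVPlan-class].
#' @export
planLOSO <- function(es, valFrac = 0.3, seed = 1L) {
  stopifnot(is(es, "EEGEpochSet"))
  subjects <- unique(es@subjectIds)
  if (length(subjects) < 2L)
    stop("leave-one-subject-out needs at least 2 subjects")
  set.seed(seed)
  folds <- lapply(subjects, function(s) {
    test <- which(es@subjectIds == s)
    pool <- which(es@subjectIds != s)
    val <- sort(pool[sample.int(length(pool))][
      seq_len(round(valFrac * length(pool)))])
    list(train = sort(setdiff(pool, val)), val = val, test = sort(test),
         subject = s)
  })
  new("CVPlan", scheme = "loso", folds = folds, seed = as.integer(seed))
}

#' Majority-class chance level
#'
#' The accuracy obtained by always predicting the most frequent class.
#'
#' @param labels factor or character label vector.
#' @return fraction in (0, 1].
#' @examples
#' chanceLevel(c("P", "P", "N"))  # 2/3
#' @export
chanceLevel <- function(labels) {
  if (length(labels) == 0L) stop("empty label vector")
  max(table(labels)) / length(labels)
}

ci95t <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) return(c(NA_real_, NA_real_))
  m <- mean(x); se <- stats::sd(x) / sqrt(n)
  m + c(-1, 1) * stats::qt(0.975, n - 1L) * se
}

#' Run a cross-validated classification experiment
#'
#' Trains the given model (a ConvNet [ModelSpec-class] on raw epochs, or a
#' [baselineSpec()] on Welch band-power features) on every fold of the
#' plan from a fresh seeded initialisation, selects the best-validation
#' checkpoint, and evaluates test accuracy.  Accuracies are aggregated
#' subject-first: the mean, sd and 95% Student-t confidence interval are
#' computed over per-subject means.  A fold whose training set contains a
#' single class is skipped with a warning and recorded as NA.
#'
#' @param spec a [ModelSpec-class] or [baselineSpec()].
#' @param es an [EEGEpochSet-class].
#' @param plan a [CVPlan-class].
#' @param tc a [trainConfig()] (ConvNet path; also sets the fcn baseline's
#'   seed offset).
#' @param features optional precomputed feature matrix for baselines
#'   (defaults to [extractBandFeatures()]).
#' @return an [EvalResult-class].
#' @export
runExperiment <- function(spec, es, plan, tc = trainConfig(),
                          features = NULL) {
  stopifnot(is(es, "EEGEpochSet"), is(plan, "CVPlan"))
  y <- droplevels(es@labels)
  yIdx <- as.integer(y)
  isBaseline <- inherits(spec, "BaselineSpec")
  if (isBaseline) {
    X <- if (is.null(features)) extractBandFeatures(es) else features
  } else {
    stopifnot(is(spec, "ModelSpec"))
    xAll <- epochsToTensor(es@epochs)
  }

  nFolds <- length(plan@folds)
  foldAcc <- rep(NA_real_, nFolds)
  history <- vector("list", nFolds)
  correct <- rep(NA, nEpochs(es))
  for (f in seq_len(nFolds)) {
    fold <- plan@folds[[f]]
    if (length(unique(yIdx[fold$train])) < 2L) {
      warning("fold ", f, " has a single training class; skipped")
      next
    }
    if (isBaseline) {
      bspec <- spec
      bspec$seed <- spec$seed + f - 1L
      fit <- fitBaseline(bspec, X[fold$train, , drop = FALSE], y[fold$train],
                         Xval = X[fold$val, , drop = FALSE],
                         yval = y[fold$val])
      pred <- predictBaseline(fit, X[fold$test, , drop = FALSE])
      ok <- as.character(pred) == as.character(y[fold$test])
    } else {
      stats <- channelStats(xAll[, , , fold$train, drop = FALSE])
      xtr <- applyChannelStats(xAll[, , , fold$train, drop = FALSE], stats)
      xva <- applyChannelStats(xAll[, , , fold$val, drop = FALSE], stats)
      xte <- applyChannelStats(xAll[, , , fold$test, drop = FALSE], stats)
      mspec <- spec
      mspec@seed <- spec@seed + f - 1L
      net <- buildModel(mspec)
      tcf <- tc; tcf$seed <- tc$seed + f - 1L
      tr <- trainConvNet(net, xtr, yIdx[fold$train], xva, yIdx[fold$val],
                         tcf)
      history[[f]] <- tr$history
      pred <- predictConvNet(tr$net, xte)
      ok <- pred == yIdx[fold$test]
    }
    foldAcc[f] <- mean(ok)
    correct[fold$test] <- ok
  }

  subjAcc <- tapply(correct, es@subjectIds, function(v) mean(v, na.rm = TRUE))
  subjAcc <- subjAcc[is.finite(subjAcc)]
  modelName <- if (isBaseline) spec$kind else
    paste0(spec@family, if (isTRUE(spec@reformed)) "+" else "")
  new("EvalResult", model = modelName, scheme = plan@scheme,
      perFoldAccuracy = foldAcc,
      perSubjectAccuracy = stats::setNames(as.numeric(subjAcc),
                                           names(subjAcc)),
      mean = mean(subjAcc), sd = stats::sd(subjAcc),
      ci95 = ci95t(as.numeric(subjAcc)),
      chanceLevel = as.numeric(chanceLevel(y)),
      history = history)
}
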