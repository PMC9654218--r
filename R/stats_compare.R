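#' One-way fixed-effects ANOVA over accuracy vectors
#'
#' Classical one-way ANOVA with a pooled (equal-variance) error term, as
#' used to test whether mean accuracies differ across models before the
#' many-to-one post hoc comparison.
#'
#' @param groups list of numeric vectors (each length >= 2).
#' @return list with `F`, `p`, `dfBetween`, `dfWithin`.
#' @examples
#' oneWayAnova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
#' @export
oneWayAnova <- function(groups) {
  if (length(groups) < 2L) stop("at least two groups required")
  if (any(lengths(groups) < 2L)) stop("every group needs at least 2 values")
  vals <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (all(vapply(groups, stats::var, numeric(1)) == 0)) {
    if (length(unique(vapply(groups, mean, numeric(1)))) == 1L)
      stop("F is undefined: zero variance within and between groups")
  }
  ft <- stats::oneway.test(vals ~ g, var.equal = TRUE)
  list(F = unname(ft$statistic), p = unname(ft$p.value),
       dfBetween = unname(ft$parameter[1L]),
       dfWithin = unname(ft$parameter[2L]))
}

# pooled many-to-one contrast statistics shared by the Dunnett routines
dunnettStats <- function(control, treatments) {
  k <- length(treatments)
  groups <- c(list(control), treatments)
  ns <- lengths(groups)
  if (any(ns < 2L)) stop("every group needs at least 2 values")
  means <- vapply(groups, mean, numeric(1))
  df <- sum(ns) - length(groups)
  mse <- sum(vapply(groups, function(g)
    sum((g - mean(g))^2), numeric(1))) / df
  tstat <- (means[-1L] - means[1L]) /
    sqrt(mse * (1 / ns[-1L] + 1 / ns[1L]))
  lam <- sqrt(ns[-1L] / (ns[-1L] + ns[1L]))
  corr <- outer(lam, lam)
  diag(corr) <- 1
  list(t = tstat, df = df, corr = corr, meanDiff = means[-1L] - means[1L],
       k = k)
}

#' Dunnett's many-to-one comparison against a control
#'
#' Two-sided Dunnett procedure: each treatment mean is compared with the
#' control mean using the pooled ANOVA error term, and the per-comparison
#' p values are adjusted via the joint multivariate-t distribution of the
#' k contrast statistics (correlation `sqrt(ni nj / ((ni+n0)(nj+n0)))`),
#' evaluated with mvtnorm's deterministic-by-seed quadrature.
#'
#' @param control numeric accuracy vector of the control (the proposed
#'   model).
#' @param treatments list of numeric vectors, one per comparison model.
#' @param alpha family-wise level used for the significance flags.
#' @param seed seed for the multivariate-t evaluation (recorded in the
#'   output).
#' @return data.frame with one row per treatment: `comparison`,
#'   `mean.diff`, `t`, `df`, `p.adjusted`, `significant`.
#' @examples
#' set.seed(1)
#' ctrl <- rnorm(10, 0.8, 0.05)
#' trt <- list(a = rnorm(10, 0.75, 0.05), b = rnorm(10, 0.8, 0.05))
#' dunnettManyToOne(ctrl, trt)
#' @export
dunnettManyToOne <- function(control, treatments, alpha = 0.05, seed = 1L) {
  if (!is.list(treatments)) treatments <- list(treatments)
  if (length(treatments) < 1L) stop("at least one treatment required")
  st <- dunnettStats(control, treatments)
  padj <- vapply(seq_len(st$k), function(i) {
    set.seed(seed)
    1 - mvtnorm::pmvt(lower = rep(-abs(st$t[i]), st$k),
                      upper = rep(abs(st$t[i]), st$k),
                      df = st$df, corr = st$corr,
                      algorithm = mvtnorm::GenzBretz(abseps = 1e-5,
                                                     maxpts = 100000L))[1L]
  }, numeric(1))
  padj <- pmin(pmax(padj, 0), 1)
  nms <- names(treatments)
  if (is.null(nms)) nms <- paste0("treatment", seq_len(st$k))
  data.frame(comparison = nms, mean.diff = st$meanDiff, t = st$t,
             df = st$df, p.adjusted = padj,
             significant = padj < alpha, row.names = NULL)
}

#' Equicoordinate Dunnett critical value
#'
#' The two-sided critical value c with
#' `P(max_j |T_j| <= c) = 1 - alpha` under the joint multivariate-t null of
#' k many-to-one contrasts; a family rejects at level alpha exactly when
#' `max |t| > c`.
#'
#' @param k number of comparisons.
#' @param ns group sizes `c(n_control, n_1, ..., n_k)`.
#' @param alpha family-wise level.
#' @param seed seed for the quantile evaluation.
#' @return the critical value.
#' @export
dunnettCritical <- function(k, ns, alpha = 0.05, seed = 1L) {
  stopifnot(length(ns) == k + 1L)
  df <- sum(ns) - (k + 1L)
  lam <- sqrt(ns[-1L] / (ns[-1L] + ns[1L]))
  corr <- outer(lam, lam)
  diag(corr) <- 1
  set.seed(seed)
  mvtnorm::qmvt(1 - alpha, tail = "both.tails", df = df, corr = corr,
                algorithm = mvtnorm::GenzBretz(abseps = 1e-5,
                                               maxpts = 100000L))$quantile
}

#' Two-sided paired t-test
#'
#' @param a,b numeric vectors of equal length (>= 2), paired by position.
#' @return list with `t`, `df`, `p`.
#' @examples
#' pairedT(c(2, 4, 6), c(1, 2, 3))  # t = 2*sqrt(3), df = 2
#' @export
pairedT <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop("paired vectors must have equal length >= 2")
  d <- a - b
  if (stats::sd(d) == 0)
    stop("degenerate paired test: zero variance of the differences")
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Compare models' accuracy vectors against a control
#'
#' Assembles the full comparison report: one-way ANOVA across all groups,
#' Dunnett's many-to-one comparison of every model against the control,
#' and optional paired t-tests for specified pairs.
#'
#' @param accuracies named list of per-model accuracy vectors (fractions
#'   or percentages; all statistics are invariant under a common affine
#'   rescaling).
#' @param control name of the control entry (the proposed model).
#' @param pairs optional list of `c(nameA, nameB)` pairs for paired
#'   t-tests (vectors must be fold-aligned).
#' @param alpha significance level for the flags.
#' @param seed Dunnett evaluation seed.
#' @return a [ComparisonReport-class].
#' @export
compareModels <- function(accuracies, control, pairs = NULL, alpha = 0.05,
                          seed = 1L) {
  stopifnot(control %in% names(accuracies))
  anv <- oneWayAnova(unname(accuracies))
  trt <- accuracies[setdiff(names(accuracies), control)]
  dn <- dunnettManyToOne(accuracies[[control]], trt, alpha = alpha,
                         seed = seed)
  pt <- data.frame(comparison = character(), t = numeric(), df = numeric(),
                   p = numeric())
  for (pr in pairs) {
    r <- pairedT(accuracies[[pr[1L]]], accuracies[[pr[2L]]])
    pt <- rbind(pt, data.frame(comparison = paste(pr[1L], "vs", pr[2L]),
                               t = r$t, df = r$df, p = r$p))
  }
  new("ComparisonReport", anova = anv, dunnett = dn, pairedT = pt,
      control = control)
}
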