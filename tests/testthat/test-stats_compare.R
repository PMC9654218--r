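test_that("two-group ANOVA F equals the squared pooled-variance t", {
  set.seed(51)
  a <- rnorm(12, 0.8, 0.05); b <- rnorm(15, 0.74, 0.06)
  anv <- oneWayAnova(list(a, b))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(anv$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(anv$p, tt$p.value, tolerance = 1e-12)
  expect_equal(anv$dfBetween, 1)
  expect_equal(anv$dfWithin, 25)
})

test_that("identical groups give F = 0, p = 1; degenerate input errors", {
  g <- c(1, 2, 3, 4)
  anv <- oneWayAnova(list(g, g, g))
  expect_equal(anv$F, 0)
  expect_equal(anv$p, 1)
  expect_error(oneWayAnova(list(c(1, 1), c(1, 1))), "undefined")
  expect_error(oneWayAnova(list(c(1, 2))), "two groups")
  expect_error(oneWayAnova(list(c(1, 2), 3)), "at least 2 values")
})

test_that("ANOVA matches a hand-computed sums-of-squares oracle", {
  groups <- list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  vals <- unlist(groups)
  gm <- mean(vals)
  ssB <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssW <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  Fo <- (ssB / 2) / (ssW / 6)
  anv <- oneWayAnova(groups)
  expect_equal(anv$F, Fo, tolerance = 1e-12)
  expect_equal(anv$p, stats::pf(Fo, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("one-treatment Dunnett reduces to the pooled two-sample t-test", {
  set.seed(52)
  ctrl <- rnorm(10, 0.8, 0.05)
  trt <- rnorm(10, 0.75, 0.05)
  d <- dunnettManyToOne(ctrl, list(trt))
  tt <- stats::t.test(trt, ctrl, var.equal = TRUE)
  expect_equal(d$p.adjusted, tt$p.value, tolerance = 1e-4)
  expect_equal(d$t, unname(tt$statistic), tolerance = 1e-12)

  # treatment identical to the control: adjusted p ~ 1
  d2 <- dunnettManyToOne(ctrl, list(ctrl, trt))
  expect_gt(d2$p.adjusted[1L], 0.999)
})

test_that("adjusted p values are monotone in the number of comparisons", {
  # shifted copies keep the within-group scatter, hence the pooled error
  # and the first contrast's t, identical while the family grows
  set.seed(53)
  v <- rnorm(12, 0, 0.05)
  ctrl <- v + 0.80
  trts <- lapply(1:4, function(i) v + 0.76)
  pPrev <- 0
  for (k in 1:4) {
    d <- dunnettManyToOne(ctrl, trts[seq_len(k)])
    expect_gte(d$p.adjusted[1L] + 1e-9, pPrev)
    pPrev <- d$p.adjusted[1L]
  }
  set.seed(53)
  ctrl <- rnorm(12, 0.8, 0.05)
  trts <- lapply(1:4, function(i) rnorm(12, 0.76, 0.05))
  # and every adjusted p is at least the unadjusted two-sample p
  d4 <- dunnettManyToOne(ctrl, trts)
  for (i in 1:4) {
    praw <- stats::t.test(trts[[i]], ctrl, var.equal = TRUE)$p.value
    expect_gte(d4$p.adjusted[i] + 1e-4, praw)
  }
})

test_that("Dunnett agrees with the multcomp reference implementation", {
  skip_if_not_installed("multcomp")
  set.seed(54)
  groups <- list(ctrl = rnorm(10, 0.80, 0.05),
                 m1 = rnorm(10, 0.74, 0.05),
                 m2 = rnorm(12, 0.79, 0.06),
                 m3 = rnorm(8, 0.70, 0.04))
  mine <- dunnettManyToOne(groups$ctrl, groups[-1L], seed = 5L)
  df <- data.frame(y = unlist(groups),
                   g = factor(rep(names(groups), lengths(groups)),
                              levels = names(groups)))
  fit <- stats::aov(y ~ g, data = df)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  ref <- summary(gl, test = multcomp::adjusted("single-step"))
  expect_equal(unname(mine$t), unname(ref$test$tstat), tolerance = 1e-10)
  expect_equal(unname(mine$p.adjusted), unname(as.vector(ref$test$pvalues)),
               tolerance = 5e-3)
})

test_that("paired t matches the closed form and is antisymmetric", {
  r <- pairedT(c(2, 4, 6), c(1, 2, 3))     # differences 1, 2, 3
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2)
  r2 <- pairedT(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r2$t, -r$t, tolerance = 1e-12)
  expect_equal(r2$p, r$p, tolerance = 1e-12)
  expect_error(pairedT(c(2, 3, 4), c(1, 2, 3)), "degenerate")
  expect_error(pairedT(1:3, 1:4), "equal length")
})

test_that("all p values are invariant under common affine rescaling", {
  set.seed(55)
  groups <- lapply(1:4, function(i) rnorm(9, 0.7 + 0.02 * i, 0.05))
  resc <- lapply(groups, function(g) 100 * g - 17)
  a1 <- oneWayAnova(groups); a2 <- oneWayAnova(resc)
  expect_equal(a1$p, a2$p, tolerance = 1e-10)
  d1 <- dunnettManyToOne(groups[[1L]], groups[-1L], seed = 2L)
  d2 <- dunnettManyToOne(resc[[1L]], resc[-1L], seed = 2L)
  expect_equal(d1$p.adjusted, d2$p.adjusted, tolerance = 1e-6)
  p1 <- pairedT(groups[[1L]], groups[[2L]])
  p2 <- pairedT(resc[[1L]], resc[[2L]])
  expect_equal(p1$p, p2$p, tolerance = 1e-10)
})

test_that("ANOVA and paired t reject at the nominal rate under the null", {
  set.seed(56)
  reps <- 10000L
  n <- 10L
  # paired t: vectorised closed form over the simulated nulls, checked
  # against pairedT on a subsample
  D <- matrix(rnorm(reps * n), n)
  tstat <- colMeans(D) / sqrt(apply(D, 2, stats::var) / n)
  pvals <- 2 * stats::pt(-abs(tstat), n - 1)
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 2.58 * sqrt(0.05 * 0.95 / reps) + 1e-9)
  for (j in c(1L, 500L)) {
    r <- pairedT(D[, j], rep(0, n))
    expect_equal(r$p, pvals[j], tolerance = 1e-10)
  }

  # one-way ANOVA null rejection rate via the package function
  rej <- 0L
  nrep <- 2000L
  for (i in seq_len(nrep)) {
    g <- list(rnorm(8), rnorm(8), rnorm(8))
    if (oneWayAnova(g)$p < 0.05) rej <- rej + 1L
  }
  expect_lt(abs(rej / nrep - 0.05), 2.58 * sqrt(0.05 * 0.95 / nrep))
})

test_that("the comparison report flags significance and stays consistent", {
  set.seed(57)
  acc <- list(multits = rnorm(10, 0.85, 0.04),
              deep = rnorm(10, 0.80, 0.04),
              knn = rnorm(10, 0.60, 0.05))
  rep <- compareModels(acc, control = "multits",
                       pairs = list(c("multits", "deep")))
  expect_s4_class(rep, "ComparisonReport")
  expect_equal(nrow(rep@dunnett), 2L)
  expect_true(rep@dunnett$significant[rep@dunnett$comparison == "knn"])
  expect_equal(nrow(rep@pairedT), 1L)
  out <- capture.output(show(rep))
  expect_true(any(grepl("ANOVA", out)))
  expect_true(any(grepl("\\*\\*", out)))
})
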