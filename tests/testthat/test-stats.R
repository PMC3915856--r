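# The statistical layer, cross-checked against hand formulas and
# enumeration oracles.

test_that("summarizeGroup computes n, mean, SE", {
  s <- summarizeGroup(c(3, 5))
  expect_equal(s$mean, 4); expect_equal(s$se, 1); expect_equal(s$n, 2L)
  expect_equal(summarizeGroup(rep(7, 5))$se, 0)
  expect_warning(s1 <- summarizeGroup(4), "SE undefined")
  expect_true(is.na(s1$se)); expect_true(s1$seUndefined)
  expect_error(summarizeGroup(numeric(0)), "empty")
  # delta-method scale check on the generator's day-0 flows
  prof <- calibrationProfile(seed = 31, nHemoRats = 6L)
  flows <- vapply(1:6, function(r) meanFlow(genFlowTrace(prof, r, 0)) * 60, 0)
  s6 <- summarizeGroup(flows)
  expect_lt(abs(s6$se - s6$mean * 0.05 / sqrt(6)) / (s6$mean * 0.05 / sqrt(6)), 1.5)
})

test_that("ttestBaseline matches the pooled-t hand computation", {
  r <- ttestBaseline(c(1, 2, 3), c(4, 5, 6))
  o <- oraclePooledT(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, o$t, tolerance = 1e-12)
  expect_equal(r$statistic, -3.674, tolerance = 1e-3)
  expect_equal(r$pValue, 0.0213, tolerance = 1e-3)
  same <- ttestBaseline(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0); expect_equal(same$pValue, 1)
  expect_error(ttestBaseline(1, c(1, 2)), "n >= 2")
  # invariance under common shift and positive scaling
  set.seed(2)
  x <- rnorm(6); y <- rnorm(6)
  p0 <- ttestBaseline(x, y)$pValue
  expect_equal(ttestBaseline(x + 5, y + 5)$pValue, p0, tolerance = 1e-12)
  expect_equal(ttestBaseline(3 * x, 3 * y)$pValue, p0, tolerance = 1e-12)
})

test_that("type-I error of the baseline t-test is calibrated", {
  set.seed(123)
  rej <- mean(vapply(1:1000, function(i)
    ttestBaseline(rnorm(4), rnorm(4))$pValue < 0.05, TRUE))
  expect_gte(rej, 0.03); expect_lte(rej, 0.07)
})

test_that("compareMulti gates on variance equality", {
  set.seed(11)
  v <- rnorm(8)
  # shifted copies: identical spread, so the gate passes by construction
  eq <- list(a = v, b = v + 0.3, c = v - 0.2)
  r <- compareMulti(eq)
  expect_equal(r$method, "anova")
  expect_gte(r$varianceGateP, 0.05)
  uneq <- list(a = rnorm(8, sd = 0.1), b = rnorm(8, sd = 0.1),
               c = rnorm(8, sd = 10))
  r2 <- compareMulti(uneq)
  expect_true(all(r2$method == "mann_whitney"))
  expect_lt(r2$varianceGateP[1], 0.05)
  expect_equal(nrow(r2), 2L)
  # a large shift is significant on either branch
  shifted <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8) + 50)
  expect_lt(min(compareMulti(shifted)$pValue), 0.01)
  expect_error(compareMulti(eq[1:2]), "3 groups")
  expect_error(compareMulti(list(a = 1, b = rnorm(3), c = rnorm(3))), "n >= 2")
  # ANOVA branch p-values are roughly uniform under the null
  set.seed(77)
  ps <- replicate(300, {
    g <- list(a = rnorm(6), b = rnorm(6), c = rnorm(6))
    r <- compareMulti(g)
    if (r$method[1] == "anova") r$pValue else NA
  })
  ps <- ps[!is.na(ps)]
  expect_gt(length(ps), 200)
  expect_lt(abs(mean(ps < 0.5) - 0.5), 0.1)
})

test_that("pearsonCorr matches hand computation and is affine invariant", {
  x <- 1:4; y <- c(2, 1, 4, 3)
  r <- pearsonCorr(x, y)
  expect_equal(r$r, 0.6, tolerance = 1e-12)
  expect_equal(pearsonCorr(x, 2 * x + 1)$r, 1)
  expect_equal(pearsonCorr(x, -x)$r, -1)
  expect_error(pearsonCorr(x, rep(2, 4)), "zero variance")
  expect_error(pearsonCorr(1:2, 1:2), "at least 3")
  set.seed(8)
  a <- rnorm(10); b <- rnorm(10)
  r0 <- pearsonCorr(a, b)
  r1 <- pearsonCorr(3 * a + 2, 0.5 * b - 7)
  expect_equal(r1$r, r0$r, tolerance = 1e-12)
  expect_equal(r1$pValue, r0$pValue, tolerance = 1e-12)
})

test_that("statistical routines agree with independent references", {
  set.seed(202)
  for (i in 1:100) {
    x <- rnorm(sample(4:9, 1)); y <- rnorm(sample(4:9, 1), mean = runif(1))
    tt <- ttestBaseline(x, y); ot <- oraclePooledT(x, y)
    expect_equal(tt$statistic, ot$t, tolerance = 1e-10)
    expect_equal(tt$pValue, ot$p, tolerance = 1e-10)
    y2 <- rnorm(length(x)) + x
    pc <- pearsonCorr(x, y2)
    oc <- oraclePearson(x, y2)
    expect_equal(pc$r, oc$r, tolerance = 1e-10)
    expect_equal(pc$pValue, oc$p, tolerance = 1e-10)
    g <- list(a = rnorm(5), b = rnorm(5, sd = runif(1, 0.5, 2)), c = rnorm(5))
    r <- compareMulti(g)
    ol <- oracleLeveneP(unlist(g), rep(names(g), times = lengths(g)))
    expect_equal(r$varianceGateP[1], ol, tolerance = 1e-10)
  }
  # exact Mann-Whitney p by rank-sum enumeration (small n, no ties)
  set.seed(5)
  for (i in 1:20) {
    x <- runif(4); y <- runif(5)
    w <- suppressWarnings(wilcox.test(x, y))$p.value
    expect_equal(w, oracleMannWhitneyP(x, y), tolerance = 1e-10)
  }
})

test_that("correlateTimecourses handles both modes and degenerate input", {
  wss <- data.frame(day = c(-1, 1, 3, 7), meanTau = c(0.8, 4.5, 6.5, 10.6))
  meas <- data.frame(day = c(-1, 1, 3, 7), mean = c(10, 11, 13, 16))
  r1 <- correlateTimecourses(wss, meas, "vs_time")
  expect_equal(r1$n, 4L)
  r2 <- correlateTimecourses(wss, meas, "vs_wss")
  # measure defined as an exact linear function of the WSS means: r = 1
  meas2 <- data.frame(day = wss$day, mean = 2 * wss$meanTau + 3)
  expect_equal(correlateTimecourses(wss, meas2, "vs_wss")$r, 1)
  expect_error(correlateTimecourses(wss, data.frame(day = c(-1, 1, 3, 7),
                                                    mean = rep(4, 4)),
                                    "vs_wss"),
               "zero variance")
  expect_error(correlateTimecourses(wss[1:2, ],
                                    data.frame(day = c(-1, 1), mean = 1:2),
                                    "vs_wss"),
               "fewer than 3")
})
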