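## Statistical layer: mean +/- SE summaries, unpaired two-tailed t-tests vs
## baseline, the variance-gated ANOVA / Mann-Whitney choice, Pearson
## correlation and simple linear regression for time-course relationships.

#' Group summary: n, mean, standard error
#'
#' @param values numeric vector, n >= 1.
#' @return data.frame with `n`, `mean`, `se` (SE is NA and flagged for
#'   n = 1).
#' @export
#' @examples
#' summarizeGroup(c(3, 5))  # mean 4, se 1
summarizeGroup <- function(values) {
  if (!length(values)) stop("empty group")
  n <- length(values)
  out <- data.frame(n = n, mean = mean(values),
                    se = if (n > 1) sd(values) / sqrt(n) else NA_real_)
  out$seUndefined <- n == 1L
  if (n == 1L) warning("SE undefined for a single observation")
  out
}

#' Unpaired two-tailed t-test against the baseline group
#'
#' Classical pooled-variance unpaired t-test by default; Welch's correction
#' behind a flag.
#'
#' @param group numeric vector, n >= 2.
#' @param baseline numeric baseline vector, n >= 2.
#' @param welch if TRUE use Welch's unequal-variance t-test.
#' @param comparison label stored in the result.
#' @return data.frame with `comparison`, `method`, `statistic`, `pValue`,
#'   `varianceGateP` (NA for t-tests).
#' @export
#' @examples
#' ttestBaseline(c(4, 5, 6), c(1, 2, 3))
ttestBaseline <- function(group, baseline, welch = FALSE,
                          comparison = "group vs baseline") {
  if (length(group) < 2L || length(baseline) < 2L)
    stop("both groups need n >= 2 for a t-test")
  tt <- t.test(group, baseline, var.equal = !welch)
  data.frame(comparison = comparison, method = "t_test",
             statistic = unname(tt$statistic), pValue = tt$p.value,
             varianceGateP = NA_real_)
}

#' Multi-group comparison with a variance-equality gate
#'
#' With three or more groups, Levene's test (center = median, alpha = 0.05)
#' decides the branch: equal variances lead to one-way ANOVA; unequal
#' variances lead to pairwise Mann-Whitney tests of each group against the
#' baseline group.
#'
#' @param groups named list of numeric vectors (>= 3 groups, each n >= 2).
#' @param baseline name of the baseline group (default: the first).
#' @param alpha significance level of the variance gate (default 0.05).
#' @return data.frame: one row (ANOVA branch) or one row per non-baseline
#'   group (Mann-Whitney branch) with `comparison`, `method`, `statistic`,
#'   `pValue`, `varianceGateP`.
#' @export
compareMulti <- function(groups, baseline = names(groups)[1], alpha = 0.05) {
  if (length(groups) < 3L) stop("need at least 3 groups")
  ns <- vapply(groups, length, 0L)
  if (any(ns < 2L))
    stop("every group needs n >= 2 for a variance estimate")
  if (is.null(names(groups)) || !baseline %in% names(groups))
    stop("baseline must name one of the groups")
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), ns), levels = names(groups))
  gate <- car::leveneTest(values ~ fac, center = median)
  gateP <- gate[1, "Pr(>F)"]
  if (gateP >= alpha) {
    fit <- aov(values ~ fac)
    an <- anova(fit)
    data.frame(comparison = "omnibus", method = "anova",
               statistic = an[1, "F value"], pValue = an[1, "Pr(>F)"],
               varianceGateP = gateP)
  } else {
    others <- setdiff(names(groups), baseline)
    do.call(rbind, lapply(others, function(g) {
      wt <- suppressWarnings(wilcox.test(groups[[g]], groups[[baseline]]))
      data.frame(comparison = paste(g, "vs", baseline),
                 method = "mann_whitney", statistic = unname(wt$statistic),
                 pValue = wt$p.value, varianceGateP = gateP)
    }))
  }
}

#' Pearson correlation with two-tailed p-value and optional regression
#'
#' @param x,y numeric vectors, n >= 3, finite, non-constant.
#' @param regression if TRUE (default) include least-squares slope and
#'   intercept of y on x.
#' @param pair label stored in the result.
#' @return data.frame with `pair`, `n`, `r`, `pValue`, `slope`, `intercept`.
#' @export
#' @examples
#' pearsonCorr(1:4, c(2, 1, 4, 3))  # r = 0.6
pearsonCorr <- function(x, y, regression = TRUE, pair = "x vs y") {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 finite pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")
  ct <- cor.test(x, y, method = "pearson")
  out <- data.frame(pair = pair, n = length(x), r = unname(ct$estimate),
                    pValue = ct$p.value)
  if (regression) {
    b <- coef(lm(y ~ x))
    out$slope <- unname(b[2]); out$intercept <- unname(b[1])
  }
  out
}

#' Correlate measurement time-courses with time or with wall shear stress
#'
#' Mode "vs_time" correlates each group's per-day means against the study
#' day; mode "vs_wss" correlates them against the per-day mean WSS on the
#' shared day grid. The baseline day participates like any other day, so a
#' full-grid correlation uses n = 8 points.
#'
#' @param wssTable data.frame with columns `day`, `meanTau` (from
#'   [wssTimecourse()]; ignored in mode "vs_time").
#' @param measureTable data.frame with columns `day`, `mean` and optional
#'   grouping columns (e.g. `marker`/`pair`, `compartment`).
#' @param mode "vs_time" or "vs_wss".
#' @param groupCols grouping columns present in `measureTable` (default:
#'   those of `marker`, `pair`, `compartment` that exist).
#' @return data.frame: one [pearsonCorr()] row per group.
#' @export
correlateTimecourses <- function(wssTable, measureTable,
                                 mode = c("vs_time", "vs_wss"),
                                 groupCols = NULL) {
  mode <- match.arg(mode)
  if (is.null(groupCols))
    groupCols <- intersect(c("marker", "pair", "compartment"),
                           names(measureTable))
  keys <- if (length(groupCols))
    unique(measureTable[, groupCols, drop = FALSE])
  else data.frame(.all = "all")
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- rep(TRUE, nrow(measureTable))
    label <- "measure"
    if (length(groupCols)) {
      for (k in groupCols) sel <- sel & measureTable[[k]] == keys[[k]][i]
      label <- paste(unlist(keys[i, , drop = TRUE]), collapse = "/")
    }
    mi <- measureTable[sel, ]
    if (mode == "vs_time") {
      x <- mi$day; y <- mi$mean
    } else {
      shared <- merge(mi[, c("day", "mean")],
                      wssTable[, c("day", "meanTau")], by = "day")
      x <- shared$meanTau; y <- shared$mean
    }
    if (length(x) < 3L)
      stop("fewer than 3 shared days for ", label)
    out[[i]] <- pearsonCorr(x, y,
      pair = paste(label, if (mode == "vs_time") "vs time" else "vs WSS"))
  }
  do.call(rbind, out)
}
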