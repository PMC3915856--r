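# Independent oracles used to cross-check the implementation, written as
# naive reference algorithms that share no code with the package internals.

# Queue-based flood fill: label connected components of a logical matrix.
oracleLabel <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8)
    rbind(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  else rbind(c(-1,0), c(0,-1), c(0,1), c(1,0))
  cur <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    cur <- cur + 1L
    queue <- list(c(r0, c0)); lab[r0, c0] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        r <- p[1] + nb[k, 1]; cc <- p[2] + nb[k, 2]
        if (r >= 1 && r <= nr && cc >= 1 && cc <= nc &&
            mask[r, cc] && lab[r, cc] == 0L) {
          lab[r, cc] <- cur
          queue[[length(queue) + 1L]] <- c(r, cc)
        }
      }
    }
  }
  lab
}

# Brute-force event counting: flood fill + re-application of the size rules.
oracleCountEvents <- function(image, threshold = 100, minArea = 2,
                              maxSingle = 50, medianSize = 10,
                              connectivity = 8) {
  lab <- oracleLabel(image >= threshold, connectivity)
  if (!max(lab)) return(0)
  areas <- as.numeric(table(lab[lab > 0]))
  areas <- areas[areas >= minArea]
  sum(as.numeric(ifelse(areas > maxSingle,
                        floor(areas / medianSize + 0.5), 1)))
}

# Hand formulas for the statistical layer.
oraclePooledT <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * pt(-abs(t), nx + ny - 2))
}

oraclePearson <- function(x, y) {
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  n <- length(x)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

# Brown-Forsythe / Levene with median centring, via the ANOVA on |x - med|.
oracleLeveneP <- function(values, groups) {
  z <- abs(values - ave(values, groups, FUN = median))
  anova(aov(z ~ factor(groups)))[1, "Pr(>F)"]
}

# Exact Mann-Whitney p by enumeration of the rank-sum distribution (small n,
# no ties).
oracleMannWhitneyP <- function(x, y) {
  n <- length(x); m <- length(y)
  ranks <- rank(c(x, y))
  u <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  all <- combn(n + m, n)
  us <- apply(all, 2, function(idx) sum(rank(seq_len(n + m))[idx])) -
    n * (n + 1) / 2
  min(1, 2 * min(mean(us <= u), mean(us >= u)))
}

# Small profiles for fast tests.
testProfile <- function(seed = 1, ...) {
  calibrationProfile(
    seed = seed,
    ifPhantom = vesselPhantom(60, 14, 36, imageShape = c(256L, 256L),
                              nZSlices = 1L, zStepUm = 12, zVolumeUm = 12),
    plaPhantom = vesselPhantom(90, 14, 40, imageShape = c(320L, 320L)),
    plaBaselineDensity = 4000, mediaDensity = 500,
    ...)
}
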