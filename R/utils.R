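## Internal utilities: seeded evaluation, stream seeds, connected components,
## rounding conventions shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so that generator functions are
#' deterministic without perturbing the session stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministic string hash (polynomial rolling hash mod 2^31 - 1).
## Products stay below 2^36 so double arithmetic is exact.
.hashString <- function(s) {
  b <- utf8ToInt(s)
  h <- 0
  for (x in b) h <- (h * 31 + x) %% 2147483647
  h
}

#' Derive a reproducible sub-stream seed
#'
#' Combines a root seed with a string key (e.g. "flow/rat3/day42") so that
#' every rat/day/channel gets an independent stream and adding a new marker or
#' pair never perturbs existing streams.
#'
#' @param rootSeed integer root seed.
#' @param ... components of the stream key (coerced to character).
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' streamSeed(1, "flow", 3, 42)
streamSeed <- function(rootSeed, ...) {
  key <- paste(vapply(list(...), as.character, ""), collapse = "/")
  s <- (as.numeric(rootSeed) + .hashString(key)) %% 2147483646
  as.integer(s) + 1L
}

## Round half away from zero (ties up for positive input), the convention used
## for merged-blob event assignment.
.roundHalfUp <- function(x) floor(x + 0.5)

## Connected-component labelling of a logical matrix.
## connectivity 8 (default) or 4. Returns an integer matrix of labels
## (0 = background). Edges are built vectorised from shifted index matrices
## and components come from igraph.
.labelComponents <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  K <- sum(mask)
  lab <- matrix(0L, nr, nc)
  if (K == 0L) return(lab)
  im <- matrix(0L, nr, nc)
  im[mask] <- seq_len(K)
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  edges <- integer(0)
  for (o in offs) {
    dr <- o[1]; dc <- o[2]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0) seq_len(nc - dc) else seq.int(1 - dc, nc)
    a <- im[r1, c1, drop = FALSE]
    b <- im[r1 + dr, c1 + dc, drop = FALSE]
    sel <- a > 0L & b > 0L
    if (any(sel)) edges <- c(edges, rbind(a[sel], b[sel]))
  }
  if (length(edges)) {
    g <- igraph::make_graph(edges, n = K, directed = FALSE)
    memb <- igraph::components(g)$membership
  } else {
    memb <- seq_len(K)
  }
  lab[mask] <- as.integer(memb)
  lab
}

## Particle table for one 2-D image: label, pixel area, centroid, peak gray.
.particleStats <- function(image, threshold, connectivity = 8) {
  mask <- image >= threshold
  lab <- .labelComponents(mask, connectivity)
  idx <- which(lab > 0L)
  if (!length(idx)) {
    return(data.frame(label = integer(0), area = integer(0),
                      crow = numeric(0), ccol = numeric(0), peak = numeric(0)))
  }
  l <- lab[idx]
  nr <- nrow(image)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  area <- tabulate(l)
  keep <- which(area > 0L)
  data.frame(
    label = keep,
    area = area[keep],
    crow = as.numeric(tapply(r, l, mean)),
    ccol = as.numeric(tapply(cc, l, mean)),
    peak = as.numeric(tapply(image[idx], l, max))
  )
}

## Clip to the 8-bit range and round to whole gray values.
.clip8 <- function(x) pmin(pmax(round(x), 0), 255)

## Lognormal multiplicative replicate factor with unit mean and the given CV.
.replicateFactor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}
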