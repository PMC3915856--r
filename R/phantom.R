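## Phantom image synthesis: annular marker rings and PLA spot fields with
## known ground truth.

## Pixel offsets of a digital disc, ordered by distance from the centre and,
## within a distance shell, starting east and proceeding counter-clockwise.
## Taking the first A offsets yields a connected blob of exactly A pixels.
.spotOffsetTable <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      g <- expand.grid(dr = -8:8, dc = -8:8)
      d <- sqrt(g$dr^2 + g$dc^2)
      a <- (atan2(g$dr, g$dc) + 2 * pi) %% (2 * pi)
      o <- order(d, a)
      tab <<- as.matrix(g[o, ])
    }
    tab
  }
})

## Draw spot areas: discretized lognormal with the given median, truncated.
.drawSpotAreas <- function(n, medianArea, sigmaLog, minArea, maxArea) {
  if (n == 0L) return(integer(0))
  a <- integer(0)
  while (length(a) < n) {
    x <- round(rlnorm(2L * (n - length(a)) + 8L, log(medianArea), sigmaLog))
    a <- c(a, x[x >= minArea & x <= maxArea])
  }
  as.integer(a[seq_len(n)])
}

## Linear indices of a blob of `area` pixels centred at (r, c) in slice z.
.spotIndices <- function(r, c, z, area, d) {
  off <- .spotOffsetTable()[seq_len(area), , drop = FALSE]
  rr <- r + off[, 1]; cc <- c + off[, 2]
  ok <- rr >= 1 & rr <= d[1] & cc >= 1 & cc <= d[2]
  (z - 1) * d[1] * d[2] + (cc[ok] - 1) * d[1] + rr[ok]
}

## Candidate spot-centre slots for one compartment.
## Endothelium: a ring of tangentially spaced positions centred in the band.
## Media: square grids inside each media circle.
.compartmentSlots <- function(seg, rois, imaging) {
  sp <- imaging$slotSpacingPx
  depthPx <- rois[[1]]@params$depthPx
  rho <- seg$lumenRadiusPx + depthPx / 2
  K <- floor(2 * pi * rho / sp)
  th <- 2 * pi * seq(0, K - 1) / K
  endo <- cbind(row = seg$center[1] + rho * sin(th),
                col = seg$center[2] + rho * cos(th), theta = th)
  media <- do.call(rbind, lapply(rois[4:6], function(roi) {
    ctr <- roi@params$center; rad <- roi@params$radiusPx - 1.5
    g <- expand.grid(dr = seq(-rad, rad, by = sp), dc = seq(-rad, rad, by = sp))
    g <- g[g$dr^2 + g$dc^2 <= rad^2, ]
    cbind(row = ctr[1] + g$dr, col = ctr[2] + g$dc, theta = NA_real_)
  }))
  list(endothelium = endo, media = media,
       bandRange = c(seg$lumenRadiusPx, seg$lumenRadiusPx + depthPx))
}

## Snap a real-valued centre to an integer pixel whose own radius stays
## strictly inside the band (endothelium) or circle (media).
.snapCenter <- function(r, c, seg, compartment, bandRange, rois) {
  cand <- expand.grid(rr = round(r) + (-1:1), cc = round(c) + (-1:1))
  cand$dist <- (cand$rr - r)^2 + (cand$cc - c)^2
  cand <- cand[order(cand$dist), ]
  if (compartment == "endothelium") {
    rad <- sqrt((cand$rr - seg$center[1])^2 + (cand$cc - seg$center[2])^2)
    ok <- rad >= bandRange[1] + 0.05 & rad < bandRange[2] - 0.05
  } else {
    ## 1.2 px margin keeps the rendered particle's centroid inside the
    ## circle mask despite discretization drift
    ok <- rep(FALSE, nrow(cand))
    for (roi in rois[4:6]) {
      ctr <- roi@params$center
      ok <- ok | sqrt((cand$rr - ctr[1])^2 + (cand$cc - ctr[2])^2) <=
        roi@params$radiusPx - 1.2
    }
  }
  i <- if (any(ok)) which(ok)[1] else 1L
  c(cand$rr[i], cand$cc[i])
}

## Seed one compartment's spots: singles plus merged clusters, followed by
## `nNonspecific` nonspecific singles drawn through the same slot pool so
## that specific and nonspecific spots never collide.
.seedSpots <- function(nEvents, slots, compartment, seg, rois, imaging,
                       mergeFraction, bandRange, nNonspecific = 0L) {
  empty <- data.frame(row = integer(0), col = integer(0), area = integer(0),
                      cluster = integer(0), specific = logical(0))
  if (nEvents + nNonspecific == 0L) return(empty)
  cs <- imaging$clusterSize
  nClust <- floor(round(mergeFraction * nEvents) / cs)
  nSingle <- nEvents - nClust * cs + nNonspecific
  avail <- rep(TRUE, nrow(slots))
  spots <- list()
  blockR <- imaging$clusterStepPx * cs / 2 + 4
  clusterId <- 0L
  for (i in seq_len(nClust)) {
    open <- which(avail)
    if (!length(open))
      stop("pla event rate too high for the phantom geometry; reduce the rate")
    s <- open[sample.int(length(open), 1L)]
    d2 <- (slots[, 1] - slots[s, 1])^2 + (slots[, 2] - slots[s, 2])^2
    avail[d2 <= blockR^2] <- FALSE
    clusterId <- clusterId + 1L
    th <- slots[s, 3]
    tangent <- if (is.na(th)) {
      a <- runif(1, 0, 2 * pi); c(sin(a), cos(a))
    } else c(cos(th), -sin(th))
    jj <- (seq_len(cs) - (cs + 1) / 2) * imaging$clusterStepPx
    areas <- .drawSpotAreas(cs, imaging$spotMedianArea, imaging$spotSigmaLog,
                            max(8L, imaging$spotMinArea), imaging$spotMaxArea)
    for (m in seq_len(cs)) {
      p <- c(slots[s, 1], slots[s, 2]) + jj[m] * tangent
      p <- .snapCenter(p[1], p[2], seg, compartment, bandRange, rois)
      spots[[length(spots) + 1L]] <-
        data.frame(row = p[1], col = p[2], area = areas[m],
                   cluster = clusterId, specific = TRUE)
    }
  }
  open <- which(avail)
  if (nSingle > length(open))
    stop("pla event rate too high for the phantom geometry; reduce the rate")
  pick <- open[sample.int(length(open), nSingle)]
  nSpecificSingle <- nSingle - nNonspecific
  if (nSingle > 0L) {
    areas <- .drawSpotAreas(nSingle, imaging$spotMedianArea,
                            imaging$spotSigmaLog, imaging$spotMinArea,
                            imaging$spotMaxArea)
    for (m in seq_len(nSingle)) {
      s <- pick[m]
      th <- slots[s, 3]
      if (is.na(th)) {
        p <- c(slots[s, 1] + runif(1, -1, 1), slots[s, 2] + runif(1, -1, 1))
      } else {
        rho <- sqrt(sum((c(slots[s, 1], slots[s, 2]) - seg$center)^2))
        dth <- runif(1, -1, 1) / rho
        rj <- runif(1, -0.4, 0.4)
        p <- seg$center + (rho + rj) * c(sin(th + dth), cos(th + dth))
      }
      p <- .snapCenter(p[1], p[2], seg, compartment, bandRange, rois)
      spots[[length(spots) + 1L]] <-
        data.frame(row = p[1], col = p[2], area = areas[m], cluster = 0L,
                   specific = m <= nSpecificSingle)
    }
  }
  if (!length(spots)) empty else do.call(rbind, spots)
}

## Background + noise stack for a phantom.
.noiseStack <- function(phantom, baseGray, noiseSd) {
  d <- c(phantom@imageShape, phantom@nZSlices)
  if (noiseSd > 0) {
    arr <- array(baseGray + rnorm(prod(d), 0, noiseSd), d)
  } else {
    arr <- array(baseGray, d)
  }
  arr
}

#' Generate one phantom specimen (marker, PLA and negative-control stacks)
#'
#' Builds a synthetic vessel cross-section: the marker channel has intima and
#' media rings at known mean gray above a shared ambient background; the PLA
#' channel has sub-threshold background noise plus seeded fluorescent spots
#' (median area 10 px) whose count follows the requested density, including a
#' configurable fraction placed as merged clusters larger than 50 px; the
#' negative control carries only background plus a nonspecific spot field.
#' All seeded quantities are returned as ground truth.
#'
#' @param phantom a [VesselPhantom-class].
#' @param markerLevel endothelial (intima ring) marker signal, gray values.
#' @param mediaMarkerLevel media ring marker signal, gray values.
#' @param plaRateEndo endothelial PLA event density, events/mm^2 (seeded in
#'   the endothelial band the ROIs sample).
#' @param plaRateMedia media PLA event density, events/mm^2 (seeded in the
#'   media circles).
#' @param nonspecificRate nonspecific spot density, events/mm^2, applied to
#'   both compartments of the PLA channel and of the negative control.
#' @param seed integer seed.
#' @param mergeFraction fraction of true events seeded as merged clusters.
#' @param poissonCounts if TRUE spot counts are Poisson draws; if FALSE the
#'   rounded expectation is used (noise-free calibration checks).
#' @param channels subset of c("marker", "pla", "control") to synthesize.
#' @param imaging image-formation constants; see [calibrationProfile()].
#' @param ratId,day,target metadata stored on the stacks.
#' @return list with elements `marker`, `pla`, `control` ([ImageStack-class]
#'   or NULL) and `truth` (list: `trueCounts`, `nonspecificCounts`, `spots`,
#'   `markerLevels`, `roiAreas`, `trueDensities`).
#' @export
genVesselImage <- function(phantom, markerLevel = 0, mediaMarkerLevel = 0,
                           plaRateEndo = 0, plaRateMedia = 0,
                           nonspecificRate = 0, seed = 1L,
                           mergeFraction = 0, poissonCounts = TRUE,
                           channels = c("marker", "pla", "control"),
                           imaging = .defaultImaging(),
                           ratId = "rat1", day = 0, target = "") {
  stopifnot(markerLevel >= 0, plaRateEndo >= 0, plaRateMedia >= 0,
            nonspecificRate >= 0)
  validObject(phantom)
  imaging <- modifyList(.defaultImaging(), imaging)
  seg <- phantomSegmentation(phantom)
  rois <- placeROIs(seg, bandDepthUm = imaging$bandDepthUm)
  slots <- .compartmentSlots(seg, rois, imaging)
  areas <- list(
    endothelium = sum(vapply(rois[1:3], roiArea, 0)),
    media = sum(vapply(rois[4:6], roiArea, 0)))

  ## Each channel uses its own derived stream so that synthesizing a subset
  ## of channels never perturbs the others.
  out <- list(marker = NULL, pla = NULL, control = NULL)
  truth <- list(markerLevels = c(endothelium = markerLevel,
                                 media = mediaMarkerLevel),
                ambientGray = imaging$ambientGray,
                roiAreas = unlist(areas))

  if ("marker" %in% channels) withSeed(streamSeed(seed, "marker"), {
      pf <- .polarFields(seg$dim, seg$center)
      intima <- pf$r >= seg$lumenRadiusPx &
        pf$r < seg$lumenRadiusPx + seg$intimaThicknessPx
      mediaRing <- pf$r >= seg$lumenRadiusPx + seg$intimaThicknessPx &
        pf$r < seg$lumenRadiusPx + seg$intimaThicknessPx + seg$mediaThicknessPx
      base <- matrix(imaging$ambientGray, seg$dim[1], seg$dim[2])
      base[intima] <- base[intima] + markerLevel
      base[mediaRing] <- base[mediaRing] + mediaMarkerLevel
      arr <- array(0, c(seg$dim, phantom@nZSlices))
      for (z in seq_len(phantom@nZSlices)) {
        sl <- base
        if (imaging$readNoiseSd > 0)
          sl <- sl + rnorm(length(sl), 0, imaging$readNoiseSd)
        arr[, , z] <- sl
      }
      out$marker <- imageStack(.clip8(arr), phantom@pixelSizeUm,
                               phantom@zStepUm, "marker", ratId, day, target)
  })

  drawN <- function(rate, areaMm2) {
    mu <- rate * areaMm2
    if (poissonCounts) rpois(1L, mu) else as.integer(round(mu))
  }

  spotsFor <- function(rateE, rateM, merge, nsRate = 0) {
      nE <- drawN(rateE, areas$endothelium)
      nM <- drawN(rateM, areas$media)
      nsE <- drawN(nsRate, areas$endothelium)
      nsM <- drawN(nsRate, areas$media)
      sE <- .seedSpots(nE, slots$endothelium, "endothelium", seg, rois,
                       imaging, merge, slots$bandRange, nNonspecific = nsE)
      sM <- .seedSpots(nM, slots$media, "media", seg, rois, imaging, merge,
                       slots$bandRange, nNonspecific = nsM)
      sE$compartment <- rep("endothelium", nrow(sE))
      sM$compartment <- rep("media", nrow(sM))
      list(spots = rbind(sE, sM), counts = c(endothelium = nE, media = nM),
           nsCounts = c(endothelium = nsE, media = nsM))
  }

  paintAll <- function(arr, spots) {
    d <- dim(arr)
    if (nrow(spots)) {
      zs <- sample.int(d[3], nrow(spots), replace = TRUE)
      idx <- unlist(lapply(seq_len(nrow(spots)), function(i)
        .spotIndices(spots$row[i], spots$col[i], zs[i], spots$area[i], d)))
      arr[idx] <- pmax(arr[idx], imaging$spotGray)
    }
    arr
  }

  if ("pla" %in% channels) withSeed(streamSeed(seed, "pla"), {
    ## specific and nonspecific spots share one slot pool so they never
    ## collide; the negative control carries an independent nonspecific field
    fld <- spotsFor(plaRateEndo, plaRateMedia, mergeFraction,
                    nsRate = nonspecificRate)
    arr <- .noiseStack(phantom, imaging$bgGray, imaging$bgNoiseSd)
    arr <- paintAll(arr, fld$spots)
    out$pla <- imageStack(.clip8(arr), phantom@pixelSizeUm, phantom@zStepUm,
                          "pla", ratId, day, target)
    truth$trueCounts <- fld$counts
    truth$nonspecificOnPla <- fld$nsCounts
    truth$spots <- fld$spots[fld$spots$specific, , drop = FALSE]
    truth$trueDensities <- fld$counts / unlist(areas)
  })

  ## The control emulates whatever channel it controls: a primary-antibody
  ## control (ambient background + read noise, no rings) when paired with a
  ## marker channel, or a PLA negative control (PLA background + nonspecific
  ## spot field) otherwise.
  if ("control" %in% channels) withSeed(streamSeed(seed, "control"), {
    if ("marker" %in% channels && !"pla" %in% channels) {
      arr <- .noiseStack(phantom, imaging$ambientGray, imaging$readNoiseSd)
      truth$nonspecificCounts <- c(endothelium = 0L, media = 0L)
    } else {
      ns <- spotsFor(nonspecificRate, nonspecificRate, 0)
      arr <- .noiseStack(phantom, imaging$bgGray, imaging$bgNoiseSd)
      arr <- paintAll(arr, ns$spots)
      truth$nonspecificCounts <- ns$counts
    }
    out$control <- imageStack(.clip8(arr), phantom@pixelSizeUm,
                              phantom@zStepUm, "negative_control",
                              ratId, day, target)
  })

  out$truth <- truth
  out
}
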