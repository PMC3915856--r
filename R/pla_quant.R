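## PLA event calling: maximum projection, thresholded particle detection,
## size-gated event counting with the merged-blob area/10 rule, and
## negative-control background subtraction.

#' @rdname maxProject
setMethod("maxProject", "ImageStack", function(stack) {
  d <- dim(stack@data)
  out <- stack@data[, , 1]
  if (d[3] > 1) for (z in 2:d[3]) out <- pmax(out, stack@data[, , z])
  out
})

#' @rdname maxProject
setMethod("maxProject", "list", function(stack) {
  dims <- lapply(stack, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("slices have mismatched shapes")
  Reduce(pmax, stack)
})

#' Detect fluorescent particles in an ROI
#'
#' Thresholds the image at `threshold` gray values, labels connected
#' components (8-connectivity by default), discards components smaller than
#' `minArea` pixels (1-px specks are below the 2-px particle minimum), and
#' returns the particles whose centroid falls inside the ROI. Particles
#' straddling an ROI boundary are assigned to the ROI containing their
#' centroid, with their full area.
#'
#' @param image matrix (use [maxProject()] on a stack first) or
#'   [ImageStack-class].
#' @param roi an [ROI-class].
#' @param threshold positive-signal threshold, gray values (default 100).
#' @param minArea smallest retained particle area, px (default 2).
#' @param connectivity 8 (default) or 4.
#' @return data.frame with columns `label`, `area`, `crow`, `ccol`, `peak`.
#' @export
detectParticles <- function(image, roi, threshold = 100, minArea = 2,
                            connectivity = 8) {
  if (is(image, "ImageStack")) image <- maxProject(image)
  stopifnot(threshold >= 0, threshold <= 255)
  p <- .particleStats(image, threshold, connectivity)
  p <- p[p$area >= minArea, , drop = FALSE]
  .particlesInROI(p, roi)
}

## Restrict a particle table to particles whose centroid lies in the ROI.
.particlesInROI <- function(p, roi) {
  if (!nrow(p)) return(p)
  nr <- roi@dim[1]
  idx <- (pmin(pmax(round(p$ccol), 1L), roi@dim[2]) - 1L) * nr +
    pmin(pmax(round(p$crow), 1L), nr)
  p[idx %in% roi@pixels, , drop = FALSE]
}

#' Count PLA events from detected particles
#'
#' A particle of area 2-50 px counts as one event. A merged particle larger
#' than 50 px contributes its area divided by 10 (the median single-event
#' size), rounded to the nearest integer with ties rounding up; a fractional
#' mode is available for sensitivity analysis.
#'
#' @param particles data.frame from [detectParticles()].
#' @param maxSingleArea largest single-event area, px (default 50).
#' @param medianEventArea median single-event area used for merged blobs
#'   (default 10).
#' @param fractional if TRUE merged blobs contribute area/10 unrounded.
#' @return Event count (numeric).
#' @export
#' @examples
#' countEvents(data.frame(area = c(10, 10, 10)))  # 3
#' countEvents(data.frame(area = 500))            # 50
countEvents <- function(particles, maxSingleArea = 50, medianEventArea = 10,
                        fractional = FALSE) {
  if (!nrow(particles)) return(0)
  a <- particles$area
  merged <- a > maxSingleArea
  ev <- numeric(length(a))
  ev[!merged] <- 1
  ev[merged] <- if (fractional) a[merged] / medianEventArea
                else .roundHalfUp(a[merged] / medianEventArea)
  sum(ev)
}

#' Background-correct an event density using the negative control
#'
#' @param rawDensity events/mm^2 measured on the specimen.
#' @param controlDensity events/mm^2 measured on the matching negative
#'   control with identical threshold and size rules.
#' @return Corrected density with attribute `negative` flagging values below
#'   zero (retained, not clamped).
#' @export
#' @examples
#' backgroundCorrect(120, 20)  # 100
backgroundCorrect <- function(rawDensity, controlDensity) {
  if (any(is.na(controlDensity)))
    stop("missing matched negative-control density")
  out <- rawDensity - controlDensity
  attr(out, "negative") <- out < 0
  out
}

#' Quantify one specimen's PLA stack against its negative control
#'
#' Projects both stacks, detects particles once per projection, assigns them
#' to the six protocol ROIs by centroid, applies the event-counting rules,
#' and reports per-ROI raw, control and corrected densities.
#'
#' @param plaStack PLA-channel [ImageStack-class].
#' @param controlStack negative-control [ImageStack-class].
#' @param rois list of [ROI-class].
#' @param pair receptor-ligand pair name for the output table.
#' @param threshold,minArea,maxSingleArea,medianEventArea counting rules
#'   (defaults 100, 2, 50, 10).
#' @param connectivity component connectivity (default 8).
#' @return data.frame: one row per ROI with `particles`, `events`, `areaMm2`,
#'   `rawDensity`, `controlDensity`, `correctedDensity`, `negativeFlag`.
#' @export
quantifyPLA <- function(plaStack, controlStack, rois, pair = "",
                        threshold = 100, minArea = 2, maxSingleArea = 50,
                        medianEventArea = 10, connectivity = 8) {
  proj <- maxProject(plaStack)
  projC <- maxProject(controlStack)
  p <- .particleStats(proj, threshold, connectivity)
  p <- p[p$area >= minArea, , drop = FALSE]
  pc <- .particleStats(projC, threshold, connectivity)
  pc <- pc[pc$area >= minArea, , drop = FALSE]
  rows <- lapply(seq_along(rois), function(i) {
    roi <- rois[[i]]
    pr <- .particlesInROI(p, roi)
    prc <- .particlesInROI(pc, roi)
    ev <- countEvents(pr, maxSingleArea, medianEventArea)
    evc <- countEvents(prc, maxSingleArea, medianEventArea)
    raw <- ev / roi@areaMm2
    ctl <- evc / roi@areaMm2
    corr <- backgroundCorrect(raw, ctl)
    data.frame(ratId = plaStack@ratId, day = plaStack@day, pair = pair,
               roiId = i, compartment = roi@compartment,
               particles = nrow(pr), events = ev, areaMm2 = roi@areaMm2,
               rawDensity = raw, controlDensity = ctl,
               correctedDensity = as.numeric(corr),
               negativeFlag = attr(corr, "negative"))
  })
  do.call(rbind, rows)
}

#' PLA time-course: group mean, SE and percent change vs baseline
#'
#' Per-ROI corrected densities are first averaged within each rat and
#' compartment (three ROIs per compartment), then summarized per pair x day x
#' compartment as group mean, SE and percent change versus the baseline-day
#' group mean.
#'
#' @param eventTables data.frame from [quantifyPLA()] / [runPLAArm()].
#' @param baselineDay baseline day (default -1).
#' @return data.frame with columns `pair`, `compartment`, `day`, `n`, `mean`,
#'   `se`, `pctChange`.
#' @export
plaTimecourse <- function(eventTables, baselineDay = -1) {
  perRat <- aggregate(correctedDensity ~ ratId + day + pair + compartment,
                      eventTables, mean)
  .timecourseTable(perRat, valueCol = "correctedDensity",
                   keyCols = c("pair", "compartment"),
                   baselineDay = baselineDay)
}
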