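## Immunofluorescence quantification: mean gray value in ROIs with
## primary-antibody-control correction.

#' Mean gray value of an ROI
#'
#' Arithmetic mean of the pixel values inside the ROI mask, computed on the
#' maximum projection when given a stack.
#'
#' @param image a matrix (projection) or an [ImageStack-class] (projected
#'   first).
#' @param roi an [ROI-class] placed on an image of the same dimension.
#' @return Mean gray value.
#' @export
#' @examples
#' img <- matrix(37, 64, 64)
#' roi <- placeROIs(vesselPhantom(20, 4, 6, imageShape = c(64, 64)))[[1]]
#' meanGray(img, roi)  # 37
meanGray <- function(image, roi) {
  if (is(image, "ImageStack")) image <- maxProject(image)
  stopifnot(is.matrix(image), is(roi, "ROI"))
  if (!identical(dim(image), as.integer(roi@dim)))
    stop("ROI was defined on an image of different dimension")
  if (!length(roi@pixels)) stop("empty ROI mask")
  mean(image[roi@pixels])
}

#' Correct FIU using the primary-antibody control
#'
#' Default correction is subtraction (fiu_raw - fiu_control); a ratio mode is
#' available. Negative corrected values are retained, not clamped, to keep
#' group means unbiased; the `negative` attribute flags them.
#'
#' @param fiuRaw raw mean gray value(s).
#' @param fiuControl control mean gray value(s), same specimen and
#'   compartment.
#' @param method "subtract" (default) or "ratio".
#' @return Corrected FIU with attribute `negative` (logical).
#' @export
#' @examples
#' correctFIU(150, 20)  # 130
correctFIU <- function(fiuRaw, fiuControl, method = c("subtract", "ratio")) {
  method <- match.arg(method)
  if (any(is.na(fiuControl)))
    stop("missing primary-antibody control measurement")
  out <- if (method == "subtract") fiuRaw - fiuControl else fiuRaw / fiuControl
  attr(out, "negative") <- out < 0
  out
}

#' Quantify one specimen's marker image against its control
#'
#' @param markerStack marker-channel [ImageStack-class].
#' @param controlStack primary-antibody-control [ImageStack-class].
#' @param rois list of [ROI-class] from [placeROIs()].
#' @param marker marker name for the output table.
#' @return data.frame: one row per rat x compartment with the per-ROI mean of
#'   raw, control and corrected FIU.
#' @export
quantifyIF <- function(markerStack, controlStack, rois, marker = "") {
  proj <- maxProject(markerStack)
  projC <- maxProject(controlStack)
  per <- lapply(rois, function(roi) {
    raw <- meanGray(proj, roi)
    ctl <- meanGray(projC, roi)
    data.frame(compartment = roi@compartment, fiuRaw = raw, fiuControl = ctl)
  })
  d <- do.call(rbind, per)
  agg <- aggregate(cbind(fiuRaw, fiuControl) ~ compartment, d, mean)
  corr <- correctFIU(agg$fiuRaw, agg$fiuControl)
  data.frame(ratId = markerStack@ratId, day = markerStack@day,
             marker = marker, compartment = agg$compartment,
             fiuRaw = agg$fiuRaw, fiuControl = agg$fiuControl,
             fiuCorrected = as.numeric(corr),
             negativeFlag = attr(corr, "negative"))
}

#' Marker time-course: group mean, SE and percent change vs baseline
#'
#' Summarizes per-rat corrected FIU per marker x day x compartment and
#' expresses each day as percent change relative to the baseline-day group
#' mean.
#'
#' @param measurements data.frame as returned by [quantifyIF()] /
#'   [runIFArm()].
#' @param baselineDay baseline day (default -1, the pre-AVF sham controls).
#' @return data.frame with columns `marker`, `compartment`, `day`, `n`,
#'   `mean`, `se`, `pctChange`.
#' @export
markerTimecourse <- function(measurements, baselineDay = -1) {
  .timecourseTable(measurements, valueCol = "fiuCorrected",
                   keyCols = c("marker", "compartment"),
                   baselineDay = baselineDay)
}

## Shared grouped summary + percent-change machinery for FIU and PLA tables.
.timecourseTable <- function(d, valueCol, keyCols, baselineDay) {
  if (!baselineDay %in% d$day)
    stop(sprintf("baseline day %g absent from the measurements", baselineDay))
  d$.value <- d[[valueCol]]
  keys <- unique(d[, keyCols, drop = FALSE])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- rep(TRUE, nrow(d))
    for (k in keyCols) sel <- sel & d[[k]] == keys[[k]][i]
    di <- d[sel, ]
    days <- sort(unique(di$day))
    s <- do.call(rbind, lapply(days, function(dy) {
      v <- di$.value[di$day == dy]
      data.frame(day = dy, n = length(v), mean = mean(v),
                 se = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_)
    }))
    base <- s$mean[s$day == baselineDay]
    if (!length(base))
      stop(sprintf("baseline day %g absent for %s", baselineDay,
                   paste(unlist(keys[i, ]), collapse = "/")))
    s$pctChange <- percentChange(s$mean, base)
    for (k in rev(keyCols)) s <- cbind(setNames(data.frame(keys[[k]][i]), k), s)
    out[[i]] <- s
  }
  do.call(rbind, out)
}
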