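## Image and table I/O: multi-page grayscale TIFF stacks with an 8-bit
## scale, plus manifest-driven loading.

#' Write an ImageStack as a multi-page 8-bit grayscale TIFF
#'
#' One page per z slice. Gray values 0-255 map to the unit range of the TIFF
#' samples; the pixel size is carried by the study manifest, not the file.
#'
#' @param stack an [ImageStack-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeImageStack <- function(stack, path) {
  d <- dim(stack@data)
  pages <- lapply(seq_len(d[3]), function(z) stack@data[, , z] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a multi-page grayscale TIFF as an ImageStack
#'
#' @param path TIFF file path.
#' @param pixelSizeUm,zStepUm imaging metadata (from the manifest).
#' @param channel,ratId,day,target stack metadata.
#' @return An [ImageStack-class] with gray values 0-255.
#' @export
readImageStack <- function(path, pixelSizeUm = 2, zStepUm = 2,
                           channel = "pla", ratId = "rat1", day = 0,
                           target = "") {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) arr[, , z] <- round(pages[[z]] * 255)
  imageStack(arr, pixelSizeUm, zStepUm, channel, ratId, day, target)
}

#' Load flow traces from a long-format flow table
#'
#' @param flows data.frame or CSV path with columns `ratId`, `day`,
#'   `vesselLabel`, `tS`, `flowMlMin`.
#' @return List of [FlowTrace-class], one per rat x day.
#' @export
readFlowTable <- function(flows) {
  if (is.character(flows)) flows <- read.csv(flows)
  keys <- unique(flows[, c("ratId", "day")])
  lapply(seq_len(nrow(keys)), function(i) {
    fi <- flows[flows$ratId == keys$ratId[i] & flows$day == keys$day[i], ]
    fi <- fi[order(fi$tS), ]
    flowTrace(fi$tS, fi$flowMlMin, vesselLabel = fi$vesselLabel[1],
              ratId = keys$ratId[i], day = keys$day[i])
  })
}

#' Quantify a study from its on-disk manifest
#'
#' Loads every specimen listed in a [genStudy()] manifest and runs the
#' matching quantification ([quantifyIF()] or [quantifyPLA()]).
#'
#' @param dir study directory containing `manifest.csv` and `images/`.
#' @param profile the [CalibrationProfile-class] used to generate the study
#'   (supplies the ROI geometry).
#' @param threshold PLA detection threshold (default 100).
#' @return list with data.frames `fiu` and `pla` (either may be NULL).
#' @export
quantifyStudyDir <- function(dir, profile, threshold = 100) {
  man <- read.csv(file.path(dir, "manifest.csv"))
  fiu <- list(); pla <- list()
  roisIF <- placeROIs(profile@ifPhantom, bandDepthUm = profile@imaging$bandDepthUm)
  roisPLA <- placeROIs(profile@plaPhantom, bandDepthUm = profile@imaging$bandDepthUm)
  keys <- unique(man[, c("target", "type", "ratId", "day")])
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    mi <- man[man$target == k$target & man$type == k$type &
                man$ratId == k$ratId & man$day == k$day, ]
    get <- function(channel) {
      row <- mi[mi$channel == channel, ]
      readImageStack(file.path(dir, row$file), row$pixelSizeUm, row$zStepUm,
                     channel = if (channel == "negative_control") channel
                               else if (k$type == "if") "marker" else "pla",
                     ratId = k$ratId, day = k$day, target = k$target)
    }
    if (k$type == "if") {
      fiu[[length(fiu) + 1L]] <- quantifyIF(get("marker"),
                                            get("negative_control"),
                                            roisIF, marker = k$target)
    } else {
      pla[[length(pla) + 1L]] <- quantifyPLA(get("pla"),
                                             get("negative_control"),
                                             roisPLA, pair = k$target,
                                             threshold = threshold)
    }
  }
  list(fiu = if (length(fiu)) do.call(rbind, fiu) else NULL,
       pla = if (length(pla)) do.call(rbind, pla) else NULL)
}
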