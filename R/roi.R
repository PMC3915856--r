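## ROI placement: three polygon band ROIs hugging the lumen (endothelium)
## and three circular ROIs in the media, plus import of hand-drawn ROI files.

## Segmentation descriptor shared by the generator and the ROI engine.
## A list: center (row, col), lumenRadiusPx, intimaThicknessPx,
## mediaThicknessPx, dim (rows, cols), pixelSizeUm.

#' Segmentation geometry of a vessel phantom
#'
#' Derives the lumen/intima/media segmentation used for automated ROI
#' placement from a phantom's known geometry (centered vessel).
#'
#' @param phantom a [VesselPhantom-class].
#' @return A list with fields `center`, `lumenRadiusPx`, `intimaThicknessPx`,
#'   `mediaThicknessPx`, `dim`, `pixelSizeUm`.
#' @export
phantomSegmentation <- function(phantom) {
  list(center = (phantom@imageShape + 1) / 2,
       lumenRadiusPx = phantom@lumenRadiusPx,
       intimaThicknessPx = phantom@intimaThicknessPx,
       mediaThicknessPx = phantom@mediaThicknessPx,
       dim = phantom@imageShape,
       pixelSizeUm = phantom@pixelSizeUm)
}

## Radius and angle fields of an image grid relative to a center.
.polarFields <- function(dim, center) {
  r <- sqrt(outer((seq_len(dim[1]) - center[1])^2,
                  (seq_len(dim[2]) - center[2])^2, "+"))
  ang <- atan2(outer(seq_len(dim[1]) - center[1], rep(1, dim[2])),
               outer(rep(1, dim[1]), seq_len(dim[2]) - center[2]))
  list(r = r, ang = (ang + 2 * pi) %% (2 * pi))
}

.mkROI <- function(shape, compartment, pixels, dim, pixelSizeUm, params) {
  pixels <- as.integer(pixels)
  nr <- dim[1]
  rows <- ((pixels - 1L) %% nr) + 1L
  cols <- ((pixels - 1L) %/% nr) + 1L
  new("ROI", shape = shape, compartment = compartment, pixels = pixels,
      dim = as.integer(dim),
      areaMm2 = length(pixels) * (pixelSizeUm / 1000)^2,
      centroid = c(mean(rows), mean(cols)), params = params)
}

#' Place the six protocol ROIs on a segmented vessel cross-section
#'
#' Places three polygon regions of interest evenly (120 degrees apart) along
#' the vessel lumen, extending a fixed depth (default 5 um) into the tunica
#' intima to envelope the endothelium, and three circular regions evenly
#' within the tunica media (offset 60 degrees from the bands). Band depth in
#' pixels is `max(1, round(bandDepthUm / pixelSizeUm))`.
#'
#' @param segmentation segmentation list as from [phantomSegmentation()], or a
#'   [VesselPhantom-class].
#' @param angleOffset rotation of the ROI layout, radians (default 0).
#' @param bandDepthUm endothelial band depth, microns (default 5).
#' @param mediaCircleAreaMm2 requested media circle area in mm^2; default
#'   `NULL` uses the largest circle that fits the media ring with a 2 px
#'   margin. If the requested area needs a circle thicker than the media,
#'   the error reports the maximum feasible area.
#' @param areaBounds optional c(min, max) bounds in mm^2 checked against every
#'   ROI (the acquisition protocol used 0.5-1.0 mm^2 on full-scale images);
#'   `NULL` (default) skips the check, appropriate for phantom-scale images.
#' @return A list of six [ROI-class] objects (3 endothelium, 3 media).
#' @export
#' @examples
#' ph <- vesselPhantom(60, 12, 40, imageShape = c(256, 256))
#' rois <- placeROIs(ph)
#' vapply(rois, roiCompartment, "")
placeROIs <- function(segmentation, angleOffset = 0, bandDepthUm = 5,
                      mediaCircleAreaMm2 = NULL, areaBounds = NULL) {
  if (is(segmentation, "VesselPhantom"))
    segmentation <- phantomSegmentation(segmentation)
  seg <- segmentation
  px <- seg$pixelSizeUm
  depthPx <- max(1, round(bandDepthUm / px))
  pf <- .polarFields(seg$dim, seg$center)
  R0 <- seg$lumenRadiusPx
  band <- pf$r >= R0 & pf$r < R0 + depthPx
  relAng <- (pf$ang - angleOffset) %% (2 * pi)
  sector <- floor(relAng / (2 * pi / 3))  # 0, 1, 2

  rois <- vector("list", 6L)
  for (k in 0:2) {
    idx <- which(band & sector == k)
    rois[[k + 1L]] <- .mkROI("polygon", "endothelium", idx, seg$dim, px,
      list(center = seg$center, rIn = R0, rOut = R0 + depthPx,
           thetaFrom = angleOffset + k * 2 * pi / 3,
           thetaTo = angleOffset + (k + 1) * 2 * pi / 3, depthPx = depthPx))
  }

  mediaIn <- R0 + seg$intimaThicknessPx
  mediaMid <- mediaIn + seg$mediaThicknessPx / 2
  maxRad <- seg$mediaThicknessPx / 2 - 2
  if (maxRad < 1) stop("media ring too thin for circular ROIs")
  if (is.null(mediaCircleAreaMm2)) {
    circRad <- maxRad
  } else {
    circRad <- sqrt(mediaCircleAreaMm2 / pi) * 1000 / px
    if (circRad > maxRad)
      stop(sprintf(
        "media too thin for requested circle area %.4f mm2; maximum feasible area is %.4f mm2",
        mediaCircleAreaMm2, pi * (maxRad * px / 1000)^2))
  }
  for (k in 0:2) {
    th <- angleOffset + pi / 3 + k * 2 * pi / 3
    ctr <- seg$center + mediaMid * c(sin(th), cos(th))
    rc <- sqrt(outer((seq_len(seg$dim[1]) - ctr[1])^2,
                     (seq_len(seg$dim[2]) - ctr[2])^2, "+"))
    idx <- which(rc <= circRad)
    rois[[k + 4L]] <- .mkROI("circle", "media", idx, seg$dim, px,
      list(center = ctr, radiusPx = circRad, theta = th))
  }

  if (!is.null(areaBounds)) {
    ar <- vapply(rois, roiArea, 0)
    bad <- ar < areaBounds[1] | ar > areaBounds[2]
    if (any(bad))
      warning(sprintf("%d ROI(s) outside the configured area bounds [%g, %g] mm2",
                      sum(bad), areaBounds[1], areaBounds[2]))
  }
  ov <- unlist(lapply(rois, slot, "pixels"))
  if (anyDuplicated(ov)) stop("internal error: overlapping ROIs")
  rois
}

#' Import hand-drawn ROIs from a JSON geometry file
#'
#' The file holds an array of objects with fields `shape` ("polygon" or
#' "circle"), `compartment`, and either `vertices` (list of [row, col]) or
#' `center` + `radius` in pixel coordinates.
#'
#' @param path JSON file path.
#' @param dim image dimension c(rows, cols).
#' @param pixelSizeUm microns per pixel.
#' @param areaBounds optional c(min, max) area bounds in mm^2 (warning if
#'   violated).
#' @return List of [ROI-class] objects.
#' @export
readROIs <- function(path, dim, pixelSizeUm, areaBounds = NULL) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(spec)) spec <- split(spec, seq_len(nrow(spec)))
  rois <- lapply(spec, function(s) {
    s <- as.list(s)
    if (s$shape == "circle") {
      ctr <- unlist(s$center)
      rc <- sqrt(outer((seq_len(dim[1]) - ctr[1])^2,
                       (seq_len(dim[2]) - ctr[2])^2, "+"))
      idx <- which(rc <= s$radius)
      .mkROI("circle", s$compartment, idx, dim, pixelSizeUm,
             list(center = ctr, radiusPx = s$radius))
    } else {
      v <- s$vertices
      if (is.list(v)) v <- do.call(rbind, lapply(v, unlist))
      v <- matrix(as.numeric(v), ncol = 2)
      grid <- expand.grid(row = seq_len(dim[1]), col = seq_len(dim[2]))
      inside <- pracma::inpolygon(grid$row, grid$col, v[, 1], v[, 2],
                                  boundary = TRUE)
      idx <- which(matrix(inside, dim[1], dim[2]))
      .mkROI("polygon", s$compartment, idx, dim, pixelSizeUm,
             list(vertices = v))
    }
  })
  if (!is.null(areaBounds)) {
    ar <- vapply(rois, roiArea, 0)
    bad <- ar < areaBounds[1] | ar > areaBounds[2]
    if (any(bad))
      warning(sprintf("%d ROI(s) outside the configured area bounds [%g, %g] mm2",
                      sum(bad), areaBounds[1], areaBounds[2]))
  }
  rois
}
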