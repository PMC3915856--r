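## S4 classes for the core data objects. Tabular results (event tables,
## time-courses, study tables) are plain data.frames.

#' VesselPhantom: geometry of a synthetic vessel cross-section image
#'
#' Describes the annular vessel phantom used by the synthetic-data generator:
#' a circular lumen surrounded by an intima ring (carrying the endothelium)
#' and a media ring, imaged as a z-stack at a known pixel size.
#'
#' @slot lumenRadiusPx lumen radius in pixels.
#' @slot intimaThicknessPx intima ring thickness in pixels.
#' @slot mediaThicknessPx media ring thickness in pixels.
#' @slot pixelSizeUm microns per pixel.
#' @slot imageShape integer c(rows, cols).
#' @slot nZSlices number of z slices.
#' @slot zStepUm z step between slices, microns.
#' @slot zVolumeUm total z volume, microns; must equal nZSlices * zStepUm.
#' @export
setClass("VesselPhantom",
  representation(
    lumenRadiusPx = "numeric", intimaThicknessPx = "numeric",
    mediaThicknessPx = "numeric", pixelSizeUm = "numeric",
    imageShape = "integer", nZSlices = "integer",
    zStepUm = "numeric", zVolumeUm = "numeric"
  )
)

setValidity("VesselPhantom", function(object) {
  msg <- character(0)
  if (object@lumenRadiusPx <= 0) msg <- c(msg, "lumenRadiusPx must be > 0")
  if (object@intimaThicknessPx <= 0) msg <- c(msg, "intimaThicknessPx must be > 0")
  if (object@mediaThicknessPx <= 0) msg <- c(msg, "mediaThicknessPx must be > 0")
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be > 0")
  if (length(object@imageShape) != 2L || any(object@imageShape < 8L))
    msg <- c(msg, "imageShape must be two integers >= 8")
  outer <- object@lumenRadiusPx + object@intimaThicknessPx +
    object@mediaThicknessPx
  if (outer + 1 > min(object@imageShape) / 2)
    msg <- c(msg, sprintf(
      "vessel annulus (outer radius %.0f px) does not fit inside image of shape %s",
      outer, paste(object@imageShape, collapse = "x")))
  if (object@nZSlices < 1L) msg <- c(msg, "nZSlices must be >= 1")
  if (abs(object@nZSlices * object@zStepUm - object@zVolumeUm) > 1e-9)
    msg <- c(msg, "nZSlices * zStepUm must equal zVolumeUm")
  if (length(msg)) msg else TRUE
})

#' Construct a VesselPhantom
#'
#' @param lumenRadiusPx,intimaThicknessPx,mediaThicknessPx ring geometry (px).
#' @param pixelSizeUm microns per pixel (default 2).
#' @param imageShape image dimensions c(rows, cols).
#' @param nZSlices,zStepUm,zVolumeUm z-stack geometry; the confocal protocol
#'   default is 6 slices, 2 um apart, 12 um total.
#' @return A [VesselPhantom-class] object.
#' @export
#' @examples
#' vesselPhantom(120, 25, 80, imageShape = c(512, 512))
vesselPhantom <- function(lumenRadiusPx, intimaThicknessPx, mediaThicknessPx,
                          pixelSizeUm = 2, imageShape = c(512L, 512L),
                          nZSlices = 6L, zStepUm = 2, zVolumeUm = nZSlices * zStepUm) {
  new("VesselPhantom",
      lumenRadiusPx = as.numeric(lumenRadiusPx),
      intimaThicknessPx = as.numeric(intimaThicknessPx),
      mediaThicknessPx = as.numeric(mediaThicknessPx),
      pixelSizeUm = as.numeric(pixelSizeUm),
      imageShape = as.integer(imageShape),
      nZSlices = as.integer(nZSlices),
      zStepUm = as.numeric(zStepUm), zVolumeUm = as.numeric(zVolumeUm))
}

#' CalibrationProfile: study-design constants for the synthetic generator
#'
#' Encodes the study conditions the generator emulates: the day grid with a
#' single pre-AVF baseline day, the flow and wall-shear-stress trends, the
#' per-marker and per-interaction-pair true percent-change time-courses,
#' replicate noise, and group sizes. Defaults are set by
#' [calibrationProfile()].
#'
#' @slot timeGridDays imaging-arm day grid (baseline coded -1).
#' @slot hemoDays hemodynamic-arm day grid (includes day 0, the fistula
#'   creation day).
#' @slot baselineDay the pre-AVF baseline day.
#' @slot flowBaselineMlMin pre-AVF carotid flow, mL/min.
#' @slot flowDay0Fold flow fold-increase immediately after fistula creation.
#' @slot flowPeakFold day-42 flow as a multiple of day-0 fistula flow.
#' @slot wssBaseline,wssDay0,wssDay42 shear-stress trend anchors, dyn/cm^2.
#' @slot viscosity blood viscosity, dyn s/cm^2.
#' @slot markerTimecourses named list: per-day true percent change of each
#'   marker's endothelial FIU vs baseline.
#' @slot interactionTimecourses named list: per-day true percent change of
#'   each receptor-ligand pair's endothelial PLA event density vs baseline.
#' @slot markerBaselineGray,mediaBaselineGray baseline marker signal (gray).
#' @slot plaBaselineDensity baseline endothelial PLA event density, events/mm^2.
#' @slot mediaDensity media PLA event density, events/mm^2 (no time effect).
#' @slot nonspecificFraction nonspecific spot density as a fraction of
#'   plaBaselineDensity.
#' @slot mergeFraction fraction of true events seeded in merged clusters.
#' @slot replicateNoiseCV specimen-level lognormal CV.
#' @slot ratsPerTimepoint rats per day in the imaging arms.
#' @slot nHemoRats rats in the hemodynamic arm.
#' @slot poissonCounts logical; draw spot counts as Poisson (TRUE) or use the
#'   rounded expectation (FALSE, for noise-free calibration checks).
#' @slot ifPhantom,plaPhantom [VesselPhantom-class] geometries for the two arms.
#' @slot imaging list of image-formation constants (gray levels, noise SDs,
#'   spot distribution, slot spacing).
#' @slot seed integer root seed.
#' @export
setClass("CalibrationProfile",
  representation(
    timeGridDays = "numeric", hemoDays = "numeric", baselineDay = "numeric",
    flowBaselineMlMin = "numeric", flowDay0Fold = "numeric",
    flowPeakFold = "numeric",
    wssBaseline = "numeric", wssDay0 = "numeric", wssDay42 = "numeric",
    viscosity = "numeric",
    markerTimecourses = "list", interactionTimecourses = "list",
    markerBaselineGray = "numeric", mediaBaselineGray = "numeric",
    plaBaselineDensity = "numeric", mediaDensity = "numeric",
    nonspecificFraction = "numeric", mergeFraction = "numeric",
    replicateNoiseCV = "numeric", ratsPerTimepoint = "integer",
    nHemoRats = "integer", poissonCounts = "logical",
    ifPhantom = "VesselPhantom", plaPhantom = "VesselPhantom",
    imaging = "list", seed = "integer"
  )
)

setValidity("CalibrationProfile", function(object) {
  msg <- character(0)
  tg <- object@timeGridDays
  if (is.unsorted(tg, strictly = TRUE)) msg <- c(msg, "timeGridDays must be strictly increasing")
  if (sum(tg == object@baselineDay) != 1L)
    msg <- c(msg, "time grid must contain the baseline day exactly once")
  if (object@replicateNoiseCV < 0) msg <- c(msg, "replicateNoiseCV must be >= 0")
  if (object@ratsPerTimepoint < 1L) msg <- c(msg, "ratsPerTimepoint must be >= 1")
  if (object@flowBaselineMlMin <= 0) msg <- c(msg, "flowBaselineMlMin must be > 0")
  if (object@wssDay0 <= 0 || object@wssDay42 <= 0 || object@wssBaseline <= 0)
    msg <- c(msg, "shear-stress anchors must be > 0")
  nDays <- sum(tg != object@baselineDay)
  for (nm in names(object@markerTimecourses))
    if (length(object@markerTimecourses[[nm]]) != nDays)
      msg <- c(msg, sprintf("marker '%s' time-course must have %d values", nm, nDays))
  for (nm in names(object@interactionTimecourses))
    if (length(object@interactionTimecourses[[nm]]) != nDays)
      msg <- c(msg, sprintf("pair '%s' time-course must have %d values", nm, nDays))
  if (length(msg)) msg else TRUE
})

#' FlowTrace: a sampled volumetric flow-rate series
#'
#' @slot timeS sample times in seconds, strictly increasing.
#' @slot flowMlMin flow rate in mL/min.
#' @slot vesselLabel one of "carotid_proximal", "fistula_vein", "draining_vein".
#' @slot ratId rat identifier.
#' @slot day study day.
#' @export
setClass("FlowTrace",
  representation(timeS = "numeric", flowMlMin = "numeric",
                 vesselLabel = "character", ratId = "character", day = "numeric"))

setValidity("FlowTrace", function(object) {
  msg <- character(0)
  if (!length(object@timeS)) msg <- c(msg, "trace must contain at least one sample")
  if (length(object@timeS) != length(object@flowMlMin))
    msg <- c(msg, "timeS and flowMlMin must have equal length")
  if (length(object@timeS) > 1 && is.unsorted(object@timeS, strictly = TRUE))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (!object@vesselLabel %in% c("carotid_proximal", "fistula_vein", "draining_vein"))
    msg <- c(msg, "unknown vesselLabel")
  if (length(msg)) msg else TRUE
})

#' Construct a FlowTrace
#' @param timeS sample times (s). @param flowMlMin flow (mL/min).
#' @param vesselLabel vessel label. @param ratId rat id. @param day study day.
#' @return A [FlowTrace-class].
#' @export
flowTrace <- function(timeS, flowMlMin, vesselLabel = "fistula_vein",
                      ratId = "rat1", day = 0) {
  new("FlowTrace", timeS = as.numeric(timeS), flowMlMin = as.numeric(flowMlMin),
      vesselLabel = vesselLabel, ratId = as.character(ratId), day = as.numeric(day))
}

#' VesselGeometry: radius and viscosity for shear computation
#'
#' @slot radiusCm internal radius, cm.
#' @slot viscosity blood viscosity, dyn s/cm^2.
#' @export
setClass("VesselGeometry",
  representation(radiusCm = "numeric", viscosity = "numeric"))

setValidity("VesselGeometry", function(object) {
  msg <- character(0)
  if (object@radiusCm <= 0) msg <- c(msg, "radius must be > 0")
  if (object@viscosity <= 0) msg <- c(msg, "viscosity must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a VesselGeometry
#' @param radiusCm internal radius (cm).
#' @param viscosity blood viscosity (dyn s/cm^2); 0.04 is typical rat whole blood.
#' @return A [VesselGeometry-class].
#' @export
vesselGeometry <- function(radiusCm, viscosity = 0.04) {
  new("VesselGeometry", radiusCm = as.numeric(radiusCm),
      viscosity = as.numeric(viscosity))
}

#' ShearStressEstimate: result of the Poiseuille computation
#'
#' @slot tau wall shear stress, dyn/cm^2.
#' @slot meanFlowCm3S mean flow used, cm^3/s.
#' @slot radiusCm,viscosity inputs echoed for provenance.
#' @export
setClass("ShearStressEstimate",
  representation(tau = "numeric", meanFlowCm3S = "numeric",
                 radiusCm = "numeric", viscosity = "numeric"))

#' ImageStack: a grayscale z-stack with imaging metadata
#'
#' Pixel values are whole gray values on the 8-bit scale (0-255). The third
#' array dimension indexes z slices.
#'
#' @slot data numeric array rows x cols x z.
#' @slot pixelSizeUm microns per pixel.
#' @slot zStepUm z step, microns.
#' @slot channel one of "marker", "pla", "negative_control".
#' @slot ratId,day,target specimen keys (target is a marker or pair name).
#' @export
setClass("ImageStack",
  representation(data = "array", pixelSizeUm = "numeric", zStepUm = "numeric",
                 channel = "character", ratId = "character", day = "numeric",
                 target = "character"))

setValidity("ImageStack", function(object) {
  msg <- character(0)
  if (length(dim(object@data)) != 3L) msg <- c(msg, "data must be a 3-D array")
  if (!object@channel %in% c("marker", "pla", "negative_control"))
    msg <- c(msg, "unknown channel")
  if (length(msg)) msg else TRUE
})

#' Construct an ImageStack
#' @param data rows x cols x z numeric array (a matrix is promoted to one slice).
#' @param pixelSizeUm microns per pixel. @param zStepUm z step (um).
#' @param channel channel role. @param ratId,day,target specimen keys.
#' @return An [ImageStack-class].
#' @export
imageStack <- function(data, pixelSizeUm = 2, zStepUm = 2, channel = "pla",
                       ratId = "rat1", day = 0, target = "") {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  new("ImageStack", data = data, pixelSizeUm = as.numeric(pixelSizeUm),
      zStepUm = as.numeric(zStepUm), channel = channel,
      ratId = as.character(ratId), day = as.numeric(day), target = target)
}

#' ROI: a quantification region of interest
#'
#' ROIs are stored as sets of pixel indices into an image of known dimension,
#' together with their compartment and physical area.
#'
#' @slot shape "polygon" (endothelial band sector) or "circle" (media).
#' @slot compartment "endothelium" or "media".
#' @slot pixels integer linear pixel indices.
#' @slot dim image dimension c(rows, cols) the indices refer to.
#' @slot areaMm2 area in mm^2.
#' @slot centroid c(row, col) centroid.
#' @slot params geometry parameters (center, radii, angles).
#' @export
setClass("ROI",
  representation(shape = "character", compartment = "character",
                 pixels = "integer", dim = "integer", areaMm2 = "numeric",
                 centroid = "numeric", params = "list"))

setValidity("ROI", function(object) {
  msg <- character(0)
  if (!object@shape %in% c("polygon", "circle")) msg <- c(msg, "unknown shape")
  if (!object@compartment %in% c("endothelium", "media"))
    msg <- c(msg, "unknown compartment")
  if (!length(object@pixels)) msg <- c(msg, "ROI has no pixels")
  if (length(msg)) msg else TRUE
})
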