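## Generics and show methods.

#' Time-averaged flow of a trace, in cm^3/s
#'
#' Trapezoidal time-average of the flow trace, converted from mL/min using
#' 1 mL/min = 1/60 cm^3/s. A single-sample trace returns that sample with a
#' warning; an empty trace is an error (prevented by the class validity).
#'
#' @param trace a [FlowTrace-class].
#' @return Mean flow in cm^3/s.
#' @export
#' @examples
#' tr <- flowTrace(seq(0, 1, 0.01), rep(5.2, 101))
#' meanFlow(tr)  # 5.2/60
setGeneric("meanFlow", function(trace) standardGeneric("meanFlow"))

#' Maximum-intensity projection of a z-stack
#'
#' @param stack an [ImageStack-class] or a list of equally sized matrices.
#' @return A matrix: the pixelwise maximum across slices.
#' @export
setGeneric("maxProject", function(stack) standardGeneric("maxProject"))

#' @describeIn VesselPhantom-class area of one pixel in mm^2
#' @param phantom a [VesselPhantom-class].
#' @export
pixelAreaMm2 <- function(phantom) (phantom@pixelSizeUm / 1000)^2

setMethod("show", "VesselPhantom", function(object) {
  cat(sprintf(
    "VesselPhantom: lumen %g px, intima %g px, media %g px, %g um/px\n  image %s, %d z-slices x %g um (%g um volume)\n",
    object@lumenRadiusPx, object@intimaThicknessPx, object@mediaThicknessPx,
    object@pixelSizeUm, paste(object@imageShape, collapse = "x"),
    object@nZSlices, object@zStepUm, object@zVolumeUm))
})

setMethod("show", "CalibrationProfile", function(object) {
  cat("CalibrationProfile\n")
  cat("  days:", paste(object@timeGridDays, collapse = ", "),
      sprintf("(baseline %g)\n", object@baselineDay))
  cat(sprintf("  flow: %.1f mL/min baseline, x%.1f at day 0, x%.0f at day 42\n",
              object@flowBaselineMlMin, object@flowDay0Fold, object@flowPeakFold))
  cat(sprintf("  WSS trend: %.1f -> %.1f dyn/cm2 (day 0 -> 42), baseline %.1f\n",
              object@wssDay0, object@wssDay42, object@wssBaseline))
  cat(sprintf("  %d markers, %d interaction pairs; %d rats/day, CV %.2f, seed %d\n",
              length(object@markerTimecourses),
              length(object@interactionTimecourses),
              object@ratsPerTimepoint, object@replicateNoiseCV, object@seed))
})

setMethod("show", "FlowTrace", function(object) {
  cat(sprintf("FlowTrace %s day %g (%s): %d samples over %.2f s, mean %.2f mL/min\n",
              object@ratId, object@day, object@vesselLabel,
              length(object@timeS), diff(range(object@timeS)),
              mean(object@flowMlMin)))
})

setMethod("show", "VesselGeometry", function(object) {
  cat(sprintf("VesselGeometry: R_i = %.4f cm, eta = %.3f dyn s/cm2\n",
              object@radiusCm, object@viscosity))
})

setMethod("show", "ShearStressEstimate", function(object) {
  cat(sprintf("ShearStressEstimate: tau = %.3f dyn/cm2 (Q = %.4f cm3/s, R = %.4f cm, eta = %.3f)\n",
              object@tau, object@meanFlowCm3S, object@radiusCm, object@viscosity))
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageStack [%s] %s day %g target '%s': %dx%d px, %d slices, %g um/px\n",
              object@channel, object@ratId, object@day, object@target,
              d[1], d[2], d[3], object@pixelSizeUm))
})

setMethod("show", "ROI", function(object) {
  cat(sprintf("ROI (%s, %s): %d px, %.5f mm2, centroid (%.1f, %.1f)\n",
              object@shape, object@compartment, length(object@pixels),
              object@areaMm2, object@centroid[1], object@centroid[2]))
})

#' Accessors for ShearStressEstimate
#' @param object a [ShearStressEstimate-class].
#' @return `tau()` the shear stress in dyn/cm^2.
#' @export
tau <- function(object) object@tau

#' @rdname tau
#' @return `roiArea()` the ROI area in mm^2.
#' @param roi an [ROI-class].
#' @export
roiArea <- function(roi) roi@areaMm2

#' @rdname tau
#' @return `roiCompartment()` the ROI compartment.
#' @export
roiCompartment <- function(roi) roi@compartment
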