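## Seeded generation of the study's flow traces, vessel geometries and
## phantom image arms, calibrated so that the downstream pipeline recovers
## the profile's true trends.

.validDays <- function(profile) sort(unique(c(profile@hemoDays, profile@timeGridDays)))

.checkDay <- function(profile, day) {
  vd <- .validDays(profile)
  if (!day %in% vd)
    stop(sprintf("unknown day %g; valid days are %s", day,
                 paste(vd, collapse = ", ")))
}

#' Generate a pulsatile flow trace for one rat and day
#'
#' The trace is a positive sinusoidal modulation (heart rate 5 Hz, relative
#' amplitude 0.3) around the profile's true mean flow for that day, scaled by
#' a lognormal replicate factor with CV `replicateNoiseCV` (unit mean).
#' Sampling covers 5 s at 100 Hz, a whole number of cycles, so the
#' trapezoidal time-average equals the scaled mean exactly.
#'
#' @param profile a [CalibrationProfile-class].
#' @param ratId rat identifier (integer or string).
#' @param day study day; must lie on the profile's day grid.
#' @return A [FlowTrace-class].
#' @export
#' @examples
#' prof <- calibrationProfile(seed = 1, replicateNoiseCV = 0)
#' tr <- genFlowTrace(prof, 1, -1)
#' meanFlow(tr) * 60   # 5.2 mL/min
genFlowTrace <- function(profile, ratId, day) {
  .checkDay(profile, day)
  mu <- .trueFlowMlMin(profile, day)
  fac <- withSeed(streamSeed(profile@seed, "flow", ratId, day),
                  .replicateFactor(1L, profile@replicateNoiseCV))
  t <- seq(0, 5, by = 0.01)
  flow <- mu * fac * (1 + 0.3 * sin(2 * pi * 5 * t))
  label <- if (day == profile@baselineDay) "carotid_proximal" else "fistula_vein"
  flowTrace(t, flow, vesselLabel = label, ratId = paste0("rat", ratId),
            day = day)
}

#' Generate the per-day vessel geometry series for one rat
#'
#' Radii are solved from the profile's target shear-stress trend by inverting
#' the Poiseuille relation, R = (4 eta Q / (pi tau))^(1/3), using the rat's
#' own generated mean flows, so that the forward shear computation reproduces
#' the trend exactly when replicate noise is zero.
#'
#' @param profile a [CalibrationProfile-class].
#' @param ratId rat identifier.
#' @param days days to cover (default the hemodynamic grid).
#' @return data.frame with columns `ratId`, `day`, `radiusCm`, `viscosity`,
#'   `meanFlowCm3S`, `tauTarget`.
#' @export
genGeometrySeries <- function(profile, ratId, days = profile@hemoDays) {
  rows <- lapply(days, function(d) {
    tt <- .trueWss(profile, d)
    if (tt <= 0) stop("target shear stress must be > 0")
    q <- meanFlow(genFlowTrace(profile, ratId, d))
    r <- (4 * profile@viscosity * q / (pi * tt))^(1 / 3)
    if (r < 0.01 || r > 0.5)
      warning(sprintf("solved radius %.4f cm outside the physiological range 0.01-0.5 cm", r))
    data.frame(ratId = paste0("rat", ratId), day = d, radiusCm = r,
               viscosity = profile@viscosity, meanFlowCm3S = q, tauTarget = tt)
  })
  do.call(rbind, rows)
}

#' Run the hemodynamic arm of the synthetic study
#'
#' Generates flow traces and matched geometries for all hemodynamic-arm rats
#' and days and summarizes the shear-stress time-course.
#'
#' @param profile a [CalibrationProfile-class].
#' @return list with `traces` (list of [FlowTrace-class]), `geometries`
#'   (data.frame) and `wss` (the [wssTimecourse()] table).
#' @export
runHemoArm <- function(profile) {
  rats <- seq_len(profile@nHemoRats)
  traces <- list()
  geoms <- list()
  for (r in rats) {
    for (d in profile@hemoDays)
      traces[[length(traces) + 1L]] <- genFlowTrace(profile, r, d)
    geoms[[r]] <- genGeometrySeries(profile, r)
  }
  geometries <- do.call(rbind, geoms)
  list(traces = traces, geometries = geometries,
       wss = wssTimecourse(traces, geometries))
}

## Generate one imaging-arm specimen and return stacks plus truth.
.genSpecimen <- function(profile, target, ratId, day, type = c("if", "pla")) {
  type <- match.arg(type)
  fac <- withSeed(streamSeed(profile@seed, type, target, ratId, day),
                  .replicateFactor(1L, profile@replicateNoiseCV))
  seed <- streamSeed(profile@seed, "img", type, target, ratId, day)
  if (type == "if") {
    eff <- .trueEffect(profile@markerTimecourses, target, day,
                       profile@baselineDay)
    genVesselImage(profile@ifPhantom,
                   markerLevel = profile@markerBaselineGray * (1 + eff / 100) * fac,
                   mediaMarkerLevel = profile@mediaBaselineGray * fac,
                   seed = seed, channels = c("marker", "control"),
                   imaging = profile@imaging,
                   ratId = paste0("rat", ratId), day = day, target = target)
  } else {
    eff <- .trueEffect(profile@interactionTimecourses, target, day,
                       profile@baselineDay)
    genVesselImage(profile@plaPhantom,
                   plaRateEndo = profile@plaBaselineDensity * (1 + eff / 100) * fac,
                   plaRateMedia = profile@mediaDensity * fac,
                   nonspecificRate = profile@nonspecificFraction *
                     profile@plaBaselineDensity,
                   seed = seed, mergeFraction = profile@mergeFraction,
                   poissonCounts = profile@poissonCounts,
                   channels = c("pla", "control"),
                   imaging = profile@imaging,
                   ratId = paste0("rat", ratId), day = day, target = target)
  }
}

#' Run one immunofluorescence arm: generate, quantify, summarize
#'
#' Generates marker and primary-antibody-control phantoms for every rat and
#' day, quantifies mean gray in the six protocol ROIs of the (projected)
#' images, applies the control correction, and returns the per-rat
#' measurement table.
#'
#' @param profile a [CalibrationProfile-class].
#' @param marker marker name (must be in the profile's time-courses).
#' @return data.frame of per-rat, per-compartment corrected FIU measurements
#'   (columns `ratId`, `day`, `marker`, `compartment`, `fiuRaw`,
#'   `fiuControl`, `fiuCorrected`, `negativeFlag`).
#' @export
runIFArm <- function(profile, marker) {
  if (!marker %in% names(profile@markerTimecourses))
    stop("unknown marker: ", marker)
  rois <- placeROIs(profile@ifPhantom,
                    bandDepthUm = profile@imaging$bandDepthUm)
  rows <- list()
  for (day in profile@timeGridDays) {
    for (r in seq_len(profile@ratsPerTimepoint)) {
      sp <- .genSpecimen(profile, marker, r, day, "if")
      rows[[length(rows) + 1L]] <-
        quantifyIF(sp$marker, sp$control, rois, marker = marker)
    }
  }
  do.call(rbind, rows)
}

#' Run one PLA arm: generate, quantify, summarize
#'
#' Generates PLA and negative-control phantom z-stacks for every rat and day,
#' counts events per ROI (threshold, size gate, merged-blob rule), subtracts
#' the control density, and returns the per-rat event table.
#'
#' @param profile a [CalibrationProfile-class].
#' @param pair receptor-ligand pair name (must be in the profile's
#'   time-courses).
#' @return data.frame: one row per ROI with raw, control and corrected
#'   densities (see [quantifyPLA()]).
#' @export
runPLAArm <- function(profile, pair) {
  if (!pair %in% names(profile@interactionTimecourses))
    stop("unknown pair: ", pair)
  rois <- placeROIs(profile@plaPhantom,
                    bandDepthUm = profile@imaging$bandDepthUm)
  rows <- list()
  for (day in profile@timeGridDays) {
    for (r in seq_len(profile@ratsPerTimepoint)) {
      sp <- .genSpecimen(profile, pair, r, day, "pla")
      rows[[length(rows) + 1L]] <-
        quantifyPLA(sp$pla, sp$control, rois, pair = pair)
    }
  }
  do.call(rbind, rows)
}

#' Write a complete synthetic study to disk
#'
#' Emits TIFF stacks, flow tables, a file manifest and the ground truth for
#' the configured markers and pairs. Fully reproducible from (profile, seed);
#' partially written output is removed on failure.
#'
#' @param profile a [CalibrationProfile-class].
#' @param outDir output directory (created; must not already contain a
#'   manifest).
#' @param markers marker names to emit (default: all in the profile).
#' @param pairs pair names to emit (default: none, as image volume is large;
#'   pass names explicitly).
#' @return Invisibly, the manifest data.frame.
#' @export
genStudy <- function(profile, outDir, markers = names(profile@markerTimecourses),
                     pairs = character(0)) {
  created <- !dir.exists(outDir)
  dir.create(file.path(outDir, "images"), recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok) {
    if (created) unlink(outDir, recursive = TRUE)
    else unlink(file.path(outDir, c("images", "manifest.csv", "flows.csv",
                                    "geometry.csv", "groundtruth.csv")),
                recursive = TRUE)
  })

  hemo <- runHemoArm(profile)
  flows <- do.call(rbind, lapply(hemo$traces, function(tr) {
    data.frame(ratId = tr@ratId, day = tr@day, vesselLabel = tr@vesselLabel,
               tS = tr@timeS, flowMlMin = tr@flowMlMin)
  }))
  write.csv(flows, file.path(outDir, "flows.csv"), row.names = FALSE)
  write.csv(hemo$geometries, file.path(outDir, "geometry.csv"),
            row.names = FALSE)

  man <- list(); gt <- list()
  emit <- function(stack, target, type, ratId, day, channel) {
    fn <- sprintf("%s_%s_rat%d_day%g_%s.tif", type, gsub("[^A-Za-z0-9]", "", target),
                  ratId, day, channel)
    writeImageStack(stack, file.path(outDir, "images", fn))
    data.frame(file = file.path("images", fn), target = target, type = type,
               ratId = paste0("rat", ratId), day = day, channel = channel,
               pixelSizeUm = stack@pixelSizeUm, zStepUm = stack@zStepUm,
               nSlices = dim(stack@data)[3])
  }
  for (m in markers) {
    for (day in profile@timeGridDays) {
      for (r in seq_len(profile@ratsPerTimepoint)) {
        sp <- .genSpecimen(profile, m, r, day, "if")
        man[[length(man) + 1L]] <- emit(sp$marker, m, "if", r, day, "marker")
        man[[length(man) + 1L]] <- emit(sp$control, m, "if", r, day, "negative_control")
        gt[[length(gt) + 1L]] <- data.frame(
          target = m, type = "if", ratId = paste0("rat", r), day = day,
          compartment = c("endothelium", "media"),
          trueLevel = unname(sp$truth$markerLevels), trueCount = NA_real_)
      }
    }
  }
  for (p in pairs) {
    for (day in profile@timeGridDays) {
      for (r in seq_len(profile@ratsPerTimepoint)) {
        sp <- .genSpecimen(profile, p, r, day, "pla")
        man[[length(man) + 1L]] <- emit(sp$pla, p, "pla", r, day, "pla")
        man[[length(man) + 1L]] <- emit(sp$control, p, "pla", r, day, "negative_control")
        gt[[length(gt) + 1L]] <- data.frame(
          target = p, type = "pla", ratId = paste0("rat", r), day = day,
          compartment = c("endothelium", "media"),
          trueLevel = unname(sp$truth$trueDensities),
          trueCount = unname(sp$truth$trueCounts))
      }
    }
  }
  manifest <- do.call(rbind, man)
  write.csv(manifest, file.path(outDir, "manifest.csv"), row.names = FALSE)
  if (length(gt))
    write.csv(do.call(rbind, gt), file.path(outDir, "groundtruth.csv"),
              row.names = FALSE)
  ok <- TRUE
  invisible(manifest)
}
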