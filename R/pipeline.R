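## Pipeline orchestration: config validation and the end-to-end study run
## (generate -> quantify WSS / FIU / PLA -> statistics -> report bundle).

.configSchema <- list(
  schema_version = "integer",
  seed = "integer",
  markers = "character",
  pairs = "character",
  calibration = list(
    replicate_noise_cv = "numeric",
    rats_per_timepoint = "integer",
    n_hemo_rats = "integer",
    poisson_counts = "logical",
    merge_fraction = "numeric",
    pla_baseline_density = "numeric",
    marker_baseline_gray = "numeric"
  ),
  pla = list(
    threshold = "numeric",
    min_size = "numeric",
    max_size = "numeric",
    median_size = "numeric"
  ),
  stats = list(
    alpha = "numeric",
    welch = "logical",
    holm = "logical"
  ),
  phantoms = list(
    `if` = "list",
    pla = "list"
  )
)

.defaultConfig <- function() {
  list(schema_version = 1L, seed = 1L,
       markers = c("caspase3", "Notch1"), pairs = c("Notch1-Delta1"),
       calibration = list(replicate_noise_cv = 0.05, rats_per_timepoint = 4L,
                          n_hemo_rats = 6L, poisson_counts = TRUE,
                          merge_fraction = 0.1, pla_baseline_density = 9700,
                          marker_baseline_gray = 90),
       pla = list(threshold = 100, min_size = 2, max_size = 50,
                  median_size = 10),
       stats = list(alpha = 0.05, welch = FALSE, holm = FALSE),
       phantoms = list())
}

.collectConfigErrors <- function(cfg) {
  errs <- character(0)
  checkNode <- function(node, schema, path) {
    unknown <- setdiff(names(node), names(schema))
    if (length(unknown))
      errs <<- c(errs, sprintf("unknown key(s) at %s: %s", path,
                               paste(unknown, collapse = ", ")))
    for (nm in intersect(names(node), names(schema))) {
      want <- schema[[nm]]
      val <- node[[nm]]
      p <- paste0(path, "$", nm)
      if (is.list(want)) {
        if (!is.list(val)) errs <<- c(errs, sprintf("%s must be a mapping", p))
        else checkNode(val, want, p)
      } else if (want == "integer") {
        if (!is.numeric(val) || any(val != round(val)))
          errs <<- c(errs, sprintf("%s must be integer-valued", p))
      } else if (want == "numeric") {
        if (!is.numeric(val)) errs <<- c(errs, sprintf("%s must be numeric", p))
      } else if (want == "logical") {
        if (!is.logical(val)) errs <<- c(errs, sprintf("%s must be true/false", p))
      } else if (want == "character") {
        if (!is.character(val) && !is.null(val))
          errs <<- c(errs, sprintf("%s must be a string list", p))
      }
    }
  }
  checkNode(cfg, .configSchema, "config")
  if (is.null(cfg$calibration))
    errs <- c(errs, "missing required section: calibration")
  if (is.null(cfg$seed)) errs <- c(errs, "missing required key: seed")
  pla <- cfg$pla
  if (!is.null(pla$threshold) && (pla$threshold < 0 || pla$threshold > 255))
    errs <- c(errs, "config$pla$threshold must lie in [0, 255]")
  if (!is.null(pla$min_size) && pla$min_size < 1)
    errs <- c(errs, "config$pla$min_size must be >= 1")
  if (!is.null(pla$max_size) && !is.null(pla$min_size) &&
      pla$max_size <= pla$min_size)
    errs <- c(errs, "config$pla$max_size must exceed min_size")
  if (!is.null(cfg$stats$alpha) &&
      (cfg$stats$alpha <= 0 || cfg$stats$alpha >= 1))
    errs <- c(errs, "config$stats$alpha must lie in (0, 1)")
  cal <- cfg$calibration
  if (!is.null(cal$replicate_noise_cv) && cal$replicate_noise_cv < 0)
    errs <- c(errs, "config$calibration$replicate_noise_cv must be >= 0")
  if (!is.null(cal$rats_per_timepoint) && cal$rats_per_timepoint < 1)
    errs <- c(errs, "config$calibration$rats_per_timepoint must be >= 1")
  errs
}

#' Validate a study configuration file
#'
#' Checks the YAML config against the versioned schema: unknown keys are
#' errors (no silent typo acceptance), required sections must exist, and
#' numeric fields must respect their bounds. On success returns the typed
#' config; on failure signals an error listing every violation.
#'
#' @param path YAML file path, or a config list.
#' @return A `StudyConfig` list (class "StudyConfig") merged over the
#'   defaults.
#' @export
validateStudyConfig <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  if (!is.null(cfg$markers)) cfg$markers <- as.character(unlist(cfg$markers))
  if (!is.null(cfg$pairs)) cfg$pairs <- as.character(unlist(cfg$pairs))
  errs <- .collectConfigErrors(cfg)
  if (length(errs))
    stop("invalid study config:\n", paste("-", errs, collapse = "\n"))
  merged <- modifyList(.defaultConfig(), cfg)
  structure(merged, class = "StudyConfig")
}

#' @export
print.StudyConfig <- function(x, ...) {
  cat("StudyConfig (schema", x$schema_version, ")\n")
  cat("  seed:", x$seed, "\n")
  cat("  markers:", paste(x$markers, collapse = ", "), "\n")
  cat("  pairs:", paste(x$pairs, collapse = ", "), "\n")
  cat(sprintf("  pla rules: threshold %g, size %g-%g px, median %g px\n",
              x$pla$threshold, x$pla$min_size, x$pla$max_size,
              x$pla$median_size))
  invisible(x)
}

#' Build the calibration profile encoded by a config
#'
#' @param config a validated `StudyConfig`.
#' @return A [CalibrationProfile-class].
#' @export
profileFromConfig <- function(config) {
  cal <- config$calibration
  extra <- list()
  if (!is.null(cal$merge_fraction)) extra$mergeFraction <- cal$merge_fraction
  if (!is.null(cal$pla_baseline_density))
    extra$plaBaselineDensity <- cal$pla_baseline_density
  if (!is.null(cal$marker_baseline_gray))
    extra$markerBaselineGray <- cal$marker_baseline_gray
  ph <- config$phantoms
  mkPh <- function(spec, default) {
    if (is.null(spec)) return(default)
    do.call(vesselPhantom, spec)
  }
  extra$ifPhantom <- mkPh(ph$`if`, .defaultIfPhantom())
  extra$plaPhantom <- mkPh(ph$pla, .defaultPlaPhantom())
  do.call(calibrationProfile, c(list(
    seed = config$seed,
    replicateNoiseCV = cal$replicate_noise_cv,
    ratsPerTimepoint = cal$rats_per_timepoint,
    nHemoRats = cal$n_hemo_rats,
    poissonCounts = cal$poisson_counts), extra))
}

#' Statistics stage on saved quantification outputs
#'
#' Computes the paper-style report from quantification tables: group
#' summaries with percent change vs baseline, baseline t-tests per day, and
#' the correlation set (flow and WSS vs time over days 0-42, each marker and
#' pair vs time and vs WSS over the full grid including baseline, and the
#' pooled interaction-vs-WSS correlation).
#'
#' @param fiuTable per-rat FIU table ([runIFArm()] rows), or NULL.
#' @param plaTable per-ROI PLA table ([runPLAArm()] rows), or NULL.
#' @param hemo hemodynamic arm output ([runHemoArm()]), or a `wss`
#'   time-course data.frame.
#' @param opts stats options list (`alpha`, `welch`, `holm`).
#' @param baselineDay baseline day (default -1).
#' @return list of data.frames: `wss`, `fiuSummary`, `plaSummary`, `tests`,
#'   `correlations`.
#' @export
runStatsStage <- function(fiuTable = NULL, plaTable = NULL, hemo = NULL,
                          opts = list(alpha = 0.05, welch = FALSE,
                                      holm = FALSE),
                          baselineDay = -1) {
  res <- list()
  wssTab <- if (is.data.frame(hemo)) hemo else hemo$wss
  res$wss <- wssTab
  tests <- list(); corrs <- list()

  if (!is.null(hemo) && !is.data.frame(hemo)) {
    perFlow <- do.call(rbind, lapply(hemo$traces, function(tr)
      data.frame(day = tr@day, flow = meanFlow(tr) * 60)))
    fl <- aggregate(flow ~ day, perFlow, mean)
    rising <- fl$day >= 0 & fl$day <= 42
    corrs[[length(corrs) + 1L]] <-
      pearsonCorr(fl$day[rising], fl$flow[rising], pair = "flow vs time (days 0-42)")
    wr <- wssTab$day >= 0 & wssTab$day <= 42
    corrs[[length(corrs) + 1L]] <-
      pearsonCorr(wssTab$day[wr], wssTab$meanTau[wr],
                  pair = "WSS vs time (days 0-42)")
  }

  baselineTests <- function(d, valueCol, keyCols, label) {
    perKey <- unique(d[, keyCols, drop = FALSE])
    out <- list()
    for (i in seq_len(nrow(perKey))) {
      sel <- rep(TRUE, nrow(d))
      for (k in keyCols) sel <- sel & d[[k]] == perKey[[k]][i]
      di <- d[sel, ]
      base <- di[[valueCol]][di$day == baselineDay]
      if (length(base) < 2) next
      for (dy in setdiff(sort(unique(di$day)), baselineDay)) {
        v <- di[[valueCol]][di$day == dy]
        if (length(v) < 2) next
        out[[length(out) + 1L]] <- ttestBaseline(
          v, base, welch = isTRUE(opts$welch),
          comparison = sprintf("%s %s day %g vs baseline", label,
                               paste(unlist(perKey[i, ]), collapse = "/"), dy))
      }
    }
    do.call(rbind, out)
  }

  if (!is.null(fiuTable)) {
    res$fiuSummary <- markerTimecourse(fiuTable, baselineDay)
    tests[[length(tests) + 1L]] <-
      baselineTests(fiuTable, "fiuCorrected", c("marker", "compartment"), "FIU")
    for (m in unique(res$fiuSummary$marker)) {
      mi <- res$fiuSummary[res$fiuSummary$marker == m &
                             res$fiuSummary$compartment == "endothelium", ]
      corrs[[length(corrs) + 1L]] <-
        pearsonCorr(mi$day, mi$mean, pair = paste(m, "vs time"))
      if (!is.null(wssTab)) {
        sh <- merge(mi[, c("day", "mean")], wssTab[, c("day", "meanTau")],
                    by = "day")
        corrs[[length(corrs) + 1L]] <-
          pearsonCorr(sh$meanTau, sh$mean, pair = paste(m, "vs WSS"))
      }
    }
  }

  if (!is.null(plaTable)) {
    res$plaSummary <- plaTimecourse(plaTable, baselineDay)
    perRat <- aggregate(correctedDensity ~ ratId + day + pair + compartment,
                        plaTable, mean)
    tests[[length(tests) + 1L]] <-
      baselineTests(perRat, "correctedDensity", c("pair", "compartment"),
                    "PLA")
    endo <- res$plaSummary[res$plaSummary$compartment == "endothelium", ]
    for (p in unique(endo$pair)) {
      pi <- endo[endo$pair == p, ]
      corrs[[length(corrs) + 1L]] <-
        pearsonCorr(pi$day, pi$mean, pair = paste(p, "vs time"))
      if (!is.null(wssTab)) {
        sh <- merge(pi[, c("day", "mean")], wssTab[, c("day", "meanTau")],
                    by = "day")
        corrs[[length(corrs) + 1L]] <-
          pearsonCorr(sh$meanTau, sh$mean, pair = paste(p, "vs WSS"))
      }
    }
    if (!is.null(wssTab) && length(unique(endo$pair)) > 1) {
      pooled <- aggregate(pctChange ~ day, endo, mean)
      sh <- merge(pooled, wssTab[, c("day", "meanTau")], by = "day")
      corrs[[length(corrs) + 1L]] <-
        pearsonCorr(sh$meanTau, sh$pctChange,
                    pair = "pooled interactions vs WSS")
    }
  }

  res$tests <- if (length(tests)) do.call(rbind, tests) else NULL
  if (!is.null(res$tests) && isTRUE(opts$holm))
    res$tests$pHolm <- stats::p.adjust(res$tests$pValue, "holm")
  res$correlations <- if (length(corrs)) do.call(rbind, corrs) else NULL
  res
}

#' Run the full study pipeline
#'
#' Validates the config, generates the synthetic study arms, quantifies WSS,
#' FIU and PLA, runs the statistics stage and writes the report bundle
#' (wss.csv, fiu.csv, pla.csv, summaries, tests, correlations, and a
#' machine-readable run manifest with seed, config hash and package
#' version). Any stage failure aborts with the stage name and marks the
#' output directory invalid.
#'
#' @param config a YAML path or a validated `StudyConfig`.
#' @param outDir output directory for the report bundle.
#' @return Invisibly, the list of result tables from [runStatsStage()].
#' @export
runStudy <- function(config, outDir) {
  if (!inherits(config, "StudyConfig")) config <- validateStudyConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  invalidFlag <- file.path(outDir, "INVALID")
  file.create(invalidFlag)
  logFile <- file.path(outDir, "run.log")
  logLine <- function(...) {
    msg <- sprintf(...)
    message(msg)
    cat(msg, "\n", file = logFile, append = TRUE, sep = "")
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s (partial outputs marked invalid)",
                   name, conditionMessage(e)), call. = FALSE))
    logLine("stage %-10s done in %6.1f s", name, proc.time()[3] - t0)
    out
  }
  unlink(logFile)
  profile <- stage("config", profileFromConfig(config))

  hemo <- stage("wss", runHemoArm(profile))
  write.csv(hemo$wss, file.path(outDir, "wss.csv"), row.names = FALSE)

  fiu <- stage("ifquant", {
    if (length(config$markers)) {
      tab <- do.call(rbind, lapply(config$markers,
                                   function(m) runIFArm(profile, m)))
      write.csv(tab, file.path(outDir, "fiu.csv"), row.names = FALSE)
      logLine("ifquant: %d measurements (%d markers)", nrow(tab),
              length(config$markers))
      tab
    } else NULL
  })

  pla <- stage("pla", {
    if (length(config$pairs)) {
      tab <- do.call(rbind, lapply(config$pairs,
                                   function(p) runPLAArm(profile, p)))
      write.csv(tab, file.path(outDir, "pla.csv"), row.names = FALSE)
      logLine("pla: %d ROI rows (%d pairs)", nrow(tab), length(config$pairs))
      tab
    } else NULL
  })

  stats <- stage("stats", runStatsStage(fiu, pla, hemo, opts = config$stats,
                                        baselineDay = -1))
  if (!is.null(stats$fiuSummary))
    write.csv(stats$fiuSummary, file.path(outDir, "fiu_summary.csv"),
              row.names = FALSE)
  if (!is.null(stats$plaSummary))
    write.csv(stats$plaSummary, file.path(outDir, "pla_summary.csv"),
              row.names = FALSE)
  if (!is.null(stats$tests))
    write.csv(stats$tests, file.path(outDir, "tests.csv"), row.names = FALSE)
  if (!is.null(stats$correlations))
    write.csv(stats$correlations, file.path(outDir, "correlations.csv"),
              row.names = FALSE)

  manifest <- list(
    seed = config$seed,
    configHash = .hashString(paste(deparse(unclass(config)), collapse = "")),
    package = "avfquant",
    version = as.character(packageVersion("avfquant")))
  jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  unlink(invalidFlag)
  logLine("run complete: %s", outDir)
  invisible(stats)
}
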