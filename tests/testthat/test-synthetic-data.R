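# Synthetic-data generator: flow traces, geometry inversion, phantom images
# and the on-disk study writer.

test_that("flow traces reproduce the calibrated means and are deterministic", {
  prof0 <- calibrationProfile(seed = 3, replicateNoiseCV = 0)
  # pre-AVF carotid mean 5.2 mL/min; day 0 is 2.4x (the +140% step)
  expect_equal(meanFlow(genFlowTrace(prof0, 1, -1)) * 60, 5.2, tolerance = 1e-10)
  expect_equal(meanFlow(genFlowTrace(prof0, 1, 0)) * 60, 5.2 * 2.4,
               tolerance = 1e-10)
  # day-42 plateau: 11x the day-0 fistula flow, held to day 84
  expect_equal(meanFlow(genFlowTrace(prof0, 1, 42)) * 60, 12.48 * 11,
               tolerance = 1e-10)
  expect_equal(meanFlow(genFlowTrace(prof0, 1, 84)) * 60, 12.48 * 11,
               tolerance = 1e-10)
  # pulsatile and never negative
  tr <- genFlowTrace(prof0, 1, 7)
  expect_gt(sd(tr@flowMlMin), 0)
  expect_true(all(tr@flowMlMin >= 0))
  # determinism under a fixed seed; independence across rats with noise
  prof <- calibrationProfile(seed = 3)
  expect_identical(genFlowTrace(prof, 2, 7)@flowMlMin,
                   genFlowTrace(prof, 2, 7)@flowMlMin)
  expect_false(identical(genFlowTrace(prof, 1, 7)@flowMlMin,
                         genFlowTrace(prof, 2, 7)@flowMlMin))
  expect_error(genFlowTrace(prof, 1, 5), "valid days")
})

test_that("geometry series inverts the Poiseuille relation", {
  prof0 <- calibrationProfile(seed = 1, replicateNoiseCV = 0)
  g <- genGeometrySeries(prof0, 1, days = 0)
  # oracle: R = (4 eta Q / (pi tau))^(1/3) at Q = 12.48 mL/min, tau = 3.5
  oracleR <- (4 * 0.04 * (12.48 / 60) / (pi * 3.5))^(1 / 3)
  expect_equal(g$radiusCm, oracleR, tolerance = 1e-12)
  expect_equal(oracleR, 0.14465, tolerance = 1e-4)
  # doubling the shear target shrinks R by 2^(1/3)
  prof2 <- calibrationProfile(seed = 1, replicateNoiseCV = 0, wssDay0 = 7)
  g2 <- genGeometrySeries(prof2, 1, days = 0)
  expect_equal(g$radiusCm / g2$radiusCm, 2^(1 / 3), tolerance = 1e-10)
  # forward substitution recovers every target to 1e-9 relative
  gAll <- genGeometrySeries(prof0, 1)
  tauBack <- vapply(seq_len(nrow(gAll)), function(i)
    tau(poiseuilleWSS(gAll$meanFlowCm3S[i],
                      vesselGeometry(gAll$radiusCm[i], gAll$viscosity[i]))), 0)
  expect_equal(tauBack, gAll$tauTarget, tolerance = 1e-9)
})

test_that("phantom images honour rates, spot sizes and marker linearity", {
  ph <- vesselPhantom(80, 12, 40, imageShape = c(288L, 288L))
  # empty field: no pixel reaches the threshold after projection
  img0 <- genVesselImage(ph, plaRateEndo = 0, plaRateMedia = 0,
                         nonspecificRate = 0, seed = 2,
                         channels = c("pla", "control"))
  expect_lt(max(maxProject(img0$pla)), 100)
  expect_lt(max(maxProject(img0$control)), 100)

  # seeded isolated spots are recovered exactly by the counting chain
  img <- genVesselImage(ph, plaRateEndo = 3000, plaRateMedia = 400,
                        nonspecificRate = 0, seed = 7, mergeFraction = 0,
                        poissonCounts = FALSE, channels = c("pla", "control"),
                        imaging = list(bgNoiseSd = 0))
  rois <- placeROIs(ph)
  q <- quantifyPLA(img$pla, img$control, rois)
  expect_identical(sum(q$events[q$compartment == "endothelium"]),
                   as.numeric(img$truth$trueCounts["endothelium"]))
  expect_identical(sum(q$events[q$compartment == "media"]),
                   as.numeric(img$truth$trueCounts["media"]))

  # median seeded spot area is 10 px over >= 1000 spots
  areas <- unlist(lapply(1:20, function(s) {
    gi <- genVesselImage(ph, plaRateEndo = 8000, plaRateMedia = 2000,
                         seed = s, mergeFraction = 0, channels = "pla")
    gi$truth$spots$area
  }))
  expect_gte(length(areas), 1000)
  expect_lte(abs(median(areas) - 10), 1)

  # marker linearity: doubling the level doubles the background-corrected
  # ring mean (noise-free)
  mk <- function(level) {
    gi <- genVesselImage(ph, markerLevel = level, seed = 3,
                         channels = c("marker", "control"),
                         imaging = list(readNoiseSd = 0))
    r <- placeROIs(ph)[[1]]
    meanGray(gi$marker, r) - meanGray(gi$control, r)
  }
  expect_equal(mk(80) / mk(40), 2, tolerance = 1e-12)
})

test_that("spot-count ground truth holds across many random phantoms", {
  ph <- vesselPhantom(40, 8, 22, imageShape = c(148L, 148L), nZSlices = 3L,
                      zStepUm = 4, zVolumeUm = 12)
  rois <- placeROIs(ph)
  for (s in 1:100) {
    rate <- 800 + (s %% 7) * 500
    gi <- genVesselImage(ph, plaRateEndo = rate, plaRateMedia = rate / 6,
                         nonspecificRate = 0, seed = 1000 + s,
                         mergeFraction = 0, channels = c("pla", "control"),
                         imaging = list(bgNoiseSd = 0))
    q <- quantifyPLA(gi$pla, gi$control, rois)
    cnt <- tapply(q$events, q$compartment, sum)
    expect_identical(as.numeric(cnt["endothelium"]),
                     as.numeric(gi$truth$trueCounts["endothelium"]))
    expect_identical(as.numeric(cnt["media"]),
                     as.numeric(gi$truth$trueCounts["media"]))
  }
})

test_that("excessive spot rates fail with a helpful error", {
  ph <- vesselPhantom(40, 8, 22, imageShape = c(148L, 148L))
  expect_error(
    genVesselImage(ph, plaRateEndo = 2e5, seed = 1, channels = "pla",
                   poissonCounts = FALSE),
    "rate too high")
})

test_that("the on-disk study is complete and byte-reproducible", {
  prof <- testProfile(seed = 9,
                      markerTimecourses = list(
                        caspase3 = setNames(c(10, 15, 20, 25, 30, 35, 34),
                                            c("1","3","7","14","21","42","84"))),
                      ratsPerTimepoint = 2L, nHemoRats = 2L)
  d1 <- file.path(tempdir(), "study1"); d2 <- file.path(tempdir(), "study2")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- genStudy(prof, d1, markers = "caspase3")
  m2 <- genStudy(prof, d2, markers = "caspase3")
  # 8 days x 2 rats, marker + control per specimen
  expect_equal(nrow(m1), 8 * 2 * 2)
  expect_true(all(file.exists(file.path(d1, m1$file))))
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  # image payloads identical across runs
  f <- m1$file[1]
  expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                   readBin(file.path(d2, f), "raw", 1e6))
  # quantification from disk matches in-memory quantification
  qd <- quantifyStudyDir(d1, prof)
  qm <- runIFArm(prof, "caspase3")
  expect_equal(sort(qd$fiu$fiuCorrected), sort(qm$fiuCorrected),
               tolerance = 1e-12)
  unlink(c(d1, d2), recursive = TRUE)
})
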