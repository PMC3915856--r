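# PLA event calling: projection, ROI placement, particle detection, the
# counting rules, and background correction.

mkROIcover <- function(dim) {
  new("ROI", shape = "polygon", compartment = "endothelium",
      pixels = seq_len(prod(dim)), dim = as.integer(dim),
      areaMm2 = prod(dim) * (2 / 1000)^2, centroid = dim / 2, params = list())
}

test_that("maxProject is the pixelwise maximum", {
  sl <- matrix(7, 16, 16)
  st <- imageStack(array(sl, c(16, 16, 4)))
  expect_equal(maxProject(st), sl)
  arr <- array(0, c(16, 16, 6))
  arr[5, 9, 3] <- 200
  expect_equal(maxProject(imageStack(arr))[5, 9], 200)
  # brute-force elementwise oracle on a random 6-slice stack
  set.seed(1)
  arr2 <- array(sample(0:255, 16 * 16 * 6, TRUE), c(16, 16, 6))
  ref <- matrix(0, 16, 16)
  for (r in 1:16) for (cc in 1:16) ref[r, cc] <- max(arr2[r, cc, ])
  expect_equal(maxProject(imageStack(arr2)), ref)
  expect_error(maxProject(list(matrix(0, 4, 4), matrix(0, 5, 5))),
               "mismatched")
})

test_that("placeROIs yields the protocol geometry", {
  ph <- vesselPhantom(80, 12, 40, pixelSizeUm = 2, imageShape = c(288L, 288L))
  rois <- placeROIs(ph)
  expect_length(rois, 6L)
  expect_equal(vapply(rois, roiCompartment, ""),
               rep(c("endothelium", "media"), each = 3))
  # band depth: round(5 um / 2 um per px) = 2 px
  expect_equal(rois[[1]]@params$depthPx, 2)
  # 120-degree spacing of the media circle centroids
  ctr <- phantomSegmentation(ph)$center
  angs <- sort(vapply(rois[4:6], function(r)
    atan2(r@centroid[1] - ctr[1], r@centroid[2] - ctr[2]), 0))
  expect_equal(diff(angs), rep(2 * pi / 3, 2), tolerance = 0.02)
  # pixel-counted areas match the closed-form annulus sector / circle within 2%
  sector <- (2 * pi / 3) / 2 * ((80 + 2)^2 - 80^2) * (2 / 1000)^2
  expect_lt(abs(roiArea(rois[[1]]) - sector) / sector, 0.02)
  circ <- pi * rois[[4]]@params$radiusPx^2 * (2 / 1000)^2
  expect_lt(abs(roiArea(rois[[4]]) - circ) / circ, 0.02)
  # rotation equivariance: rotating the layout rotates the centroids
  rois90 <- placeROIs(ph, angleOffset = pi / 2)
  a0 <- atan2(rois[[4]]@centroid[1] - ctr[1], rois[[4]]@centroid[2] - ctr[2])
  a90 <- atan2(rois90[[4]]@centroid[1] - ctr[1], rois90[[4]]@centroid[2] - ctr[2])
  expect_equal((a90 - a0) %% (2 * pi), pi / 2, tolerance = 0.02)
  # infeasible media circle area reports the maximum feasible area
  expect_error(placeROIs(ph, mediaCircleAreaMm2 = 0.05), "maximum feasible")
})

test_that("detectParticles applies threshold, connectivity and the 2-px floor", {
  img <- matrix(0, 64, 64)
  roi <- mkROIcover(c(64, 64))
  expect_equal(nrow(detectParticles(img, roi)), 0L)
  img[10:12, 20:22] <- 255
  p <- detectParticles(img, roi)
  expect_equal(nrow(p), 1L)
  expect_equal(p$area, 9)
  expect_equal(p$peak, 255)
  # 1-px specks are discarded; 2-px particles survive
  img2 <- matrix(0, 64, 64)
  img2[5, 5] <- 200
  img2[30, 30:31] <- 200
  expect_equal(detectParticles(img2, roi)$area, 2)
  # sub-threshold pixels are not particles
  img3 <- matrix(0, 64, 64); img3[8:9, 8:9] <- 99
  expect_equal(nrow(detectParticles(img3, roi)), 0L)
  # diagonal chain: one particle at 8-connectivity, pieces at 4
  img4 <- matrix(0, 64, 64)
  for (k in 0:3) img4[20 + k, 20 + k] <- 180
  img4[20, 21] <- 180  # make each diagonal step 2-px wide for the area floor
  expect_equal(nrow(detectParticles(img4, roi, connectivity = 8)), 1L)
  expect_gt(nrow(detectParticles(img4, roi, connectivity = 4, minArea = 1)), 1L)
})

test_that("detection + counting equals the brute-force oracle on random crops", {
  set.seed(99)
  roi <- mkROIcover(c(48, 48))
  for (i in 1:500) {
    img <- matrix(0, 48, 48)
    n <- sample(0:8, 1)
    for (k in seq_len(n)) {
      r <- sample(3:46, 1); cc <- sample(3:46, 1)
      w <- sample(1:6, 1); h <- sample(1:6, 1)
      img[r:min(48, r + h - 1), cc:min(48, cc + w - 1)] <-
        sample(100:255, 1)
    }
    if (runif(1) < 0.3) img <- img + matrix(sample(0:60, 48^2, TRUE), 48)
    img <- pmin(img, 255)
    mine <- countEvents(detectParticles(img, roi))
    expect_identical(mine, oracleCountEvents(img))
  }
})

test_that("countEvents applies the size gate and the area/10 merge rule", {
  expect_equal(countEvents(data.frame(area = c(10, 10, 10))), 3)
  blob <- data.frame(area = 500)
  expect_equal(countEvents(blob), 50)
  expect_equal(500 / countEvents(blob), 10)
  # boundary areas: 2 and 50 are singles; 51 -> 5.1 -> 5
  expect_equal(countEvents(data.frame(area = c(2, 50, 51))), 7)
  # ties round up: 55 -> 5.5 -> 6
  expect_equal(countEvents(data.frame(area = 55)), 6)
  expect_equal(countEvents(data.frame(area = 55), fractional = TRUE), 5.5)
  expect_equal(countEvents(data.frame(area = numeric(0))), 0)
})

test_that("event counts are monotone in spots and threshold", {
  set.seed(3)
  roi <- mkROIcover(c(64, 64))
  img <- matrix(0, 64, 64)
  img[10:11, 10:11] <- 150
  img[40:41, 40:41] <- 150
  base <- countEvents(detectParticles(img, roi))
  img2 <- img; img2[25:26, 25:26] <- 220   # add a disjoint spot
  expect_gte(countEvents(detectParticles(img2, roi)), base)
  # raising the threshold never increases the particle count
  for (th in c(100, 140, 160, 200, 230)) {
    expect_gte(nrow(detectParticles(img2, roi, threshold = 100)),
               nrow(detectParticles(img2, roi, threshold = th)))
  }
})

test_that("translation invariance of the full ROI counting chain", {
  ph <- vesselPhantom(40, 8, 22, imageShape = c(180L, 180L), nZSlices = 1L,
                      zStepUm = 12, zVolumeUm = 12)
  gi <- genVesselImage(ph, plaRateEndo = 3000, plaRateMedia = 600, seed = 11,
                       channels = "pla", imaging = list(bgNoiseSd = 0))
  img <- maxProject(gi$pla)
  shift <- c(7L, -5L)
  imgS <- matrix(0, 180, 180)
  imgS[(1 + max(shift[1], 0)):(180 + min(shift[1], 0)),
       (1 + max(shift[2], 0)):(180 + min(shift[2], 0))] <-
    img[(1 - min(shift[1], 0)):(180 - max(shift[1], 0)),
        (1 - min(shift[2], 0)):(180 - max(shift[2], 0))]
  seg <- phantomSegmentation(ph)
  segS <- seg; segS$center <- seg$center + shift
  rois <- placeROIs(seg); roisS <- placeROIs(segS)
  ev <- vapply(rois, function(r) countEvents(detectParticles(img, r)), 0)
  evS <- vapply(roisS, function(r) countEvents(detectParticles(imgS, r)), 0)
  expect_identical(ev, evS)
})

test_that("backgroundCorrect subtracts and flags negatives", {
  expect_equal(as.numeric(backgroundCorrect(120, 20)), 100)
  expect_equal(as.numeric(backgroundCorrect(55, 55)), 0)
  expect_true(attr(backgroundCorrect(10, 20), "negative"))
  expect_error(backgroundCorrect(10, NA), "missing")
})

test_that("density is preserved under ROI subdivision of a homogeneous field", {
  # halving the ROI (one 120-degree band vs the union of all three) leaves
  # the expected density unchanged within Poisson error
  ph <- vesselPhantom(90, 14, 40, imageShape = c(320L, 320L))
  dens <- sapply(1:12, function(s) {
    gi <- genVesselImage(ph, plaRateEndo = 5000, seed = 300 + s,
                         channels = "pla", imaging = list(bgNoiseSd = 0))
    img <- maxProject(gi$pla)
    rois <- placeROIs(ph)
    perROI <- vapply(rois[1:3], function(r)
      countEvents(detectParticles(img, r)) / roiArea(r), 0)
    c(one = perROI[1], all = mean(perROI))
  })
  expect_lt(abs(mean(dens["one", ]) - mean(dens["all", ])) /
              mean(dens["all", ]), 0.15)
})

test_that("pla time-course recovers effects and separates compartments", {
  tc7 <- setNames(c(5, 10, 14, 18, 21, 23, 23), c("1","3","7","14","21","42","84"))
  prof0 <- testProfile(seed = 8, replicateNoiseCV = 0, poissonCounts = FALSE,
                       ratsPerTimepoint = 2L, mergeFraction = 0,
                       nonspecificFraction = 0,
                       interactionTimecourses = list(p = tc7),
                       plaBaselineDensity = 6000)
  tc <- plaTimecourse(runPLAArm(prof0, "p"))
  endo <- tc[tc$compartment == "endothelium", ]
  # recovery up to the count granularity of the small phantom (~27 events
  # per specimen band, i.e. ~3.7% steps)
  expect_lt(max(abs(endo$pctChange[match(as.numeric(names(tc7)), endo$day)] -
                      unname(tc7))), 3)
  med <- tc[tc$compartment == "media", ]
  expect_lt(max(abs(med$pctChange)), 10)
  expect_error(plaTimecourse(data.frame(ratId = "r", day = 1, pair = "p",
                                        compartment = "media",
                                        correctedDensity = 1)),
               "baseline")
})
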