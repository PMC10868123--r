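# Segmentation: background correction, thresholding/labeling, the size
# gate, and occupancy metrics.

test_that("rolling-ball correction removes flat and ramped backgrounds but keeps objects", {
  cfg <- analysisConfig(rollingBallRadiusPx = 10)
  # pure background
  expect_equal(preprocessFrame(matrix(7, 60, 60), cfg), matrix(0, 60, 60))
  # bright disk on flat background: disk preserved within 5% of peak
  f <- matrix(5, 60, 60)
  disk <- diskMask(60, c(30, 30), 4)
  f[disk] <- 205
  p <- preprocessFrame(f, cfg)
  expect_lt(abs(max(p) - 200) / 200, 0.05)
  expect_equal(max(p[!disk]), 0)
  # linear ramp with radius much larger than any object: >= 90% removed
  ramp <- matrix(rep(seq(0, 50, length.out = 60), each = 60), 60, 60)
  pr <- preprocessFrame(ramp, cfg)
  interior <- pr[, 11:50]   # away from the edge-replicated border
  expect_lt(diff(range(interior)), 0.1 * diff(range(ramp)))
  # idempotence on flat background
  expect_equal(preprocessFrame(p, cfg), p, tolerance = 1e-12)
  # radius as large as the image is refused
  expect_error(preprocessFrame(matrix(0, 20, 20), analysisConfig(rollingBallRadiusPx = 10L)),
               "too large")
})

test_that("thresholding labels objects with 8-connectivity and accurate centroids", {
  cfg <- analysisConfig()
  # blank frame -> no objects, not an error
  seg0 <- thresholdAndLabel(matrix(0, 32, 32), cfg, pixelSizeUm = 0.1)
  expect_equal(nrow(seg0$objects), 0L)
  # three disks -> three objects with centroids within 1 px of truth
  f <- matrix(0, 64, 64)
  ctrs <- list(c(12, 14), c(40, 22), c(25, 50))  # 0-based (row, col)
  for (ct in ctrs) f[diskMask(64, ct, 3)] <- 100
  seg <- thresholdAndLabel(f, cfg, pixelSizeUm = 0.1)
  expect_equal(nrow(seg$objects), 3L)
  got <- seg$objects[order(seg$objects$row0), ]
  want <- do.call(rbind, ctrs)[order(sapply(ctrs, `[`, 1)), ]
  expect_true(all(abs(got$row0 - want[, 1]) <= 1))
  expect_true(all(abs(got$col0 - want[, 2]) <= 1))
  # two objects touching diagonally merge into one (8-connectivity)
  f2 <- matrix(0, 16, 16)
  f2[4:6, 4:6] <- 100
  f2[7:9, 7:9] <- 100
  seg2 <- thresholdAndLabel(f2, cfg, pixelSizeUm = 0.1)
  expect_equal(nrow(seg2$objects), 1L)
  # heavily overlapping disks merge into one object
  f3 <- matrix(0, 32, 32)
  f3[diskMask(32, c(15, 14), 4) | diskMask(32, c(15, 17), 4)] <- 100
  expect_equal(nrow(thresholdAndLabel(f3, cfg, pixelSizeUm = 0.1)$objects), 1L)
})

test_that("size gate is a closed interval, order-preserving and idempotent", {
  obj <- data.frame(object_id = 1:5,
                    equiv_diameter_um = c(0.05, 0.1, 1.3, 2.0, 2.5))
  got <- filterBySize(obj, 0.1, 2.0)
  expect_equal(got$object_id, 2:4)      # 0.05 and 2.5 removed
  expect_true(2.0 %in% got$equiv_diameter_um)   # boundary retained
  expect_true(0.1 %in% got$equiv_diameter_um)
  expect_identical(filterBySize(got, 0.1, 2.0), got)   # idempotent
  expect_equal(nrow(filterBySize(obj[0, ], 0.1, 2.0)), 0L)
})

test_that("area fraction is exact arithmetic on binaries", {
  lab <- matrix(0L, 100, 100)
  lab[1:10, 1:10] <- 1L
  cm <- matrix(TRUE, 100, 100)
  expect_equal(areaFraction(lab, cm), 1.0)
  expect_equal(areaFraction(matrix(0L, 100, 100), cm), 0.0)
  expect_equal(areaFraction(matrix(1L, 100, 100), cm), 100.0)
  expect_error(areaFraction(lab, matrix(FALSE, 100, 100)), "empty cell mask")
  # invariant to intensity rescaling: the gated binary alone decides
  f <- matrix(0, 40, 40); f[10:14, 10:14] <- 80
  cfg <- analysisConfig(rollingBallRadiusPx = 8)
  segA <- thresholdAndLabel(preprocessFrame(f, cfg), cfg, pixelSizeUm = 0.1)
  segB <- thresholdAndLabel(preprocessFrame(f * 7.3, cfg), cfg, pixelSizeUm = 0.1)
  cm40 <- matrix(TRUE, 40, 40)
  expect_equal(areaFraction(segA$labels, cm40), areaFraction(segB$labels, cm40))
})

test_that("mean object size is the arithmetic mean with a histogram companion", {
  obj <- data.frame(equiv_diameter_um = c(0.5, 1.5))
  res <- meanObjectSize(obj)
  expect_equal(res$mean_um, 1.0)
  expect_equal(sum(res$histogram$count), 2L)
  expect_equal(meanObjectSize(data.frame(equiv_diameter_um = rep(0.7, 5)))$mean_um, 0.7)
  expect_error(meanObjectSize(obj[0, , drop = FALSE]), "undefined")
})

test_that("detection recovers simulated vesicle sizes within rendering bias", {
  cfg <- simulationConfig(nParticles = 12, nFrames = 3, seed = 5,
                          pOn = 0, burnInFrames = 0, perinuclearBias = 0)
  sim <- simulateCell(cfg)
  det <- detectObjects(sim$movie, "lysosome", simulationAnalysisConfig())
  d <- do.call(rbind, det$objectsByFrame)$equiv_diameter_um
  # PSF-broadened spot binaries: diameters land in the gate and are
  # consistent across frames (rendering bias bound, not truth equality)
  expect_true(all(d >= 0.1 & d <= 2))
  expect_lt(sd(d) / mean(d), 0.5)
  expect_equal(mean(vapply(det$objectsByFrame, nrow, integer(1))), 12,
               tolerance = 0.05)
})
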