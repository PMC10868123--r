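# Tracking: optimal-assignment linking, motility metrics, kymographs.

test_that("an unambiguous mover yields a single full-length track", {
  pts <- lapply(0:10, function(t) cbind(1 + 0.2 * t, 3))
  tracks <- linkTracks(objectsFromPoints(pts), analysisConfig())
  expect_equal(length(unique(tracks$track_id)), 1L)
  expect_equal(tracks$frame, 0:10)
  expect_false(any(tracks$shared))
})

test_that("crossing particles keep their identities (optimal assignment)", {
  # two particles on converging-then-diverging x-paths, step 0.2 um/frame,
  # never closer than 1 um in y: optimal matching never swaps
  pts <- lapply(0:20, function(t)
    rbind(c(1 + 0.2 * t, 2), c(5 - 0.2 * t, 3.2)))
  tracks <- linkTracks(objectsFromPoints(pts), analysisConfig())
  expect_equal(length(unique(tracks$track_id)), 2L)
  t1 <- tracks[tracks$track_id == 1, ]
  # brute-force oracle: particle 1's true x-path
  expect_equal(t1$x_um, 1 + 0.2 * (0:20))
  expect_equal(t1$y_um, rep(2, 21))
})

test_that("a one-frame disappearance splits a track (no gap closing)", {
  pts <- lapply(0:10, function(t)
    if (t == 5) matrix(numeric(0), 0, 2) else cbind(1 + 0.1 * t, 2))
  tracks <- linkTracks(objectsFromPoints(pts), analysisConfig())
  expect_equal(length(unique(tracks$track_id)), 2L)
})

test_that("merge handling carries both identities through a shared object", {
  # two particles approach, occupy one object for three frames, separate
  pts <- list(rbind(c(1, 2), c(2, 2)), rbind(c(1.4, 2), c(1.8, 2)),
              cbind(1.6, 2), cbind(1.6, 2), cbind(1.6, 2),
              rbind(c(1.3, 2), c(1.9, 2)), rbind(c(1.0, 2), c(2.2, 2)))
  areas <- list(c(9L, 9L), c(9L, 9L), 18L, 18L, 18L, c(9L, 9L), c(9L, 9L))
  tracks <- linkTracks(objectsFromPoints(pts, areasByFrame = areas),
                       analysisConfig())
  expect_equal(length(unique(tracks$track_id)), 2L)
  merged <- tracks[tracks$frame %in% 2:4, ]
  expect_equal(nrow(merged), 6L)           # both tracks present while merged
  expect_true(any(merged$shared))
  expect_equal(as.integer(table(tracks$track_id)), c(7L, 7L))
})

test_that("motility metrics follow the 60 s window arithmetic", {
  cfg <- analysisConfig()
  # straight mover at 0.25 um per 2 s frame over 91 frames
  pts <- lapply(0:90, function(t) cbind(1 + 0.25 * t, 5))
  tracks <- linkTracks(objectsFromPoints(pts), cfg)
  mot <- motilityMetrics(tracks, cfg, dtS = 2)
  expect_equal(mot$distance_60s_um, 7.5)
  expect_equal(mot$mean_speed_um_s, 0.125)
  # static particle: zero distance and speed
  ptsS <- lapply(0:90, function(t) cbind(2, 2))
  motS <- motilityMetrics(linkTracks(ptsS |> objectsFromPoints(), cfg), cfg, dtS = 2)
  expect_equal(motS$distance_60s_um, 0)
  expect_equal(motS$mean_speed_um_s, 0)
  # eligibility is duration >= 60 s exactly: 31 frames qualify, 30 do not
  pts30 <- lapply(0:29, function(t) cbind(1 + 0.1 * t, 1))
  expect_warning(m30 <- motilityMetrics(linkTracks(objectsFromPoints(pts30), cfg), cfg, dtS = 2),
                 "window")
  expect_equal(nrow(m30), 0L)
  pts31 <- lapply(0:30, function(t) cbind(1 + 0.1 * t, 1))
  expect_equal(nrow(motilityMetrics(linkTracks(objectsFromPoints(pts31), cfg), cfg, dtS = 2)), 1L)
})

test_that("doubling dt halves mean speed for the same pixel trajectory", {
  cfg <- analysisConfig()
  pts <- lapply(0:60, function(t) cbind(1 + 0.2 * t, 1))
  tracks <- linkTracks(objectsFromPoints(pts), cfg)
  m2 <- motilityMetrics(tracks, cfg, dtS = 2)
  m4 <- motilityMetrics(tracks, cfg, dtS = 4)
  expect_equal(m4$mean_speed_um_s, m2$mean_speed_um_s / 2)
})

test_that("path length dominates displacement on random walks", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      pts <- list(cbind(5, 5))
      for (t in 2:30)
        pts[[t]] <- pts[[t - 1]] + matrix(rnorm(2, 0, 0.15), 1, 2)
      s <- trackSummaries(linkTracks(objectsFromPoints(pts), analysisConfig()), 2)
      expect_gte(s$path_length_um, s$displacement_um)
    }
  })
})

test_that("kymographs turn motion into stripe slopes", {
  cfg <- simulationConfig(nParticles = 1, nFrames = 10, seed = 1,
                          cellRadiusUm = 3, nucleusRadiusUm = 0.5,
                          bgPhotons = 0, readNoise = 0)
  side <- 2 * ceiling((3 + 0.8) / 0.1 / 2) * 1  # rendered side (px)
  ctr <- 3.8
  # static spot: vertical stripe
  posS <- lapply(1:10, function(t) matrix(c(ctr, ctr), 1, 2))
  pixS <- vapply(posS, function(p) renderFrame(p, 0.06, 500, cfg, noise = FALSE),
                 matrix(0, 76, 76))
  movS <- MovieStack(array(pixS, c(76, 76, 10, 1)), 0.1, 2)
  line <- cbind(ctr / 0.1, seq(10, 65))  # horizontal polyline at the spot row
  kS <- kymograph(movS, rbind(line[1, ], line[nrow(line), ]), widthPx = 3)
  peaks <- apply(kS, 1, which.max)
  expect_true(all(peaks == peaks[1]))
  # constant-velocity spot along the line: linear peak drift
  posM <- lapply(1:10, function(t) matrix(c(ctr - 1 + 0.2 * t, ctr), 1, 2))
  pixM <- vapply(posM, function(p) renderFrame(p, 0.06, 500, cfg, noise = FALSE),
                 matrix(0, 76, 76))
  movM <- MovieStack(array(pixM, c(76, 76, 10, 1)), 0.1, 2)
  kM <- kymograph(movM, rbind(line[1, ], line[nrow(line), ]), widthPx = 3)
  drift <- apply(kM, 1, which.max)
  expect_equal(unique(diff(drift)), 2)   # 0.2 um / 0.1 um px = 2 px per frame
  # blank movie: flat kymograph
  movB <- MovieStack(array(3, c(76, 76, 4, 1)), 0.1, 2)
  kB <- kymograph(movB, rbind(c(10, 10), c(10, 60)), widthPx = 3)
  expect_true(all(kB == 3))
  # polyline outside the frame is refused
  expect_error(kymograph(movB, rbind(c(-5, 10), c(10, 60))), "outside")
})
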