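# Contact detection: per-frame contact, maximal runs, censoring, the
# stability fraction, sampling, and cross-channel fractions.

# Build a two-object scene: squares at controlled separations per frame.
twoSquareScene <- function(colB, nFrames = 25, side = 48) {
  squares <- lapply(seq_len(nFrames), function(t)
    data.frame(row = c(20, 20), col = c(15, colB[min(t, length(colB))]),
               half = 1, id = 1:2))
  labels <- labelsFromSquares(side, squares)
  objects <- lapply(seq_len(nFrames), function(t) {
    sq <- squares[[t]]
    data.frame(object_id = sq$id, frame_index = t - 1L,
               row0 = sq$row - 1, col0 = sq$col - 1, area_px = 9L,
               equiv_diameter_um = 0.34, mean_intensity = 100,
               x_um = (sq$col - 1) * 0.1, y_um = (sq$row - 1) * 0.1)
  })
  list(objects = objects, labels = labels)
}

test_that("contact runs follow the (last - first + 1) * dt duration convention", {
  # objects adjacent (1 px gap) for frames 0..20, then far apart
  sc <- twoSquareScene(colB = c(rep(19, 21), rep(30, 4)))
  cfg <- analysisConfig(contactGapPx = 1L)
  tracks <- linkTracks(sc$objects, cfg)
  ev <- detectPairContacts(sc$objects, sc$labels, tracks, cfg, dtS = 2)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$first_frame, 0L)
  expect_equal(ev$last_frame, 20L)
  expect_equal(ev$min_duration_s, 42)            # (20 - 0 + 1) * 2
  expect_false(ev$censored)
  # brute-force frame-scan oracle agrees exactly
  expect_equal(bruteContactFrames(sc$labels, 1L, 2L, 1L), 0:20)
})

test_that("a full-movie contact is censored and categorized as the 180 s cap", {
  sc <- twoSquareScene(colB = 19, nFrames = 91)
  cfg <- analysisConfig(contactGapPx = 1L)
  tracks <- linkTracks(sc$objects, cfg)
  ev <- detectPairContacts(sc$objects, sc$labels, tracks, cfg, dtS = 2)
  expect_equal(nrow(ev), 1L)
  expect_true(ev$censored)
  expect_equal(ev$min_duration_s, 180)           # 91 frames * 2 s clipped
})

test_that("pairs beyond the gap tolerance produce no events", {
  sc <- twoSquareScene(colB = 30)
  cfg <- analysisConfig(contactGapPx = 1L)
  tracks <- linkTracks(sc$objects, cfg)
  ev <- detectPairContacts(sc$objects, sc$labels, tracks, cfg, dtS = 2)
  expect_equal(nrow(ev), 0L)
})

test_that("event frame coverage equals a brute-force scan on simulated movies", {
  cfg <- simulationConfig(nParticles = 12, nFrames = 40, seed = 21,
                          startTethered = TRUE, burnInFrames = 0)
  sim <- simulateCell(cfg)
  ac <- simulationAnalysisConfig()
  det <- detectObjects(sim$movie, "lysosome", ac)
  tracks <- linkTracks(det$objectsByFrame, ac)
  ev <- detectPairContacts(det$objectsByFrame, det$labelsByFrame, tracks, ac, 2)
  # for every pair: the union of its events' frames must match the per-frame
  # contact indicator (same object or within-gap adjacency), no frame lost
  # or double-counted
  byFrame <- split(tracks, tracks$frame)
  pairs <- unique(ev[, c("member_a", "member_b")])
  for (k in seq_len(nrow(pairs))) {
    a <- pairs$member_a[k]; b <- pairs$member_b[k]
    evk <- ev[ev$member_a == a & ev$member_b == b, ]
    covered <- unlist(mapply(seq, evk$first_frame, evk$last_frame,
                             SIMPLIFY = FALSE))
    expect_equal(anyDuplicated(covered), 0L)
    brute <- integer(0)
    for (t in seq_along(det$objectsByFrame)) {
      tt <- byFrame[[as.character(t - 1L)]]
      oa <- tt$object_id[tt$track_id == a]
      ob <- tt$object_id[tt$track_id == b]
      if (!length(oa) || !length(ob)) next
      inContact <- oa == ob ||
        length(intersect(
          bruteContactFrames(det$labelsByFrame[t], oa, ob, ac@contactGapPx),
          0L)) > 0
      if (inContact) brute <- c(brute, t - 1L)
    }
    expect_equal(sort(covered), brute)
  }
})

test_that("stable-contact fraction counts frame-0 lysosomes in stable pairs", {
  # ten lysosomes at frame 0; tracks 1&2 and 3&4 in stable contacts
  tracks <- data.frame(track_id = 1:10, frame = 0L, object_id = 1:10,
                       x_um = 1:10, y_um = 1, shared = FALSE)
  events <- data.frame(member_a = c(1L, 3L, 5L),
                       member_b = c(2L, 4L, 6L),
                       first_frame = c(0L, 0L, 0L),
                       last_frame = c(10L, 5L, 3L),   # elapsed 20 s, 10 s, 6 s
                       censored = FALSE,
                       min_duration_s = c(22, 12, 8))
  cfg <- analysisConfig()
  expect_equal(stableContactFraction(events, tracks, cfg, dtS = 2), 40)
  # all contacts dissolving early: 0%
  early <- transform(events, last_frame = c(2L, 3L, 1L))
  expect_equal(stableContactFraction(early, tracks, cfg, dtS = 2), 0)
  expect_error(stableContactFraction(events, tracks[0, ], cfg, dtS = 2),
               "frame 0")
})

test_that("minimum-duration sampling is capped at five and seed-deterministic", {
  ev <- data.frame(member_a = 1:20, member_b = 21:40, first_frame = 0L,
                   last_frame = 10L, censored = FALSE,
                   min_duration_s = seq(2, 40, by = 2))
  cfg <- analysisConfig(rngSeed = 99L)
  s1 <- sampleMinDurations(ev, cfg)
  s2 <- sampleMinDurations(ev, cfg)
  expect_equal(nrow(s1), 5L)
  expect_identical(s1, s2)
  expect_false(identical(s1, sampleMinDurations(ev, analysisConfig(rngSeed = 100L))))
  # fewer eligible than the sample size: all returned
  ev3 <- ev[1:3, ]
  expect_equal(nrow(sampleMinDurations(ev3, cfg)), 3L)
  # only frame-0 contacts are eligible
  evLate <- transform(ev, first_frame = 1L)
  expect_equal(nrow(sampleMinDurations(evLate, cfg)), 0L)
})

test_that("cross-channel contact fractions follow the overlap binary", {
  sc <- twoSquareScene(colB = 30, nFrames = 10)
  cfg <- analysisConfig()
  full <- matrix(TRUE, 48, 48)
  res <- crossChannelContactFraction(sc$objects, sc$labels, full, config = cfg)
  expect_equal(res$percent, 100)
  none <- matrix(FALSE, 48, 48)
  res0 <- crossChannelContactFraction(sc$objects, sc$labels, none, config = cfg)
  expect_equal(res0$percent, 0)
  expect_equal(nrow(res0$events), 0L)
  expect_error(crossChannelContactFraction(sc$objects, sc$labels,
                                           matrix(TRUE, 5, 5), config = cfg),
               "shape")
})

test_that("a static partner mask recovers its share of accessible area", {
  # uniformly placed vesicles vs a half-plane partner: fraction ~ area share
  cfg <- simulationConfig(nParticles = 40, nFrames = 30, seed = 31, pOn = 0,
                          perinuclearBias = 0, burnInFrames = 0)
  sim <- simulateCell(cfg)
  ac <- simulationAnalysisConfig()
  det <- detectObjects(sim$movie, "lysosome", ac)
  side <- nrow(cellMask(sim$truth@geometry))
  half <- matrix(FALSE, side, side); half[, seq_len(side %/% 2)] <- TRUE
  res <- crossChannelContactFraction(det$objectsByFrame, det$labelsByFrame,
                                     half, config = ac)
  expect_equal(res$percent, 50, tolerance = 0.15)
  # events come with track identities and the duration convention
  tracks <- linkTracks(det$objectsByFrame, ac)
  rese <- crossChannelContactFraction(det$objectsByFrame, det$labelsByFrame,
                                      half, trackTable = tracks, config = ac,
                                      dtS = 2)
  expect_true(nrow(rese$events) > 0)
  expect_true(all(rese$events$min_duration_s ==
    pmin((rese$events$last_frame - rese$events$first_frame + 1L) * 2, 180)))
  expect_true(all(rese$events$censored == (rese$events$last_frame == 29L)))
})
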