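# Simulator: tether state machine, dwell-time law, rendering and the
# condition-dataset writer.

test_that("absorbing tethers (pOff = 0) run to the final frame", {
  cfg <- simulationConfig(nParticles = 10, nFrames = 30, seed = 2, pOff = 0,
                          startTethered = TRUE, burnInFrames = 0)
  ti <- simulateCell(cfg, render = FALSE)$truth@tetherIntervals
  expect_equal(nrow(ti), 5L)
  expect_true(all(ti$first_frame == 0L))
  expect_true(all(ti$last_frame == 29L))
})

test_that("zero diffusion and no tethering freeze all positions", {
  cfg <- simulationConfig(nParticles = 6, nFrames = 12, seed = 1,
                          diffusionUm2S = 0, pOn = 0, perinuclearBias = 0,
                          burnInFrames = 0)
  tr <- simulateCell(cfg, render = FALSE)$truth
  for (t in 2:12)
    expect_equal(tr@positionsUm[, , t], tr@positionsUm[, , 1])
})

test_that("tether dwell times follow Geometric(pOff) with mean dt/pOff", {
  # long movies so window truncation is negligible; intervals formed early
  durs <- integer(0)
  for (s in 1:12) {
    cfg <- simulationConfig(nParticles = 30, nFrames = 600, seed = 500 + s,
                            burnInFrames = 30, pOff = 0.1,
                            perinuclearBias = 0)
    ti <- simulateCell(cfg, render = FALSE)$truth@tetherIntervals
    keep <- ti$first_frame > 0 & ti$first_frame <= 300 & ti$last_frame < 599
    durs <- c(durs, ti$last_frame[keep] - ti$first_frame[keep] + 1L)
  }
  expect_gt(length(durs), 1000)
  # analytic mean of the geometric dwell: dt / pOff = 20 s
  expect_equal(mean(durs) * 2, 20, tolerance = 0.08)
  # goodness of fit against the geometric law
  kmax <- 30L
  obs <- tabulate(pmin(durs, kmax), kmax)
  p <- dgeom(0:(kmax - 2L), 0.1)
  p <- c(p, 1 - sum(p))
  gof <- suppressWarnings(chisq.test(obs, p = p))
  expect_gt(gof$p.value, 0.001)
})

test_that("untethered unbiased particles diffuse with MSD ~ 4 D t", {
  D <- 0.02; dt <- 2
  sq <- c()
  for (s in 1:4) {
    cfg <- simulationConfig(nParticles = 40, nFrames = 40, seed = 600 + s,
                            pOn = 0, perinuclearBias = 0, burnInFrames = 0,
                            cellRadiusUm = 18, diffusionUm2S = D)
    pos <- simulateCell(cfg, render = FALSE)$truth@positionsUm
    for (lag in 1:4) {
      d2 <- (pos[, 1, seq(1, 40 - lag)] - pos[, 1, seq(1 + lag, 40)])^2 +
            (pos[, 2, seq(1, 40 - lag)] - pos[, 2, seq(1 + lag, 40)])^2
      sq <- rbind(sq, c(lag, mean(d2)))
    }
  }
  for (lag in 1:4) {
    msd <- mean(sq[sq[, 1] == lag, 2])
    expect_equal(msd, 4 * D * lag * dt, tolerance = 0.12)
  }
})

test_that("truth respects its own invariants", {
  cfg <- simulationConfig(nParticles = 24, nFrames = 60, seed = 9,
                          burnInFrames = 20)
  tr <- simulateCell(cfg, render = FALSE)$truth
  ctr <- (nrow(cellMask(tr@geometry)) - 1) / 2 * cfg@pixelSizeUm
  rad <- sqrt((tr@positionsUm[, 1, ] - ctr)^2 + (tr@positionsUm[, 2, ] - ctr)^2)
  expect_true(all(rad <= cfg@cellRadiusUm))          # inside the cell
  expect_true(all(rad >= cfg@nucleusRadiusUm))       # never in the nucleus
  ti <- tr@tetherIntervals
  expect_true(all(ti$first_frame <= ti$last_frame))
  # maximal, non-overlapping per pair
  if (nrow(ti) > 1) {
    sp <- split(ti, paste(ti$particle_i, ti$particle_j))
    for (runs in sp) if (nrow(runs) > 1) {
      runs <- runs[order(runs$first_frame), ]
      expect_true(all(runs$first_frame[-1] > runs$last_frame[-nrow(runs)] + 1L))
    }
  }
  # a tether implies centre distance within capture + both radii
  for (k in seq_len(min(nrow(ti), 50))) {
    i <- ti$particle_i[k]; j <- ti$particle_j[k]
    fr <- (ti$first_frame[k]:ti$last_frame[k]) + 1L
    d <- sqrt((tr@positionsUm[i, 1, fr] - tr@positionsUm[j, 1, fr])^2 +
              (tr@positionsUm[i, 2, fr] - tr@positionsUm[j, 2, fr])^2)
    expect_true(all(d <= cfg@captureDistUm + tr@radiiUm[i] + tr@radiiUm[j] + 1e-3))
  }
})

test_that("rendering matches its noise model", {
  cfg <- simulationConfig(nParticles = 1, nFrames = 2, seed = 1,
                          cellRadiusUm = 3, nucleusRadiusUm = 0.5)
  side <- nrow(cellMask(simulateCell(cfg, render = FALSE)$truth@geometry))
  ctr <- (side - 1) / 2 * 0.1
  # empty scene: pure noise at the background level
  withr::with_seed(1, {
    img0 <- renderFrame(matrix(numeric(0), 0, 2), numeric(0), numeric(0), cfg)
    expect_equal(mean(img0), cfg@bgPhotons, tolerance = 0.05)
  })
  # noise-free single particle: argmax at the particle pixel
  pos <- matrix(c(ctr + 0.43, ctr - 0.28), 1, 2)
  imgE <- renderFrame(pos, 0.06, 500, cfg, noise = FALSE)
  pk <- which(imgE == max(imgE), arr.ind = TRUE)[1, ]
  expect_equal(unname(pk[1] - 1), round(pos[1, 2] / 0.1))  # row ~ y
  expect_equal(unname(pk[2] - 1), round(pos[1, 1] / 0.1))  # col ~ x
  # repeated noisy renders: per-pixel variance ~ Poisson + read noise
  withr::with_seed(2, {
    reps <- replicate(150, renderFrame(pos, 0.06, 500, cfg))
    px <- c(pk[1], pk[2])
    v <- var(reps[px[1], px[2], ])
    lam <- imgE[px[1], px[2]]
    expect_equal(v, lam + cfg@readNoise^2, tolerance = 0.25)
    expect_equal(mean(reps[px[1], px[2], ]), lam, tolerance = 0.05)
  })
})

test_that("condition datasets are written completely and reproducibly", {
  d1 <- file.path(tempdir(), "lysodyn_ds1")
  d2 <- file.path(tempdir(), "lysodyn_ds2")
  unlink(c(d1, d2), recursive = TRUE)
  small <- function(...) simulationConfig(nParticles = 5, nFrames = 4,
                                          cellRadiusUm = 5,
                                          nucleusRadiusUm = 1.5,
                                          burnInFrames = 2, ...)
  m1 <- makeConditionDataset(small(), small(pOff = 0.01), nCells = 3,
                             seed = 11, outDir = d1)
  expect_equal(nrow(m1), 6L)
  expect_equal(sum(m1$condition == "control"), 3L)
  expect_true(all(file.exists(file.path(d1, m1$file))))
  expect_true(all(file.exists(file.path(d1, m1$truth_file))))
  m2 <- makeConditionDataset(small(), small(pOff = 0.01), nCells = 3,
                             seed = 11, outDir = d2)
  expect_identical(m1$seed, m2$seed)
  expect_identical(readBin(file.path(d1, m1$file[1]), "raw", 1e6),
                   readBin(file.path(d2, m2$file[1]), "raw", 1e6))
  # round trip: truth positions survive JSON
  tr <- readTruth(file.path(d1, m1$truth_file[1]))
  expect_equal(dim(tr$positionsUm), c(5, 2, 4))
  unlink(c(d1, d2), recursive = TRUE)
})
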