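# Synthetic time-lapse generator with known ground truth: vesicles
# diffusing in an annular cytoplasm (reflecting at the cell edge and the
# nucleus), tethering pairwise on encounter and dissolving with a per-frame
# probability, rendered as PSF-blurred Gaussian spots with Poisson shot
# noise and Gaussian read noise.

RENDER_MARGIN_UM <- 0.8
REFRACTORY_HYSTERESIS_UM <- 0.2

sidePx <- function(cfg) as.integer(ceiling(2 * (cfg@cellRadiusUm + RENDER_MARGIN_UM) /
                                           cfg@pixelSizeUm))

arenaCenterUm <- function(cfg) (sidePx(cfg) - 1) / 2 * cfg@pixelSizeUm

arenaMasks <- function(cfg) {
  side <- sidePx(cfg)
  px <- cfg@pixelSizeUm
  ctr <- arenaCenterUm(cfg)
  xs <- (seq_len(side) - 1) * px
  dd <- sqrt(outer((xs - ctr)^2, (xs - ctr)^2, "+"))  # [row, col] distance
  cellGeometry(dd <= cfg@cellRadiusUm, dd <= cfg@nucleusRadiusUm)
}

# Draw radial coordinates from the drift-diffusion steady state
# f(r) ~ r * exp(-(r - lo) / lambda) on [lo, hi]; lambda = D / bias
# (uniform-in-area when the bias is zero).
sampleRadii <- function(k, lo, hi, lambda) {
  if (!is.finite(lambda) || lambda <= 0) lambda <- Inf
  out <- numeric(0)
  grid <- seq(lo, hi, length.out = 512)
  M <- max(grid * exp(-(grid - lo) / lambda))
  while (length(out) < k) {
    m <- 2L * (k - length(out)) + 10L
    r <- runif(m, lo, hi)
    acc <- runif(m) < r * exp(-(r - lo) / lambda) / M
    out <- c(out, r[acc])
  }
  out[seq_len(k)]
}

pairIndexUpper <- function(n) {
  ij <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
}

#' Render one synthetic frame
#'
#' Draws each particle as an isotropic Gaussian spot whose sigma combines
#' the particle radius with the PSF sigma, on a constant photon background;
#' with noise enabled, applies Poisson shot noise and additive Gaussian read
#' noise and rounds to non-negative integer counts (camera units). The
#' expected total signal is proportional to the sum of spot intensities.
#'
#' @param positionsUm n x 2 matrix of (x, y) positions, um.
#' @param radiiUm per-particle radii, um.
#' @param intensities per-particle peak photon counts.
#' @param cfg a \linkS4class{SimulationConfig} (geometry and noise model).
#' @param noise apply the shot + read noise model (default TRUE).
#' @return numeric matrix \code{[row, col]}; the noise-free variant returns
#'   the expected photon image.
#' @export
renderFrame <- function(positionsUm, radiiUm, intensities, cfg,
                        noise = TRUE) {
  side <- sidePx(cfg)
  px <- cfg@pixelSizeUm
  signal <- matrix(0, side, side)
  n <- nrow(positionsUm)
  if (n > 0) for (p in seq_len(n)) {
    sig <- sqrt((radiiUm[p] / px)^2 + (cfg@psfSigmaUm / px)^2)
    c0 <- positionsUm[p, 1] / px   # 0-based col
    r0 <- positionsUm[p, 2] / px   # 0-based row
    half <- ceiling(4 * sig)
    rr <- max(0, floor(r0) - half):min(side - 1, ceiling(r0) + half)
    cc <- max(0, floor(c0) - half):min(side - 1, ceiling(c0) + half)
    if (!length(rr) || !length(cc)) next
    patch <- intensities[p] *
      exp(-(outer((rr - r0)^2, (cc - c0)^2, "+")) / (2 * sig^2))
    signal[rr + 1, cc + 1] <- signal[rr + 1, cc + 1] + patch
  }
  lambda <- signal + cfg@bgPhotons
  if (!noise) return(lambda)
  img <- rpois(length(lambda), lambda) +
    round(rnorm(length(lambda), 0, cfg@readNoise))
  img[img < 0] <- 0
  img[img > 65535] <- 65535
  matrix(as.numeric(img), side, side)
}

# Reflect radial coordinates into [lo, hi] per particle (vectorized).
reflectRadial <- function(pos, ctr, lo, hi) {
  dx <- pos[, 1] - ctr; dy <- pos[, 2] - ctr
  r <- sqrt(dx^2 + dy^2)
  r2 <- r
  for (rep in 1:3) {
    over <- r2 > hi; under <- r2 < lo
    r2[over] <- 2 * hi[over] - r2[over]
    r2[under] <- 2 * lo[under] - r2[under]
  }
  r2 <- pmin(pmax(r2, lo), hi)
  scale <- ifelse(r > 1e-12, r2 / r, 1)
  cbind(ctr + dx * scale, ctr + dy * scale)
}

#' Simulate one cell with ground truth
#'
#' Runs the tether-and-diffuse dynamics (optionally preceded by unrecorded
#' burn-in frames so tethering occupancy and the radial distribution start
#' near steady state), records per-frame true positions and tether
#' intervals, and renders the configured channels. Tether lifetimes in
#' frames are geometric with mean 1/pOff: a tether formed (or present at
#' frame 0) survives each subsequent frame with probability 1 - pOff.
#' With \code{pOff = 0} every tether is absorbing and runs to the final
#' frame; with zero diffusion and \code{pOn = 0} positions are constant.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @param render render movie channels (set FALSE for truth-only runs).
#' @return list(truth = \linkS4class{SimulationTruth},
#'   movie = \linkS4class{MovieStack} or NULL).
#' @examples
#' sim <- simulateCell(simulationConfig(nParticles = 6, nFrames = 10,
#'                                      seed = 1), render = FALSE)
#' sim$truth
#' @export
simulateCell <- function(cfg, render = TRUE) {
  withSeed(cfg@seed, {
    n <- cfg@nParticles
    lo0 <- cfg@nucleusRadiusUm
    hi0 <- cfg@cellRadiusUm
    ctr <- arenaCenterUm(cfg)
    dt <- cfg@dtS
    lambda <- if (cfg@perinuclearBias > 0)
      cfg@diffusionUm2S / cfg@perinuclearBias else Inf
    radii <- runif(n, cfg@radiusUmRange[1], cfg@radiusUmRange[2])
    lo <- lo0 + radii + 1e-3
    hi <- hi0 - radii - 1e-3

    active <- matrix(FALSE, n, n)
    refractory <- matrix(FALSE, n, n)

    placeOne <- function(rad, existing, minSep) {
      for (try in 1:500) {
        rr <- sampleRadii(1, lo0 + rad + 1e-3, hi0 - rad - 1e-3, lambda)
        th <- runif(1, 0, 2 * pi)
        p <- c(ctr + rr * cos(th), ctr + rr * sin(th))
        if (is.null(existing) || nrow(existing) == 0L) return(p)
        d <- sqrt((existing[, 1] - p[1])^2 + (existing[, 2] - p[2])^2)
        if (min(d) > minSep) return(p)
      }
      stop("could not place ", n, " particles without overlap")
    }

    pos <- matrix(NA_real_, n, 2)
    if (cfg@startTethered) {
      npair <- n %/% 2L
      for (k in seq_len(npair)) {
        i <- 2L * k - 1L; j <- 2L * k
        d0 <- cfg@captureDistUm + radii[i] + radii[j] - 1e-6
        for (try in 1:500) {
          rc <- sampleRadii(1, lo0 + d0 / 2 + max(radii) + 1e-3,
                            hi0 - d0 / 2 - max(radii) - 1e-3, lambda)
          thc <- runif(1, 0, 2 * pi)
          cpt <- c(ctr + rc * cos(thc), ctr + rc * sin(thc))
          ori <- runif(1, 0, 2 * pi)
          u <- c(cos(ori), sin(ori))
          pi_ <- cpt - d0 / 2 * u
          pj_ <- cpt + d0 / 2 * u
          placed <- pos[!is.na(pos[, 1]), , drop = FALSE]
          okSep <- TRUE
          if (nrow(placed)) {
            dmin <- min(sqrt((placed[, 1] - pi_[1])^2 + (placed[, 2] - pi_[2])^2),
                        sqrt((placed[, 1] - pj_[1])^2 + (placed[, 2] - pj_[2])^2))
            okSep <- dmin > 2 * (cfg@captureDistUm + 2 * max(radii))
          }
          ri_ <- sqrt(sum((pi_ - ctr)^2)); rj_ <- sqrt(sum((pj_ - ctr)^2))
          if (okSep && ri_ > lo[i] && ri_ < hi[i] && rj_ > lo[j] && rj_ < hi[j]) {
            pos[i, ] <- pi_; pos[j, ] <- pj_
            active[i, j] <- TRUE
            break
          }
          if (try == 500) stop("could not place tethered pairs without overlap")
        }
      }
      if (n %% 2L == 1L)
        pos[n, ] <- placeOne(radii[n], pos[!is.na(pos[, 1]), , drop = FALSE],
                             2 * (cfg@captureDistUm + 2 * max(radii)))
    } else {
      for (i in seq_len(n))
        pos[i, ] <- placeOne(radii[i], pos[!is.na(pos[, 1]), , drop = FALSE],
                             radii[i] + max(radii) + 0.05)
    }

    eligDist <- outer(radii, radii, "+") + cfg@captureDistUm
    upper <- upper.tri(active)

    step <- function() {
      dx <- outer(pos[, 1], pos[, 1], "-")
      dy <- outer(pos[, 2], pos[, 2], "-")
      dmat <- sqrt(dx^2 + dy^2)
      # 1. stochastic dissolution (tested once per frame per tether)
      dis <- active & upper & matrix(runif(n * n) < cfg@pOff, n, n)
      active[dis] <<- FALSE
      refractory[dis] <<- TRUE
      # 2. refractory pairs re-arm once they have separated past the
      #    capture range (hysteresis prevents instant re-binding chains)
      rearm <- refractory & (dmat > eligDist + REFRACTORY_HYSTERESIS_UM)
      refractory[rearm] <<- FALSE
      # 3. formation on encounter
      elig <- upper & !active & !refractory & !dis & (dmat <= eligDist)
      form <- elig & matrix(runif(n * n) < cfg@pOn, n, n)
      active[form] <<- TRUE
      # 4. proposals: Brownian step + radial drift toward the nucleus
      prop <- matrix(rnorm(2 * n, 0, sqrt(2 * cfg@diffusionUm2S * dt)), n, 2)
      if (cfg@perinuclearBias > 0) {
        rx <- pos[, 1] - ctr; ry <- pos[, 2] - ctr
        rr <- pmax(sqrt(rx^2 + ry^2), 1e-9)
        prop[, 1] <- prop[, 1] - cfg@perinuclearBias * dt * rx / rr
        prop[, 2] <- prop[, 2] - cfg@perinuclearBias * dt * ry / rr
      }
      # 5. tethered connected components share their mean displacement
      sym <- active | t(active)
      if (any(sym)) {
        comp <- rep(0L, n); cid <- 0L
        for (s in seq_len(n)) if (comp[s] == 0L) {
          cid <- cid + 1L
          queue <- s
          while (length(queue)) {
            v <- queue[1]; queue <- queue[-1]
            if (comp[v] != 0L) next
            comp[v] <- cid
            queue <- c(queue, which(sym[v, ] & comp == 0L))
          }
        }
        for (g in unique(comp)) {
          mem <- which(comp == g)
          if (length(mem) > 1L) {
            mp <- colMeans(prop[mem, , drop = FALSE])
            prop[mem, 1] <- mp[1]; prop[mem, 2] <- mp[2]
          }
        }
      }
      pos <<- pos + prop
      # 6. kiss-and-run release impulse for freshly dissolved pairs; only
      #    when both members are otherwise free, so a release inside a
      #    cluster cannot rip its neighbours' tethers apart
      if (any(dis) && cfg@releaseKickUm > 0) {
        idx <- which(dis, arr.ind = TRUE)
        sym <- active | t(active)
        for (k in seq_len(nrow(idx))) {
          i <- idx[k, 1]; j <- idx[k, 2]
          if (any(sym[i, ]) || any(sym[j, ])) next
          u <- pos[j, ] - pos[i, ]
          du <- sqrt(sum(u^2))
          u <- if (du > 1e-9) u / du else c(cos(th <- runif(1, 0, 2 * pi)), sin(th))
          pos[i, ] <<- pos[i, ] - cfg@releaseKickUm / 2 * u
          pos[j, ] <<- pos[j, ] + cfg@releaseKickUm / 2 * u
        }
      }
      # 7. reflecting boundaries (cell edge and nucleus)
      pos <<- reflectRadial(pos, ctr, lo, hi)
      # 8. a reflection can stretch a tether past the capture range;
      #    contract the pair back onto it (the tether holds), breaking only
      #    if the geometry cannot be restored inside the arena
      dx <- outer(pos[, 1], pos[, 1], "-")
      dy <- outer(pos[, 2], pos[, 2], "-")
      dmat <- sqrt(dx^2 + dy^2)
      for (pass in 1:5) {
        stretched <- which(active & upper & (dmat > eligDist + 1e-9),
                           arr.ind = TRUE)
        if (!nrow(stretched)) break
        for (k in seq_len(nrow(stretched))) {
          i <- stretched[k, 1]; j <- stretched[k, 2]
          u <- pos[j, ] - pos[i, ]
          du <- sqrt(sum(u^2))
          if (du < 1e-12) next
          u <- u / du
          mid <- (pos[i, ] + pos[j, ]) / 2
          target <- eligDist[i, j] - 1e-6
          pos[i, ] <<- mid - u * target / 2
          pos[j, ] <<- mid + u * target / 2
          for (p in c(i, j)) {   # clamp radius without mirroring
            dv <- pos[p, ] - ctr
            rr <- sqrt(sum(dv^2))
            rc <- min(max(rr, lo[p]), hi[p])
            if (rr > 1e-12 && rc != rr) pos[p, ] <<- ctr + dv * rc / rr
          }
        }
        dx <- outer(pos[, 1], pos[, 1], "-")
        dy <- outer(pos[, 2], pos[, 2], "-")
        dmat <- sqrt(dx^2 + dy^2)
      }
      broke <- active & upper & (dmat > eligDist + 1e-3)
      active[broke] <<- FALSE
      refractory[broke] <<- TRUE
      invisible(NULL)
    }

    if (!cfg@startTethered && cfg@burnInFrames > 0L)
      for (b in seq_len(cfg@burnInFrames)) step()

    nT <- cfg@nFrames
    positions <- array(NA_real_, c(n, 2, nT))
    pairIdx <- pairIndexUpper(n)
    tetherOn <- matrix(FALSE, nrow(pairIdx), nT)
    recordState <- function(t) {
      positions[, , t + 1L] <<- pos
      tetherOn[, t + 1L] <<- active[pairIdx]
    }
    recordState(0L)
    for (t in seq_len(nT - 1L)) { step(); recordState(t) }

    intervals <- do.call(rbind, lapply(which(rowSums(tetherOn) > 0L), function(p) {
      runs <- framesToRuns(which(tetherOn[p, ]) - 1L)
      data.frame(particle_i = pairIdx[p, 1], particle_j = pairIdx[p, 2],
                 first_frame = runs$first, last_frame = runs$last,
                 row.names = NULL)
    }))
    if (is.null(intervals))
      intervals <- data.frame(particle_i = integer(0), particle_j = integer(0),
                              first_frame = integer(0), last_frame = integer(0))
    geometry <- arenaMasks(cfg)
    truth <- new("SimulationTruth", positionsUm = positions, radiiUm = radii,
                 tetherIntervals = intervals, geometry = geometry, config = cfg)

    movie <- NULL
    if (render && length(cfg@channels)) {
      side <- sidePx(cfg)
      pix <- array(0, c(side, side, nT, length(cfg@channels)))
      amp <- vapply(cfg@channels, function(ch)
        if (ch == "dye") cfg@photonScale * cfg@intensityScale else cfg@photonScale,
        numeric(1))
      for (t in seq_len(nT))
        for (ci in seq_along(cfg@channels))
          pix[, , t, ci] <- renderFrame(positions[, , t, drop = FALSE][, , 1],
                                        radii, rep(amp[ci], n), cfg)
      movie <- MovieStack(pix, pixelSizeUm = cfg@pixelSizeUm,
                          frameIntervalS = dt, channelNames = cfg@channels)
    }
    list(truth = truth, movie = movie)
  })
}

#' Control-condition simulation regime
#'
#' The baseline regime: moderate tether lifetime (pOff = 0.1 per 2 s frame,
#' mean dwell 20 s), diffusion 0.02 um^2/s, a weak perinuclear drift, and
#' full-brightness functional dye.
#'
#' @param ... overrides passed to [simulationConfig()].
#' @return a \linkS4class{SimulationConfig}.
#' @export
controlRegime <- function(...) {
  args <- list(...)
  base <- list(pOff = 0.1, diffusionUm2S = 0.02, perinuclearBias = 0.003,
               intensityScale = 1.0, channels = c("lysosome", "dye"))
  do.call(simulationConfig, modifyList(base, args))
}

#' Knockdown-condition simulation regime
#'
#' The contrast regime: tenfold longer tethers (pOff / 10), halved
#' diffusion, doubled perinuclear drift, and half-brightness functional dye
#' relative to [controlRegime()].
#'
#' @param ... overrides passed to [simulationConfig()].
#' @return a \linkS4class{SimulationConfig}.
#' @export
kdRegime <- function(...) {
  args <- list(...)
  base <- list(pOff = 0.01, diffusionUm2S = 0.01, perinuclearBias = 0.006,
               intensityScale = 0.5, channels = c("lysosome", "dye"))
  do.call(simulationConfig, modifyList(base, args))
}

# Derive a per-cell seed from the dataset seed by fixed arithmetic, so a
# dataset can be extended without reshuffling earlier cells.
cellSeed <- function(seed, condIndex, cellIndex) {
  as.integer((as.numeric(seed) * 1000003 + condIndex * 499979 +
              cellIndex * 7919) %% 2147483629) + 1L
}

#' Write a two-condition synthetic dataset
#'
#' Simulates \code{nCells} cells per condition with per-cell seeds derived
#' from one dataset seed, writes each movie as a multi-page TIFF and each
#' ground truth as JSON, and a manifest CSV mapping file to condition.
#'
#' @param cfgControl,cfgKd \linkS4class{SimulationConfig}s for the two
#'   conditions (their \code{seed} slots are overridden per cell).
#' @param nCells cells per condition (>= 1).
#' @param seed dataset seed.
#' @param outDir output directory (created if missing).
#' @return the manifest data.frame, invisibly.
#' @export
makeConditionDataset <- function(cfgControl, cfgKd, nCells, seed, outDir) {
  stopifnot(nCells >= 1L)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  configs <- list(control = cfgControl, kd = cfgKd)
  rows <- list()
  for (ci in seq_along(configs)) {
    cond <- names(configs)[ci]
    for (i in seq_len(nCells)) {
      cfg <- configs[[ci]]
      cfg@seed <- cellSeed(seed, ci, i)
      sim <- simulateCell(cfg, render = TRUE)
      movieFile <- file.path(outDir, sprintf("%s_cell%02d.tif", cond, i))
      truthFile <- file.path(outDir, sprintf("%s_cell%02d_truth.json", cond, i))
      writeMovie(sim$movie, movieFile)
      writeTruth(sim$truth, truthFile)
      rows[[length(rows) + 1L]] <-
        data.frame(file = basename(movieFile), truth_file = basename(truthFile),
                   condition = cond, cell = i, seed = cfg@seed)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(outDir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
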