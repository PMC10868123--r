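#' @import methods
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' MovieStack: a calibrated multi-channel time-lapse
#'
#' Container for a fluorescence time-lapse movie: a pixel array indexed
#' (row, col, frame, channel) together with its physical calibration
#' (micrometres per pixel and seconds per frame) and channel role labels.
#' All frames share one shape, intensities are non-negative, and both
#' calibration constants are strictly positive.
#'
#' @slot pixels numeric 4-D array \code{[row, col, frame, channel]}.
#' @slot pixelSizeUm micrometres per pixel (> 0).
#' @slot frameIntervalS seconds per frame (> 0).
#' @slot channelNames character vector of marker labels, one per channel
#'   (e.g. \code{"lysosome"}, \code{"er"}, \code{"mito"}, \code{"dye"}).
#' @exportClass MovieStack
setClass("MovieStack",
  representation(
    pixels = "array",
    pixelSizeUm = "numeric",
    frameIntervalS = "numeric",
    channelNames = "character"
  )
)

setValidity("MovieStack", function(object) {
  msg <- NULL
  d <- dim(object@pixels)
  if (length(d) != 4L)
    msg <- c(msg, "pixels must be a 4-D array [row, col, frame, channel]")
  else {
    if (d[4] != length(object@channelNames))
      msg <- c(msg, "length(channelNames) must equal the number of channels")
    if (anyDuplicated(object@channelNames))
      msg <- c(msg, "channelNames must be unique")
  }
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a single positive number")
  if (length(object@frameIntervalS) != 1L || !is.finite(object@frameIntervalS) ||
      object@frameIntervalS <= 0)
    msg <- c(msg, "frameIntervalS must be a single positive number")
  if (anyNA(object@pixels) || min(object@pixels) < 0)
    msg <- c(msg, "pixel intensities must be non-negative and non-missing")
  if (is.null(msg)) TRUE else msg
})

#' Construct a MovieStack
#'
#' @param pixels a 4-D array \code{[row, col, frame, channel]}, a 3-D array
#'   \code{[row, col, frame]} (promoted to one channel), or a matrix (one
#'   frame, one channel).
#' @param pixelSizeUm micrometres per pixel.
#' @param frameIntervalS seconds per frame.
#' @param channelNames channel role labels; defaults to \code{"lysosome"}
#'   for single-channel input.
#' @return a validated \linkS4class{MovieStack}.
#' @examples
#' m <- MovieStack(array(0, c(8, 8, 3)), pixelSizeUm = 0.1, frameIntervalS = 2)
#' nFrames(m)
#' @export
MovieStack <- function(pixels, pixelSizeUm, frameIntervalS,
                       channelNames = NULL) {
  if (missing(pixelSizeUm) || missing(frameIntervalS))
    stop("calibration (pixelSizeUm, frameIntervalS) must be supplied explicitly")
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L, 1L)
  if (length(dim(pixels)) == 3L) dim(pixels) <- c(dim(pixels), 1L)
  if (is.null(channelNames)) {
    channelNames <- if (dim(pixels)[4] == 1L) "lysosome" else
      paste0("channel", seq_len(dim(pixels)[4]))
  }
  new("MovieStack", pixels = pixels, pixelSizeUm = pixelSizeUm,
      frameIntervalS = frameIntervalS, channelNames = channelNames)
}

#' CellGeometry: cell and nucleus masks
#'
#' Binary cell and nucleus masks sharing the shape of one movie frame; the
#' nucleus mask must be contained in the cell mask.
#'
#' @slot cellMask logical matrix.
#' @slot nucleusMask logical matrix.
#' @exportClass CellGeometry
setClass("CellGeometry",
  representation(cellMask = "matrix", nucleusMask = "matrix")
)

setValidity("CellGeometry", function(object) {
  msg <- NULL
  if (!is.logical(object@cellMask) || !is.logical(object@nucleusMask))
    msg <- c(msg, "masks must be logical matrices")
  else {
    if (!identical(dim(object@cellMask), dim(object@nucleusMask)))
      msg <- c(msg, "cellMask and nucleusMask must share one shape")
    else if (any(object@nucleusMask & !object@cellMask))
      msg <- c(msg, "nucleusMask must be contained in cellMask")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a CellGeometry
#' @param cellMask,nucleusMask logical (or coercible) matrices of one frame's
#'   shape; the nucleus must lie inside the cell.
#' @return a validated \linkS4class{CellGeometry}.
#' @export
cellGeometry <- function(cellMask, nucleusMask) {
  storage.mode(cellMask) <- "logical"
  storage.mode(nucleusMask) <- "logical"
  new("CellGeometry", cellMask = cellMask, nucleusMask = nucleusMask)
}

#' AnalysisConfig: analysis parameters
#'
#' All tunable parameters of the quantification pipeline. Defaults are the
#' study's procedural constants: size gate (0.1, 2) um equivalent diameter,
#' contact stability cutoff 10 s, censoring cap 180 s, perinuclear cutoff
#' 7 um, motility window 60 s, five sampled contacts per cell.
#'
#' @slot sizeGateUm closed (d_min, d_max) equivalent-diameter window, um.
#' @slot stableContactS stability cutoff, seconds of elapsed contact.
#' @slot movieCapS censoring cap for minimum contact durations, seconds.
#' @slot perinuclearUm nuclear-distance cutoff, um (strict `<` = perinuclear).
#' @slot motilityWindowS minimum track duration for motility analysis, s.
#' @slot contactSampleN contacts sampled per cell for duration monitoring.
#' @slot rngSeed integer seed governing the contact sampling.
#' @slot thresholdMethod \code{"otsu"} or \code{"fixed"}.
#' @slot fixedThreshold threshold used when \code{thresholdMethod == "fixed"}.
#' @slot rollingBallRadiusPx rolling-ball background radius, pixels.
#' @slot linkMaxDispUm per-frame displacement gate for track linking, um.
#' @slot mergeAttachUm merge-plausibility range for tracking: a track that
#'   loses the one-to-one assignment continues as a shared occupant of a
#'   neighbouring object only if the two tracks were within this distance
#'   of each other in the previous frame (and the object is large enough
#'   to be their fusion).
#' @slot contactGapPx max pixel gap for two vesicles to count as touching.
#' @slot lysoChannel,dyeChannel channel role names used by the pipeline.
#' @slot plaSizeGateUm equivalent-diameter gate for PLA puncta, um.
#' @slot minNucleusAreaUm2 minimum DAPI object area counted as a nucleus.
#' @exportClass AnalysisConfig
setClass("AnalysisConfig",
  representation(
    sizeGateUm = "numeric",
    stableContactS = "numeric",
    movieCapS = "numeric",
    perinuclearUm = "numeric",
    motilityWindowS = "numeric",
    contactSampleN = "integer",
    rngSeed = "integer",
    thresholdMethod = "character",
    fixedThreshold = "numeric",
    rollingBallRadiusPx = "integer",
    linkMaxDispUm = "numeric",
    mergeAttachUm = "numeric",
    contactGapPx = "integer",
    lysoChannel = "character",
    dyeChannel = "character",
    plaSizeGateUm = "numeric",
    minNucleusAreaUm2 = "numeric"
  ),
  prototype(
    sizeGateUm = c(0.1, 2.0),
    stableContactS = 10,
    movieCapS = 180,
    perinuclearUm = 7,
    motilityWindowS = 60,
    contactSampleN = 5L,
    rngSeed = 1L,
    thresholdMethod = "otsu",
    fixedThreshold = NA_real_,
    rollingBallRadiusPx = 50L,
    linkMaxDispUm = 1.0,
    mergeAttachUm = 0.8,
    contactGapPx = 1L,
    lysoChannel = "lysosome",
    dyeChannel = "dye",
    plaSizeGateUm = c(0.1, 1.0),
    minNucleusAreaUm2 = 10
  )
)

setValidity("AnalysisConfig", function(object) {
  msg <- NULL
  g <- object@sizeGateUm
  if (length(g) != 2L || !(g[1] < g[2]) || g[1] <= 0)
    msg <- c(msg, "sizeGateUm must be (d_min, d_max) with 0 < d_min < d_max")
  pos <- c(stableContactS = object@stableContactS,
           movieCapS = object@movieCapS,
           perinuclearUm = object@perinuclearUm,
           motilityWindowS = object@motilityWindowS,
           linkMaxDispUm = object@linkMaxDispUm,
           mergeAttachUm = object@mergeAttachUm)
  if (any(!is.finite(pos)) || any(pos <= 0))
    msg <- c(msg, "all durations and distances must be positive")
  if (object@contactSampleN < 1L)
    msg <- c(msg, "contactSampleN must be >= 1")
  if (object@contactGapPx < 0L)
    msg <- c(msg, "contactGapPx must be >= 0")
  if (!object@thresholdMethod %in% c("otsu", "fixed"))
    msg <- c(msg, "thresholdMethod must be 'otsu' or 'fixed'")
  if (object@thresholdMethod == "fixed" && !is.finite(object@fixedThreshold))
    msg <- c(msg, "fixedThreshold must be set when thresholdMethod == 'fixed'")
  if (object@rollingBallRadiusPx < 1L)
    msg <- c(msg, "rollingBallRadiusPx must be >= 1")
  p <- object@plaSizeGateUm
  if (length(p) != 2L || !(p[1] < p[2]) || p[1] <= 0)
    msg <- c(msg, "plaSizeGateUm must be (d_min, d_max) with 0 < d_min < d_max")
  if (is.null(msg)) TRUE else msg
})

#' Construct an AnalysisConfig
#'
#' Any slot can be overridden by name; unspecified parameters keep the
#' study defaults (see \linkS4class{AnalysisConfig}).
#'
#' @param ... named parameter overrides, e.g. \code{rngSeed = 7}.
#' @return a validated \linkS4class{AnalysisConfig}.
#' @examples
#' cfg <- analysisConfig(rngSeed = 42, contactGapPx = 3)
#' cfg
#' @export
analysisConfig <- function(...) {
  args <- list(...)
  ints <- c("contactSampleN", "rngSeed", "rollingBallRadiusPx", "contactGapPx")
  for (nm in intersect(names(args), ints)) args[[nm]] <- as.integer(args[[nm]])
  bad <- setdiff(names(args), slotNames("AnalysisConfig"))
  if (length(bad)) stop("unknown analysis parameters: ", paste(bad, collapse = ", "))
  do.call(new, c(list(Class = "AnalysisConfig"), args))
}

#' Analysis configuration matched to the bundled simulator
#'
#' The package default \code{analysisConfig()} carries the study constants
#' (50 px rolling ball, 1 px contact gap). For movies produced by
#' [simulateCell()] two instrument-matched adjustments apply, fixed from
#' the simulator geometry: the background is flat so a 25 px rolling ball
#' suffices, and the contact gap tolerance is 3 px so that the operational
#' contact range (two thresholded spot binaries within the gap) spans the
#' tether capture range (0.4 um surface distance) given the rendered spot
#' extent (PSF sigma 0.1 um on 0.1 um pixels).
#'
#' @param ... further overrides passed to [analysisConfig()].
#' @return an \linkS4class{AnalysisConfig}.
#' @export
simulationAnalysisConfig <- function(...) {
  args <- modifyList(list(rollingBallRadiusPx = 25L, contactGapPx = 3L),
                     list(...))
  do.call(analysisConfig, args)
}

#' SimulationConfig: synthetic time-lapse parameters
#'
#' Parameters of the ground-truth simulator: vesicles diffusing in an annular
#' cytoplasm between a circular nucleus and the cell boundary, tethering
#' pairwise on encounter and releasing stochastically, rendered as PSF-blurred
#' Gaussian spots with Poisson shot noise and Gaussian read noise. Frame
#' geometry defaults to the acquisition used throughout: 91 frames at 2 s,
#' i.e. a 180 s movie.
#'
#' @slot nParticles number of vesicles.
#' @slot cellRadiusUm,nucleusRadiusUm arena geometry, um.
#' @slot diffusionUm2S per-particle diffusion coefficient, um^2/s.
#' @slot radiusUmRange (min, max) particle radii, um.
#' @slot captureDistUm surface-to-surface distance below which tethering may
#'   initiate.
#' @slot pOn per-frame tether formation probability for eligible pairs.
#' @slot pOff per-frame tether dissociation probability.
#' @slot perinuclearBias radial drift speed toward the nucleus, um/s.
#' @slot nFrames,dtS recorded frames and frame interval (s).
#' @slot psfSigmaUm isotropic PSF sigma used for rendering, um.
#' @slot pixelSizeUm rendered pixel size, um.
#' @slot photonScale expected peak signal photons of one vesicle.
#' @slot bgPhotons expected background photons per pixel.
#' @slot readNoise Gaussian read noise s.d., photons.
#' @slot intensityScale brightness multiplier of the functional-dye channel.
#' @slot seed integer RNG seed; the whole simulation is reproducible from it.
#' @slot burnInFrames unrecorded frames run before frame 0 so tethering and
#'   spatial distribution start near steady state.
#' @slot startTethered if TRUE, particles are placed as tethered pairs at
#'   frame 0 (burn-in is skipped); used for contact-analysis validations
#'   where every frame-0 vesicle must begin in a contact.
#' @slot releaseKickUm separation impulse applied to a pair on tether release
#'   (kiss-and-run-style); keeps measured appositions aligned with tethers.
#' @slot channels channels to render ("lysosome" and/or "dye").
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    nParticles = "integer",
    cellRadiusUm = "numeric",
    nucleusRadiusUm = "numeric",
    diffusionUm2S = "numeric",
    radiusUmRange = "numeric",
    captureDistUm = "numeric",
    pOn = "numeric",
    pOff = "numeric",
    perinuclearBias = "numeric",
    nFrames = "integer",
    dtS = "numeric",
    psfSigmaUm = "numeric",
    pixelSizeUm = "numeric",
    photonScale = "numeric",
    bgPhotons = "numeric",
    readNoise = "numeric",
    intensityScale = "numeric",
    seed = "integer",
    burnInFrames = "integer",
    startTethered = "logical",
    releaseKickUm = "numeric",
    channels = "character"
  ),
  prototype(
    nParticles = 30L,
    cellRadiusUm = 12,
    nucleusRadiusUm = 3.5,
    diffusionUm2S = 0.02,
    radiusUmRange = c(0.05, 0.08),
    captureDistUm = 0.4,
    pOn = 1.0,
    pOff = 0.1,
    perinuclearBias = 0.003,
    nFrames = 91L,
    dtS = 2,
    psfSigmaUm = 0.1,
    pixelSizeUm = 0.1,
    photonScale = 800,
    bgPhotons = 10,
    readNoise = 3,
    intensityScale = 1.0,
    seed = 1L,
    burnInFrames = 50L,
    startTethered = FALSE,
    releaseKickUm = 0.5,
    channels = "lysosome"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- NULL
  if (object@pOn < 0 || object@pOn > 1 || object@pOff < 0 || object@pOff > 1)
    msg <- c(msg, "pOn and pOff must lie in [0, 1]")
  if (object@nucleusRadiusUm >= object@cellRadiusUm)
    msg <- c(msg, "nucleus radius must be smaller than cell radius")
  if (object@nFrames < 2L)
    msg <- c(msg, "nFrames must be >= 2")
  r <- object@radiusUmRange
  if (length(r) != 2L || r[1] <= 0 || r[1] > r[2])
    msg <- c(msg, "radiusUmRange must be (min, max) with 0 < min <= max")
  else if (r[2] > (object@cellRadiusUm - object@nucleusRadiusUm) / 4)
    msg <- c(msg, "particle radii too large for the arena to render sensibly")
  if (object@dtS <= 0 || object@pixelSizeUm <= 0 || object@psfSigmaUm <= 0)
    msg <- c(msg, "dtS, pixelSizeUm and psfSigmaUm must be positive")
  if (object@nParticles < 1L)
    msg <- c(msg, "nParticles must be >= 1")
  if (!all(object@channels %in% c("lysosome", "dye")))
    msg <- c(msg, "channels must be a subset of c('lysosome', 'dye')")
  if (is.null(msg)) TRUE else msg
})

#' Construct a SimulationConfig
#'
#' @param ... named overrides of \linkS4class{SimulationConfig} slots.
#' @return a validated \linkS4class{SimulationConfig}.
#' @seealso [controlRegime()], [kdRegime()] for the two study regimes.
#' @export
simulationConfig <- function(...) {
  args <- list(...)
  ints <- c("nParticles", "nFrames", "seed", "burnInFrames")
  for (nm in intersect(names(args), ints)) args[[nm]] <- as.integer(args[[nm]])
  bad <- setdiff(names(args), slotNames("SimulationConfig"))
  if (length(bad)) stop("unknown simulation parameters: ", paste(bad, collapse = ", "))
  do.call(new, c(list(Class = "SimulationConfig"), args))
}

#' SimulationTruth: ground truth emitted by the simulator
#'
#' @slot positionsUm numeric array \code{[particle, 2 (x, y), frame]}, um.
#' @slot radiiUm per-particle radii, um.
#' @slot tetherIntervals data.frame (particle_i, particle_j, first_frame,
#'   last_frame), maximal and non-overlapping per pair, 0-based frames.
#' @slot geometry the rendered \linkS4class{CellGeometry}.
#' @slot config the generating \linkS4class{SimulationConfig}.
#' @exportClass SimulationTruth
setClass("SimulationTruth",
  representation(
    positionsUm = "array",
    radiiUm = "numeric",
    tetherIntervals = "data.frame",
    geometry = "CellGeometry",
    config = "SimulationConfig"
  )
)

setValidity("SimulationTruth", function(object) {
  msg <- NULL
  d <- dim(object@positionsUm)
  if (length(d) != 3L || d[2] != 2L)
    msg <- c(msg, "positionsUm must be [particle, 2, frame]")
  if (d[1] != length(object@radiiUm))
    msg <- c(msg, "radiiUm must have one entry per particle")
  ti <- object@tetherIntervals
  need <- c("particle_i", "particle_j", "first_frame", "last_frame")
  if (!all(need %in% names(ti)))
    msg <- c(msg, "tetherIntervals must have columns particle_i, particle_j, first_frame, last_frame")
  else if (nrow(ti) && any(ti$first_frame > ti$last_frame))
    msg <- c(msg, "tether intervals must satisfy first_frame <= last_frame")
  if (is.null(msg)) TRUE else msg
})

#' GroupResult: one group comparison
#'
#' Result container of the statistics layer: per-group mean and SEM
#' (sd/sqrt(n) over cells), the test used, its statistic and two-sided
#' p-value, and (for three or more groups) the all-pairs Tukey table.
#'
#' @slot groups group labels.
#' @slot means,sems,n per-group mean, SEM, and number of cells.
#' @slot test test name.
#' @slot statistic test statistic (t or F).
#' @slot pValue two-sided p-value.
#' @slot pairwise Tukey HSD table for >= 3 groups, else NULL.
#' @exportClass GroupResult
setClass("GroupResult",
  representation(
    groups = "character",
    means = "numeric",
    sems = "numeric",
    n = "integer",
    test = "character",
    statistic = "numeric",
    pValue = "numeric",
    pairwise = "data.frameOrNULL"
  )
)

setValidity("GroupResult", function(object) {
  msg <- NULL
  if (length(object@pValue) != 1L || is.na(object@pValue) ||
      object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in [0, 1]")
  k <- length(object@groups)
  if (length(object@means) != k || length(object@sems) != k ||
      length(object@n) != k)
    msg <- c(msg, "means, sems and n must align with groups")
  if (k >= 3L && is.null(object@pairwise))
    msg <- c(msg, "pairwise table must be present for >= 3 groups")
  if (is.null(msg)) TRUE else msg
})
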