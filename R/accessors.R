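# Accessor generics and show methods for the core classes.

#' @name MovieStack-accessors
#' @title Accessors for MovieStack and CellGeometry
#' @param x,object a \linkS4class{MovieStack} or \linkS4class{CellGeometry}.
#' @param frame 1-based frame index.
#' @param channel channel name or 1-based index.
#' @return the requested component; \code{getFrame} returns a numeric matrix.
NULL

#' @rdname MovieStack-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname MovieStack-accessors
#' @export
setGeneric("pixelSizeUm", function(x) standardGeneric("pixelSizeUm"))
#' @rdname MovieStack-accessors
#' @export
setGeneric("frameIntervalS", function(x) standardGeneric("frameIntervalS"))
#' @rdname MovieStack-accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname MovieStack-accessors
#' @export
setGeneric("movieDurationS", function(x) standardGeneric("movieDurationS"))
#' @rdname MovieStack-accessors
#' @export
setGeneric("getFrame", function(x, frame, channel = 1L) standardGeneric("getFrame"))
#' @rdname MovieStack-accessors
#' @export
setGeneric("cellMask", function(x) standardGeneric("cellMask"))
#' @rdname MovieStack-accessors
#' @export
setGeneric("nucleusMask", function(x) standardGeneric("nucleusMask"))

#' @rdname MovieStack-accessors
setMethod("nFrames", "MovieStack", function(x) dim(x@pixels)[3])

#' @rdname MovieStack-accessors
setMethod("pixelSizeUm", "MovieStack", function(x) x@pixelSizeUm)

#' @rdname MovieStack-accessors
setMethod("frameIntervalS", "MovieStack", function(x) x@frameIntervalS)

#' @rdname MovieStack-accessors
setMethod("channelNames", "MovieStack", function(x) x@channelNames)

#' @rdname MovieStack-accessors
setMethod("movieDurationS", "MovieStack",
          function(x) (nFrames(x) - 1L) * x@frameIntervalS)

#' @rdname MovieStack-accessors
setMethod("getFrame", "MovieStack", function(x, frame, channel = 1L) {
  if (is.character(channel)) {
    ch <- match(channel, x@channelNames)
    if (is.na(ch)) stop("no channel named '", channel, "'")
  } else ch <- as.integer(channel)
  if (frame < 1L || frame > nFrames(x)) stop("frame index out of range")
  x@pixels[, , frame, ch]
})

#' @rdname MovieStack-accessors
setMethod("cellMask", "CellGeometry", function(x) x@cellMask)

#' @rdname MovieStack-accessors
setMethod("nucleusMask", "CellGeometry", function(x) x@nucleusMask)

setMethod("show", "MovieStack", function(object) {
  d <- dim(object@pixels)
  cat("MovieStack:", d[1], "x", d[2], "px,", d[3], "frames,",
      d[4], "channel(s) [", paste(object@channelNames, collapse = ", "), "]\n")
  cat("  calibration:", object@pixelSizeUm, "um/px,",
      object@frameIntervalS, "s/frame (", movieDurationS(object), "s )\n")
})

setMethod("show", "CellGeometry", function(object) {
  cat("CellGeometry:", nrow(object@cellMask), "x", ncol(object@cellMask),
      "px; cell", sum(object@cellMask), "px, nucleus",
      sum(object@nucleusMask), "px\n")
})

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig\n")
  cat("  size gate:", object@sizeGateUm[1], "-", object@sizeGateUm[2], "um;",
      "stable contact >=", object@stableContactS, "s; cap", object@movieCapS, "s\n")
  cat("  perinuclear <", object@perinuclearUm, "um; motility window",
      object@motilityWindowS, "s; sample", object@contactSampleN, "contacts\n")
  cat("  threshold:", object@thresholdMethod, "; rolling ball",
      object@rollingBallRadiusPx, "px; link gate", object@linkMaxDispUm,
      "um; contact gap", object@contactGapPx, "px; seed", object@rngSeed, "\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nParticles, "particles,",
      object@nFrames, "frames @", object@dtS, "s\n")
  cat("  arena: cell", object@cellRadiusUm, "um / nucleus",
      object@nucleusRadiusUm, "um; D =", object@diffusionUm2S,
      "um2/s; bias", object@perinuclearBias, "um/s\n")
  cat("  tethering: capture", object@captureDistUm, "um, pOn", object@pOn,
      ", pOff", object@pOff, "\n")
  cat("  rendering:", paste(object@channels, collapse = "+"), "@",
      object@pixelSizeUm, "um/px, PSF sigma", object@psfSigmaUm,
      "um, peak", object@photonScale, "photons; seed", object@seed, "\n")
})

setMethod("show", "SimulationTruth", function(object) {
  d <- dim(object@positionsUm)
  cat("SimulationTruth:", d[1], "particles over", d[3], "frames;",
      nrow(object@tetherIntervals), "tether intervals\n")
})

setMethod("show", "GroupResult", function(object) {
  cat("GroupResult:", object@test, "\n")
  for (i in seq_along(object@groups))
    cat(sprintf("  %s: %.4g +/- %.4g (n = %d)\n", object@groups[i],
                object@means[i], object@sems[i], object@n[i]))
  cat(sprintf("  statistic = %.4g, p = %.4g %s\n", object@statistic,
              object@pValue, significanceStars(object@pValue)))
  if (!is.null(object@pairwise)) {
    cat("  pairwise (Tukey HSD):\n")
    print(object@pairwise, row.names = FALSE)
  }
})
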