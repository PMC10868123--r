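# Vesicle segmentation: background correction, thresholding with
# 8-connected labeling, the physical size gate, and occupancy metrics.

#' Rolling-ball background correction
#'
#' Subtracts the local background estimated by a grayscale morphological
#' opening (the rolling-ball family of background estimators) with a square
#' structuring element of side \code{2 * rollingBallRadiusPx + 1}, computed
#' with an O(n) separable running-minimum/maximum filter (edge-replicated
#' borders). The result is non-negative by construction and leaves an
#' already-flat background at zero.
#'
#' @param frame 2-D intensity matrix.
#' @param config an \linkS4class{AnalysisConfig}; uses
#'   \code{rollingBallRadiusPx}.
#' @return background-subtracted matrix of the same shape.
#' @examples
#' f <- matrix(5, 40, 40); f[18:22, 18:22] <- 105
#' p <- preprocessFrame(f, analysisConfig(rollingBallRadiusPx = 10))
#' max(p)  # the bright object survives; the flat background is removed
#' @export
preprocessFrame <- function(frame, config = analysisConfig()) {
  stopifnot(is.matrix(frame))
  r <- config@rollingBallRadiusPx
  if (2L * r + 1L >= min(dim(frame)))
    stop("rolling-ball radius (", r, " px) too large for a ",
         nrow(frame), "x", ncol(frame), " frame")
  bg <- box_open(frame, r)
  out <- frame - bg
  out[out < 0] <- 0
  out
}

#' Threshold a frame and label vesicle objects
#'
#' Thresholds a (preprocessed) frame — Otsu's method by default, or a fixed
#' threshold — and labels connected components with 8-connectivity. Touching
#' vesicles merge into one object; this is the expected behaviour of
#' connectivity-based labeling on diffraction-limited data and is handled
#' downstream by the tracking layer.
#'
#' @param frame 2-D intensity matrix (background-corrected).
#' @param config an \linkS4class{AnalysisConfig}; uses \code{thresholdMethod}
#'   and \code{fixedThreshold}.
#' @param frameIndex 0-based frame index recorded on each object.
#' @param pixelSizeUm micrometres per pixel, used for equivalent diameters.
#' @return a list with \code{objects} (data.frame: object_id, frame_index,
#'   row0/col0 0-based centroid, area_px, equiv_diameter_um, mean_intensity,
#'   x_um/y_um), \code{labels} (integer matrix), and \code{threshold}.
#' @export
thresholdAndLabel <- function(frame, config = analysisConfig(),
                              frameIndex = 0L, pixelSizeUm = 1) {
  stopifnot(is.matrix(frame))
  mx <- max(frame)
  if (mx <= 0)
    return(list(objects = emptyObjects(), labels = matrix(0L, nrow(frame), ncol(frame)),
                threshold = NA_real_))
  thr <- switch(config@thresholdMethod,
    otsu = EBImage::otsu(EBImage::Image(frame), range = c(0, mx), levels = 256L),
    fixed = config@fixedThreshold)
  binary <- frame > thr
  labels <- labelConnected8(binary)
  n <- max(labels)
  if (n == 0L)
    return(list(objects = emptyObjects(), labels = labels, threshold = thr))
  idx <- which(labels > 0L)
  l <- labels[idx]
  nr <- nrow(frame)
  rows0 <- (idx - 1L) %% nr          # 0-based pixel coordinates
  cols0 <- (idx - 1L) %/% nr
  area <- tabulate(l, nbins = n)
  rowc <- rowsum(rows0, l)[, 1] / area
  colc <- rowsum(cols0, l)[, 1] / area
  mfi <- rowsum(frame[idx], l)[, 1] / area
  objects <- data.frame(
    object_id = seq_len(n),
    frame_index = as.integer(frameIndex),
    row0 = rowc, col0 = colc,
    area_px = as.integer(area),
    equiv_diameter_um = pixelSizeUm * 2 * sqrt(area / pi),
    mean_intensity = mfi,
    x_um = colc * pixelSizeUm,
    y_um = rowc * pixelSizeUm)
  list(objects = objects, labels = labels, threshold = thr)
}

#' Size-gate detected objects
#'
#' Keeps objects whose equivalent circular diameter lies in the closed
#' interval \code{[dMin, dMax]} (both ends inclusive); order is preserved
#' and the operation is idempotent.
#'
#' @param objects object data.frame from [thresholdAndLabel()].
#' @param dMin,dMax gate bounds in micrometres (defaults 0.1 and 2).
#' @return the gated subset of \code{objects}.
#' @export
filterBySize <- function(objects, dMin = 0.1, dMax = 2.0) {
  stopifnot(dMin < dMax)
  objects[objects$equiv_diameter_um >= dMin &
          objects$equiv_diameter_um <= dMax, , drop = FALSE]
}

#' Percent of cell area occupied by vesicles
#'
#' 100 times the number of object pixels inside the cell mask divided by the
#' cell-mask area; depends only on the binary, so it is invariant to any
#' intensity rescaling of the underlying image.
#'
#' @param labels integer label matrix from [thresholdAndLabel()].
#' @param cellMask logical matrix (non-empty).
#' @param objectIds which labels count as objects (default: all, i.e. the
#'   gated ids should be passed after size filtering).
#' @return percent in \code{[0, 100]}.
#' @export
areaFraction <- function(labels, cellMask, objectIds = NULL) {
  stopifnot(identical(dim(labels), dim(cellMask)))
  if (!any(cellMask)) stop("empty cell mask")
  inObj <- if (is.null(objectIds)) labels > 0L else
    array(labels %in% objectIds & labels > 0L, dim(labels))
  100 * sum(inObj & cellMask) / sum(cellMask)
}

#' Mean vesicle size with a histogram companion
#'
#' Arithmetic mean of the gated equivalent diameters, plus fixed-bin
#' histogram counts for size-distribution plots.
#'
#' @param objects gated object data.frame (>= 1 row).
#' @param binEdgesUm fixed histogram bin edges, um.
#' @return list(mean_um, histogram = data.frame(bin_low, bin_high, count)).
#' @export
meanObjectSize <- function(objects, binEdgesUm = seq(0, 2, by = 0.1)) {
  if (nrow(objects) == 0L)
    stop("mean object size is undefined for an empty object set")
  d <- objects$equiv_diameter_um
  counts <- hist(pmin(d, max(binEdgesUm)), breaks = binEdgesUm, plot = FALSE,
                 right = FALSE)$counts
  list(mean_um = mean(d),
       histogram = data.frame(bin_low = head(binEdgesUm, -1),
                              bin_high = binEdgesUm[-1], count = counts))
}

#' Detect and gate objects across a movie channel
#'
#' Runs preprocess -> threshold -> 8-connected label -> size gate on every
#' frame of one channel; when geometry is given, objects whose centroid lies
#' outside the cell mask are dropped.
#'
#' @param movie a \linkS4class{MovieStack}.
#' @param channel channel name or index.
#' @param config an \linkS4class{AnalysisConfig}.
#' @param geometry optional \linkS4class{CellGeometry}.
#' @return list with \code{objectsByFrame} (list of gated object
#'   data.frames, one per frame, 0-based frame_index), \code{labelsByFrame}
#'   (integer label matrices), and \code{thresholds}.
#' @export
detectObjects <- function(movie, channel = "lysosome",
                          config = analysisConfig(), geometry = NULL) {
  stopifnot(is(movie, "MovieStack"))
  px <- pixelSizeUm(movie)
  nT <- nFrames(movie)
  objectsByFrame <- vector("list", nT)
  labelsByFrame <- vector("list", nT)
  thresholds <- numeric(nT)
  for (t in seq_len(nT)) {
    fr <- preprocessFrame(getFrame(movie, t, channel), config)
    seg <- thresholdAndLabel(fr, config, frameIndex = t - 1L, pixelSizeUm = px)
    obj <- filterBySize(seg$objects, config@sizeGateUm[1], config@sizeGateUm[2])
    if (!is.null(geometry) && nrow(obj)) {
      cm <- cellMask(geometry)
      keep <- cm[cbind(pmin(pmax(round(obj$row0) + 1, 1), nrow(cm)),
                       pmin(pmax(round(obj$col0) + 1, 1), ncol(cm)))]
      obj <- obj[keep, , drop = FALSE]
    }
    objectsByFrame[[t]] <- obj
    labelsByFrame[[t]] <- seg$labels
    thresholds[t] <- if (is.null(seg$threshold)) NA_real_ else seg$threshold
  }
  list(objectsByFrame = objectsByFrame, labelsByFrame = labelsByFrame,
       thresholds = thresholds)
}
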