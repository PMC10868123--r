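# Intensity-based functional readouts: dye puncta density and mean
# fluorescence intensity, colocalization metrics, and PLA quantification.

#' Functional-dye puncta metrics
#'
#' Segments a dye frame with the standard pipeline (rolling-ball background
#' correction, threshold, 8-connected labeling, 0.1-2 um size gate), keeps
#' puncta whose centroid lies inside the cell mask, and reports the puncta
#' density per um^2 of cell area and the mean of per-object mean
#' fluorescence intensities (MFI, on the background-corrected frame).
#'
#' @param dyeFrame 2-D intensity matrix of the dye channel.
#' @param geometry a \linkS4class{CellGeometry} with a non-empty cell mask.
#' @param config an \linkS4class{AnalysisConfig}.
#' @param pixelSizeUm micrometres per pixel.
#' @return list(puncta_per_um2, mfi, n_puncta); \code{mfi} is NA (with a
#'   warning) when no puncta are found.
#' @export
punctaMetrics <- function(dyeFrame, geometry, config = analysisConfig(),
                          pixelSizeUm) {
  cm <- cellMask(geometry)
  if (!any(cm)) stop("empty cell mask")
  stopifnot(identical(dim(dyeFrame), dim(cm)))
  fr <- preprocessFrame(dyeFrame, config)
  seg <- thresholdAndLabel(fr, config, pixelSizeUm = pixelSizeUm)
  obj <- filterBySize(seg$objects, config@sizeGateUm[1], config@sizeGateUm[2])
  if (nrow(obj)) {
    keep <- cm[cbind(pmin(pmax(round(obj$row0) + 1, 1), nrow(cm)),
                     pmin(pmax(round(obj$col0) + 1, 1), ncol(cm)))]
    obj <- obj[keep, , drop = FALSE]
  }
  areaUm2 <- sum(cm) * pixelSizeUm^2
  if (nrow(obj) == 0L) {
    warning("no puncta detected; MFI is undefined")
    return(list(puncta_per_um2 = 0, mfi = NA_real_, n_puncta = 0L))
  }
  list(puncta_per_um2 = nrow(obj) / areaUm2,
       mfi = mean(obj$mean_intensity),
       n_puncta = nrow(obj))
}

#' Pixel-wise Pearson colocalization
#'
#' Pearson correlation coefficient of two channels over the pixels of the
#' cell mask; invariant to positive affine rescaling of either channel.
#'
#' @param chanA,chanB intensity matrices of one shape.
#' @param cellMask logical matrix restricting the computation.
#' @return r in \code{[-1, 1]}.
#' @export
pearsonColoc <- function(chanA, chanB, cellMask) {
  stopifnot(identical(dim(chanA), dim(chanB)),
            identical(dim(chanA), dim(cellMask)))
  a <- chanA[cellMask]; b <- chanB[cellMask]
  if (length(a) < 2L) stop("need at least two mask pixels")
  if (sd(a) == 0 || sd(b) == 0)
    stop("Pearson colocalization undefined: zero variance in a channel")
  cor(a, b)
}

#' Object-based colocalization fraction
#'
#' Percent of objects in channel A with at least one pixel overlapping the
#' channel-B binary.
#'
#' @param objects gated object data.frame of channel A.
#' @param labels label matrix of channel A.
#' @param binaryB logical matrix of the partner channel.
#' @return percent in \code{[0, 100]}.
#' @export
objectColocFraction <- function(objects, labels, binaryB) {
  stopifnot(identical(dim(labels), dim(binaryB)))
  if (nrow(objects) == 0L) stop("no objects: colocalization fraction undefined")
  hit <- sort(unique(labels[labels > 0L & binaryB]))
  100 * mean(objects$object_id %in% hit)
}

#' Quantify PLA puncta per cell
#'
#' Maximum-intensity-projects a PLA z-stack, segments puncta with the PLA
#' size gate, counts nuclei from a DAPI projection (Otsu threshold,
#' 8-connected components, minimum-area gate) or accepts a given count,
#' and reports puncta and puncta area per nucleus, plus the fold change
#' relative to a control mean when one is supplied. A control group
#' normalized to its own mean therefore has mean fold change exactly 1.
#'
#' @param zstackPla 3-D array \code{[row, col, z]} of the PLA channel (a
#'   matrix is treated as an already-projected image).
#' @param zstackDapiOrCount DAPI z-stack/projection, or a single nucleus
#'   count.
#' @param config an \linkS4class{AnalysisConfig}; uses \code{plaSizeGateUm}
#'   and \code{minNucleusAreaUm2}.
#' @param pixelSizeUm micrometres per pixel.
#' @param controlMean optional control-group mean of \code{puncta_per_cell}
#'   (> 0) for fold-change reporting.
#' @return list(puncta_count, puncta_total_area_um2, nuclei_count,
#'   puncta_per_cell, area_per_cell, fold_change_vs_control).
#' @export
plaQuantify <- function(zstackPla, zstackDapiOrCount,
                        config = analysisConfig(), pixelSizeUm,
                        controlMean = NULL) {
  mip <- function(z) if (is.matrix(z)) z else apply(z, c(1, 2), max)
  pla <- mip(zstackPla)
  if (is.numeric(zstackDapiOrCount) && length(zstackDapiOrCount) == 1L) {
    nuclei <- as.integer(zstackDapiOrCount)
  } else {
    dapi <- mip(zstackDapiOrCount)
    stopifnot(identical(dim(dapi), dim(pla)))
    seg <- thresholdAndLabel(preprocessFrame(dapi, config), config,
                             pixelSizeUm = pixelSizeUm)
    keep <- seg$objects$area_px * pixelSizeUm^2 >= config@minNucleusAreaUm2
    nuclei <- sum(keep)
  }
  if (nuclei < 1L) stop("zero nuclei: per-cell PLA ratios undefined")
  seg <- thresholdAndLabel(preprocessFrame(pla, config), config,
                           pixelSizeUm = pixelSizeUm)
  obj <- filterBySize(seg$objects, config@plaSizeGateUm[1],
                      config@plaSizeGateUm[2])
  count <- nrow(obj)
  areaUm2 <- sum(obj$area_px) * pixelSizeUm^2
  fold <- NA_real_
  if (!is.null(controlMean)) {
    if (controlMean <= 0) stop("controlMean must be positive")
    fold <- (count / nuclei) / controlMean
  }
  list(puncta_count = count,
       puncta_total_area_um2 = areaUm2,
       nuclei_count = nuclei,
       puncta_per_cell = count / nuclei,
       area_per_cell = areaUm2 / nuclei,
       fold_change_vs_control = fold)
}
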