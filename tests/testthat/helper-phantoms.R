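# Phantom builders shared across tests: all fixtures are generated in code.

# Logical disk mask on a side x side grid (0-based pixel-centre geometry).
diskMask <- function(side, centerPx, radiusPx) {
  xs <- seq_len(side) - 1
  dd <- sqrt(outer((xs - centerPx[1])^2, (xs - centerPx[2])^2, "+"))
  dd <= radiusPx
}

# Synthetic per-frame object tables from a list of (x_um, y_um) matrices,
# bypassing rendering; object ids are row numbers.
objectsFromPoints <- function(pointsByFrame, pixelSizeUm = 0.1,
                              diameterUm = 0.3, areasByFrame = NULL) {
  lapply(seq_along(pointsByFrame), function(t) {
    p <- pointsByFrame[[t]]
    if (is.null(p) || nrow(p) == 0L) return(LysoDynamics:::emptyObjects())
    areas <- if (is.null(areasByFrame)) rep(9L, nrow(p)) else areasByFrame[[t]]
    data.frame(object_id = seq_len(nrow(p)), frame_index = t - 1L,
               row0 = p[, 2] / pixelSizeUm, col0 = p[, 1] / pixelSizeUm,
               area_px = areas, equiv_diameter_um = diameterUm,
               mean_intensity = 100,
               x_um = p[, 1], y_um = p[, 2])
  })
}

# Label matrices with square objects painted at integer pixel positions:
# squares is a list (one per frame) of data.frames (row, col, half, id).
labelsFromSquares <- function(side, squaresByFrame) {
  lapply(squaresByFrame, function(sq) {
    lab <- matrix(0L, side, side)
    if (!is.null(sq)) for (k in seq_len(nrow(sq))) {
      rr <- (sq$row[k] - sq$half[k]):(sq$row[k] + sq$half[k])
      cc <- (sq$col[k] - sq$half[k]):(sq$col[k] + sq$half[k])
      lab[rr, cc] <- sq$id[k]
    }
    lab
  })
}

# Brute-force per-frame contact scan used as the oracle for event building:
# returns, for a pair of label ids, the sorted frames in which their pixel
# sets overlap or lie within Chebyshev distance gap + 1.
bruteContactFrames <- function(labelsByFrame, idA, idB, gapPx) {
  frames <- integer(0)
  for (t in seq_along(labelsByFrame)) {
    lab <- labelsByFrame[[t]]
    pa <- which(lab == idA, arr.ind = TRUE)
    pb <- which(lab == idB, arr.ind = TRUE)
    if (!nrow(pa) || !nrow(pb)) next
    ch <- min(pmax(abs(outer(pa[, 1], pb[, 1], "-")),
                   abs(outer(pa[, 2], pb[, 2], "-"))))
    if (ch <= gapPx + 1) frames <- c(frames, t - 1L)
  }
  frames
}
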