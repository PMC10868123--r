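# Frame-to-frame linking of detections into tracks, motility metrics,
# and kymograph extraction.

BIG_COST <- 1e9

# One-to-one gated assignment between two point sets (um coordinates).
# Returns an integer vector: for each row of `from`, the matched row of
# `to`, or NA when no feasible partner was assigned.
assignPoints <- function(fromXY, toXY, gateUm) {
  nf <- nrow(fromXY); nt <- nrow(toXY)
  if (nf == 0L || nt == 0L) return(rep(NA_integer_, nf))
  d <- sqrt(outer(fromXY[, 1], toXY[, 1], "-")^2 +
            outer(fromXY[, 2], toXY[, 2], "-")^2)
  cost <- ifelse(d <= gateUm, d, BIG_COST)
  if (nf <= nt) {
    a <- hungarian_assign(cost)
    a[cost[cbind(seq_len(nf), a)] >= BIG_COST] <- NA_integer_
    a
  } else {
    b <- hungarian_assign(t(cost))
    a <- rep(NA_integer_, nf)
    ok <- cost[cbind(b, seq_len(nt))] < BIG_COST
    a[b[ok]] <- which(ok)
    a
  }
}

#' Link per-frame detections into tracks
#'
#' Minimum-total-distance one-to-one linking (Hungarian algorithm) between
#' consecutive frames, with a hard displacement gate; unlinkable objects
#' start new tracks and there is no gap closing, so a one-frame disappearance
#' splits a track. A track that loses the one-to-one competition but still
#' lies within the gate of an assigned object continues as a \emph{shared}
#' occupant of that object: this carries both identities through the frames
#' in which two touching vesicles are segmented as one connected component,
#' and lets them re-separate when the component splits again.
#'
#' @param objectsByFrame list (one entry per frame) of gated object
#'   data.frames with columns \code{object_id}, \code{x_um}, \code{y_um}.
#' @param config an \linkS4class{AnalysisConfig}; uses \code{linkMaxDispUm}.
#' @return data.frame (track_id, frame, object_id, x_um, y_um, shared) with
#'   0-based frames; each (frame, object) has exactly one non-shared row.
#' @export
linkTracks <- function(objectsByFrame, config = analysisConfig()) {
  gate <- config@linkMaxDispUm
  nT <- length(objectsByFrame)
  out <- vector("list", nT)
  nextId <- 1L
  objArea <- function(obj) if ("area_px" %in% names(obj)) obj$area_px else
    rep(NA_real_, nrow(obj))
  # active tracks: id, x, y, area and id of the occupied object
  obj0 <- objectsByFrame[[1]]
  act <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                    area = numeric(0), oid = integer(0))
  if (!is.null(obj0) && nrow(obj0)) {
    act <- data.frame(id = seq_len(nrow(obj0)), x = obj0$x_um, y = obj0$y_um,
                      area = objArea(obj0), oid = obj0$object_id)
    nextId <- nrow(obj0) + 1L
    out[[1]] <- data.frame(track_id = act$id, frame = 0L,
                           object_id = obj0$object_id,
                           x_um = obj0$x_um, y_um = obj0$y_um, shared = FALSE)
  }
  if (nT >= 2L) for (t in 2:nT) {
    obj <- objectsByFrame[[t]]
    nob <- if (is.null(obj)) 0L else nrow(obj)
    rows <- NULL
    if (nrow(act) && nob) {
      a <- assignPoints(cbind(act$x, act$y), cbind(obj$x_um, obj$y_um), gate)
      # a loser may continue as a shared occupant of a neighbour's object,
      # but only when that is plausibly a segmentation merge: the two
      # tracks were within the merge range in the previous frame, and the
      # candidate object is large enough to be their fusion
      lost <- which(is.na(a))
      if (length(lost)) {
        area <- objArea(obj)
        for (li in lost) {
          d <- sqrt((act$x[li] - obj$x_um)^2 + (act$y[li] - obj$y_um)^2)
          for (o in order(d)) {         # candidates by distance
            if (d[o] > gate) break
            w <- which(a == o)[1]       # primary occupant of the candidate
            if (!is.na(w)) {
              if (act$oid[li] == act$oid[w]) { a[li] <- o; break }  # ongoing merge
              dPrev <- sqrt((act$x[li] - act$x[w])^2 + (act$y[li] - act$y[w])^2)
              fused <- is.na(area[o]) || is.na(act$area[li]) || is.na(act$area[w]) ||
                area[o] >= 0.55 * (act$area[li] + act$area[w])
              if (dPrev <= config@mergeAttachUm && fused) { a[li] <- o; break }
            } else if (d[o] <= config@mergeAttachUm) { a[li] <- o; break }
          }
        }
      }
      keep <- !is.na(a)
      shared <- logical(length(a))
      shared[keep] <- duplicated(a[keep]) | rev(duplicated(rev(a[keep])))
      # primary occupant = the Hungarian winner (first non-lost per object)
      primary <- rep(FALSE, length(a))
      if (any(keep)) {
        winners <- setdiff(which(keep), lost)
        primary[winners] <- TRUE
      }
      rows <- data.frame(track_id = act$id[keep], frame = t - 1L,
                         object_id = obj$object_id[a[keep]],
                         x_um = obj$x_um[a[keep]], y_um = obj$y_um[a[keep]],
                         shared = shared[keep] & !primary[keep])
      act <- data.frame(id = act$id[keep],
                        x = obj$x_um[a[keep]], y = obj$y_um[a[keep]],
                        area = objArea(obj)[a[keep]],
                        oid = obj$object_id[a[keep]])
      unassigned <- setdiff(seq_len(nob), a[keep & primary])
      unassigned <- unassigned[!unassigned %in% a[keep]]
    } else {
      act <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                        area = numeric(0), oid = integer(0))
      unassigned <- seq_len(nob)
    }
    if (length(unassigned)) {
      ids <- seq.int(nextId, length.out = length(unassigned))
      nextId <- nextId + length(unassigned)
      rows <- rbind(rows, data.frame(track_id = ids, frame = t - 1L,
                                     object_id = obj$object_id[unassigned],
                                     x_um = obj$x_um[unassigned],
                                     y_um = obj$y_um[unassigned],
                                     shared = FALSE))
      act <- rbind(act, data.frame(id = ids, x = obj$x_um[unassigned],
                                   y = obj$y_um[unassigned],
                                   area = objArea(obj)[unassigned],
                                   oid = obj$object_id[unassigned]))
    }
    out[[t]] <- rows
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(track_id = integer(0), frame = integer(0),
                                      object_id = integer(0), x_um = numeric(0),
                                      y_um = numeric(0), shared = logical(0))
  res[order(res$track_id, res$frame), , drop = FALSE]
}

#' Summarize tracks
#'
#' @param trackTable output of [linkTracks()].
#' @param dtS frame interval, seconds.
#' @return data.frame (track_id, first_frame, last_frame, n_frames,
#'   duration_s, path_length_um, displacement_um); duration is elapsed time
#'   \code{(last - first) * dt} and path length is the cumulative step sum,
#'   so \code{path_length_um >= displacement_um} always.
#' @export
trackSummaries <- function(trackTable, dtS) {
  if (nrow(trackTable) == 0L)
    return(data.frame(track_id = integer(0), first_frame = integer(0),
                      last_frame = integer(0), n_frames = integer(0),
                      duration_s = numeric(0), path_length_um = numeric(0),
                      displacement_um = numeric(0)))
  sp <- split(trackTable, trackTable$track_id)
  res <- lapply(sp, function(tr) {
    steps <- if (nrow(tr) > 1L)
      sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2) else numeric(0)
    data.frame(track_id = tr$track_id[1],
               first_frame = tr$frame[1],
               last_frame = tr$frame[nrow(tr)],
               n_frames = nrow(tr),
               duration_s = (tr$frame[nrow(tr)] - tr$frame[1]) * dtS,
               path_length_um = sum(steps),
               displacement_um = sqrt((tr$x_um[nrow(tr)] - tr$x_um[1])^2 +
                                      (tr$y_um[nrow(tr)] - tr$y_um[1])^2))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Motility metrics on qualifying tracks
#'
#' Restricts to tracks of duration at least the motility window (60 s by
#' default, i.e. 31 frames at 2 s), then reports the distance travelled in
#' the first window — cumulative path length, not net displacement — and the
#' mean speed (full-track path length over full-track duration).
#'
#' @param trackTable output of [linkTracks()].
#' @param config an \linkS4class{AnalysisConfig}; uses
#'   \code{motilityWindowS}.
#' @param dtS frame interval, seconds.
#' @return data.frame (track_id, distance_60s_um, mean_speed_um_s,
#'   duration_s); zero rows (with a warning) when no track qualifies.
#' @export
motilityMetrics <- function(trackTable, config = analysisConfig(), dtS) {
  win <- config@motilityWindowS
  nsteps <- round(win / dtS)
  sp <- split(trackTable, trackTable$track_id)
  res <- lapply(sp, function(tr) {
    dur <- (tr$frame[nrow(tr)] - tr$frame[1]) * dtS
    if (dur < win) return(NULL)
    steps <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
    data.frame(track_id = tr$track_id[1],
               distance_60s_um = sum(steps[seq_len(nsteps)]),
               mean_speed_um_s = sum(steps) / dur,
               duration_s = dur)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    warning("no tracks meet the ", win, " s motility window")
    return(data.frame(track_id = integer(0), distance_60s_um = numeric(0),
                      mean_speed_um_s = numeric(0), duration_s = numeric(0)))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Kymograph along a polyline
#'
#' Samples the movie at 1-pixel steps along a polyline; each kymograph row is
#' one frame, each column one position, and the value is the maximum
#' intensity across a perpendicular band of width \code{widthPx}.
#'
#' @param movie a \linkS4class{MovieStack}.
#' @param polylinePx numeric matrix of 0-based (row, col) vertices.
#' @param widthPx odd band width in pixels.
#' @param channel channel name or index.
#' @return numeric matrix \code{[frame, position]}.
#' @export
kymograph <- function(movie, polylinePx, widthPx = 3L, channel = 1L) {
  stopifnot(is.matrix(polylinePx), ncol(polylinePx) == 2L, nrow(polylinePx) >= 2L)
  if (widthPx %% 2L != 1L) stop("widthPx must be odd")
  d <- dim(movie@pixels)
  if (any(polylinePx[, 1] < 0) || any(polylinePx[, 1] > d[1] - 1) ||
      any(polylinePx[, 2] < 0) || any(polylinePx[, 2] > d[2] - 1))
    stop("polyline lies outside the frame bounds")
  # sample points at ~1 px arc-length steps, with unit normals
  pts <- NULL; nrm <- NULL
  for (k in seq_len(nrow(polylinePx) - 1L)) {
    p0 <- polylinePx[k, ]; p1 <- polylinePx[k + 1L, ]
    seg <- p1 - p0
    len <- sqrt(sum(seg^2))
    nstep <- max(1L, ceiling(len))
    tt <- seq(0, 1, length.out = nstep + 1L)
    if (k > 1L) tt <- tt[-1]
    pp <- cbind(p0[1] + tt * seg[1], p0[2] + tt * seg[2])
    nn <- matrix(rep(c(-seg[2], seg[1]) / len, each = nrow(pp)), ncol = 2)
    pts <- rbind(pts, pp); nrm <- rbind(nrm, nn)
  }
  half <- (widthPx - 1L) / 2L
  offs <- seq(-half, half)
  nT <- nFrames(movie)
  out <- matrix(0, nT, nrow(pts))
  for (t in seq_len(nT)) {
    fr <- getFrame(movie, t, channel)
    acc <- matrix(-Inf, nrow(pts), length(offs))
    for (oi in seq_along(offs)) {
      rr <- pts[, 1] + offs[oi] * nrm[, 1]
      cc <- pts[, 2] + offs[oi] * nrm[, 2]
      acc[, oi] <- bilinearAt(fr, rr, cc)
    }
    out[t, ] <- apply(acc, 1, max)
  }
  out
}
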