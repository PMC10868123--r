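# Inter-organelle contact detection: per-frame contact of tracked vesicle
# pairs, maximal contact runs, right-censored minimum durations, the
# frame-0 stability fraction, and cross-channel contact fractions.

# Label pairs whose pixel sets overlap or are 8-adjacent within a gap of
# `gapPx` background pixels, i.e. min Chebyshev distance <= gapPx + 1.
objectAdjacencyPairs <- function(labels, gapPx = 1L) {
  n <- max(labels)
  if (n < 2L) return(matrix(integer(0), 0, 2))
  idx <- which(labels > 0L)
  l <- labels[idx]
  nr <- nrow(labels)
  rows <- (idx - 1L) %% nr
  cols <- (idx - 1L) %/% nr
  reach <- gapPx + 1L
  bb <- cbind(rmin = tapply(rows, l, min), rmax = tapply(rows, l, max),
              cmin = tapply(cols, l, min), cmax = tapply(cols, l, max))
  coords <- split(data.frame(r = rows, c = cols), l)
  out <- NULL
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (bb[i, "rmin"] > bb[j, "rmax"] + reach || bb[j, "rmin"] > bb[i, "rmax"] + reach ||
        bb[i, "cmin"] > bb[j, "cmax"] + reach || bb[j, "cmin"] > bb[i, "cmax"] + reach)
      next
    ci <- coords[[i]]; cj <- coords[[j]]
    dr <- abs(outer(ci$r, cj$r, "-"))
    dc <- abs(outer(ci$c, cj$c, "-"))
    if (min(pmax(dr, dc)) <= reach) out <- rbind(out, c(i, j))
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# Turn a sorted vector of frames into maximal runs of consecutive frames.
framesToRuns <- function(frames) {
  frames <- sort(unique(frames))
  breaks <- c(0L, which(diff(frames) > 1L), length(frames))
  data.frame(first = frames[head(breaks, -1) + 1L],
             last = frames[breaks[-1]])
}

#' Detect lysosome-lysosome contact events
#'
#' A tracked pair is in contact in a frame when their objects' pixel sets
#' overlap or are 8-adjacent within the configured gap tolerance, or when
#' the two tracks momentarily occupy the same connected component (a
#' segmentation merge of touching vesicles). Maximal contiguous runs of
#' contact frames become events; an event reaching the final frame is
#' flagged censored. The reported minimum duration credits a contact seen in
#' k consecutive frames with k*dt of tethering, clipped at the censoring cap
#' (so a full 91-frame movie at 2 s is categorized as 180 s).
#'
#' @param objectsByFrame,labelsByFrame per-frame gated objects and label
#'   matrices from [detectObjects()].
#' @param trackTable output of [linkTracks()].
#' @param config an \linkS4class{AnalysisConfig}; uses \code{contactGapPx},
#'   \code{movieCapS}.
#' @param dtS frame interval, seconds.
#' @return data.frame (member_a, member_b, first_frame, last_frame,
#'   censored, min_duration_s); frames 0-based, member_a < member_b.
#' @export
detectPairContacts <- function(objectsByFrame, labelsByFrame, trackTable,
                               config = analysisConfig(), dtS) {
  nT <- length(objectsByFrame)
  if (nrow(trackTable) == 0L) return(emptyEvents())
  gap <- config@contactGapPx
  byFrame <- split(trackTable, trackTable$frame)
  pairFrames <- new.env(hash = TRUE, parent = emptyenv())
  addPair <- function(a, b, fr) {
    key <- paste0(min(a, b), "_", max(a, b))
    pairFrames[[key]] <- c(pairFrames[[key]], fr)
  }
  for (t in seq_len(nT)) {
    tt <- byFrame[[as.character(t - 1L)]]
    if (is.null(tt) || nrow(tt) < 2L) next
    # same-object occupancy (merged vesicles)
    occ <- split(tt$track_id, tt$object_id)
    for (g in occ) if (length(g) >= 2L) {
      cmb <- combn(sort(g), 2L)
      for (k in seq_len(ncol(cmb))) addPair(cmb[1, k], cmb[2, k], t - 1L)
    }
    # adjacency between distinct objects holding tracked vesicles
    adj <- objectAdjacencyPairs(labelsByFrame[[t]], gap)
    if (nrow(adj)) {
      tracked <- unique(tt$object_id)
      for (k in seq_len(nrow(adj))) {
        oi <- adj[k, 1]; oj <- adj[k, 2]
        if (!(oi %in% tracked) || !(oj %in% tracked)) next
        for (a in tt$track_id[tt$object_id == oi])
          for (b in tt$track_id[tt$object_id == oj]) addPair(a, b, t - 1L)
      }
    }
  }
  keys <- ls(pairFrames)
  if (!length(keys)) return(emptyEvents())
  res <- lapply(keys, function(key) {
    ab <- as.integer(strsplit(key, "_", fixed = TRUE)[[1]])
    runs <- framesToRuns(pairFrames[[key]])
    data.frame(member_a = ab[1], member_b = ab[2],
               first_frame = runs$first, last_frame = runs$last)
  })
  ev <- do.call(rbind, res)
  ev$censored <- ev$last_frame == nT - 1L
  ev$min_duration_s <- pmin((ev$last_frame - ev$first_frame + 1L) * dtS,
                            config@movieCapS)
  ev <- ev[order(ev$member_a, ev$member_b, ev$first_frame), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Fraction of frame-0 lysosomes in stable contacts
#'
#' Percentage of lysosomes present at t = 0 that belong to at least one
#' contact event starting at frame 0 and remaining in contact for at least
#' the stability cutoff of elapsed time (default 10 s, i.e. still in contact
#' at the fifth subsequent 2-s frame).
#'
#' @param events contact events from [detectPairContacts()].
#' @param trackTable output of [linkTracks()].
#' @param config an \linkS4class{AnalysisConfig}; uses \code{stableContactS}.
#' @param dtS frame interval, seconds.
#' @return percent in \code{[0, 100]}.
#' @export
stableContactFraction <- function(events, trackTable,
                                  config = analysisConfig(), dtS) {
  present0 <- unique(trackTable$track_id[trackTable$frame == 0L])
  if (!length(present0)) stop("no lysosomes present at frame 0")
  stable <- events[events$first_frame == 0L &
                   (events$last_frame - events$first_frame) * dtS >=
                     config@stableContactS, , drop = FALSE]
  inStable <- unique(c(stable$member_a, stable$member_b))
  100 * length(intersect(present0, inStable)) / length(present0)
}

#' Randomly sample frame-0 contacts for duration monitoring
#'
#' Among events that already existed at t = 0, draws a uniform random sample
#' without replacement of at most \code{contactSampleN} (default five)
#' events; deterministic for a given \code{rngSeed}.
#'
#' @param events contact events from [detectPairContacts()].
#' @param config an \linkS4class{AnalysisConfig}; uses \code{contactSampleN}
#'   and \code{rngSeed}.
#' @return data.frame (min_duration_s, censored), one row per sampled event.
#' @export
sampleMinDurations <- function(events, config = analysisConfig()) {
  elig <- events[events$first_frame == 0L, , drop = FALSE]
  n <- nrow(elig)
  if (n == 0L)
    return(data.frame(min_duration_s = numeric(0), censored = logical(0)))
  k <- min(config@contactSampleN, n)
  pick <- withSeed(config@rngSeed, sample.int(n, k))
  data.frame(min_duration_s = elig$min_duration_s[pick],
             censored = elig$censored[pick])
}

#' Cross-channel contact fraction and events
#'
#' Percent of gated lysosomes whose pixel set overlaps the partner-channel
#' binary (strict overlap, no adjacency tolerance), computed per frame and
#' averaged over frames; when tracks are supplied, contiguous per-track
#' overlap runs are additionally returned as contact events with the same
#' duration and censoring conventions as lysosome-lysosome contacts.
#'
#' @param objectsByFrame,labelsByFrame per-frame gated objects and label
#'   matrices of the lysosome channel.
#' @param partnerBinaryByFrame a logical matrix (static partner mask) or a
#'   list of logical matrices, one per frame.
#' @param trackTable optional output of [linkTracks()].
#' @param config an \linkS4class{AnalysisConfig}.
#' @param dtS frame interval, seconds.
#' @return list(percent, events).
#' @export
crossChannelContactFraction <- function(objectsByFrame, labelsByFrame,
                                        partnerBinaryByFrame,
                                        trackTable = NULL,
                                        config = analysisConfig(), dtS = NULL) {
  nT <- length(objectsByFrame)
  static <- is.matrix(partnerBinaryByFrame)
  getPartner <- function(t) if (static) partnerBinaryByFrame else partnerBinaryByFrame[[t]]
  perFrame <- rep(NA_real_, nT)
  overlapByFrame <- vector("list", nT)
  for (t in seq_len(nT)) {
    obj <- objectsByFrame[[t]]
    if (is.null(obj) || nrow(obj) == 0L) next
    pb <- getPartner(t)
    if (!identical(dim(pb), dim(labelsByFrame[[t]])))
      stop("partner binary shape does not match the movie frames")
    lab <- labelsByFrame[[t]]
    hit <- sort(unique(lab[lab > 0L & pb]))
    ov <- obj$object_id %in% hit
    perFrame[t] <- 100 * mean(ov)
    overlapByFrame[[t]] <- obj$object_id[ov]
  }
  events <- emptyEvents()
  if (!is.null(trackTable) && nrow(trackTable)) {
    stopifnot(!is.null(dtS))
    tr <- trackTable
    key <- paste0(tr$frame, "_", tr$object_id)
    ovKey <- unlist(lapply(seq_len(nT), function(t) {
      ids <- overlapByFrame[[t]]
      if (length(ids)) paste0(t - 1L, "_", ids) else character(0)
    }))
    tr <- tr[key %in% ovKey, , drop = FALSE]
    if (nrow(tr)) {
      sp <- split(tr$frame, tr$track_id)
      res <- lapply(names(sp), function(id) {
        runs <- framesToRuns(sp[[id]])
        data.frame(member_a = as.integer(id), member_b = NA_integer_,
                   first_frame = runs$first, last_frame = runs$last)
      })
      events <- do.call(rbind, res)
      events$censored <- events$last_frame == nT - 1L
      events$min_duration_s <- pmin(
        (events$last_frame - events$first_frame + 1L) * dtS, config@movieCapS)
    }
  }
  list(percent = mean(perFrame, na.rm = TRUE), events = events)
}
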