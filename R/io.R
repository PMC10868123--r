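# Readers and writers: multi-page TIFF movies (16-bit, channel-interleaved
# pages), TIFF/PNG masks, YAML analysis configuration, JSON ground truth.

#' Read a multi-page TIFF movie
#'
#' Pages are interpreted frame-major with channels interleaved within each
#' frame (ch1, ch2, ch1, ch2, ...). Calibration is never guessed: pixel
#' size and frame interval must be supplied explicitly and override any
#' file metadata (a mismatch with TIFF resolution metadata, when present,
#' only emits a warning — imaging metadata is unreliable).
#'
#' @param path TIFF file.
#' @param pixelSizeUm,frameIntervalS physical calibration (required).
#' @param channelNames channel role labels; their number fixes the
#'   interleaving.
#' @return a \linkS4class{MovieStack}.
#' @export
readMovie <- function(path, pixelSizeUm, frameIntervalS,
                      channelNames = "lysosome") {
  if (missing(pixelSizeUm) || missing(frameIntervalS))
    stop("calibration (pixelSizeUm, frameIntervalS) is required; ",
         "file metadata is not trusted as a silent default")
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop("unreadable movie file '", path,
                                             "': ", conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L)
    stop("inconsistent frame shapes in '", path, "'")
  nch <- length(channelNames)
  if (length(pages) %% nch != 0L)
    stop("page count ", length(pages), " is not a multiple of ", nch, " channels")
  nT <- length(pages) %/% nch
  d <- dims[[1]]
  pix <- array(0, c(d[1], d[2], nT, nch))
  for (t in seq_len(nT))
    for (ci in seq_len(nch))
      pix[, , t, ci] <- pages[[(t - 1L) * nch + ci]]
  MovieStack(pix, pixelSizeUm = pixelSizeUm, frameIntervalS = frameIntervalS,
             channelNames = channelNames)
}

#' Write a movie as 16-bit multi-page TIFF
#'
#' Integer intensities up to 65535 round-trip exactly through
#' [readMovie()]; pages are channel-interleaved to match it.
#'
#' @param movie a \linkS4class{MovieStack}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeMovie <- function(movie, path) {
  stopifnot(is(movie, "MovieStack"))
  if (max(movie@pixels) > 65535)
    stop("pixel values exceed the 16-bit range")
  d <- dim(movie@pixels)
  pages <- vector("list", d[3] * d[4])
  for (t in seq_len(d[3]))
    for (ci in seq_len(d[4]))
      pages[[(t - 1L) * d[4] + ci]] <- movie@pixels[, , t, ci] / 65535
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read and write binary masks
#'
#' TIFF or PNG by file extension; any pixel above half range is foreground.
#'
#' @param path mask file (.tif/.tiff or .png).
#' @param mask logical matrix.
#' @return \code{readMask}: a logical matrix; \code{writeMask}: the path,
#'   invisibly.
#' @export
readMask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported mask format: .", ext))
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0.5
}

#' @rdname readMask
#' @export
writeMask <- function(mask, path) {
  ext <- tolower(tools::file_ext(path))
  img <- mask * 1
  switch(ext,
    tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    png = png::writePNG(img, path),
    stop("unsupported mask format: .", ext))
  invisible(path)
}

#' Read an analysis configuration from YAML
#'
#' Accepts snake_case or camelCase keys matching the
#' \linkS4class{AnalysisConfig} parameters; unspecified keys keep the
#' study defaults.
#'
#' @param path YAML file.
#' @return an \linkS4class{AnalysisConfig}.
#' @export
readAnalysisConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  toCamel <- function(x) gsub("_(\\w)", "\\U\\1", x, perl = TRUE)
  names(vals) <- toCamel(names(vals))
  slots <- slotNames("AnalysisConfig")
  bad <- setdiff(names(vals), slots)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  vals <- lapply(vals, function(v) if (is.list(v)) unlist(v) else v)
  do.call(analysisConfig, vals)
}

#' Write and read simulation ground truth as JSON
#'
#' @param truth a \linkS4class{SimulationTruth}.
#' @param path JSON file.
#' @return \code{writeTruth}: the path, invisibly; \code{readTruth}: a list
#'   with \code{positionsUm}, \code{radiiUm} and \code{tetherIntervals}.
#' @export
writeTruth <- function(truth, path) {
  stopifnot(is(truth, "SimulationTruth"))
  d <- dim(truth@positionsUm)
  out <- list(
    n_particles = d[1], n_frames = d[3],
    positions_um = truth@positionsUm,
    radii_um = truth@radiiUm,
    tether_intervals = truth@tetherIntervals)
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pos <- x$positions_um
  ti <- as.data.frame(x$tether_intervals)
  if (nrow(ti) == 0L)
    ti <- data.frame(particle_i = integer(0), particle_j = integer(0),
                     first_frame = integer(0), last_frame = integer(0))
  list(positionsUm = pos, radiiUm = x$radii_um, tetherIntervals = ti)
}
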