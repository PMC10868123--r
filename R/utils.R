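# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# 8-connected labeling of a logical matrix. EBImage::bwlabel is 4-connected;
# labels that touch only diagonally are merged with a union-find pass.
labelConnected8 <- function(binary) {
  stopifnot(is.matrix(binary))
  lab <- EBImage::imageData(EBImage::bwlabel(binary * 1))
  nmax <- max(lab)
  if (nmax <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # \ diagonal neighbours
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # / diagonal neighbours
  keep1 <- a1 > 0 & b1 > 0 & a1 != b1
  keep2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(nmax)
  findRoot <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    ra <- findRoot(pairs[k, 1]); rb <- findRoot(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(nmax), findRoot, integer(1))
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  nz <- lab > 0
  out[nz] <- remap[lab[nz]]
  out
}

# Bilinear interpolation of `field` at 0-based continuous (row, col)
# coordinates given at pixel centres; coordinates are clamped to the grid.
bilinearAt <- function(field, row0, col0) {
  nr <- nrow(field); nc <- ncol(field)
  r <- pmin(pmax(row0, 0), nr - 1)
  c <- pmin(pmax(col0, 0), nc - 1)
  r0 <- pmin(floor(r), nr - 2); c0 <- pmin(floor(c), nc - 2)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0 + 1, c0 + 1); i10 <- cbind(r0 + 2, c0 + 1)
  i01 <- cbind(r0 + 1, c0 + 2); i11 <- cbind(r0 + 2, c0 + 2)
  field[i00] * (1 - fr) * (1 - fc) + field[i10] * fr * (1 - fc) +
    field[i01] * (1 - fr) * fc + field[i11] * fr * fc
}

# Wrap a pipeline stage so errors carry the stage name.
withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE))
}

emptyObjects <- function() {
  data.frame(object_id = integer(0), frame_index = integer(0),
             row0 = numeric(0), col0 = numeric(0), area_px = integer(0),
             equiv_diameter_um = numeric(0), mean_intensity = numeric(0),
             x_um = numeric(0), y_um = numeric(0))
}

emptyEvents <- function() {
  data.frame(member_a = integer(0), member_b = integer(0),
             first_frame = integer(0), last_frame = integer(0),
             censored = logical(0), min_duration_s = numeric(0))
}
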