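## Subpixel correlation core: NCC surface, parabolic peak refinement,
## offset accumulation into per-tile time signals.

#' Partition a frame into full N x N tiles
#'
#' The field of view is split into \code{floor(rows/N) x floor(cols/N)} full
#' tiles; edge remainders are excluded so every tile has identical area.
#'
#' @param frameShape integer \code{c(rows, cols)} in pixels.
#' @param tileSize tile side N in pixels, N >= 4.
#' @return a \linkS4class{TileGrid}.
#' @examples
#' partitionTiles(c(100, 100), 10)   # 10 x 10 tiles
#' @export
partitionTiles <- function(frameShape, tileSize) {
  frameShape <- as.integer(frameShape)
  tileSize <- as.integer(tileSize)
  if (length(frameShape) != 2L || any(is.na(frameShape)))
    stop("frameShape must be (rows, cols)")
  if (is.na(tileSize) || tileSize < 4L)
    stop("tileSize must be an integer >= 4")
  ntr <- frameShape[1] %/% tileSize
  ntc <- frameShape[2] %/% tileSize
  if (ntr < 1L || ntc < 1L)
    stop("frame is smaller than one tile")
  new("TileGrid", tileSize = tileSize, nTileRows = ntr, nTileCols = ntc,
      origin = c(0L, 0L))
}

#' Pixel coordinates of every tile center
#'
#' @param grid a \linkS4class{TileGrid}.
#' @return matrix with columns \code{row}, \code{col}: the center of each
#'   tile in pixel coordinates, tiles in column-major (R array) order.
#' @export
tileCenters <- function(grid) {
  stopifnot(is(grid, "TileGrid"))
  N <- grid@tileSize
  rc <- grid@origin[1] + (seq_len(grid@nTileRows) - 1) * N + (N + 1) / 2
  cc <- grid@origin[2] + (seq_len(grid@nTileCols) - 1) * N + (N + 1) / 2
  cbind(row = rep(rc, times = grid@nTileCols),
        col = rep(cc, each = grid@nTileRows))
}

#' Normalized cross-correlation surface between two tiles
#'
#' For every displacement \code{(u, v)} with \code{|u|, |v| <= maxShift}
#' (u along rows, v along columns), the normalized cross-correlation of the
#' two fragments is computed over their overlap region, each term
#' mean-centered by the overlap means. Values are bounded in [-1, 1];
#' normalized correlation is invariant to affine intensity changes
#' \code{b = s*a + o} (s > 0). Zero-variance overlaps yield 0, and a
#' zero-variance tile at the null displacement sets the \code{degenerate}
#' attribute.
#'
#' @param tileA,tileB numeric matrices of identical shape.
#' @param maxShift maximum displacement in pixels,
#'   \code{1 <= maxShift <= tileSize/2}.
#' @return \code{(2*maxShift+1)^2} matrix; row i holds row-displacement
#'   \code{u = i - maxShift - 1}, column j column-displacement
#'   \code{v = j - maxShift - 1}. Attribute \code{degenerate} flags a
#'   zero-variance tile.
#' @export
nccSurface <- function(tileA, tileB, maxShift = 3L) {
  if (!is.matrix(tileA) || !is.matrix(tileB) ||
      !identical(dim(tileA), dim(tileB)))
    stop("tiles must be matrices of identical shape")
  maxShift <- as.integer(maxShift)
  if (maxShift < 1L || maxShift > min(dim(tileA)) %/% 2L)
    stop("maxShift must satisfy 1 <= maxShift <= tileSize/2")
  s <- .cpp_ncc_surface(tileA, tileB, maxShift)
  dn <- as.character(seq(-maxShift, maxShift))
  dimnames(s) <- list(u = dn, v = dn)
  s
}

#' Subpixel peak location of a correlation surface
#'
#' The integer peak is the surface argmax, ties broken toward the smaller
#' displacement magnitude, then row-major order. Each axis is then refined
#' by the three-point parabola through the peak and its two neighbors:
#' \deqn{\hat\delta = \frac{S_{-1} - S_{+1}}{2 (S_{-1} - 2 S_0 + S_{+1})}}
#' If the peak lies on the surface border, or the parabola is flat
#' (denominator below 1e-12), that axis's refinement is 0 and
#' \code{borderFallback} is set; refinements are clamped to [-0.5, 0.5]
#' (beyond that the integer peak itself would have moved). An all-zero
#' (degenerate) surface yields a zero offset with \code{degenerate} set.
#'
#' @param surface square odd-sided NCC surface (from \code{\link{nccSurface}}).
#' @return list with \code{uHat}, \code{vHat} (integer peak, rows/cols),
#'   \code{deltaRow}, \code{deltaCol} (subpixel refinements),
#'   \code{offsetRow}, \code{offsetCol} (their sums), \code{magnitude},
#'   \code{borderFallback}, \code{degenerate}.
#' @export
refinePeak <- function(surface) {
  if (!is.matrix(surface) || nrow(surface) != ncol(surface) ||
      nrow(surface) %% 2L != 1L)
    stop("surface must be a square matrix with odd side")
  if (any(!is.finite(surface)))
    stop("surface must be finite")
  r <- .cpp_refine_peak(surface)
  .offsetResult(r)
}

.offsetResult <- function(r) {
  oR <- r[1] + r[3]
  oC <- r[2] + r[4]
  list(uHat = as.integer(r[1]), vHat = as.integer(r[2]),
       deltaRow = r[3], deltaCol = r[4],
       offsetRow = oR, offsetCol = oC,
       magnitude = sqrt(oR^2 + oC^2),
       borderFallback = r[5] == 1, degenerate = r[5] == 2)
}

#' Accumulate per-pair offsets into a time signal
#'
#' Inter-frame offsets are accumulated into the tile's "time signal":
#' \code{sig(n) = sum_{i<=n} offset_i}, prepended with \code{sig(0) = 0}.
#' In \code{signed_axes} mode the per-axis signed offsets are summed and
#' \code{sig = sqrt(sigRow^2 + sigCol^2)}; in \code{magnitude} mode the
#' per-pair offset magnitudes are summed (a non-decreasing signal).
#'
#' @param offsetRow,offsetCol numeric vectors of per-pair refined offsets
#'   (length \code{nFrames - 1}).
#' @param mode \code{"signed_axes"} (default) or \code{"magnitude"}.
#' @return list \code{sig}, \code{sigRow}, \code{sigCol} (the latter two
#'   NULL in magnitude mode), each of length \code{nFrames}.
#' @export
accumulateOffsets <- function(offsetRow, offsetCol,
                              mode = c("signed_axes", "magnitude")) {
  mode <- match.arg(mode)
  if (length(offsetRow) == 0L)
    stop("offset series must be non-empty")
  if (length(offsetRow) != length(offsetCol))
    stop("offsetRow and offsetCol must have equal length")
  if (mode == "signed_axes") {
    sr <- c(0, cumsum(offsetRow))
    sc <- c(0, cumsum(offsetCol))
    list(sig = sqrt(sr^2 + sc^2), sigRow = sr, sigCol = sc)
  } else {
    list(sig = c(0, cumsum(sqrt(offsetRow^2 + offsetCol^2))),
         sigRow = NULL, sigCol = NULL)
  }
}

#' Per-tile activity time signals for a whole sequence
#'
#' For every consecutive frame pair and every tile, computes the NCC surface,
#' refines the peak to subpixel precision, and accumulates the offsets into
#' the tile's time signal. This is the workhorse converting a speckle
#' sequence into the activity signal field; the inner loop runs in compiled
#' code and contains no randomness.
#'
#' Offsets are motion-signed: they give the displacement of the later
#' frame's content relative to the earlier frame — the negative of the
#' correlation-surface argmax — so content drifting by +1 px/frame along
#' rows accumulates \code{sigRow(n) ~ +n}.
#'
#' @param seq a \linkS4class{SpeckleSequence}.
#' @param tileSize tile side N in pixels (default 10).
#' @param maxShift NCC search radius in pixels (default 3; inter-frame
#'   biological motion is sub-pixel at the 30 s cadence, a small range
#'   suppresses spurious far peaks).
#' @param mode offset accumulation mode, see
#'   \code{\link{accumulateOffsets}}.
#' @return a \linkS4class{TimeSignalField}.
#' @export
computeTimeSignalField <- function(seq, tileSize = 10L, maxShift = 3L,
                                   mode = c("signed_axes", "magnitude")) {
  stopifnot(is(seq, "SpeckleSequence"))
  mode <- match.arg(mode)
  maxShift <- as.integer(maxShift)
  if (maxShift < 1L || maxShift > as.integer(tileSize) %/% 2L)
    stop("maxShift must satisfy 1 <= maxShift <= tileSize/2")
  fr <- seq@frames
  d <- dim(fr)
  grid <- partitionTiles(d[1:2], tileSize)
  ntr <- grid@nTileRows; ntc <- grid@nTileCols
  N <- grid@tileSize
  rows0 <- rep(grid@origin[1] + (seq_len(ntr) - 1L) * N, times = ntc)
  cols0 <- rep(grid@origin[2] + (seq_len(ntc) - 1L) * N, each = ntr)
  np <- d[3] - 1L
  duArr <- array(0, c(ntr, ntc, np))
  dvArr <- array(0, c(ntr, ntc, np))
  flArr <- array(0L, c(ntr, ntc, np))
  for (p in seq_len(np)) {
    res <- .cpp_pair_offsets(fr[, , p], fr[, , p + 1L],
                             rows0, cols0, N, maxShift)
    duArr[, , p] <- res[, 1] + res[, 3]
    dvArr[, , p] <- res[, 2] + res[, 4]
    flArr[, , p] <- as.integer(res[, 5])
  }
  nT <- d[3]
  cum3 <- function(a) {          # cumulative sum along the time axis
    if (dim(a)[3] > 1L)
      for (p in 2:dim(a)[3]) a[, , p] <- a[, , p - 1L] + a[, , p]
    a
  }
  sig <- array(0, c(ntr, ntc, nT))
  if (mode == "signed_axes") {
    sigR <- array(0, c(ntr, ntc, nT))
    sigC <- array(0, c(ntr, ntc, nT))
    sigR[, , -1L] <- cum3(duArr)
    sigC[, , -1L] <- cum3(dvArr)
    sig <- sqrt(sigR^2 + sigC^2)
  } else {
    sigR <- array(numeric(0), c(0L, 0L, 0L))
    sigC <- sigR
    sig[, , -1L] <- cum3(sqrt(duArr^2 + dvArr^2))
  }
  new("TimeSignalField", sig = sig, sigRow = sigR, sigCol = sigC,
      pairOffsetRow = duArr, pairOffsetCol = dvArr, pairFlags = flArr,
      mode = mode, grid = grid, frameInterval = seq@frameInterval,
      params = list(maxShift = maxShift))
}
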