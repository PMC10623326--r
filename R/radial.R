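## Colony localization and the overall growth-activity summaries: per-tile
## peak envelope maps, radii around the detected center, median radial and
## temporal profiles, radius-averaged spatiotemporal maps, cross-sections,
## and growth-arrest detection.

#' Detect colony centers from an envelope field
#'
#' Colonies are located as connected components of tiles whose temporal-max
#' envelope stands out from the background: tiles at or below the
#' \code{thresholdQuantile} quantile of the map are taken as the background
#' sample, the detection threshold is that quantile plus five background
#' MADs (so a flat, colony-free field yields no spurious detections), holes
#' are filled (a peripherally active ring detects as its full disk), and
#' connected components of at least \code{minTiles} tiles are returned,
#' each with its envelope-weighted centroid (pixel coordinates) and
#' equivalent-disk radius. A manual center can always be supplied
#' downstream instead.
#'
#' @param envField an \linkS4class{EnvelopeField}.
#' @param thresholdQuantile quantile of the tile map treated as background
#'   (default 0.5; colonies are assumed to cover less than this fraction of
#'   the field).
#' @param minTiles minimum component size in tiles (default 4).
#' @return list of \linkS4class{ColonyGeometry}, ordered by component size
#'   (largest first).
#' @export
detectColonyCenter <- function(envField, thresholdQuantile = 0.5,
                               minTiles = 4L) {
  stopifnot(is(envField, "EnvelopeField"))
  peak <- apply(envField@env, c(1, 2), max)
  bgLevel <- stats::quantile(peak, thresholdQuantile, names = FALSE)
  bg <- peak[peak <= bgLevel]
  thr <- bgLevel + 5 * stats::mad(bg)
  bin <- peak > thr
  if (!any(bin)) stop("no colony found: no tile exceeds the threshold")
  bin <- EBImage::fillHull(bin * 1) > 0
  lab <- EBImage::bwlabel(bin * 1)
  lab <- matrix(as.integer(round(lab)), nrow(bin), ncol(bin))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= minTiles)
  if (length(keep) == 0L)
    stop("no colony found: no component reaches the minimum size")
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  centers <- tileCenters(envField@grid)
  lapply(keep, function(k) {
    mask <- lab == k
    w <- peak[mask]
    idx <- which(mask)
    ctr <- c(sum(centers[idx, 1] * w), sum(centers[idx, 2] * w)) / sum(w)
    new("ColonyGeometry", center = ctr, mask = mask,
        estimatedRadius = sqrt(sum(mask) / pi) * envField@grid@tileSize)
  })
}

#' Per-tile peak envelope and peak time
#'
#' For each tile, the maximum envelope value over time and the (1-based)
#' frame index at which it is attained, earliest index on ties.
#'
#' @param envField an \linkS4class{EnvelopeField}.
#' @return a \linkS4class{PeakActivityMap}.
#' @export
peakActivityMaps <- function(envField) {
  stopifnot(is(envField, "EnvelopeField"))
  envPeak <- apply(envField@env, c(1, 2), max)
  peakFrame <- apply(envField@env, c(1, 2), which.max)  # earliest on ties
  new("PeakActivityMap", envPeak = envPeak,
      peakFrame = matrix(as.integer(peakFrame), nrow(envPeak)))
}

#' Distance of every tile center from the colony center
#'
#' \code{Rad(x, y) = sqrt((x - x_centr)^2 + (y - y_centr)^2)} evaluated at
#' tile centers, in pixel units.
#'
#' @param grid a \linkS4class{TileGrid}.
#' @param center \code{c(row, col)} colony center in pixel coordinates.
#' @return numeric matrix \code{nTileRows x nTileCols}.
#' @export
radiusMap <- function(grid, center) {
  stopifnot(is(grid, "TileGrid"), length(center) == 2L)
  centers <- tileCenters(grid)
  matrix(sqrt((centers[, 1] - center[1])^2 + (centers[, 2] - center[2])^2),
         grid@nTileRows, grid@nTileCols)
}

#' Median radial and temporal profiles of peak activity
#'
#' The two "overall" activity curves of the colony: colony tiles are grouped
#' by binned peak time and, separately, by binned distance from the center;
#' each bin reports the median peak-envelope value (the median absorbs the
#' tile-to-tile spread caused by nutrient access, cell crowding and growth
#' asynchrony). Empty bins are omitted.
#'
#' @param peaks a \linkS4class{PeakActivityMap}.
#' @param radii per-tile radius matrix from \code{\link{radiusMap}}.
#' @param geometry a \linkS4class{ColonyGeometry}; only colony tiles enter
#'   the profiles.
#' @param timeBin time bin width in frames (default: one envelope window is
#'   a natural choice).
#' @param radiusBin radius bin width in pixels (default: one tile width).
#' @return a \linkS4class{RadialActivityProfile}.
#' @export
radialMedianProfile <- function(peaks, radii, geometry, timeBin,
                                radiusBin) {
  stopifnot(is(peaks, "PeakActivityMap"), is(geometry, "ColonyGeometry"))
  if (!identical(dim(peaks@envPeak), dim(geometry@mask)) ||
      !identical(dim(radii), dim(geometry@mask)))
    stop("maps and mask must be aligned")
  if (!any(geometry@mask)) stop("empty colony mask")
  sel <- geometry@mask
  ev <- peaks@envPeak[sel]
  tm <- peaks@peakFrame[sel]
  rd <- radii[sel]
  binProfile <- function(values, by, width) {
    bin <- floor(by / width)
    agg <- tapply(values, bin, stats::median)
    n <- tapply(values, bin, length)
    data.frame(binCenter = (as.numeric(names(agg)) + 0.5) * width,
               medianEnv = as.numeric(agg), nTiles = as.integer(n),
               row.names = NULL)
  }
  new("RadialActivityProfile",
      timeProfile = binProfile(ev, tm - 1L, timeBin),
      radiusProfile = binProfile(ev, rd, radiusBin),
      timeBin = as.numeric(timeBin), radiusBin = as.numeric(radiusBin))
}

#' Radius-averaged spatiotemporal activity map
#'
#' For each radius bin around the colony center and each frame, the mean
#' envelope over the colony tiles in that bin: the smoothed radius-vs-time
#' activity map of the whole colony.
#'
#' @param envField an \linkS4class{EnvelopeField}.
#' @param geometry a \linkS4class{ColonyGeometry}.
#' @param radiusBin bin width in pixels (default: one tile width).
#' @return numeric matrix (radius bins x frames) with the bin centers in
#'   pixels as row names; attribute \code{nTiles} gives the per-bin tile
#'   count.
#' @export
radialAverageMap <- function(envField, geometry,
                             radiusBin = tileSize(envField)) {
  stopifnot(is(envField, "EnvelopeField"), is(geometry, "ColonyGeometry"))
  if (!any(geometry@mask)) stop("empty colony mask")
  radii <- radiusMap(envField@grid, geometry@center)
  sel <- which(geometry@mask)
  bin <- floor(radii[sel] / radiusBin)
  bins <- sort(unique(bin))
  nT <- dim(envField@env)[3]
  out <- matrix(0, length(bins), nT,
                dimnames = list((bins + 0.5) * radiusBin, NULL))
  flat <- matrix(envField@env, prod(dim(envField@env)[1:2]), nT)
  for (b in seq_along(bins)) {
    idx <- sel[bin == bins[b]]
    out[b, ] <- colMeans(flat[idx, , drop = FALSE])
  }
  attr(out, "nTiles") <- as.integer(table(factor(bin, bins)))
  out
}

#' Colony-aggregate activity time course
#'
#' The colony's overall activity signal over time: the median (or mean)
#' envelope over all colony tiles at each frame. This is the curve on which
#' growth arrest is detected — after arrest it decays toward zero within
#' about one envelope window.
#'
#' @param envField an \linkS4class{EnvelopeField}.
#' @param geometry a \linkS4class{ColonyGeometry}.
#' @param stat \code{"median"} (default) or \code{"mean"}.
#' @return numeric vector of length \code{nFrames}.
#' @export
activityTimeCourse <- function(envField, geometry,
                               stat = c("median", "mean")) {
  stopifnot(is(envField, "EnvelopeField"), is(geometry, "ColonyGeometry"))
  stat <- match.arg(stat)
  if (!any(geometry@mask)) stop("empty colony mask")
  flat <- matrix(envField@env, prod(dim(envField@env)[1:2]),
                 dim(envField@env)[3])
  m <- flat[which(geometry@mask), , drop = FALSE]
  if (stat == "median") apply(m, 2, stats::median) else colMeans(m)
}

#' Cross-section of a field through the colony center
#'
#' Extracts the tile row (or column) passing through the colony center
#' across all times, labeled by signed distance from the center — the
#' classic distance-vs-time section of colony activity.
#'
#' @param envField an \linkS4class{EnvelopeField}.
#' @param geometry a \linkS4class{ColonyGeometry} (or any object with a
#'   \code{center}).
#' @param axis \code{"row"}: vary the column along the tile row through the
#'   center; \code{"col"}: vary the row.
#' @return numeric matrix (positions x frames); row names are signed
#'   distances from the center in pixels.
#' @export
crossSection <- function(envField, geometry, axis = c("row", "col")) {
  stopifnot(is(envField, "EnvelopeField"))
  axis <- match.arg(axis)
  center <- if (is(geometry, "ColonyGeometry")) geometry@center
            else as.numeric(geometry)
  grid <- envField@grid
  N <- grid@tileSize
  if (axis == "row") {
    i <- max(1L, min(grid@nTileRows, ceiling((center[1] - grid@origin[1]) / N)))
    sec <- envField@env[i, , , drop = TRUE]
    pos <- tileCenters(grid)[(seq_len(grid@nTileCols) - 1L) *
                               grid@nTileRows + 1L, 2] - center[2]
  } else {
    j <- max(1L, min(grid@nTileCols, ceiling((center[2] - grid@origin[2]) / N)))
    sec <- envField@env[, j, , drop = TRUE]
    pos <- tileCenters(grid)[seq_len(grid@nTileRows), 1] - center[1]
  }
  sec <- matrix(sec, length(pos), dim(envField@env)[3])
  rownames(sec) <- sprintf("%.1f", pos)
  sec
}

#' Detect growth arrest on an activity time profile
#'
#' Operationalizes the vanishing of the activity signal after growth stops:
#' the arrest point is the first profile sample after the global peak whose
#' value falls below \code{fraction} of the peak and never rises above that
#' level again (persistence guards against transient dips). Returns
#' \code{NA} when no such sample exists (e.g. a monotone increasing
#' profile).
#'
#' @param profile numeric activity profile (e.g. from
#'   \code{\link{activityTimeCourse}}).
#' @param times optional sample times/frames (default: 1-based sample
#'   index).
#' @param fraction fraction of the peak defining "vanished" (default 0.1).
#' @return list \code{index} (sample index) and \code{time} (value of
#'   \code{times} there), both \code{NA} when no arrest is found.
#' @examples
#' detectGrowthArrest(c(0, 1, 5, 4, 0.2, 0.1, 0.1))$index  # 5
#' @export
detectGrowthArrest <- function(profile, times = seq_along(profile),
                               fraction = 0.1) {
  if (length(profile) == 0L) stop("profile must be non-empty")
  if (length(times) != length(profile))
    stop("times must match the profile length")
  pk <- which.max(profile)
  thr <- fraction * profile[pk]
  after <- seq(pk, length(profile))
  below <- profile[after] <= thr
  stays <- rev(cumprod(rev(below))) == 1    # below from here to the end
  hit <- which(below & stays)
  if (length(hit) == 0L)
    return(list(index = NA_integer_, time = NA_real_))
  idx <- after[hit[1L]]
  list(index = idx, time = times[idx])
}
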