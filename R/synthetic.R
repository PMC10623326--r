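## Synthetic biospeckle simulator: band-limited circular complex Gaussian
## speckle with controlled temporal decorrelation, growing colony disks,
## peripheral activity rings, growth arrest and camera noise. Supplies the
## ground truth used to validate every downstream stage.

# Band-limited circular complex Gaussian field with unit pixel variance.
# Synthesized in the frequency domain: white complex Gaussian spectrum times
# a Gaussian envelope H(f) = exp(-pi^2 g^2 |f|^2), so the field
# autocorrelation is ~ exp(-tau^2 / (2 g^2)) with correlation length g
# (the speckle grain size). Draws from the current RNG stream.
.bandLimitedField <- function(shape, grainSize) {
  nr <- shape[1]; nc <- shape[2]
  fr <- stats::fft   # local alias, clarity only
  fy <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
  fx <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
  if (nr == 1L) fy <- 0
  if (nc == 1L) fx <- 0
  H <- exp(-pi^2 * grainSize^2 *
             (outer(fy^2, rep(1, nc)) + outer(rep(1, nr), fx^2)))
  W <- matrix(complex(real = stats::rnorm(nr * nc, sd = 1 / sqrt(2)),
                      imaginary = stats::rnorm(nr * nc, sd = 1 / sqrt(2))),
              nr, nc)
  fr(W * H, inverse = TRUE) / sqrt(sum(H^2))
}

#' Generate one fully developed speckle frame
#'
#' Returns the intensity image \code{|E|^2} of a band-limited circular
#' complex Gaussian field, the standard model of fully developed laser
#' speckle: pointwise intensities are exponentially distributed, so the
#' intensity contrast (std/mean) is 1, and the spatial correlation length is
#' set by \code{grainSize}.
#'
#' @param shape integer \code{c(rows, cols)} in pixels; both >= grainSize.
#' @param grainSize speckle correlation length in pixels (>= 1).
#' @param seed integer RNG seed; identical arguments give bit-identical
#'   frames.
#' @return non-negative numeric matrix with mean intensity ~ 1.
#' @export
generateSpeckleFrame <- function(shape, grainSize = 2, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(is.na(shape)) || any(shape < 1L))
    stop("shape must be positive (rows, cols)")
  if (!is.finite(grainSize) || grainSize < 1)
    stop("grainSize must be >= 1 pixel")
  if (any(shape < grainSize))
    stop("shape must be >= grainSize in both dimensions")
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  Mod(.bandLimitedField(shape, grainSize))^2
}

#' Evolve a complex speckle field by one decorrelation step
#'
#' Implements the autoregressive decorrelation
#' \code{field' = rho * field + sqrt(1 - rho^2) * innovation}, the
#' innovation being a fresh band-limited complex Gaussian field, so the
#' marginal speckle statistics are preserved while the field correlation
#' between the two time points is exactly \code{rho}. \code{rho} may be a
#' scalar or a per-pixel matrix (lower rho = higher local activity).
#'
#' @param field complex matrix (e.g. from the simulator internals).
#' @param rho field correlation in [0, 1], scalar or matrix matching
#'   \code{field}.
#' @param grainSize correlation length of the innovation field, pixels.
#' @param seed integer RNG seed for the innovation.
#' @return complex matrix of the same shape.
#' @export
evolveField <- function(field, rho, grainSize = 2, seed = 1L) {
  if (!is.matrix(field) || !is.complex(field))
    stop("field must be a complex matrix")
  if (any(rho < 0 | rho > 1) || any(!is.finite(rho)))
    stop("rho must lie in [0, 1]")
  if (is.matrix(rho) && !identical(dim(rho), dim(field)))
    stop("per-pixel rho must match the field shape")
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  innov <- .bandLimitedField(dim(field), grainSize)
  rho * field + sqrt(1 - rho^2) * innov
}

#' Construct a ground-truth colony description
#'
#' @param center \code{c(row, col)} pixel coordinates of the colony center.
#' @param radius0 initial disk radius in pixels.
#' @param growthRate radial growth in pixels per frame until arrest.
#' @param arrestFrame 1-based frame index at which growth and activity stop
#'   (0 = arrested from the start; beyond \code{nFrames} = never arrests
#'   within the recording).
#' @param rhoBody per-frame field correlation inside the growing disk
#'   (lower = more active).
#' @param rhoRing field correlation in the peripheral ring band
#'   (\code{NA} = no ring); typically lower than \code{rhoBody}, emulating
#'   the concentration of growth at the colony periphery.
#' @param ringWidth ring band width in pixels.
#' @param intensityGain multiplicative brightness of the colony region
#'   relative to the background.
#' @return a \linkS4class{ColonyTruth}.
#' @export
colonyTruth <- function(center, radius0 = 5, growthRate = 0.2,
                        arrestFrame = 1e9, rhoBody = 0.9, rhoRing = NA_real_,
                        ringWidth = 6, intensityGain = 2) {
  new("ColonyTruth", center = as.numeric(center),
      radius0 = as.numeric(radius0), growthRate = as.numeric(growthRate),
      arrestFrame = as.integer(min(arrestFrame, .Machine$integer.max)),
      rhoBody = as.numeric(rhoBody), rhoRing = as.numeric(rhoRing),
      ringWidth = as.numeric(ringWidth),
      intensityGain = as.numeric(intensityGain))
}

#' Colony radius as a function of frame index
#'
#' Linear growth \code{radius0 + growthRate * (frame - 1)} up to
#' \code{arrestFrame}, constant after: monotone non-decreasing until arrest.
#'
#' @param colony a \linkS4class{ColonyTruth}.
#' @param nFrames number of frames to evaluate.
#' @return numeric vector of length \code{nFrames}.
#' @export
radiusCurve <- function(colony, nFrames) {
  stopifnot(is(colony, "ColonyTruth"))
  n <- seq_len(nFrames)
  eff <- pmax(pmin(n, colony@arrestFrame), 1L)
  colony@radius0 + colony@growthRate * (eff - 1)
}

#' Construct a synthetic biospeckle scene
#'
#' Defaults emulate the acquisition the simulator stands in for: 30 s frame
#' interval, fine speckle grain, a static substrate
#' (\code{backgroundRho = 1}) and camera noise of 1% of the mean background
#' intensity. Sequence lengths are desk-scale (hundreds of frames).
#'
#' @param fieldShape \code{c(rows, cols)} pixels.
#' @param nFrames number of frames (>= 2).
#' @param colonies list of \code{\link{colonyTruth}} objects.
#' @param grainSize speckle correlation length in pixels.
#' @param frameInterval seconds between frames.
#' @param backgroundRho per-frame field correlation of the background.
#' @param meanIntensity mean background intensity scale.
#' @param noiseSigma additive camera-noise std in intensity units; default
#'   1% of \code{meanIntensity}.
#' @param seed integer RNG seed.
#' @return a \linkS4class{SpeckleScene}.
#' @export
speckleScene <- function(fieldShape = c(200L, 200L), nFrames = 200L,
                         colonies = list(), grainSize = 2,
                         frameInterval = 30, backgroundRho = 1,
                         meanIntensity = 100,
                         noiseSigma = 0.01 * meanIntensity, seed = 1L) {
  new("SpeckleScene", fieldShape = as.integer(fieldShape),
      grainSize = as.numeric(grainSize),
      frameInterval = as.numeric(frameInterval), nFrames = as.integer(nFrames),
      colonies = colonies, backgroundRho = as.numeric(backgroundRho),
      noiseSigma = as.numeric(noiseSigma),
      meanIntensity = as.numeric(meanIntensity), seed = as.integer(seed))
}

# Per-pixel field correlation map for the transition into frame n, plus the
# colony presence mask at frame n. Colony pixels override the background
# while the colony grows; after arrest they revert to the background
# correlation (static up to background decorrelation).
.sceneMapsAt <- function(scene, distMaps, n) {
  shp <- scene@fieldShape
  rho <- matrix(scene@backgroundRho, shp[1], shp[2])
  gain <- matrix(1, shp[1], shp[2])
  presence <- matrix(FALSE, shp[1], shp[2])
  for (k in seq_along(scene@colonies)) {
    co <- scene@colonies[[k]]
    r <- radiusCurve(co, n)[n]
    inside <- distMaps[[k]] <= r
    presence <- presence | inside
    gain[inside] <- co@intensityGain
    if (n <= co@arrestFrame) {
      rho[inside] <- co@rhoBody
      if (!is.na(co@rhoRing)) {
        ring <- inside & distMaps[[k]] > (r - co@ringWidth)
        rho[ring] <- co@rhoRing
      }
    }
  }
  list(rho = rho, gain = gain, presence = presence)
}

#' Simulate a ground-truthed biospeckle sequence
#'
#' Starting from a fully developed speckle field, each pixel's complex field
#' evolves frame-to-frame with the local correlation rho prescribed by the
#' scene: the background correlation outside colonies, \code{rhoBody} /
#' \code{rhoRing} inside a growing colony disk, and the background value
#' again after growth arrest. Colony pixels are brightened by the colony's
#' \code{intensityGain}; additive Gaussian camera noise (clipped at zero
#' intensity) is applied last. The returned ground truth is the per-pixel,
#' per-frame activity \code{1 - rho} (slice n describes the transition into
#' frame n; slice 1 is zero) plus the colony presence mask.
#'
#' The whole simulation is bit-reproducible from (scene, seed).
#'
#' @param scene a \linkS4class{SpeckleScene}.
#' @return a \linkS4class{SpeckleSimulation}.
#' @export
simulateSequence <- function(scene) {
  stopifnot(is(scene, "SpeckleScene"))
  validObject(scene)
  shp <- scene@fieldShape
  nT <- scene@nFrames
  rows <- matrix(seq_len(shp[1]), shp[1], shp[2])
  cols <- matrix(rep(seq_len(shp[2]), each = shp[1]), shp[1], shp[2])
  distMaps <- lapply(scene@colonies, function(co)
    sqrt((rows - co@center[1])^2 + (cols - co@center[2])^2))
  set.seed(scene@seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  framesArr <- array(0, c(shp[1], shp[2], nT))
  activity <- array(0, c(shp[1], shp[2], nT))
  presence <- array(FALSE, c(shp[1], shp[2], nT))
  field <- .bandLimitedField(shp, scene@grainSize)
  for (n in seq_len(nT)) {
    maps <- .sceneMapsAt(scene, distMaps, n)
    if (n > 1L) {
      if (all(maps$rho == 1)) {
        # static transition: the field is carried over unchanged and no
        # innovation is consumed, so a fully static scene is exactly static
      } else {
        innov <- .bandLimitedField(shp, scene@grainSize)
        field <- maps$rho * field + sqrt(1 - maps$rho^2) * innov
      }
      activity[, , n] <- 1 - maps$rho
    }
    presence[, , n] <- maps$presence
    img <- maps$gain * Mod(field)^2 * scene@meanIntensity
    if (scene@noiseSigma > 0)
      img <- img + stats::rnorm(length(img), sd = scene@noiseSigma)
    framesArr[, , n] <- pmax(img, 0)
  }
  seq <- new("SpeckleSequence", frames = framesArr,
             frameInterval = scene@frameInterval)
  new("SpeckleSimulation", sequence = seq, activity = activity,
      presence = presence, scene = scene)
}

#' Ground-truth tile-window activity labels
#'
#' For each full tile and each non-overlapping time window:
#' \code{out_of_colony} if no colony disk ever intersects the tile during
#' the window; \code{growing} if the mean ground-truth activity
#' (\code{1 - rho}) over the tile-window exceeds \code{threshold}; else
#' \code{non_growing}. These labels train and evaluate the activity
#' classifier.
#'
#' @param sim a \linkS4class{SpeckleSimulation}.
#' @param tileSize tile side in pixels.
#' @param windowFrames window length in frames.
#' @param threshold mean-activity threshold for \code{growing}
#'   (default 0.05).
#' @return an \linkS4class{ActivityLabelMap} (scores are \code{NA}: truth
#'   has no classifier score).
#' @export
groundTruthLabels <- function(sim, tileSize = 10L, windowFrames,
                              threshold = 0.05) {
  stopifnot(is(sim, "SpeckleSimulation"))
  nT <- nFrames(sim@sequence)
  windowFrames <- as.integer(windowFrames)
  if (windowFrames > nT)
    stop("window is longer than the sequence")
  if (windowFrames < 1L)
    stop("windowFrames must be >= 1")
  grid <- partitionTiles(dim(sim@activity)[1:2], tileSize)
  nW <- nT %/% windowFrames
  if (nW < 1L) stop("fewer than one full window")
  N <- grid@tileSize
  labels <- array("out_of_colony", c(grid@nTileRows, grid@nTileCols, nW))
  scores <- array(NA_real_, dim(labels))
  starts <- (seq_len(nW) - 1L) * windowFrames + 1L
  for (w in seq_len(nW)) {
    fr <- starts[w]:(starts[w] + windowFrames - 1L)
    for (i in seq_len(grid@nTileRows)) {
      rIdx <- ((i - 1L) * N + 1L):(i * N)
      for (j in seq_len(grid@nTileCols)) {
        cIdx <- ((j - 1L) * N + 1L):(j * N)
        if (any(sim@presence[rIdx, cIdx, fr])) {
          act <- mean(sim@activity[rIdx, cIdx, fr])
          labels[i, j, w] <- if (act > threshold) "growing" else "non_growing"
        }
      }
    }
  }
  new("ActivityLabelMap", labels = labels, scores = scores,
      windowFrames = windowFrames, windowStarts = starts)
}
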