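#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib specklegrow, .registration = TRUE
NULL

#' SpeckleSequence: a time-lapse stack of speckle frames
#'
#' Ordered stack of same-shaped grayscale intensity frames together with the
#' acquisition timing. Frames are stored as a numeric array
#' \code{rows x cols x frames}; intensities are non-negative and kept on the
#' source scale (integer camera counts are preserved as-is).
#'
#' @slot frames numeric array, \code{rows x cols x n_frames}.
#' @slot frameInterval seconds between consecutive frames (> 0).
#' @slot startTime optional acquisition start timestamp (ISO string, or "").
#' @slot pixelSize optional micrometres per pixel (\code{NA} when unknown).
#' @slot bitDepth source bit depth (8 or 16 for camera data; \code{NA} for
#'   synthetic floating-point sequences).
#' @export
setClass("SpeckleSequence",
  representation(
    frames        = "array",
    frameInterval = "numeric",
    startTime     = "character",
    pixelSize     = "numeric",
    bitDepth      = "integer"
  ),
  prototype(startTime = "", pixelSize = NA_real_, bitDepth = NA_integer_)
)

setValidity("SpeckleSequence", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L)
    return("frames must be a 3-D array (rows x cols x frames)")
  if (d[3] < 2L)
    return("a sequence needs at least 2 frames")
  if (!is.numeric(object@frames))
    return("frames must be numeric")
  if (any(object@frames < 0))
    return("frame intensities must be non-negative")
  if (length(object@frameInterval) != 1L || !is.finite(object@frameInterval) ||
      object@frameInterval <= 0)
    return("frameInterval must be a single positive number (seconds)")
  TRUE
})

#' TileGrid: partition of the field of view into N x N tiles
#'
#' Tile (i, j) (1-based) covers pixel rows
#' \code{origin[1] + ((i-1)*N + 1) : (i*N)} and the analogous columns —
#' half-open in 0-based terms. Edge-partial tiles are dropped, never padded,
#' so every tile's statistics are computed over a full N x N block.
#'
#' @slot tileSize tile side N in pixels (>= 4).
#' @slot nTileRows,nTileCols tile counts.
#' @slot origin pixel offset of tile (1,1); default \code{c(0L, 0L)}.
#' @export
setClass("TileGrid",
  representation(
    tileSize  = "integer",
    nTileRows = "integer",
    nTileCols = "integer",
    origin    = "integer"
  ),
  prototype(origin = c(0L, 0L))
)

setValidity("TileGrid", function(object) {
  if (object@tileSize < 4L) return("tileSize must be >= 4")
  if (object@nTileRows < 1L || object@nTileCols < 1L)
    return("grid must contain at least one tile")
  if (length(object@origin) != 2L) return("origin must be length 2")
  TRUE
})

#' TimeSignalField: per-tile accumulated-offset activity signals
#'
#' The elementary activity trace of the method: for every tile, the
#' inter-frame subpixel offsets are accumulated into a time signal
#' \code{sig(n)}, with \code{sig(1) = 0} by convention (signal sample n
#' describes the transition from frame n-1 to frame n).
#'
#' In \code{signed_axes} mode the per-axis cumulative sums are retained and
#' \code{sig = sqrt(sigRow^2 + sigCol^2)}; in \code{magnitude} mode the
#' per-pair offset magnitudes are accumulated directly (so \code{sig} is
#' non-decreasing).
#'
#' @slot sig numeric array \code{tileRows x tileCols x n_frames}.
#' @slot sigRow,sigCol per-axis cumulative signals (zero-length array in
#'   magnitude mode).
#' @slot pairOffsetRow,pairOffsetCol raw refined per-pair offsets,
#'   \code{tileRows x tileCols x (n_frames - 1)}.
#' @slot pairFlags integer array of the same shape: 0 clean, 1 border /
#'   interpolation fallback, 2 degenerate (zero-variance) tile pair.
#' @slot mode \code{"signed_axes"} or \code{"magnitude"}.
#' @slot grid the \linkS4class{TileGrid} used.
#' @slot frameInterval seconds between frames.
#' @slot params processing parameters (max shift, ...).
#' @export
setClass("TimeSignalField",
  representation(
    sig           = "array",
    sigRow        = "array",
    sigCol        = "array",
    pairOffsetRow = "array",
    pairOffsetCol = "array",
    pairFlags     = "array",
    mode          = "character",
    grid          = "TileGrid",
    frameInterval = "numeric",
    params        = "list"
  )
)

setValidity("TimeSignalField", function(object) {
  d <- dim(object@sig)
  if (length(d) != 3L) return("sig must be 3-D (tileRows x tileCols x time)")
  if (!object@mode %in% c("signed_axes", "magnitude"))
    return("mode must be 'signed_axes' or 'magnitude'")
  if (any(abs(object@sig[, , 1L]) > 0))
    return("sig(1) must be 0 for every tile")
  TRUE
})

#' EnvelopeField: per-tile moving-RMS activity envelopes
#'
#' @slot env numeric array \code{tileRows x tileCols x n_frames}, all >= 0.
#' @slot grid the \linkS4class{TileGrid}.
#' @slot frameInterval seconds between frames.
#' @slot window envelope window length in frames.
#' @slot trimFraction proportion truncated per tail before the RMS.
#' @slot centered whether the window mean was subtracted before the RMS.
#' @export
setClass("EnvelopeField",
  representation(
    env           = "array",
    grid          = "TileGrid",
    frameInterval = "numeric",
    window        = "integer",
    trimFraction  = "numeric",
    centered      = "logical"
  )
)

setValidity("EnvelopeField", function(object) {
  if (length(dim(object@env)) != 3L) return("env must be 3-D")
  if (any(object@env < -1e-12)) return("envelope values must be non-negative")
  TRUE
})

#' PeakActivityMap: per-tile envelope maximum and its time
#'
#' @slot envPeak per-tile maximum envelope value (>= 0).
#' @slot peakFrame 1-based frame index of that maximum (earliest on ties).
#' @export
setClass("PeakActivityMap",
  representation(envPeak = "matrix", peakFrame = "matrix")
)

#' ColonyGeometry: detected colony location and tile membership
#'
#' @slot center colony center \code{c(row, col)} in pixel coordinates.
#' @slot mask logical tile matrix, TRUE for colony tiles.
#' @slot estimatedRadius equivalent-disk radius in pixels.
#' @export
setClass("ColonyGeometry",
  representation(center = "numeric", mask = "matrix",
                 estimatedRadius = "numeric")
)

setValidity("ColonyGeometry", function(object) {
  if (length(object@center) != 2L) return("center must be (row, col)")
  if (!any(object@mask)) return("colony mask must be non-empty")
  TRUE
})

#' RadialActivityProfile: overall activity vs. time and vs. radius
#'
#' The two "overall" curves: the median peak envelope grouped by binned
#' peak time, and grouped by binned distance from the colony center.
#' Empty bins are omitted, never filled in.
#'
#' @slot timeProfile data.frame \code{binCenter} (frames), \code{medianEnv},
#'   \code{nTiles}.
#' @slot radiusProfile data.frame \code{binCenter} (pixels),
#'   \code{medianEnv}, \code{nTiles}.
#' @slot timeBin,radiusBin bin widths used (frames / pixels).
#' @export
setClass("RadialActivityProfile",
  representation(timeProfile = "data.frame", radiusProfile = "data.frame",
                 timeBin = "numeric", radiusBin = "numeric")
)

#' ActivityLabelMap: per tile-window growth labels
#'
#' Labels take values \code{"out_of_colony"}, \code{"non_growing"},
#' \code{"growing"}. The out-of-colony label is assigned only by the colony
#' presence mask, never by the classifier; classifier scores are \code{NA}
#' there.
#'
#' @slot labels character array \code{tileRows x tileCols x nWindows}.
#' @slot scores numeric array of growing-class scores in [0, 1] (NA outside
#'   the colony).
#' @slot windowFrames window length in frames.
#' @slot windowStarts 1-based first frame of each window.
#' @export
setClass("ActivityLabelMap",
  representation(labels = "array", scores = "array",
                 windowFrames = "integer", windowStarts = "integer")
)

setValidity("ActivityLabelMap", function(object) {
  ok <- c("out_of_colony", "non_growing", "growing")
  if (!all(object@labels %in% ok))
    return("labels must be out_of_colony / non_growing / growing")
  if (!identical(dim(object@labels), dim(object@scores)))
    return("labels and scores must have identical shape")
  TRUE
})

#' MLPModel: serializable multilayer perceptron for tile-window activity
#'
#' A feed-forward network with one hidden layer of logistic units and a
#' logistic output scoring the growing class, together with the per-feature
#' standardization constants estimated on the training set. Prediction is a
#' deterministic function of (model, features) and is computed by the
#' package's own forward pass so that a model restored from its JSON
#' serialization predicts identically.
#'
#' @slot layerSizes \code{c(n_inputs, n_hidden, 1)}.
#' @slot wts weight vector in \pkg{nnet} layout.
#' @slot center,scale per-feature standardization constants.
#' @slot featureLength resampled envelope segment length L.
#' @slot seed training seed.
#' @slot valAccuracy held-out validation accuracy recorded at training time.
#' @slot params training configuration.
#' @export
setClass("MLPModel",
  representation(
    layerSizes    = "integer",
    wts           = "numeric",
    center        = "numeric",
    scale         = "numeric",
    featureLength = "integer",
    seed          = "integer",
    valAccuracy   = "numeric",
    params        = "list"
  )
)

#' ColonyTruth: ground-truth description of one simulated colony
#'
#' The colony is a disk whose radius grows linearly
#' (\code{radius0 + growthRate * (frame - 1)}) until \code{arrestFrame} and
#' stays constant after; growth-related activity is encoded as the per-frame
#' field correlation rho (lower rho = higher activity): \code{rhoBody} inside
#' the disk, optionally \code{rhoRing} (typically lower) in the peripheral
#' annulus of width \code{ringWidth} just inside the current radius. After
#' \code{arrestFrame} the colony is static (rho = 1 up to the background
#' decorrelation) — ground-truth non-growing.
#'
#' @slot center \code{c(row, col)} pixel coordinates.
#' @slot radius0 initial radius (pixels).
#' @slot growthRate radial growth (pixels / frame) until arrest.
#' @slot arrestFrame 1-based frame at which growth and activity stop.
#' @slot rhoBody field correlation inside the disk while growing.
#' @slot rhoRing field correlation in the peripheral ring (\code{NA} = no
#'   ring).
#' @slot ringWidth ring width in pixels.
#' @slot intensityGain multiplicative brightness of the colony region.
#' @export
setClass("ColonyTruth",
  representation(
    center        = "numeric",
    radius0       = "numeric",
    growthRate    = "numeric",
    arrestFrame   = "integer",
    rhoBody       = "numeric",
    rhoRing       = "numeric",
    ringWidth     = "numeric",
    intensityGain = "numeric"
  )
)

setValidity("ColonyTruth", function(object) {
  if (object@radius0 < 0 || object@growthRate < 0)
    return("radius0 and growthRate must be non-negative")
  if (!is.na(object@rhoBody) && (object@rhoBody < 0 || object@rhoBody > 1))
    return("rhoBody must be in [0, 1]")
  if (!is.na(object@rhoRing) && (object@rhoRing < 0 || object@rhoRing > 1))
    return("rhoRing must be in [0, 1]")
  if (object@intensityGain <= 0) return("intensityGain must be positive")
  TRUE
})

#' SpeckleScene: full specification of a synthetic biospeckle recording
#'
#' @slot fieldShape \code{c(rows, cols)} in pixels.
#' @slot grainSize speckle correlation length in pixels (>= 1).
#' @slot frameInterval seconds between frames (default 30, the acquisition
#'   cadence the simulator emulates).
#' @slot nFrames number of frames (>= 2).
#' @slot colonies list of \linkS4class{ColonyTruth}.
#' @slot backgroundRho per-frame field correlation of the background in
#'   [0, 1] (1 = static substrate).
#' @slot noiseSigma additive camera-noise standard deviation in intensity
#'   units (intensities are clipped at 0).
#' @slot meanIntensity mean background intensity scale.
#' @slot seed RNG seed; identical scene + seed gives a bit-identical
#'   sequence.
#' @export
setClass("SpeckleScene",
  representation(
    fieldShape    = "integer",
    grainSize     = "numeric",
    frameInterval = "numeric",
    nFrames       = "integer",
    colonies      = "list",
    backgroundRho = "numeric",
    noiseSigma    = "numeric",
    meanIntensity = "numeric",
    seed          = "integer"
  )
)

setValidity("SpeckleScene", function(object) {
  if (length(object@fieldShape) != 2L || any(object@fieldShape < 1L))
    return("fieldShape must be positive (rows, cols)")
  if (object@grainSize < 1) return("grainSize must be >= 1 pixel")
  if (any(object@fieldShape < object@grainSize))
    return("fieldShape must be >= grainSize in both dimensions")
  if (object@nFrames < 2L) return("nFrames must be >= 2")
  if (object@backgroundRho < 0 || object@backgroundRho > 1)
    return("backgroundRho must be in [0, 1]")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  if (!all(vapply(object@colonies, is, logical(1), "ColonyTruth")))
    return("colonies must be a list of ColonyTruth")
  for (co in object@colonies) {
    if (co@center[1] < 1 || co@center[1] > object@fieldShape[1] ||
        co@center[2] < 1 || co@center[2] > object@fieldShape[2])
      return("colony center must lie inside the field")
  }
  TRUE
})

#' SpeckleSimulation: a simulated sequence with its ground truth
#'
#' @slot sequence the generated \linkS4class{SpeckleSequence}.
#' @slot activity ground-truth activity array (\code{1 - rho} per pixel per
#'   frame; slice n describes the transition into frame n, slice 1 is 0).
#' @slot presence logical array, TRUE where a colony disk covers the pixel
#'   at that frame.
#' @slot scene the generating \linkS4class{SpeckleScene}.
#' @export
setClass("SpeckleSimulation",
  representation(sequence = "SpeckleSequence", activity = "array",
                 presence = "array", scene = "SpeckleScene")
)
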