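#' @describeIn SpeckleSequence frames as a rows x cols x frames array
#' @param x object
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @export
setMethod("frames", "SpeckleSequence", function(x) x@frames)

#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @export
setMethod("frameInterval", "SpeckleSequence", function(x) x@frameInterval)
#' @export
setMethod("frameInterval", "TimeSignalField", function(x) x@frameInterval)
#' @export
setMethod("frameInterval", "EnvelopeField", function(x) x@frameInterval)

#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @export
setMethod("nFrames", "SpeckleSequence", function(x) dim(x@frames)[3L])
#' @export
setMethod("nFrames", "TimeSignalField", function(x) dim(x@sig)[3L])
#' @export
setMethod("nFrames", "EnvelopeField", function(x) dim(x@env)[3L])

#' Total duration of a sequence in seconds
#'
#' \code{(nFrames - 1) * frameInterval}: the time spanned from the first to
#' the last frame.
#' @param x a SpeckleSequence
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))
#' @export
setMethod("duration", "SpeckleSequence",
          function(x) (nFrames(x) - 1) * x@frameInterval)

#' @export
setGeneric("tileSize", function(x) standardGeneric("tileSize"))
#' @export
setMethod("tileSize", "TileGrid", function(x) x@tileSize)
#' @export
setMethod("tileSize", "TimeSignalField", function(x) x@grid@tileSize)
#' @export
setMethod("tileSize", "EnvelopeField", function(x) x@grid@tileSize)

#' @export
setGeneric("tileGrid", function(x) standardGeneric("tileGrid"))
#' @export
setMethod("tileGrid", "TimeSignalField", function(x) x@grid)
#' @export
setMethod("tileGrid", "EnvelopeField", function(x) x@grid)

#' Per-tile signal / envelope arrays
#' @param x a TimeSignalField or EnvelopeField
#' @export
setGeneric("signals", function(x) standardGeneric("signals"))
#' @export
setMethod("signals", "TimeSignalField", function(x) x@sig)

#' @export
setGeneric("envelopes", function(x) standardGeneric("envelopes"))
#' @export
setMethod("envelopes", "EnvelopeField", function(x) x@env)

#' @export
setGeneric("colonyCenter", function(x) standardGeneric("colonyCenter"))
#' @export
setMethod("colonyCenter", "ColonyGeometry", function(x) x@center)

#' @export
setGeneric("colonyMask", function(x) standardGeneric("colonyMask"))
#' @export
setMethod("colonyMask", "ColonyGeometry", function(x) x@mask)

#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))
#' @export
setMethod("labelArray", "ActivityLabelMap", function(x) x@labels)

#' @export
setGeneric("scoreArray", function(x) standardGeneric("scoreArray"))
#' @export
setMethod("scoreArray", "ActivityLabelMap", function(x) x@scores)

setMethod("show", "SpeckleSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf("SpeckleSequence: %d x %d px, %d frames @ %.3g s (%.4g s total)\n",
              d[1], d[2], d[3], object@frameInterval, duration(object)))
  cat(sprintf("  intensity range [%.4g, %.4g], bit depth %s\n",
              min(object@frames), max(object@frames),
              ifelse(is.na(object@bitDepth), "float", object@bitDepth)))
})

setMethod("show", "TileGrid", function(object) {
  cat(sprintf("TileGrid: %d x %d tiles of %d x %d px (origin %d,%d)\n",
              object@nTileRows, object@nTileCols, object@tileSize,
              object@tileSize, object@origin[1], object@origin[2]))
})

setMethod("show", "TimeSignalField", function(object) {
  d <- dim(object@sig)
  cat(sprintf("TimeSignalField: %d x %d tiles, %d samples, mode '%s'\n",
              d[1], d[2], d[3], object@mode))
  cat(sprintf("  max |sig| %.4g; flagged pairs %.2f%%\n",
              max(abs(object@sig)),
              100 * mean(object@pairFlags != 0L)))
})

setMethod("show", "EnvelopeField", function(object) {
  d <- dim(object@env)
  cat(sprintf(
    "EnvelopeField: %d x %d tiles, %d samples (window %d, trim %.2g, %s)\n",
    d[1], d[2], d[3], object@window, object@trimFraction,
    if (object@centered) "centered" else "plain RMS"))
})

setMethod("show", "ColonyGeometry", function(object) {
  cat(sprintf(
    "ColonyGeometry: center (%.1f, %.1f) px, %d tiles, radius ~%.1f px\n",
    object@center[1], object@center[2], sum(object@mask),
    object@estimatedRadius))
})

setMethod("show", "ActivityLabelMap", function(object) {
  tab <- table(factor(object@labels,
                      c("out_of_colony", "non_growing", "growing")))
  d <- dim(object@labels)
  cat(sprintf("ActivityLabelMap: %d x %d tiles, %d windows of %d frames\n",
              d[1], d[2], d[3], object@windowFrames))
  cat(sprintf("  out_of_colony %d | non_growing %d | growing %d\n",
              tab[1], tab[2], tab[3]))
})

setMethod("show", "MLPModel", function(object) {
  cat(sprintf(
    "MLPModel: %d-%d-%d logistic MLP, %d weights, val. accuracy %.3f\n",
    object@layerSizes[1], object@layerSizes[2], object@layerSizes[3],
    length(object@wts), object@valAccuracy))
})

setMethod("show", "SpeckleScene", function(object) {
  cat(sprintf(
    "SpeckleScene: %d x %d px, %d frames @ %.3g s, grain %.3g px, %d colon%s\n",
    object@fieldShape[1], object@fieldShape[2], object@nFrames,
    object@frameInterval, object@grainSize, length(object@colonies),
    if (length(object@colonies) == 1) "y" else "ies"))
})

setMethod("show", "SpeckleSimulation", function(object) {
  cat("SpeckleSimulation with ground truth\n")
  show(object@sequence)
})
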