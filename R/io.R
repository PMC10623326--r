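## Reading and writing speckle sequences (multi-page TIFF, PNG frame
## directories, RDS containers), signal/envelope field stores, result
## tables (CSV) and run configurations (YAML/JSON).

#' Construct a SpeckleSequence
#'
#' @param frames numeric array \code{rows x cols x frames} (>= 2 frames,
#'   non-negative) or a list of identically shaped matrices.
#' @param frameInterval seconds between frames.
#' @param startTime optional ISO timestamp string.
#' @param pixelSize optional micrometres per pixel.
#' @param bitDepth source bit depth (8 or 16), \code{NA} for floating-point
#'   data.
#' @return a \linkS4class{SpeckleSequence}.
#' @export
SpeckleSequence <- function(frames, frameInterval = 30, startTime = "",
                            pixelSize = NA_real_, bitDepth = NA_integer_) {
  if (is.list(frames)) {
    shp <- dim(frames[[1L]])
    if (!all(vapply(frames, function(f) identical(dim(f), shp), logical(1))))
      stop("frames differ in shape")
    frames <- array(unlist(frames), c(shp, length(frames)))
  }
  new("SpeckleSequence", frames = frames,
      frameInterval = as.numeric(frameInterval),
      startTime = as.character(startTime), pixelSize = as.numeric(pixelSize),
      bitDepth = as.integer(bitDepth))
}

.sidecarPath <- function(path) paste0(path, ".json")

.writeSidecar <- function(seq, path) {
  meta <- list(format = "specklegrow-sequence-meta-1",
               frame_interval = seq@frameInterval,
               start_time = seq@startTime, pixel_size = seq@pixelSize,
               bit_depth = seq@bitDepth, n_frames = nFrames(seq))
  jsonlite::write_json(meta, .sidecarPath(path), digits = NA,
                       auto_unbox = TRUE, null = "null", na = "null")
}

.readSidecar <- function(path) {
  sp <- .sidecarPath(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Quantize a floating-point sequence to integer camera counts
#'
#' Scales intensities so the sequence maximum maps to the top count
#' (\code{2^bitDepth - 1}) and rounds — the step needed before writing a
#' simulated floating-point sequence to an integer TIFF container.
#'
#' @param seq a \linkS4class{SpeckleSequence}.
#' @param bitDepth 8 or 16 (default 16).
#' @return a \linkS4class{SpeckleSequence} with integer-valued frames.
#' @export
quantizeSequence <- function(seq, bitDepth = 16L) {
  stopifnot(is(seq, "SpeckleSequence"))
  bitDepth <- as.integer(bitDepth)
  if (!bitDepth %in% c(8L, 16L)) stop("bitDepth must be 8 or 16")
  top <- 2^bitDepth - 1
  mx <- max(seq@frames)
  fr <- if (mx > 0) round(seq@frames / mx * top) else seq@frames
  new("SpeckleSequence", frames = fr, frameInterval = seq@frameInterval,
      startTime = seq@startTime, pixelSize = seq@pixelSize,
      bitDepth = bitDepth)
}

#' Write a speckle sequence to disk
#'
#' \code{format = "tiff"} writes a lossless grayscale multi-page TIFF
#' (8- or 16-bit; integer-valued frames required — see
#' \code{\link{quantizeSequence}} for floating-point data) with the timing
#' metadata in a JSON sidecar \code{<path>.json}. \code{format = "rds"}
#' stores any sequence, including floating point, bit-identically.
#'
#' @param seq a \linkS4class{SpeckleSequence}.
#' @param path output file path.
#' @param format \code{"tiff"} or \code{"rds"}.
#' @return \code{path}, invisibly.
#' @export
writeSequence <- function(seq, path, format = c("tiff", "rds")) {
  stopifnot(is(seq, "SpeckleSequence"))
  validObject(seq)
  format <- match.arg(format)
  if (!dir.exists(dirname(path)))
    stop("unwritable path: directory does not exist: ", dirname(path))
  if (format == "rds") {
    saveRDS(list(format = "specklegrow-sequence-1", frames = seq@frames,
                 frameInterval = seq@frameInterval,
                 startTime = seq@startTime, pixelSize = seq@pixelSize,
                 bitDepth = seq@bitDepth), path)
    return(invisible(path))
  }
  bd <- seq@bitDepth
  if (is.na(bd)) {
    if (any(seq@frames != round(seq@frames)))
      stop("TIFF output needs integer-valued frames; ",
           "quantizeSequence() first or use format = 'rds'")
    bd <- if (max(seq@frames) <= 255) 8L else 16L
  }
  top <- 2^bd - 1
  if (max(seq@frames) > top)
    stop("frame values exceed the ", bd, "-bit range")
  pages <- lapply(seq_len(nFrames(seq)),
                  function(k) seq@frames[, , k] / top)
  tiff::writeTIFF(pages, path, bits.per.sample = bd)
  .writeSidecar(seq, path)
  invisible(path)
}

.readFrameFile <- function(f, pngBitDepth) {
  lf <- tolower(f)
  if (grepl("\\.(tif|tiff)$", lf)) {
    img <- tiff::readTIFF(f, as.is = TRUE)
  } else if (grepl("\\.png$", lf)) {
    img <- round(png::readPNG(f) * (2^pngBitDepth - 1))
  } else {
    return(NULL)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1L]   # first channel
  img
}

#' Read a speckle sequence
#'
#' Accepts a multi-page TIFF (8/16-bit, integer values preserved
#' losslessly), an RDS container written by \code{\link{writeSequence}}, or
#' a directory of lexicographically ordered single-frame TIFF/PNG files.
#' The frame interval is taken from the JSON sidecar \code{<path>.json}
#' when present, else from the \code{frameInterval} argument.
#'
#' @param path file or directory path.
#' @param frameInterval seconds between frames when no sidecar metadata is
#'   found (required in that case).
#' @param pngBitDepth bit depth assumed for PNG frames (default 8).
#' @return a \linkS4class{SpeckleSequence}.
#' @export
readSequence <- function(path, frameInterval = NULL, pngBitDepth = 8L) {
  if (!file.exists(path)) stop("path not found: ", path)
  meta <- NULL
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) < 2L)
      stop("format error: a sequence needs at least 2 frames, found ",
           length(files))
    pages <- lapply(files, .readFrameFile, pngBitDepth = pngBitDepth)
    shp <- dim(pages[[1L]])
    if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1))))
      stop("format error: frames differ in shape")
    mp <- file.path(path, "metadata.json")
    if (file.exists(mp)) meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  } else if (grepl("\\.rds$", tolower(path))) {
    obj <- readRDS(path)
    if (!identical(obj$format, "specklegrow-sequence-1"))
      stop("format error: not a specklegrow sequence container")
    return(new("SpeckleSequence", frames = obj$frames,
               frameInterval = obj$frameInterval, startTime = obj$startTime,
               pixelSize = obj$pixelSize, bitDepth = obj$bitDepth))
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2L)
      stop("format error: a sequence needs at least 2 frames, found ",
           length(pages))
    pages <- lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p[, , 1L] else p
    })
    shp <- dim(pages[[1L]])
    if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1))))
      stop("format error: frames differ in shape")
    meta <- .readSidecar(path)
  }
  fi <- if (!is.null(meta$frame_interval)) meta$frame_interval
        else frameInterval
  if (is.null(fi))
    stop("frameInterval not found in metadata; pass it explicitly")
  SpeckleSequence(pages, frameInterval = fi,
                  startTime = if (is.null(meta$start_time)) ""
                              else as.character(meta$start_time),
                  pixelSize = if (is.null(meta$pixel_size) ||
                                  is.na(meta$pixel_size)) NA_real_
                              else meta$pixel_size,
                  bitDepth = if (is.null(meta$bit_depth) ||
                                 is.na(meta$bit_depth)) NA_integer_
                             else as.integer(meta$bit_depth))
}

#' Store a signal or envelope field
#'
#' Bit-identical persistence of a \linkS4class{TimeSignalField} or
#' \linkS4class{EnvelopeField}, laid out as tile-rows x tile-cols x time
#' with the tile size, frame interval and processing parameters stored
#' alongside.
#'
#' @param field a \linkS4class{TimeSignalField} or
#'   \linkS4class{EnvelopeField}.
#' @param path output file path (RDS container).
#' @return \code{path}, invisibly.
#' @export
writeSignalField <- function(field, path) {
  if (is(field, "TimeSignalField")) {
    if (prod(dim(field@sig)[1:2]) == 0L)
      stop("format error: empty field (0 tiles)")
    obj <- list(format = "specklegrow-field-1", class = "TimeSignalField",
                tileSize = field@grid@tileSize,
                nTileRows = field@grid@nTileRows,
                nTileCols = field@grid@nTileCols,
                origin = field@grid@origin,
                frameInterval = field@frameInterval,
                sig = field@sig, sigRow = field@sigRow,
                sigCol = field@sigCol, pairOffsetRow = field@pairOffsetRow,
                pairOffsetCol = field@pairOffsetCol,
                pairFlags = field@pairFlags, mode = field@mode,
                params = field@params)
  } else if (is(field, "EnvelopeField")) {
    if (prod(dim(field@env)[1:2]) == 0L)
      stop("format error: empty field (0 tiles)")
    obj <- list(format = "specklegrow-field-1", class = "EnvelopeField",
                tileSize = field@grid@tileSize,
                nTileRows = field@grid@nTileRows,
                nTileCols = field@grid@nTileCols,
                origin = field@grid@origin,
                frameInterval = field@frameInterval,
                env = field@env, window = field@window,
                trimFraction = field@trimFraction, centered = field@centered)
  } else {
    stop("field must be a TimeSignalField or EnvelopeField")
  }
  saveRDS(obj, path)
  invisible(path)
}

#' Read back a stored signal or envelope field
#'
#' @param path file written by \code{\link{writeSignalField}}.
#' @return the stored \linkS4class{TimeSignalField} or
#'   \linkS4class{EnvelopeField}, element-wise identical to what was
#'   written.
#' @export
readSignalField <- function(path) {
  if (!file.exists(path)) stop("path not found: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("format error: ",
                                           conditionMessage(e)))
  if (!identical(obj$format, "specklegrow-field-1"))
    stop("format error: not a specklegrow field container")
  req <- c("class", "tileSize", "nTileRows", "nTileCols", "frameInterval")
  miss <- setdiff(req, names(obj))
  if (length(miss) > 0L)
    stop("format error: missing attributes: ", paste(miss, collapse = ", "))
  grid <- new("TileGrid", tileSize = as.integer(obj$tileSize),
              nTileRows = as.integer(obj$nTileRows),
              nTileCols = as.integer(obj$nTileCols),
              origin = as.integer(obj$origin))
  if (obj$class == "TimeSignalField") {
    new("TimeSignalField", sig = obj$sig, sigRow = obj$sigRow,
        sigCol = obj$sigCol, pairOffsetRow = obj$pairOffsetRow,
        pairOffsetCol = obj$pairOffsetCol, pairFlags = obj$pairFlags,
        mode = obj$mode, grid = grid, frameInterval = obj$frameInterval,
        params = obj$params)
  } else if (obj$class == "EnvelopeField") {
    new("EnvelopeField", env = obj$env, grid = grid,
        frameInterval = obj$frameInterval, window = as.integer(obj$window),
        trimFraction = obj$trimFraction, centered = obj$centered)
  } else {
    stop("format error: unknown field class ", obj$class)
  }
}

#' Write tile-window labels as CSV
#'
#' Columns: \code{tile_row}, \code{tile_col}, \code{window_index},
#' \code{label}, \code{score} (1-based indices).
#'
#' @param map an \linkS4class{ActivityLabelMap}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeLabelMapCSV <- function(map, path) {
  stopifnot(is(map, "ActivityLabelMap"))
  d <- dim(map@labels)
  df <- data.frame(
    tile_row = rep(seq_len(d[1]), times = d[2] * d[3]),
    tile_col = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    window_index = rep(seq_len(d[3]), each = d[1] * d[2]),
    label = as.vector(map@labels),
    score = as.vector(map@scores))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write radial/temporal activity profiles as CSV
#'
#' Columns: \code{bin_kind} (\code{time} in frames / \code{radius} in
#' pixels), \code{bin_center}, \code{median_env}, \code{n_tiles}.
#'
#' @param profile a \linkS4class{RadialActivityProfile}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeProfileCSV <- function(profile, path) {
  stopifnot(is(profile, "RadialActivityProfile"))
  df <- rbind(
    data.frame(bin_kind = "time", bin_center = profile@timeProfile$binCenter,
               median_env = profile@timeProfile$medianEnv,
               n_tiles = profile@timeProfile$nTiles),
    data.frame(bin_kind = "radius",
               bin_center = profile@radiusProfile$binCenter,
               median_env = profile@radiusProfile$medianEnv,
               n_tiles = profile@radiusProfile$nTiles))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' @param path configuration file; \code{.yaml}/\code{.yml} or
#'   \code{.json}.
#' @return named list, as given in the file (defaults are resolved by
#'   \code{\link{runPipeline}}).
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("path not found: ", path)
  if (grepl("\\.(yaml|yml)$", tolower(path))) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", tolower(path))) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml, .yml or .json")
  }
}

#' Build a SpeckleScene from a configuration list
#'
#' The \code{scene} section of a run configuration: scalar scene fields
#' (\code{fieldShape}, \code{nFrames}, \code{grainSize},
#' \code{frameInterval}, \code{backgroundRho}, \code{meanIntensity},
#' \code{noiseSigma}, \code{seed}) plus a \code{colonies} list whose
#' entries hold \code{\link{colonyTruth}} arguments.
#'
#' @param cfg named list (e.g. \code{readRunConfig(path)$scene}).
#' @return a \linkS4class{SpeckleScene}.
#' @export
sceneFromConfig <- function(cfg) {
  cols <- cfg$colonies
  if (is.data.frame(cols))   # JSON readers may tabulate the colony list
    cols <- lapply(seq_len(nrow(cols)), function(i)
      lapply(cols, function(col) if (is.list(col)) col[[i]] else col[i]))
  colonies <- lapply(cols, function(co) do.call(colonyTruth, co))
  args <- cfg[setdiff(names(cfg), "colonies")]
  args$colonies <- colonies
  do.call(speckleScene, args)
}
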