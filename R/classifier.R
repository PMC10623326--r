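## Growing / non-growing classification of tile-windows: feature extraction
## from envelope segments, MLP training (nnet), deterministic forward-pass
## prediction, JSON model serialization, and label evaluation.

#' TileWindowFeatures: per tile-window feature vectors
#'
#' One row per (tile, window): the envelope segment linearly resampled to a
#' fixed length L, followed by four summary statistics (window mean, max,
#' last-minus-first slope, standard deviation).
#'
#' @slot features numeric matrix, one row per sample, \code{L + 4} columns.
#' @slot provenance data.frame \code{tileRow}, \code{tileCol},
#'   \code{window}.
#' @slot windowFrames window length in frames.
#' @slot windowStarts 1-based first frame of each window.
#' @slot featureLength resampled segment length L.
#' @export
setClass("TileWindowFeatures",
  representation(features = "matrix", provenance = "data.frame",
                 windowFrames = "integer", windowStarts = "integer",
                 featureLength = "integer")
)

#' Extract tile-window classification features from an envelope field
#'
#' The time axis is cut into non-overlapping consecutive windows of
#' \code{windowFrames} frames (a trailing partial window is dropped); each
#' tile-window yields one feature vector: the envelope segment resampled by
#' linear interpolation to \code{featureLength} points, plus its mean,
#' maximum, last-minus-first slope, and standard deviation.
#'
#' @param envField an \linkS4class{EnvelopeField}.
#' @param windowFrames window length in frames (3 h at a 30 s cadence — 360
#'   frames — for full-scale recordings; shorter for desk-scale sequences).
#' @param featureLength resampled segment length L (default 32).
#' @return a \linkS4class{TileWindowFeatures}.
#' @export
extractFeatures <- function(envField, windowFrames, featureLength = 32L) {
  stopifnot(is(envField, "EnvelopeField"))
  windowFrames <- as.integer(windowFrames)
  featureLength <- as.integer(featureLength)
  d <- dim(envField@env)
  if (is.na(windowFrames) || windowFrames < 2L)
    stop("windowFrames must be an integer >= 2")
  if (windowFrames > d[3])
    stop("window is longer than the sequence")
  nW <- d[3] %/% windowFrames
  if (nW < 1L) stop("fewer than one full window")
  starts <- (seq_len(nW) - 1L) * windowFrames + 1L
  nS <- d[1] * d[2] * nW
  X <- matrix(0, nS, featureLength + 4L)
  prov <- data.frame(tileRow = integer(nS), tileCol = integer(nS),
                     window = integer(nS))
  xout <- seq(1, windowFrames, length.out = featureLength)
  s <- 0L
  for (w in seq_len(nW)) {
    fr <- starts[w]:(starts[w] + windowFrames - 1L)
    for (j in seq_len(d[2])) {
      for (i in seq_len(d[1])) {
        seg <- envField@env[i, j, fr]
        s <- s + 1L
        X[s, ] <- c(stats::approx(seq_len(windowFrames), seg, xout)$y,
                    mean(seg), max(seg), seg[windowFrames] - seg[1L],
                    stats::sd(seg))
        prov$tileRow[s] <- i; prov$tileCol[s] <- j; prov$window[s] <- w
      }
    }
  }
  colnames(X) <- c(paste0("seg", seq_len(featureLength)),
                   "mean", "max", "slope", "sd")
  new("TileWindowFeatures", features = X, provenance = prov,
      windowFrames = windowFrames, windowStarts = starts,
      featureLength = featureLength)
}

# Deterministic forward pass through a trained model in nnet weight layout:
# one hidden layer of logistic units, logistic output scoring "growing".
.mlpForward <- function(model, X) {
  X <- sweep(sweep(X, 2, model@center), 2, model@scale, "/")
  p <- model@layerSizes[1]; h <- model@layerSizes[2]
  Wh <- matrix(model@wts[seq_len((p + 1L) * h)], p + 1L, h)
  wo <- model@wts[((p + 1L) * h + 1L):length(model@wts)]
  sig <- function(z) 1 / (1 + exp(-z))
  hid <- sig(cbind(1, X) %*% Wh)
  as.numeric(sig(cbind(1, hid) %*% wo))
}

#' Growing-class scores for a feature set
#'
#' @param model an \linkS4class{MLPModel}.
#' @param features a \linkS4class{TileWindowFeatures} or a feature matrix
#'   with the model's input dimensionality.
#' @return numeric vector of scores in [0, 1].
#' @export
mlpScores <- function(model, features) {
  stopifnot(is(model, "MLPModel"))
  X <- if (is(features, "TileWindowFeatures")) features@features
       else as.matrix(features)
  if (ncol(X) != model@layerSizes[1])
    stop("feature dimensionality does not match the model")
  .mlpForward(model, X)
}

#' Train the growing / non-growing MLP
#'
#' Fits a feed-forward network (one hidden layer of logistic units, logistic
#' output) on standardized features with inverse-class-frequency sample
#' weights; a random \code{valFraction} of the samples is held out and the
#' validation accuracy recorded on the model. Training is reproducible from
#' the seed.
#'
#' @param features a \linkS4class{TileWindowFeatures} or feature matrix.
#' @param labels per-sample labels, \code{"growing"} / \code{"non_growing"}
#'   (an \linkS4class{ActivityLabelMap} restricted to in-colony samples is
#'   the usual source).
#' @param hidden hidden layer width (default 32).
#' @param decay L2 weight decay passed to \pkg{nnet} (default 1e-3).
#' @param maxit maximum optimizer iterations (default 300).
#' @param valFraction held-out validation fraction (default 0.2).
#' @param seed integer training seed.
#' @return an \linkS4class{MLPModel}.
#' @export
trainMLP <- function(features, labels, hidden = 32L, decay = 1e-3,
                     maxit = 300L, valFraction = 0.2, seed = 1L) {
  X <- if (is(features, "TileWindowFeatures")) features@features
       else as.matrix(features)
  L <- if (is(features, "TileWindowFeatures")) features@featureLength
       else NA_integer_
  labels <- as.character(labels)
  if (!all(labels %in% c("growing", "non_growing")))
    stop("labels must be 'growing' or 'non_growing'")
  if (nrow(X) != length(labels))
    stop("features and labels must have equal length")
  if (nrow(X) < 20L) stop("need at least 20 samples")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present in the training labels")
  if (any(!is.finite(X))) stop("features must be finite")
  y <- as.integer(labels == "growing")
  center <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scl, "/")
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  nVal <- max(1L, round(valFraction * nrow(Xs)))
  valIdx <- sample.int(nrow(Xs), nVal)
  trIdx <- setdiff(seq_len(nrow(Xs)), valIdx)
  if (length(unique(y[trIdx])) < 2L)  # degenerate split: train on all
    trIdx <- seq_len(nrow(Xs))
  tab <- table(y[trIdx])   # inverse-frequency weights, mean weight 1
  w <- length(trIdx) / (length(tab) * as.numeric(tab[as.character(y[trIdx])]))
  fit <- nnet::nnet(Xs[trIdx, , drop = FALSE], y[trIdx], weights = w,
                    size = as.integer(hidden), entropy = TRUE,
                    decay = decay, maxit = as.integer(maxit),
                    MaxNWts = 100000L, trace = FALSE)
  model <- new("MLPModel",
               layerSizes = c(ncol(X), as.integer(hidden), 1L),
               wts = as.numeric(fit$wts), center = as.numeric(center),
               scale = as.numeric(scl),
               featureLength = as.integer(L), seed = as.integer(seed),
               valAccuracy = NA_real_,
               params = list(decay = decay, maxit = as.integer(maxit),
                             valFraction = valFraction))
  valPred <- .mlpForward(model, X[valIdx, , drop = FALSE]) >= 0.5
  model@valAccuracy <- mean(valPred == (y[valIdx] == 1L))
  model
}

#' Classify tiles into growing / non-growing / out-of-colony
#'
#' Tiles outside the colony presence mask are labeled
#' \code{out_of_colony} unconditionally — presence is determined by the
#' mask, never by the classifier, whose scores are \code{NA} there. For
#' in-mask tile-windows the MLP score of the growing class decides:
#' \code{growing} when the score reaches \code{threshold}, else
#' \code{non_growing}.
#'
#' @param model an \linkS4class{MLPModel}.
#' @param envField an \linkS4class{EnvelopeField}.
#' @param colonyMasks logical tile matrix (constant over windows) or
#'   logical array \code{tileRows x tileCols x nWindows} of per-window
#'   colony presence.
#' @param windowFrames window length in frames (must reproduce the
#'   training-time extraction).
#' @param featureLength resampled segment length L used at training time.
#' @param threshold growing-score threshold (default 0.5).
#' @return an \linkS4class{ActivityLabelMap}.
#' @export
classifyTiles <- function(model, envField, colonyMasks, windowFrames,
                          featureLength = 32L, threshold = 0.5) {
  stopifnot(is(model, "MLPModel"), is(envField, "EnvelopeField"))
  feats <- extractFeatures(envField, windowFrames, featureLength)
  if (ncol(feats@features) != model@layerSizes[1])
    stop("feature dimensionality does not match the model")
  d <- dim(envField@env)
  nW <- length(feats@windowStarts)
  if (is.matrix(colonyMasks))
    colonyMasks <- array(colonyMasks, c(dim(colonyMasks), nW))
  if (!identical(dim(colonyMasks), c(d[1], d[2], nW)))
    stop("colonyMasks must be tileRows x tileCols (x nWindows)")
  sc <- .mlpForward(model, feats@features)
  labels <- array("out_of_colony", c(d[1], d[2], nW))
  scores <- array(NA_real_, c(d[1], d[2], nW))
  idx <- cbind(feats@provenance$tileRow, feats@provenance$tileCol,
               feats@provenance$window)
  inMask <- colonyMasks[idx]
  labels[idx[inMask, , drop = FALSE]] <-
    ifelse(sc[inMask] >= threshold, "growing", "non_growing")
  scores[idx[inMask, , drop = FALSE]] <- sc[inMask]
  new("ActivityLabelMap", labels = labels, scores = scores,
      windowFrames = feats@windowFrames, windowStarts = feats@windowStarts)
}

#' Compare predicted labels with ground truth
#'
#' Metrics are computed over in-colony tile-windows only (tile-windows the
#' truth marks \code{out_of_colony} are excluded: the presence mask is an
#' input to the classifier, not its output).
#'
#' @param predicted,truth aligned \linkS4class{ActivityLabelMap}s.
#' @return list: \code{accuracy}, \code{confusion} (2 x 2,
#'   truth x predicted), \code{precision} and \code{recall} per class,
#'   \code{n} evaluated tile-windows.
#' @export
evaluateLabels <- function(predicted, truth) {
  stopifnot(is(predicted, "ActivityLabelMap"), is(truth, "ActivityLabelMap"))
  if (!identical(dim(predicted@labels), dim(truth@labels)))
    stop("label maps are misaligned")
  sel <- truth@labels != "out_of_colony"
  p <- factor(predicted@labels[sel], c("growing", "non_growing"))
  t <- factor(truth@labels[sel], c("growing", "non_growing"))
  if (anyNA(p))
    stop("predicted labels mark in-colony truth tiles as out_of_colony; ",
         "the maps are misaligned")
  conf <- table(truth = t, predicted = p)
  prec <- diag(conf) / pmax(colSums(conf), 1L)
  rec <- diag(conf) / pmax(rowSums(conf), 1L)
  list(accuracy = mean(p == t), confusion = conf,
       precision = prec, recall = rec, n = length(p))
}

#' Serialize an MLP model to portable JSON
#'
#' @param model an \linkS4class{MLPModel}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeMLPModel <- function(model, path) {
  stopifnot(is(model, "MLPModel"))
  # weights are stored as %.17g strings: exact double round-trip, so the
  # restored model predicts bit-identically
  obj <- list(format = "specklegrow-mlp-1",
              layerSizes = model@layerSizes,
              wts = sprintf("%.17g", model@wts),
              center = sprintf("%.17g", model@center),
              scale = sprintf("%.17g", model@scale),
              featureLength = model@featureLength, seed = model@seed,
              valAccuracy = model@valAccuracy, params = model@params)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' Restore an MLP model from its JSON serialization
#'
#' @param path file written by \code{\link{writeMLPModel}}.
#' @return an \linkS4class{MLPModel} predicting identically to the one
#'   serialized.
#' @export
readMLPModel <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "specklegrow-mlp-1"))
    stop("not a specklegrow MLP model file")
  new("MLPModel", layerSizes = as.integer(obj$layerSizes),
      wts = as.numeric(obj$wts), center = as.numeric(obj$center),
      scale = as.numeric(obj$scale),
      featureLength = if (is.null(obj$featureLength)) NA_integer_
                      else as.integer(obj$featureLength),
      seed = as.integer(obj$seed), valAccuracy = as.numeric(obj$valAccuracy),
      params = as.list(obj$params))
}
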