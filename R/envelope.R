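## Moving-RMS activity envelopes with truncated-mean outlier handling, and
## the boxcar spatial-smoothing comparison path for raw speckle frames.

.movingRMSVector <- function(x, window, trimFraction, centered) {
  n <- length(x)
  env <- numeric(n)
  for (i in seq_len(n)) {
    k0 <- max(1L, i - window + 1L)       # trailing window, warm-up uses
    w <- x[k0:i]                          # the partial window as-is
    if (centered) w <- w - mean(w)
    len <- length(w)
    kdrop <- ceiling(trimFraction * len)
    kdrop <- min(kdrop, (len - 1L) %/% 2L)  # keep >= 1 value in warm-up
    if (kdrop > 0L) w <- sort(w)[(kdrop + 1L):(len - kdrop)]
    env[i] <- sqrt(mean(w^2))
  }
  env
}

#' Moving-RMS envelope of a time signal
#'
#' For each sample n the trailing window \code{sig(k)},
#' \code{k in [n - window + 1, n]} (clipped at the start; warm-up samples
#' use the partial window) is reduced to its root mean square after two
#' optional robustness steps: subtraction of the window mean
#' (\code{centered}, the default, which turns the envelope into a
#' local-dispersion measure that decays to zero for static scenes — the
#' plain RMS of an accumulated signal would plateau instead), and
#' truncated-mean style dropping of the \code{ceiling(trimFraction * len)}
#' largest and smallest window values to suppress transient spikes.
#'
#' @param sig numeric time signal.
#' @param window window length in frames (>= 2). Default 120 frames: 1 hour
#'   at the 30 s acquisition cadence the package targets.
#' @param trimFraction proportion truncated per tail, in [0, 0.5)
#'   (default 0.1).
#' @param centered subtract the window mean before the RMS (default TRUE);
#'   \code{FALSE} gives the literal moving RMS.
#' @return non-negative numeric vector of the same length as \code{sig}.
#' @examples
#' movingRMSEnvelope(rep(2, 10), window = 4)            # centered: all 0
#' movingRMSEnvelope(c(3, 4), window = 2, trimFraction = 0,
#'                   centered = FALSE)                  # sqrt(25/2) at n=2
#' @export
movingRMSEnvelope <- function(sig, window = 120L, trimFraction = 0.1,
                              centered = TRUE) {
  window <- as.integer(window)
  if (is.na(window) || window < 2L)
    stop("window must be an integer >= 2")
  if (!is.finite(trimFraction) || trimFraction < 0 || trimFraction >= 0.5)
    stop("trimFraction must lie in [0, 0.5)")
  if (2L * ceiling(trimFraction * window) >= window)
    stop("window would be fully truncated")
  if (length(sig) < 1L) stop("signal must be non-empty")
  .movingRMSVector(as.numeric(sig), window, trimFraction, centered)
}

#' Tile-wise envelope of a time-signal field
#'
#' Applies \code{\link{movingRMSEnvelope}} to every tile's signal. In
#' \code{signed_axes} mode the per-axis cumulative signals are enveloped
#' separately and combined as \code{sqrt(EnvRow^2 + EnvCol^2)}, so the
#' envelope measures the local dispersion of the two-dimensional offset
#' walk; in \code{magnitude} mode the accumulated magnitude signal is
#' enveloped directly.
#'
#' @param field a \linkS4class{TimeSignalField}.
#' @inheritParams movingRMSEnvelope
#' @return an \linkS4class{EnvelopeField} with the same tile grid and
#'   signal length.
#' @export
envelopeField <- function(field, window = 120L, trimFraction = 0.1,
                          centered = TRUE) {
  stopifnot(is(field, "TimeSignalField"))
  window <- as.integer(window)
  if (is.na(window) || window < 2L)
    stop("window must be an integer >= 2")
  if (!is.finite(trimFraction) || trimFraction < 0 || trimFraction >= 0.5)
    stop("trimFraction must lie in [0, 0.5)")
  if (2L * ceiling(trimFraction * window) >= window)
    stop("window would be fully truncated")
  d <- dim(field@sig)
  env <- array(0, d)
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      if (field@mode == "signed_axes") {
        er <- .movingRMSVector(field@sigRow[i, j, ], window, trimFraction,
                               centered)
        ec <- .movingRMSVector(field@sigCol[i, j, ], window, trimFraction,
                               centered)
        env[i, j, ] <- sqrt(er^2 + ec^2)
      } else {
        env[i, j, ] <- .movingRMSVector(field@sig[i, j, ], window,
                                        trimFraction, centered)
      }
    }
  }
  new("EnvelopeField", env = env, grid = field@grid,
      frameInterval = field@frameInterval, window = window,
      trimFraction = trimFraction, centered = centered)
}

#' Boxcar spatial smoothing of a speckle frame
#'
#' Moving-average smoothing with an odd square kernel and edge replication:
#' the minimal processing applied to raw speckle images when they are used
#' for presence (rather than activity) assessment. \code{kernelSize = 1} is
#' the identity.
#'
#' @param frame numeric matrix.
#' @param kernelSize odd kernel side in pixels (>= 1).
#' @return smoothed matrix of the same shape.
#' @export
spatialSmooth <- function(frame, kernelSize = 3L) {
  if (!is.matrix(frame)) stop("frame must be a matrix")
  kernelSize <- as.integer(kernelSize)
  if (is.na(kernelSize) || kernelSize < 1L || kernelSize %% 2L == 0L)
    stop("kernelSize must be an odd integer >= 1")
  if (kernelSize == 1L) return(frame)
  kern <- matrix(1 / kernelSize^2, kernelSize, kernelSize)
  out <- EBImage::filter2(frame, kern, boundary = "replicate")
  out <- as.matrix(out)
  dimnames(out) <- dimnames(frame)
  out
}
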