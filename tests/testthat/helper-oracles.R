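# Independent oracles and small scene builders shared across the tests.

# Literal double-loop normalized cross-correlation: for each displacement
# (u, v) the sums run over the overlap of the two fragments, each term
# mean-centered by the overlap means. Deliberately naive — this is the
# reference the fast implementation is checked against.
oracleNCC <- function(a, b, maxShift) {
  n <- nrow(a); m <- ncol(a)
  out <- matrix(NA_real_, 2 * maxShift + 1, 2 * maxShift + 1)
  for (u in -maxShift:maxShift) {
    for (v in -maxShift:maxShift) {
      num <- 0; da <- 0; db <- 0
      ra <- max(1, 1 + u):min(n, n + u)
      ca <- max(1, 1 + v):min(m, m + v)
      ma <- mean(a[ra, ca])
      mb <- mean(b[ra - u, ca - v])
      for (x in ra) for (y in ca) {
        xa <- a[x, y] - ma
        xb <- b[x - u, y - v] - mb
        num <- num + xa * xb
        da <- da + xa^2
        db <- db + xb^2
      }
      out[u + maxShift + 1, v + maxShift + 1] <-
        if (da <= 0 || db <= 0) 0 else num / sqrt(da * db)
    }
  }
  out
}

# Exact subpixel translation via the Fourier shift theorem.
fourierShift <- function(img, sRow, sCol) {
  d <- dim(img)
  fr <- c(0:(d[1] %/% 2), -((d[1] - d[1] %/% 2 - 1):1)) / d[1]
  fc <- c(0:(d[2] %/% 2), -((d[2] - d[2] %/% 2 - 1):1)) / d[2]
  ph <- exp(-2i * pi * (matrix(fr, d[1], d[2]) * sRow +
                          matrix(fc, d[1], d[2], byrow = TRUE) * sCol))
  Re(stats::fft(stats::fft(img) * ph, inverse = TRUE) / length(img))
}

# Full width at half maximum of the central row of the spatial
# autocorrelation of a (mean-removed) image, by linear interpolation.
autocorrFWHM <- function(img) {
  x <- img - mean(img)
  F <- stats::fft(x)
  ac <- Re(stats::fft(F * Conj(F), inverse = TRUE)) / length(x)
  ac <- ac / ac[1, 1]
  prof <- ac[1:(nrow(ac) %/% 2), 1]
  k <- which(prof < 0.5)[1]
  stopifnot(!is.na(k), k > 1)
  # lag of prof[i] is i - 1; interpolate the half-crossing
  lag <- (k - 2) + (prof[k - 1] - 0.5) / (prof[k - 1] - prof[k])
  2 * lag
}

# A small active-disk scene: one colony of constant radius, uniformly
# active at fieldRho, on a static background.
diskScene <- function(rho, seed, shape = c(100L, 100L), nFrames = 60L,
                      radius = 35, noiseSigma = 1) {
  speckleScene(fieldShape = shape, nFrames = nFrames,
               colonies = list(colonyTruth(center = (shape + 1) / 2,
                                           radius0 = radius, growthRate = 0,
                                           rhoBody = rho,
                                           intensityGain = 1)),
               noiseSigma = noiseSigma, seed = seed)
}

# Scenes for classifier training/evaluation: growing colonies with varied
# radii, growth rates, arrest frames and ring activity.
classifierScene <- function(k, seed) {
  speckleScene(fieldShape = c(128L, 128L), nFrames = 180L,
    colonies = list(colonyTruth(c(64, 64),
      radius0 = 18 + 2 * (k %% 4),
      growthRate = 0.05 + 0.02 * (k %% 3),
      arrestFrame = as.integer(90 + 10 * (k %% 4)),
      rhoBody = 0.9 - 0.02 * (k %% 3),
      rhoRing = if (k %% 2 == 0) 0.82 else NA_real_,
      ringWidth = 10, intensityGain = 2)),
    noiseSigma = 1, seed = seed)
}

# Envelope field + in-colony features/labels for one classifier scene.
classifierData <- function(k, seed, windowFrames = 30L) {
  sim <- simulateSequence(classifierScene(k, seed))
  env <- envelopeField(computeTimeSignalField(sim@sequence, 10L, 3L),
                       window = 21L)
  truth <- groundTruthLabels(sim, 10L, windowFrames)
  feats <- extractFeatures(env, windowFrames)
  idx <- cbind(feats@provenance$tileRow, feats@provenance$tileCol,
               feats@provenance$window)
  list(sim = sim, env = env, truth = truth, feats = feats, idx = idx,
       labels = truth@labels[idx])
}
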