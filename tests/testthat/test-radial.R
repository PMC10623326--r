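# shared small simulation for the radial tests: one active disk
.radialFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- diskScene(0.9, seed = 40, shape = c(100L, 100L), nFrames = 40L,
                      radius = 30)
      fld <- computeTimeSignalField(simulateSequence(sc)@sequence, 10, 3)
      cache <<- envelopeField(fld, window = 10)
    }
    cache
  }
})

test_that("peak maps report the maximum and its earliest time", {
  env <- array(0, c(1, 2, 3))
  env[1, 1, ] <- c(0, 2, 1)
  env[1, 2, ] <- c(0, 2, 2)      # tie: earliest index wins
  ef <- new("EnvelopeField", env = env,
            grid = partitionTiles(c(10, 20), 10), frameInterval = 30,
            window = 2L, trimFraction = 0, centered = TRUE)
  pm <- peakActivityMaps(ef)
  expect_equal(pm@envPeak[1, 1], 2)
  expect_equal(pm@peakFrame[1, 1], 2L)
  expect_equal(pm@peakFrame[1, 2], 2L)
  # all-zero envelope: peak 0 at the first frame
  ef0 <- new("EnvelopeField", env = array(0, c(1, 2, 3)),
             grid = partitionTiles(c(10, 20), 10), frameInterval = 30,
             window = 2L, trimFraction = 0, centered = TRUE)
  pm0 <- peakActivityMaps(ef0)
  expect_equal(pm0@envPeak[1, 1], 0)
  expect_equal(pm0@peakFrame[1, 1], 1L)
})

test_that("radius maps follow Euclidean distance from the center", {
  g <- partitionTiles(c(100, 100), 10)
  r <- radiusMap(g, c(0, 0))
  # tile (1,1) center is (5.5, 5.5)
  expect_equal(r[1, 1], sqrt(2 * 5.5^2))
  r2 <- radiusMap(g, c(5.5 + 30, 5.5 + 40))   # 3-4-5 from tile (1,1)
  expect_equal(r2[1, 1], 50)
  expect_equal(r2[4, 1], sqrt(0^2 + 40^2))
  # mirror symmetry about the center
  rc <- radiusMap(g, c(50.5, 50.5))
  expect_equal(rc[1, 1], rc[10, 10])
  expect_equal(rc[1, 10], rc[10, 1])
  # translation covariance: shifting grid origin and center together
  g2 <- new("TileGrid", tileSize = 10L, nTileRows = 10L, nTileCols = 10L,
            origin = c(7L, 3L))
  expect_equal(radiusMap(g2, c(50.5 + 7, 50.5 + 3)), rc)
})

test_that("median profiles are robust per bin and locate ring maxima", {
  # hand-constructed peaks: medians per time bin
  pm <- new("PeakActivityMap",
            envPeak = matrix(c(5, 5, 5, 1, 2, 100), 2, 3),
            peakFrame = matrix(c(1L, 1L, 1L, 11L, 11L, 11L), 2, 3))
  geom <- new("ColonyGeometry", center = c(10, 15),
              mask = matrix(TRUE, 2, 3), estimatedRadius = 10)
  radii <- matrix(c(1, 1, 1, 25, 25, 25), 2, 3)
  prof <- radialMedianProfile(pm, radii, geom, timeBin = 10, radiusBin = 10)
  expect_equal(prof@timeProfile$medianEnv, c(5, 2))   # median beats outlier
  expect_equal(prof@timeProfile$nTiles, c(3L, 3L))
  expect_equal(prof@radiusProfile$medianEnv, c(5, 2))
  expect_equal(prof@radiusProfile$binCenter, c(5, 25))
  expect_true(all(prof@radiusProfile$medianEnv >= 0))
  expect_error(radialMedianProfile(pm, radii,
    new("ColonyGeometry", center = c(1, 1), mask = matrix(TRUE, 3, 3),
        estimatedRadius = 1), 10, 10), "aligned")
})

test_that("colony detection recovers simulated centers and rejects flat fields", {
  env <- .radialFixture()
  geoms <- detectColonyCenter(env)
  expect_length(geoms, 1)
  expect_lt(max(abs(colonyCenter(geoms[[1]]) - c(50.5, 50.5))), 10)
  # flat static field: error
  sc0 <- speckleScene(fieldShape = c(80, 80), nFrames = 20, noiseSigma = 1,
                      seed = 41)
  env0 <- envelopeField(
    computeTimeSignalField(simulateSequence(sc0)@sequence, 10, 3),
    window = 10)
  expect_error(detectColonyCenter(env0), "no colony found")
  # two disjoint colonies give two geometries
  sc2 <- speckleScene(fieldShape = c(200, 100), nFrames = 30,
    colonies = list(colonyTruth(c(50, 50), radius0 = 25, growthRate = 0,
                                rhoBody = 0.9),
                    colonyTruth(c(150, 50), radius0 = 25, growthRate = 0,
                                rhoBody = 0.9)),
    noiseSigma = 1, seed = 42)
  env2 <- envelopeField(
    computeTimeSignalField(simulateSequence(sc2)@sequence, 10, 3),
    window = 10)
  geoms2 <- detectColonyCenter(env2)
  expect_length(geoms2, 2)
  ctrs <- t(vapply(geoms2, colonyCenter, numeric(2)))
  ctrs <- ctrs[order(ctrs[, 1]), ]
  expect_lt(max(abs(ctrs - rbind(c(50, 50), c(150, 50)))), 10)
})

test_that("radius-averaged maps reduce variance and vanish on zero fields", {
  env <- .radialFixture()
  geom <- detectColonyCenter(env)[[1]]
  m <- radialAverageMap(env, geom)
  expect_equal(ncol(m), nFrames(env))
  # averaging reduces variance: per-bin temporal variance bounded by the
  # max per-tile variance in that bin
  radii <- radiusMap(tileGrid(env), colonyCenter(geom))
  binw <- tileSize(env)
  flat <- matrix(env@env, 100, nFrames(env))
  sel <- which(colonyMask(geom))
  bins <- floor(radii[sel] / binw)
  for (b in unique(bins)) {
    tiles <- sel[bins == b]
    vBin <- var(m[as.character((b + 0.5) * binw), ])
    vMax <- max(apply(flat[tiles, , drop = FALSE], 1, var))
    expect_lte(vBin, vMax + 1e-12)
  }
  # rotationally symmetric activity: a bin row tracks its member tiles
  ring <- which(bins == 1)[1]
  expect_gt(cor(m["15", ], flat[sel[ring], ]), 0.5)
  # all-zero envelope gives an all-zero map
  env0 <- new("EnvelopeField", env = array(0, c(4, 4, 5)),
              grid = partitionTiles(c(40, 40), 10), frameInterval = 30,
              window = 2L, trimFraction = 0, centered = TRUE)
  geom0 <- new("ColonyGeometry", center = c(20, 20),
               mask = matrix(TRUE, 4, 4), estimatedRadius = 20)
  expect_true(all(radialAverageMap(env0, geom0) == 0))
  # an empty colony mask is rejected by the class itself
  expect_error(new("ColonyGeometry", center = c(1, 1),
                   mask = matrix(FALSE, 2, 2), estimatedRadius = 1),
               "non-empty")
})

test_that("cross-sections span the grid and are symmetric for symmetric colonies", {
  env <- .radialFixture()
  geom <- detectColonyCenter(env)[[1]]
  sec <- crossSection(env, geom, axis = "row")
  expect_equal(nrow(sec), tileGrid(env)@nTileCols)
  expect_equal(ncol(sec), nFrames(env))
  # static flanks carry much less activity than the center
  mid <- apply(sec[4:7, ], 1, mean)
  flank <- apply(sec[c(1, 10), ], 1, mean)
  expect_gt(min(mid), max(flank))
  # near-symmetry about the center for an interior mirror pair
  # (sampling noise allowed)
  expect_lt(abs(mean(sec[4, ]) - mean(sec[7, ])), mean(sec[4:7, ]))
  secC <- crossSection(env, geom, axis = "col")
  expect_equal(nrow(secC), tileGrid(env)@nTileRows)
})

test_that("growth arrest detection applies the fraction-of-peak persistence rule", {
  # direct rule evaluation on a hand profile
  r <- detectGrowthArrest(c(0, 1, 5, 4, 0.2, 0.1, 0.1), fraction = 0.1)
  expect_equal(r$index, 5L)
  # monotone increasing profile: no arrest
  rNo <- detectGrowthArrest(c(0, 1, 2, 3), fraction = 0.1)
  expect_true(is.na(rNo$index))
  # a transient dip below threshold does not count
  rDip <- detectGrowthArrest(c(0, 5, 0.2, 5, 0.2, 0.1), fraction = 0.1)
  expect_equal(rDip$index, 5L)
  # times vector is honored
  rt <- detectGrowthArrest(c(0, 5, 0.1), times = c(10, 20, 30))
  expect_equal(rt$time, 30)
})

test_that("simulated growth arrest is recovered within one envelope window", {
  w <- 15L
  sc <- speckleScene(fieldShape = c(100, 100), nFrames = 120,
    colonies = list(colonyTruth(c(50, 50), radius0 = 30, growthRate = 0,
                                arrestFrame = 60L, rhoBody = 0.9,
                                intensityGain = 2)),
    noiseSigma = 1, seed = 44)
  fld <- computeTimeSignalField(simulateSequence(sc)@sequence, 10, 3)
  env <- envelopeField(fld, window = w)
  geom <- detectColonyCenter(env)[[1]]
  arr <- detectGrowthArrest(activityTimeCourse(env, geom))
  expect_false(is.na(arr$index))
  expect_lte(abs(arr$index - 60L), w)
})
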