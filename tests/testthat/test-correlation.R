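test_that("tile partition uses floor semantics and rejects tiny frames", {
  g <- partitionTiles(c(100, 100), 10)
  expect_equal(c(g@nTileRows, g@nTileCols), c(10L, 10L))
  g2 <- partitionTiles(c(105, 98), 10)
  expect_equal(c(g2@nTileRows, g2@nTileCols), c(10L, 9L))
  expect_error(partitionTiles(c(8, 8), 10), "smaller than one tile")
  expect_error(partitionTiles(c(100, 100), 3), "tileSize")
  ctr <- tileCenters(g)
  expect_equal(ctr[1, ], c(row = 5.5, col = 5.5))
  expect_equal(nrow(ctr), 100)
})

test_that("NCC surface is exact for self-correlation and affine intensity changes", {
  a <- generateSpeckleFrame(c(12, 12), 2, seed = 3)
  s <- nccSurface(a, a, maxShift = 3)
  expect_equal(s["0", "0"], 1, tolerance = 1e-12)
  expect_equal(which.max(s), 25L)  # argmax at the center (0,0)
  s2 <- nccSurface(a, 2 * a + 3, maxShift = 3)
  expect_equal(s2["0", "0"], 1, tolerance = 1e-12)
  expect_true(all(s >= -1 - 1e-9 & s <= 1 + 1e-9))
  expect_error(nccSurface(a, a[1:10, 1:10], 3), "identical shape")
  expect_error(nccSurface(a, a, maxShift = 8), "maxShift")
})

test_that("fast NCC equals the literal double-loop evaluation on random tiles", {
  set.seed(11)
  for (rep in 1:50) {
    a <- matrix(rnorm(100), 10, 10)
    b <- matrix(rnorm(100), 10, 10)
    fast <- nccSurface(a, b, maxShift = 3)
    slow <- oracleNCC(a, b, maxShift = 3)
    expect_lt(max(abs(fast - slow)), 1e-9)
  }
  # larger tiles too
  for (n in c(16, 32)) {
    a <- matrix(rnorm(n * n), n, n)
    b <- matrix(rnorm(n * n), n, n)
    expect_lt(max(abs(nccSurface(a, b, 3) - oracleNCC(a, b, 3))), 1e-9)
  }
  # degenerate (constant) tile: all-zero surface, flagged
  cst <- matrix(5, 10, 10)
  sd <- nccSurface(cst, matrix(rnorm(100), 10, 10), 3)
  expect_true(all(sd == 0))
  expect_true(attr(sd, "degenerate"))
})

test_that("peak refinement matches the three-point parabola formula", {
  base <- matrix(-0.5, 7, 7)
  base[4, 4] <- 1
  # symmetric triple: no refinement
  s <- base; s[3, 4] <- 0.5; s[5, 4] <- 0.5; s[4, 3] <- 0.5; s[4, 5] <- 0.5
  r <- refinePeak(s)
  expect_equal(r$deltaRow, 0)
  expect_equal(r$deltaCol, 0)
  expect_false(r$borderFallback)
  # hand-evaluated asymmetric triple: (0.4, 1.0, 0.6) -> +0.1
  s2 <- base; s2[3, 4] <- 0.4; s2[5, 4] <- 0.6; s2[4, 3] <- 0.5; s2[4, 5] <- 0.5
  r2 <- refinePeak(s2)
  expect_equal(r2$deltaRow, (0.4 - 0.6) / (2 * (0.4 - 2 + 0.6)))
  expect_equal(r2$deltaRow, 0.1)
  # exact quadratic: vertex recovered to 1e-12
  u <- -3:3
  q <- outer(1 - 0.2 * (u - 0.3)^2, rep(1, 7)) +
       outer(rep(1, 7), -0.15 * (u + 0.2)^2)
  rq <- refinePeak(q)
  expect_equal(rq$offsetRow, 0.3, tolerance = 1e-12)
  expect_equal(rq$offsetCol, -0.2, tolerance = 1e-12)
  expect_false(rq$borderFallback)
})

test_that("refinement falls back at borders, flat parabolas and degenerate surfaces", {
  # peak at the corner of a maxShift = 1 surface: integer offset, flagged
  s <- matrix(0.1, 3, 3); s[1, 1] <- 0.9
  r <- refinePeak(s)
  expect_equal(c(r$uHat, r$vHat), c(-1L, -1L))
  expect_equal(c(r$deltaRow, r$deltaCol), c(0, 0))
  expect_true(r$borderFallback)
  # flat parabola on one axis
  s2 <- matrix(0, 5, 5); s2[3, 3] <- 0.5; s2[2, 3] <- 0.5; s2[4, 3] <- 0.5
  s2[3, 2] <- 0.2; s2[3, 4] <- 0.1
  r2 <- refinePeak(s2)   # row-axis triple (0.5, 0.5, 0.5): denominator 0
  expect_true(r2$borderFallback)
  expect_equal(r2$deltaRow, 0)
  # all-zero degenerate surface: zero offset, degenerate flag, no error
  r3 <- refinePeak(matrix(0, 5, 5))
  expect_true(r3$degenerate)
  expect_equal(r3$magnitude, 0)
  # ties break toward the smaller displacement: equal peak at (0,0) wins
  s4 <- matrix(0, 5, 5); s4[3, 3] <- 0.8; s4[1, 1] <- 0.8
  r4 <- refinePeak(s4)
  expect_equal(c(r4$uHat, r4$vHat), c(0L, 0L))
})

test_that("offset accumulation reproduces hand-computed signals", {
  # signed x-offsets (0.1, 0.2, -0.1), y zero
  acc <- accumulateOffsets(c(0.1, 0.2, -0.1), c(0, 0, 0), "signed_axes")
  expect_equal(acc$sigRow, c(0, 0.1, 0.3, 0.2))
  expect_equal(acc$sig, abs(c(0, 0.1, 0.3, 0.2)))
  # 3-4-5 magnitudes
  accM <- accumulateOffsets(rep(0.3, 3), rep(0.4, 3), "magnitude")
  expect_equal(accM$sig, c(0, 0.5, 1.0, 1.5))
  expect_true(all(diff(accM$sig) >= 0))
  # all-zero offsets
  expect_true(all(accumulateOffsets(rep(0, 5), rep(0, 5))$sig == 0))
  expect_error(accumulateOffsets(numeric(0), numeric(0)), "non-empty")
})

test_that("static sequences give exactly zero signals", {
  img <- generateSpeckleFrame(c(60, 60), 2, seed = 8)
  sq <- SpeckleSequence(array(rep(img, 5), c(60, 60, 5)), frameInterval = 30)
  fld <- computeTimeSignalField(sq, tileSize = 10, maxShift = 3)
  expect_true(all(signals(fld) == 0))
  expect_true(all(fld@pairFlags == 0L))
})

test_that("a global 1-px drift accumulates sig ~ n in interior tiles", {
  big <- generateSpeckleFrame(c(140, 120), 3, seed = 12)
  n <- 5
  frames <- lapply(0:(n - 1), function(k) big[(1 + k):(100 + k), 1:100])
  sq <- SpeckleSequence(frames, frameInterval = 30)
  fld <- computeTimeSignalField(sq, 10, 3)
  # frame t is frame t-1 with content moved by -1 row (window slides +1):
  # tiles see the texture move up; use interior tiles only
  sigRowEnd <- fld@sigRow[3:8, 3:8, n]
  expect_lt(mean(abs(sigRowEnd - (-(n - 1)))), 0.1 * (n - 1))
  expect_lt(mean(abs(fld@sigCol[3:8, 3:8, n])), 0.1 * (n - 1))
})

test_that("active-disk tiles move more than static background tiles", {
  sc <- diskScene(0.9, seed = 14, shape = c(100L, 100L), nFrames = 20L,
                  radius = 30)
  sim <- simulateSequence(sc)
  fld <- computeTimeSignalField(sim@sequence, 10, 3)
  radii <- radiusMap(tileGrid(fld), c(50.5, 50.5))
  mag <- apply(sqrt(fld@pairOffsetRow^2 + fld@pairOffsetCol^2), c(1, 2),
               mean)
  expect_gt(mean(mag[radii <= 20]), mean(mag[radii > 40]))
})

test_that("tile-level and sequence-level paths agree", {
  sc <- diskScene(0.9, seed = 21, shape = c(40L, 40L), nFrames = 3L,
                  radius = 15)
  sim <- simulateSequence(sc)
  fld <- computeTimeSignalField(sim@sequence, 10, 3)
  fr <- frames(sim@sequence)
  for (i in c(1, 3)) for (j in c(2, 4)) {
    rIdx <- ((i - 1) * 10 + 1):(i * 10)
    cIdx <- ((j - 1) * 10 + 1):(j * 10)
    s <- nccSurface(fr[rIdx, cIdx, 1], fr[rIdx, cIdx, 2], 3)
    r <- refinePeak(s)
    # pair offsets are motion-signed: the negated surface argmax
    expect_equal(fld@pairOffsetRow[i, j, 1], -r$offsetRow)
    expect_equal(fld@pairOffsetCol[i, j, 1], -r$offsetCol)
  }
})
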