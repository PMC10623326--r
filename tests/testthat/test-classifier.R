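.constEnvField <- function(envArr) {
  new("EnvelopeField", env = envArr,
      grid = partitionTiles(c(dim(envArr)[1] * 10, dim(envArr)[2] * 10), 10),
      frameInterval = 30, window = 4L, trimFraction = 0.1, centered = TRUE)
}

test_that("feature extraction reproduces hand-computed window statistics", {
  envArr <- array(0, c(2, 1, 20))
  envArr[1, 1, ] <- 3                        # constant envelope
  envArr[2, 1, 1:10] <- seq(0, 1, length.out = 10)  # ramp in window 1
  ef <- .constEnvField(envArr)
  feats <- extractFeatures(ef, windowFrames = 10, featureLength = 8)
  expect_equal(dim(feats@features), c(4L, 12L))   # 2 tiles x 2 windows
  f11 <- feats@features[feats@provenance$tileRow == 1 &
                          feats@provenance$window == 1, ]
  expect_true(all(f11[1:8] == 3))
  expect_equal(f11[["mean"]], 3)
  expect_equal(f11[["slope"]], 0)
  expect_equal(f11[["sd"]], 0)
  framp <- feats@features[feats@provenance$tileRow == 2 &
                            feats@provenance$window == 1, ]
  expect_equal(framp[["slope"]], 1)
  expect_equal(framp[["mean"]], 0.5)
  expect_equal(framp[["max"]], 1)
  # identical tiles give identical features
  envArr2 <- envArr; envArr2[2, 1, ] <- envArr2[1, 1, ]
  feats2 <- extractFeatures(.constEnvField(envArr2), 10, 8)
  expect_equal(feats2@features[1, ], feats2@features[2, ],
               ignore_attr = TRUE)
  expect_error(extractFeatures(ef, windowFrames = 50), "longer")
})

test_that("MLP training separates separable data and is reproducible", {
  set.seed(3)
  n <- 60
  X <- rbind(matrix(rnorm(2 * n, mean = 0), n, 2),
             matrix(rnorm(2 * n, mean = 4), n, 2))
  y <- rep(c("non_growing", "growing"), each = n)
  model <- trainMLP(X, y, hidden = 4, seed = 5)
  expect_s4_class(model, "MLPModel")
  pred <- ifelse(mlpScores(model, X) >= 0.5, "growing", "non_growing")
  expect_equal(mean(pred == y), 1.0)
  expect_gt(model@valAccuracy, 0.9)
  # determinism: same data + seed -> identical probe predictions
  model2 <- trainMLP(X, y, hidden = 4, seed = 5)
  probe <- matrix(rnorm(20), 10, 2)
  expect_identical(mlpScores(model, probe), mlpScores(model2, probe))
  # error cases
  expect_error(trainMLP(X, rep("growing", nrow(X))), "both classes")
  expect_error(trainMLP(X[1:10, ], y[1:10]), "20 samples")
  Xbad <- X; Xbad[1, 1] <- NA
  expect_error(trainMLP(Xbad, y), "finite")
})

test_that("the forward pass agrees with nnet and survives JSON round-trips", {
  set.seed(9)
  X <- matrix(rnorm(200), 50, 4)
  y <- ifelse(X[, 1] + X[, 2] > 0, "growing", "non_growing")
  model <- trainMLP(X, y, hidden = 3, seed = 2)
  # independent route: rebuild the same nnet fit and compare predictions
  sc <- sweep(sweep(X, 2, model@center), 2, model@scale, "/")
  probe <- matrix(rnorm(40), 10, 4)
  probeSc <- sweep(sweep(probe, 2, model@center), 2, model@scale, "/")
  fit <- structure(list(n = c(4L, 3L, 1L), wts = model@wts,
                        nunits = 9L, nconn = NULL), class = "nnet")
  # nnet's own forward pass on the stored weights
  nn <- nnet::nnet(sc, as.integer(y == "growing"), size = 3, maxit = 0,
                   Wts = model@wts, entropy = TRUE, trace = FALSE)
  expect_equal(as.numeric(predict(nn, probeSc)),
               mlpScores(model, probe), tolerance = 1e-6)
  # JSON serialization preserves predictions exactly
  p <- withr::local_tempfile(fileext = ".json")
  writeMLPModel(model, p)
  back <- readMLPModel(p)
  expect_identical(mlpScores(back, probe), mlpScores(model, probe))
  expect_error(readMLPModel(withr::local_tempfile(fileext = ".json")),
               "not found")
})

test_that("the colony mask overrides the classifier everywhere", {
  envArr <- array(abs(rnorm(2 * 2 * 12)), c(2, 2, 12))
  ef <- .constEnvField(envArr)
  set.seed(1)
  X <- rbind(matrix(rnorm(40), 20, 10), matrix(rnorm(40) + 3, 20, 10))
  model <- trainMLP(X, rep(c("growing", "non_growing"), each = 20),
                    hidden = 2, seed = 1)
  model@featureLength <- 6L
  # empty mask: everything out_of_colony, scores NA
  mask0 <- matrix(FALSE, 2, 2)
  lm0 <- classifyTiles(model, ef, mask0, windowFrames = 6,
                       featureLength = 6)
  expect_true(all(labelArray(lm0) == "out_of_colony"))
  expect_true(all(is.na(scoreArray(lm0))))
  # partial mask: out-of-mask tiles never get an MLP label
  mask <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  lm <- classifyTiles(model, ef, mask, windowFrames = 6, featureLength = 6)
  expect_true(all(labelArray(lm)[2, 1, ] == "out_of_colony"))
  expect_true(all(labelArray(lm)[1, 1, ] %in% c("growing", "non_growing")))
  expect_true(all(!is.na(scoreArray(lm)[1, 1, ])))
  expect_error(classifyTiles(model, ef, mask, windowFrames = 6,
                             featureLength = 12), "dimensionality")
})

test_that("label evaluation reproduces hand-computed confusion metrics", {
  mk <- function(labs) {
    arr <- array(labs, c(length(labs), 1, 1))
    new("ActivityLabelMap", labels = arr,
        scores = array(NA_real_, dim(arr)), windowFrames = 5L,
        windowStarts = 1L)
  }
  g <- "growing"; n <- "non_growing"; o <- "out_of_colony"
  # TP=3, FP=1, FN=1, TN=5 (out-of-colony rows ignored)
  truth <- mk(c(g, g, g, g, n, n, n, n, n, n, o, o))
  pred <- mk(c(g, g, g, n, g, n, n, n, n, n, o, o))
  m <- evaluateLabels(pred, truth)
  expect_equal(m$n, 10L)
  expect_equal(as.numeric(m$precision["growing"]), 0.75)
  expect_equal(as.numeric(m$recall["growing"]), 0.75)
  expect_equal(m$accuracy, 0.8)
  # perfect and inverted predictions
  expect_equal(evaluateLabels(truth, truth)$accuracy, 1.0)
  inv <- mk(c(n, n, n, n, g, g, g, g, g, g, o, o))
  expect_equal(evaluateLabels(inv, truth)$accuracy, 0.0)
  expect_error(evaluateLabels(mk(c(g, n)), truth), "misaligned")
})

test_that("a classifier trained on simulated colonies generalizes to a held-out colony", {
  dat <- lapply(1:4, function(k) classifierData(k, 200 + k))
  trX <- do.call(rbind, lapply(dat[1:3], function(d)
    d$feats@features[d$labels != "out_of_colony", , drop = FALSE]))
  trY <- unlist(lapply(dat[1:3], function(d)
    d$labels[d$labels != "out_of_colony"]))
  model <- trainMLP(trX, trY, seed = 7)
  ho <- dat[[4]]
  mask <- labelArray(ho$truth) != "out_of_colony"
  pred <- classifyTiles(model, ho$env, mask, windowFrames = 30)
  m <- evaluateLabels(pred, ho$truth)
  expect_gt(m$accuracy, 0.85)
  # post-arrest windows are overwhelmingly non-growing
  arrest <- ho$sim@scene@colonies[[1]]@arrestFrame
  postW <- which(pred@windowStarts > arrest)
  sel <- mask[, , postW, drop = FALSE]
  expect_gt(mean(labelArray(pred)[, , postW][sel] == "non_growing"), 0.9)
})
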