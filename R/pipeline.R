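## End-to-end orchestration: one configuration drives simulate/read ->
## signals -> envelope -> radial summaries -> classification -> report,
## with every intermediate written to the run directory and a manifest of
## parameters, seed and output checksums.

.defaultConfig <- function() {
  list(
    input = NULL,             # sequence path, or NULL when scene is given
    scene = NULL,             # simulation scene config (list)
    tileSize = 10L,
    maxShift = 3L,
    accumulateMode = "signed_axes",
    envelope = list(window = 120L, trimFraction = 0.1, centered = TRUE),
    center = "auto",          # or c(row, col) in pixels
    arrestFraction = 0.1,
    classifier = list(model = NULL, windowFrames = NULL, featureLength = 32L,
                      threshold = 0.5, hidden = 32L, maxit = 300L),
    outDir = "specklegrow-run",
    seed = 1L,
    figures = TRUE
  )
}

.mergeConfig <- function(user, def = .defaultConfig()) {
  for (k in names(user)) {
    if (is.list(def[[k]]) && is.list(user[[k]]))
      def[[k]] <- .mergeConfig(user[[k]], def[[k]])
    else def[[k]] <- user[[k]]
  }
  def
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

.plotMap <- function(m, path, main, xlab = "time (frame)",
                     ylab = "position") {
  grDevices::png(path, width = 900, height = 500)
  on.exit(grDevices::dev.off())
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m),
                  col = grDevices::hcl.colors(64, "inferno"),
                  xlab = xlab, ylab = ylab, main = main, useRaster = TRUE)
}

#' Run the full biospeckle analysis pipeline
#'
#' Executes simulate/read -> time signals -> envelopes -> colony radial
#' summaries -> (optional) classification from one configuration, writing
#' every intermediate artifact plus a machine-readable manifest
#' (parameters, seed, package version, MD5 checksum per output) to the run
#' directory. The same configuration and seed reproduce bit-identical
#' numeric outputs. The global seed fans out deterministically: the scene
#' uses \code{seed}, classifier training \code{seed + 1}.
#'
#' When the input is a simulated scene and no trained model is supplied,
#' a demonstration classifier is trained on this run's own ground-truth
#' labels and applied back to it (for honest accuracy estimates train on
#' separate scenes via \code{\link{trainMLP}} and pass the model in).
#'
#' @param config configuration list or path to a YAML/JSON file; see
#'   \code{\link{readRunConfig}}. Defaults: tile size 10 px, max shift
#'   3 px, signed-axes accumulation, envelope window 120 frames (trim 0.1,
#'   centered), automatic center detection.
#' @return invisibly, a list with the run artifacts (paths and in-memory
#'   objects, including the manifest).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  cfg <- .mergeConfig(config)
  if (is.null(cfg$input) && is.null(cfg$scene))
    stop("configuration error: either 'input' (sequence path) or 'scene' ",
         "(simulation) must be given")
  outDir <- cfg$outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  sim <- NULL

  if (!is.null(cfg$scene)) {
    sq <- .stage("simulate", {
      scfg <- cfg$scene
      if (is.null(scfg$seed)) scfg$seed <- cfg$seed
      sim <- simulateSequence(sceneFromConfig(scfg))
      sim@sequence
    })
    paths$sequence <- file.path(outDir, "sequence.rds")
    .stage("simulate", writeSequence(sq, paths$sequence, format = "rds"))
  } else {
    sq <- .stage("read", readSequence(cfg$input))
  }

  field <- .stage("signals", computeTimeSignalField(
    sq, tileSize = cfg$tileSize, maxShift = cfg$maxShift,
    mode = cfg$accumulateMode))
  paths$signals <- file.path(outDir, "signals.rds")
  writeSignalField(field, paths$signals)

  env <- .stage("envelope", envelopeField(
    field, window = cfg$envelope$window,
    trimFraction = cfg$envelope$trimFraction,
    centered = cfg$envelope$centered))
  paths$envelope <- file.path(outDir, "envelope.rds")
  writeSignalField(env, paths$envelope)

  radial <- .stage("radial", {
    geom <- if (identical(cfg$center, "auto")) {
      detectColonyCenter(env)[[1L]]
    } else {
      ctr <- as.numeric(cfg$center)
      radii0 <- radiusMap(env@grid, ctr)
      new("ColonyGeometry", center = ctr,
          mask = radii0 <= max(radii0),   # manual center: all tiles
          estimatedRadius = NA_real_)
    }
    peaks <- peakActivityMaps(env)
    radii <- radiusMap(env@grid, geom@center)
    profile <- radialMedianProfile(peaks, radii, geom,
                                   timeBin = env@window,
                                   radiusBin = env@grid@tileSize)
    course <- activityTimeCourse(env, geom)
    arrest <- detectGrowthArrest(course, fraction = cfg$arrestFraction)
    list(geometry = geom, peaks = peaks, profile = profile,
         course = course, arrest = arrest,
         map = radialAverageMap(env, geom),
         section = crossSection(env, geom))
  })
  paths$profile <- file.path(outDir, "profile.csv")
  writeProfileCSV(radial$profile, paths$profile)
  paths$timecourse <- file.path(outDir, "timecourse.csv")
  utils::write.csv(data.frame(frame = seq_along(radial$course),
                              median_env = radial$course),
                   paths$timecourse, row.names = FALSE)

  labels <- NULL
  model <- NULL
  wf <- cfg$classifier$windowFrames
  if (is.null(wf))   # 3 h at the recording cadence, capped by the sequence
    wf <- max(2L, min(nFrames(sq) %/% 2L,
                      as.integer(round(3 * 3600 / sq@frameInterval))))
  canClassify <- !is.null(cfg$classifier$model) || !is.null(sim)
  if (canClassify && nFrames(sq) >= 2L * wf || !is.null(cfg$classifier$model)) {
    labels <- .stage("classify", {
      if (!is.null(cfg$classifier$model)) {
        model <- readMLPModel(cfg$classifier$model)
      } else {
        truth <- groundTruthLabels(sim, tileSize = cfg$tileSize,
                                   windowFrames = wf)
        feats <- extractFeatures(env, wf, cfg$classifier$featureLength)
        idx <- cbind(feats@provenance$tileRow, feats@provenance$tileCol,
                     feats@provenance$window)
        lab <- truth@labels[idx]
        keep <- lab != "out_of_colony"
        model <- trainMLP(feats@features[keep, , drop = FALSE], lab[keep],
                           hidden = cfg$classifier$hidden,
                           maxit = cfg$classifier$maxit,
                           seed = cfg$seed + 1L)
        model@featureLength <- as.integer(cfg$classifier$featureLength)
      }
      masks <- if (!is.null(sim)) {
        truth <- groundTruthLabels(sim, tileSize = cfg$tileSize,
                                   windowFrames = wf)
        truth@labels != "out_of_colony"
      } else {
        radial$geometry@mask
      }
      classifyTiles(model, env, masks, windowFrames = wf,
                    featureLength = cfg$classifier$featureLength,
                    threshold = cfg$classifier$threshold)
    })
    paths$labels <- file.path(outDir, "labels.csv")
    writeLabelMapCSV(labels, paths$labels)
    if (is.null(cfg$classifier$model)) {
      paths$model <- file.path(outDir, "model.json")
      writeMLPModel(model, paths$model)
    }
  }

  if (isTRUE(cfg$figures)) {
    .stage("report", {
      .plotMap(radial$section, file.path(outDir, "cross_section.png"),
               "Cross-sectional activity through the colony center",
               ylab = "tile along section")
      .plotMap(radial$map, file.path(outDir, "radial_average.png"),
               "Radius-averaged activity envelope",
               ylab = "radius bin")
      grDevices::png(file.path(outDir, "profile.png"), 900, 400)
      graphics::par(mfrow = c(1, 2))
      graphics::plot(radial$profile@timeProfile$binCenter,
                     radial$profile@timeProfile$medianEnv, type = "b",
                     xlab = "peak time (frame)", ylab = "median peak Env",
                     main = "Overall activity vs. time")
      graphics::plot(radial$profile@radiusProfile$binCenter,
                     radial$profile@radiusProfile$medianEnv, type = "b",
                     xlab = "radius (px)", ylab = "median peak Env",
                     main = "Overall activity vs. radius")
      grDevices::dev.off()
      if (!is.null(labels)) {
        lw <- dim(labels@labels)[3]
        num <- array(match(labels@labels,
                           c("out_of_colony", "non_growing", "growing")),
                     dim(labels@labels))
        grDevices::png(file.path(outDir, "label_map.png"), 900, 400)
        graphics::par(mfrow = c(1, min(lw, 4L)))
        for (w in seq_len(min(lw, 4L)))
          graphics::image(t(num[, , w])[, rev(seq_len(dim(num)[1]))],
                          col = c("#4477EE", "#8B5A2B", "#2E8B57"),
                          zlim = c(1, 3), axes = FALSE,
                          main = sprintf("window %d", w))
        grDevices::dev.off()
      }
    })
  }

  manifest <- list(
    package = as.character(utils::packageVersion("specklegrow")),
    seed = cfg$seed,
    parameters = cfg[c("tileSize", "maxShift", "accumulateMode",
                       "envelope", "center", "arrestFraction")],
    arrestFrame = radial$arrest$time,
    checksums = as.list(tools::md5sum(unlist(paths))))
  names(manifest$checksums) <- basename(unlist(paths))
  paths$manifest <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, digits = NA,
                       auto_unbox = TRUE, na = "null")

  invisible(list(paths = paths, sequence = sq, signals = field,
                 envelope = env, radial = radial, labels = labels,
                 model = model, manifest = manifest, simulation = sim))
}
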