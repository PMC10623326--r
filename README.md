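# specklegrow

Growing or not? A bacterial colony on an agar plate is easy to *see* —
under white light, or in a raw laser speckle image — but its image says
nothing about whether the cells inside are still proliferating or have
arrested (nutrient depletion, antibiotics, age). `specklegrow` answers the
growth question from time-lapse **laser speckle** recordings: microscopic
motion inside a growing colony decorrelates the speckle pattern between
frames, and that decorrelation can be measured per image tile with
subpixel precision.

The package is aimed at microbiologists and image-analysis researchers
working with biospeckle recordings of colonies (or anyone evaluating the
method), and provides the full chain:

1. **Subpixel correlation signals** — the field of view is split into
   N×N-pixel tiles (default 10); for every consecutive frame pair and
   tile, the normalized cross-correlation surface

   NCC(u,v) = Σ(a−ā)(b−b̄) / √(Σ(a−ā)² Σ(b−b̄)²)

   is evaluated over displacements |u|,|v| ≤ 3 px, its peak
   (û,v̂) = argmax NCC is refined per axis by a three-point parabola
   δ̂ = (NCC(û−1) − NCC(û+1)) / (2(NCC(û−1) − 2NCC(û) + NCC(û+1))),
   and the per-pair offsets are accumulated into the tile's activity
   *time signal* sig(n), with sig(0) = 0.
2. **Activity envelopes** — a trailing moving RMS (window-mean-centered,
   extremes trimmed) turns the signal into a non-negative activity
   envelope Env(n) that decays to zero when motion stops.
3. **Colony summaries** — automatic colony-center detection, per-tile
   envelope peaks Env_peak(x,y) and peak times, radii
   Rad(x,y) = √((x−x_c)² + (y−y_c)²), median "overall activity"
   profiles vs. time and vs. radius, radius-averaged spatiotemporal maps,
   cross-sections, and growth-arrest detection (first persistent drop
   below 10% of the activity peak).
4. **Growing / non-growing classification** — envelope segments per tile
   and 3-hour time window feed a multilayer perceptron; out-of-colony
   tiles are masked by presence, never classified.
5. **A synthetic biospeckle simulator** — band-limited circular complex
   Gaussian speckle with per-pixel autoregressive decorrelation
   (E′ = ρE + √(1−ρ²)·ξ, activity ≡ 1−ρ), growing colony disks with
   peripheral activity rings, growth arrest, brightness gain and camera
   noise — with exact ground truth for every stage.

Input formats: multi-page 8/16-bit TIFF (with a JSON metadata sidecar),
directories of TIFF/PNG frames, or the package's lossless RDS container;
results go to CSV/JSON; models serialize to portable JSON. A thin CLI
(`inst/scripts/specklegrow`) wraps the exported functions
(`run`, `simulate`, `signals`, `envelope`, `radial`, `classify`).

## Worked example

A simulated colony (radius 25 px growing at 0.1 px/frame, field
correlation ρ = 0.88 inside, arrest at frame 40 of 60, 30 s frame
interval) processed end to end:

```r
library(specklegrow)

scene <- speckleScene(
  fieldShape = c(100, 100), nFrames = 60, noiseSigma = 1,
  colonies = list(colonyTruth(c(50, 50), radius0 = 25, growthRate = 0.1,
                              arrestFrame = 40L, rhoBody = 0.88,
                              intensityGain = 2)),
  seed = 5)
sim   <- simulateSequence(scene)
field <- computeTimeSignalField(sim@sequence, tileSize = 10, maxShift = 3)
env   <- envelopeField(field, window = 10)
geom  <- detectColonyCenter(env)[[1]]
geom
#> ColonyGeometry: center (50.0, 49.8) px, 33 tiles, radius ~32.4 px

detectGrowthArrest(activityTimeCourse(env, geom))$index
#> [1] 48

peaks <- peakActivityMaps(env)
radialMedianProfile(peaks, radiusMap(tileGrid(env), colonyCenter(geom)),
                    geom, timeBin = 10, radiusBin = 10)@radiusProfile
#>   binCenter medianEnv nTiles
#> 1         5 1.2842999      4
#> 2        15 1.6034951      8
#> 3        25 0.8196863     19
#> 4        35 0.0877700      2
```

The detected center sits on the simulated one (50, 50); the arrest is
flagged at frame 48 — the true arrest frame 40 plus part of the 10-frame
envelope lag; and the median radial profile shows activity concentrated
inside the colony radius and falling off outside — the radial decline of
growth activity the method is designed to expose. The same run as one
call: `runPipeline(system.file("extdata", "quickstart.yaml",
package = "specklegrow"))`, which writes signals, envelopes, profiles,
labels, figures, and a checksummed manifest to a run directory.

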