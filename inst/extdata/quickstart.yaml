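# Quickstart: one growing colony that arrests mid-recording, desk scale.
# Run with:  specklegrow run --config quickstart.yaml
#        or  runPipeline(system.file("extdata", "quickstart.yaml",
#                                    package = "specklegrow"))
scene:
  fieldShape: [100, 100]
  nFrames: 60
  frameInterval: 30        # seconds
  grainSize: 2             # speckle correlation length, px
  noiseSigma: 1            # camera noise, 1% of mean background intensity
  colonies:
    - center: [50, 50]
      radius0: 25          # px
      growthRate: 0.1      # px / frame until arrest
      arrestFrame: 40
      rhoBody: 0.88        # per-frame field correlation while growing
      intensityGain: 2
tileSize: 10
maxShift: 3
envelope:
  window: 10               # frames (desk-scale; 120 = 1 h for real data)
classifier:
  windowFrames: 20
outDir: specklegrow-quickstart
seed: 5
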