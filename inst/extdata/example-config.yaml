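# Example configuration for the scmsi.R command-line wrapper / runPipeline().
# Simulates 2 matrix-application pairs (one CTR + one EGF slide each) and
# runs the full analysis. All omitted parameters take pipelineDefaults().
sim:
  nPairs: 2
  gridShape: [90, 90]
  nColonies: 3
  nSingletons: 14
  noiseCv: 0.2
nIter: 100        # consensus iterations (500 reproduces the full procedure)
seed: 42
doTsne: false
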