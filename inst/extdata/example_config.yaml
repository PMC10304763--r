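# Example pipeline configuration for runPipeline()/readPipelineConfig().
# All randomness derives from this one seed.
seed: 7
nCellTypes: 10
nCpGs: 5000
nMarkersPerType: 10
markerContrast: 0.9
qCutoff: 0.01
diffCutoff: 25
cvFolds: 10
cvRepeats: 10
batchShift: 1.0
batchScale: 1.0
spec:
  groupSizes: {control: 8, STEMI: 8, NSTEMI: 7, UA: 6}
  nPlantedDMRs: 10
  delta: 40
  nSeverityWindows: 10
  severitySlope: 0.05
  coverageLambda: 8
validationGroupSizes: {control: 2, STEMI: 4, NSTEMI: 3, UA: 2}
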