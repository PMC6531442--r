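optics:
  pixelSizeUm: 0.254
  frameIntervalS: 10.0
  nFrames: 20
  fovPx:
  - 64
  - 64
  psfSigmaUm: 0.3
  backgroundLevel: 100.0
  photonScale: 5000.0
  readNoiseSd: 3.0
  penetrationDepthUm: 0.12
behaviors:
- label: stationary
  nParticles: 4
  diffusionCoeffUm2S: 0.0
  speedUmS: 0.0
  jitterSdUm: 0.02
  zStartUm: 0.0
  zRateUmS: 0.0
  birthFrameRange:
  - 1
  - 1
  deathFrameRange:
  - -1
  - -1
  intensity: 1.0
  rampRate: 0.0
  missProb: 0.0
- label: diffusive
  nParticles: 4
  diffusionCoeffUm2S: 0.004
  speedUmS: 0.0
  jitterSdUm: 0.0
  zStartUm: 0.0
  zRateUmS: 0.0
  birthFrameRange:
  - 1
  - 1
  deathFrameRange:
  - -1
  - -1
  intensity: 1.0
  rampRate: 0.0
  missProb: 0.0
- label: directed
  nParticles: 2
  diffusionCoeffUm2S: 0.001
  speedUmS: 0.05
  jitterSdUm: 0.0
  zStartUm: 0.0
  zRateUmS: 0.0
  birthFrameRange:
  - 1
  - 1
  deathFrameRange:
  - -1
  - -1
  intensity: 1.0
  rampRate: 0.0
  missProb: 0.0
- label: appearing
  nParticles: 3
  diffusionCoeffUm2S: 0.0
  speedUmS: 0.0
  jitterSdUm: 0.0
  zStartUm: 0.36
  zRateUmS: 0.002
  birthFrameRange:
  - 1
  - 1
  deathFrameRange:
  - -1
  - -1
  intensity: 1.0
  rampRate: 0.0
  missProb: 0.0
- label: vanishing
  nParticles: 3
  diffusionCoeffUm2S: 0.0
  speedUmS: 0.0
  jitterSdUm: 0.0
  zStartUm: 0.0
  zRateUmS: 0.002
  birthFrameRange:
  - 1
  - 1
  deathFrameRange:
  - -1
  - -1
  intensity: 1.0
  rampRate: 0.0
  missProb: 0.0
detection:
  blobDiameterUm: 0.6
  qualityMin: 120.0
  useAutoThreshold: no
  dogSigmaRatio: 1.6
  subpixel: yes
linking:
  maxLinkDistUm: 1.0
  maxGapDistUm: 1.0
  maxFrameGap: 2
  alternativeCostFactor: 1.05
  gapConvention: frame_difference
profile:
  r2Min: 0.6
  pMax: 0.05
  minPoints: 3
duration:
  shortMaxS: 8.0
  longRule: yes
clearance:
  areaMinUm2: 1.0
  areaMaxUm2: 40.0
  circMin: 0.2
  circMax: 1.0
  connectivity: 8
  excludeBorder: yes
cortex:
  imageSizePx:
  - 256
  - 256
  pixelSizeUm: 0.107
  nClearances: 3
  clearanceAxesUm: ~
  axisRangeUm:
  - 0.8
  - 1.5
  orientations: ~
  clearanceDepth: 0.85
  filamentDensity: 8.0
  filamentWidthUm: 0.08
  rimWidthUm: 0.35
  noiseSd: 0.05
  edgeFalloffStart: 0.7
  edgeLevel: 0.22
  rejectOverlap: yes
  seed: 1
seed: 20260929
outputDir: cg-output
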