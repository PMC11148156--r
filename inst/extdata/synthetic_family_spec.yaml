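nSequences: 8
length: 60
cladeSizes:
- 3
- 3
- 2
substitutionRate: 0.15
plantedPositions:
- 12
- 30
plantedResidues:
- - G
  - A
  - S
  - V
  - F
- - D
  - E
  - Q
  - K
plantedSlopes:
- -0.012
- 0.008
baselineLog10: 1.0
noiseSd: 0.15
detectionFloor: 0.001
indelRate: 0.0
seed: 2026
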