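# Carcinoma-associated fibroblast panel. aSMA is intensity-tiered at the
# cohort-wide mean over positive cells (high = strictly above the mean);
# "_single" phenotypes are negative for all other panel markers. The
# denominator definition (any CAF marker positive) is the population over
# which combination fractions are computed.
name: caf
markers: [aSMA, FAP, CD90, NGFR, COL1A1]
tiered_markers: [aSMA]
phenotypes:
  - name: FAP_single
    positive: [FAP]
    exclusive_single: true
  - name: aSMA_high_single
    positive: [aSMA]
    tiers: {aSMA: high}
    exclusive_single: true
  - name: aSMA_low_single
    positive: [aSMA]
    tiers: {aSMA: low}
    exclusive_single: true
  - name: COL1A1_single
    positive: [COL1A1]
    exclusive_single: true
  - name: NGFR_single
    positive: [NGFR]
    exclusive_single: true
  - name: CD90_COL1A1
    positive: [CD90, COL1A1]
  - name: aSMA_COL1A1
    positive: [aSMA, COL1A1]
  - name: aSMA_CD90_COL1A1
    positive: [aSMA, CD90, COL1A1]
  - name: FAP_aSMA
    positive: [FAP, aSMA]
  - name: FAP_CD90
    positive: [FAP, CD90]
  - name: NGFR_CD90
    positive: [NGFR, CD90]
  - name: NGFR_COL1A1
    positive: [NGFR, COL1A1]
partitions: []
denominator:
  name: fibroblast_any
  positive: [aSMA, FAP, CD90, NGFR, COL1A1]
  match_any: true
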