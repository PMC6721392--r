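# mixstrat pipeline configuration template.
# Any key may be omitted; the package default then applies.

mode: simulate          # simulate | ingest
# input: cohort.csv     # patient CSV, ingest mode only
seed: 1                 # drives every random draw in simulate mode

method: dichotomy       # dichotomy | feature_matrix
correction: holm        # holm | bonferroni (pairwise Mann-Whitney family)

# Variables summarized per group and tested pairwise.
variables: [age, t_memory, t_executive, md_z, mmp1, mmp10, ptau]

# Biomarker cut-points. Positivity holds at the exact cut
# (>= for "high" markers, <= for "low" markers).
thresholds:
  ptau_high: 68            # pg/mL; at or above is tau-positive
  ab_ratio_low: 0.07       # amyloid 42/40 ratio; at or below is amyloid-positive
  md_z_high: 2.0           # MD z-score; at or above is vascular-positive
  t_memory_low: 40         # T-score; at or below marks a memory deficit
  t_executive_low: 40      # T-score; at or below marks an executive deficit
  albumin_index_high: 7    # at or above marks blood-brain-barrier leakage
  ad_axis_rule: either     # either | both | ptau_only | amyloid_only

# Synthetic-cohort sizes per biological group (simulate mode).
cohort:
  sizes:
    SIVD: 53
    AD: 25
    MX: 22
    MI: 18
    LA: 29
    CONTROL: 25
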