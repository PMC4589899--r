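# Example run configuration for the tagarray CLI.
# Any key omitted falls back to the package default.
r2_threshold: 0.8        # pairwise tagging threshold
window_bp: 250000        # LD horizon in base pairs
budget: 782000           # array marker budget
min_mac_exclusive: 5     # keep markers with MAC > 5 in the reference DB
maf_cutoffs:             # booster common-variant cutoffs (strict >)
  CEU: 0.02
  AFR: 0.05
mask_fraction: 0.002     # masked-SNP imputation evaluation (0.2%)
info_threshold: 0.8      # INFO filter for headline masked accuracy
seed: 1

# Synthetic-study conditions used by `simulate`
populations:
  CEU: 48
  ASN: 24
  YRI: 13
n_blocks: 50
markers_per_block: 20
n_trios: 8
n_duplicate_pairs: 50
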