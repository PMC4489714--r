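# Algorithm 1: open ISPO-style analysis grid (version 1).
# DELETION when R/G <= ratio_max; NORMAL for the listed combinations;
# IMBALANCED otherwise (undefined ratio, green = 0, falls here too).
name: ALG1
kind: grid
ratio_max: 0.5
normal:
  - "2/2"
deletion_cutoff: 55.0
imbalance_cutoff: 30.0
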