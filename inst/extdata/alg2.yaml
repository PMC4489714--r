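# Algorithm 2: closed 24-combination lookup (version 1).
# Combinations not listed are UNCLASSIFIED.
name: ALG2
kind: lookup
classes:
  DELETION:
    - "2/0"
    - "2/1"
    - "3/0"
    - "3/1"
    - "4/1"
    - "4/2"
    - "5/2"
    - "6/2"
    - "6/3"
  NORMAL:
    - "2/2"
    - "1/2"
  IMBALANCED:
    - "1/3"
    - "1/4"
    - "2/3"
    - "2/4"
    - "2/5"
    - "3/3"
    - "3/4"
    - "4/3"
    - "4/4"
    - "4/5"
    - "5/4"
    - "5/5"
    - "5/6"
deletion_cutoff: 55.0
imbalance_cutoff: 20.0
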