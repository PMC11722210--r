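# Default minimal NK-cell signaling network: six protein species and
# six mass-action reactions. Rates tagged free:K reference the freely
# varying parameter theta_K; the three fixed rates (0.12, 0.14, 0.05
# 1/s) pin down the remaining reactions so all rates are identifiable.
# Edit this file (species order = state column order) to change the
# topology or the placement of the fixed rates without touching code.
species:
  - Syk
  - Vav1
  - SykVav1
  - pVav1
  - SHP1
  - SHP1pVav1
reactions:
  - "Syk + Vav1 -> SykVav1 @ free:1"
  - "SykVav1 -> Syk + Vav1 @ fixed:0.12"
  - "SykVav1 -> Syk + pVav1 @ free:2"
  - "SHP1 + pVav1 -> SHP1pVav1 @ free:3"
  - "SHP1pVav1 -> SHP1 + pVav1 @ fixed:0.14"
  - "SHP1pVav1 -> SHP1 + Vav1 @ fixed:0.05"
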