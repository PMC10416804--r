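# Bundled example data

- `housekeeping_counts_synthetic.csv` — **synthetic** raw counts of a
  22-gene housekeeping panel across 43 single cells, generated from a fixed
  seed with negative-binomial draws. It mirrors the *structure* of a
  published housekeeping QC table (cell naming scheme `E-*`/`Es-*`/`A-*`,
  eight planted failed libraries: A-59, A-60, A-62, E-13, Es-30, Es-36,
  Es-37, Es-55) so the housekeeping filter's accounting can be demonstrated
  end to end. It is not measured data and does not reproduce any published
  measurement.
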