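# Demonstration run: study-like synthetic design (41 adults, 4 groups),
# shortened observation effort so the demo completes quickly.
synthetic:
  n_scans: 150
  periods: [resocialisation, year2]
behaviours: [proximity, grooming]
alpha: 0.05
min_class_n: 3
random_by: group
seed: 42
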