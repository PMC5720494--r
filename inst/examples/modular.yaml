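# modular analysis battery: decouple/clamp module 1 and 2 for both genotypes
genotype: WT
scan:
  ktt_grid: [0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0]
  ras_onset: 24
integrator:
  burn_in: 240
output_dir: modular_run
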