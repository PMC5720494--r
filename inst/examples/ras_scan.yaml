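# RAS dose-response: transient period vs ktt on the knockout background
genotype: KO
scan:
  ktt_grid: [0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0]
  ras_onset: 24
integrator:
  burn_in: 240
output_dir: ras_scan_run
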