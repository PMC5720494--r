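# Ink4a/Arf double knockout at normal RAS (ktt = 1)
genotype: KO
integrator:
  burn_in: 240
  horizon: 130
  out_dt: 0.02
analysis:
  species: [Bmal, Per, Cry, Rev, Ror]
output_dir: ko_run
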