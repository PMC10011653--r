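# Univariable synthetic scenario at the operating point of a large
# two-sample binary-exposure/binary-outcome MR analysis: 128 instruments
# explaining 13.9% of exposure variance, true log odds ratio ln(1.069).
scenario:
  theta: 0.0667239
  n_snps: 128
  r2_target: 0.139
  pleiotropy_mode: none
  n_exposure: 659316
  n_outcome: 256896
  seed: 1
ivw_model: auto
n_boot: 1000
presso_n_sim: 1000
presso_alpha: 0.05
seed: 1
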