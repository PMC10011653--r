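# Two-exposure synthetic scenario for multivariable MR: 829 joint
# instruments, true direct effects ln(1.080) (primary exposure) and
# ln(1.189) (adjustment exposure), exposure-effect correlation 0.4.
scenario:
  theta: [0.0769610, 0.1731656]
  n_snps: 829
  r2_target: [0.139, 0.06]
  pleiotropy_mode: none
  exposure_correlation: 0.4
  n_exposure: [659316, 681275]
  n_outcome: 256896
  seed: 1
ivw_model: auto
n_boot: 1000
presso_n_sim: 0
seed: 1
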