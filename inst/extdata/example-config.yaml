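# Example run configuration: overrides merge into the named preset
# (see read_run_config()).
name: mid
reduced: yes
adaptation:
  n_spinup: 10
  n_adapt: 15
  kappa: 5
fiber:
  tp:
    u_t: 0.0
    slope: 0.2
    height: 0.3
seed: 1
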