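# Example model/forcing/thermal configuration. All keys optional; model
# keys mirror the parameter names of nfkb_params().
model:
  k_Nin: 5.4
  IKK_tot: 2.0
forcing:
  tnf_base: 0.5
  temp_mode: sinusoid
  temp_base: 37
  temp_amplitude: 1.0
  temp_frequency: 0.01
thermal:
  T_ref_K: 310.15
  rates:
    k_i: {law: reaction, S: 20}
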