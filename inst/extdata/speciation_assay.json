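{
  "total_roh_uM": 2,
  "total_rbp_uM": 2,
  "total_ttr_uM": 4,
  "kd_roh_rbp_uM": 0.1,
  "kd_holo_ttr_uM": 0.25,
  "variant": "wt"
}
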