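{
  "required_fields": ["gpc", "levels", "conditional", "inference", "qol_table", "tox_table", "survival", "meta"],
  "gpc_fields": ["n_pairs", "total_a_wins", "total_b_wins", "final_ties", "p_better_a", "p_better_b", "ntb", "win_ratio"],
  "inference_fields": ["ntb_ci", "win_ratio_ci", "p_value", "n_boot", "n_perm", "alpha"]
}
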