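# Default 24-month cohort study configuration: 14 control vs 8 transgenic
# animals, genotype effects from the arcab_24mo table, 5% biological
# scatter, measurement noise at SNR 40.
seed: 1
out_dir: qvasc_out
cohort:
  n_control: 14
  n_transgenic: 8
  effects: arcab_24mo
  noise_sigma: 0.025
  scatter_sd: 0.05
  shape: [24, 24, 6]
  ge_upsample: 2
  n_frames: 300
  baseline_frames: 75
  age_group: 24mo
  modalities: [steady_state, dsc]
acquisition:
  te_ge_s: 0.0055
  te_se_s: 0.030
  te_dsc_s: 0.010
  tr_dsc_s: 0.4
processing:
  r_trunc: 0.2
  aif_voxels: 10
  epsilon: 1.0e-6
  n_perm: 2000
  statistic: mean
write_volumes: false
log_level: info
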