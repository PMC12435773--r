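{
  "name": "wt_cag0",
  "zone1_weight": -0.07,
  "dim_prevalence": 0.1,
  "dim_colocal_prob": 0.2,
  "spb_locus_mean_dist": 0.8,
  "spb_locus_sd_dist": 0.15,
  "nucleus_radius": 1,
  "pixel_size": 0.065,
  "z_step": 0.175,
  "n_planes": 25,
  "psf_sigma": 0.11,
  "psf_sigma_z": 0.27,
  "snr": 10,
  "stage_mix": {
    "G1": 0.25,
    "earlyS": 0.15,
    "midlateS": 0.6
  }
}
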