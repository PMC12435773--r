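{
  "name": "mms_hu",
  "zone1_weight": 0.22,
  "dim_prevalence": 0.87,
  "dim_colocal_prob": 0.5,
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
    "G1": 0,
    "earlyS": 0,
    "midlateS": 1
  }
}
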