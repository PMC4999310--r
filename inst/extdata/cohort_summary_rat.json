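{
  "species": "rat",
  "source": "published cohort means: MPFA N_frs and LM contact counts per connection; AZ areas and docked-vesicle counts per AZ from serial-section EM reconstructions",
  "mean_n_frs": 4.7,
  "mean_n_lm": 2.9,
  "mean_az_area_um2": 0.041,
  "mean_docked_per_az": 1.3
}
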