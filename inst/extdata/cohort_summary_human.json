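{
  "species": "human",
  "source": "published cohort means: MPFA N_frs and LM contact counts per connection; AZ areas and docked-vesicle counts per AZ from serial-section EM reconstructions",
  "mean_n_frs": 20.5,
  "mean_n_lm": 3.3,
  "mean_az_area_um2": 0.077,
  "mean_docked_per_az": 4.2
}
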