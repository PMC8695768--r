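paper2012:
  stand_id: '2012'
  planting_year: 2012
  n_trees: 5
  A_mean: 358.5
  A_sd: 71.7
  beta: 1.68
  k: 0.0064
  pulse_split: 0.55
  pulse2_offset: 90.0
  enlarge_days: 18.0
  thicken_days: 40.0
  cambial_baseline: 2.5
  cambial_gain: 10.0
  noise_model: poisson
  noise_sd: 1.0
  sampling_interval_days: 9
  season_start_doy: 51
  season_end_doy: 340
  grow_start_doy: 72.0
  grow_end_doy: 300.0
  onset_sd_days: 4.0
  end_sd_days: 10.0
paper2006:
  stand_id: '2006'
  planting_year: 2006
  n_trees: 5
  A_mean: 116.4
  A_sd: 23.28
  beta: 1.46
  k: 0.0073
  pulse_split: 0.55
  pulse2_offset: 90.0
  enlarge_days: 18.0
  thicken_days: 40.0
  cambial_baseline: 2.5
  cambial_gain: 10.0
  noise_model: poisson
  noise_sd: 1.0
  sampling_interval_days: 9
  season_start_doy: 51
  season_end_doy: 340
  grow_start_doy: 72.0
  grow_end_doy: 298.0
  onset_sd_days: 4.0
  end_sd_days: 10.0
paper2000:
  stand_id: '2000'
  planting_year: 2000
  n_trees: 5
  A_mean: 243.4
  A_sd: 48.68
  beta: 1.67
  k: 0.0073
  pulse_split: 0.55
  pulse2_offset: 90.0
  enlarge_days: 18.0
  thicken_days: 40.0
  cambial_baseline: 2.5
  cambial_gain: 10.0
  noise_model: poisson
  noise_sd: 1.0
  sampling_interval_days: 9
  season_start_doy: 51
  season_end_doy: 340
  grow_start_doy: 72.0
  grow_end_doy: 288.0
  onset_sd_days: 4.0
  end_sd_days: 10.0
paper1993:
  stand_id: '1993'
  planting_year: 1993
  n_trees: 5
  A_mean: 123.4
  A_sd: 24.68
  beta: 1.49
  k: 0.0075
  pulse_split: 0.55
  pulse2_offset: 90.0
  enlarge_days: 18.0
  thicken_days: 40.0
  cambial_baseline: 2.5
  cambial_gain: 10.0
  noise_model: poisson
  noise_sd: 1.0
  sampling_interval_days: 9
  season_start_doy: 51
  season_end_doy: 340
  grow_start_doy: 72.0
  grow_end_doy: 280.0
  onset_sd_days: 4.0
  end_sd_days: 10.0
paper1969:
  stand_id: '1969'
  planting_year: 1969
  n_trees: 5
  A_mean: 94.7
  A_sd: 18.94
  beta: 1.38
  k: 0.0077
  pulse_split: 0.55
  pulse2_offset: 90.0
  enlarge_days: 18.0
  thicken_days: 40.0
  cambial_baseline: 2.5
  cambial_gain: 10.0
  noise_model: poisson
  noise_sd: 1.0
  sampling_interval_days: 9
  season_start_doy: 51
  season_end_doy: 340
  grow_start_doy: 72.0
  grow_end_doy: 272.0
  onset_sd_days: 4.0
  end_sd_days: 10.0
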