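# Default synthetic scenario: two workers, one hour, resting workload.
n_workers: 2
duration_min: 60
hr_profiles:
  - t_start_min: [0]
    bpm: [72]
skin_profiles:
  - t_start_min: [0]
    temp_c: [35.2]
hr_noise_sd: 1
spike_rate: 0.01
weather_args:
  ta_mean_c: 33
  ta_amp_c: 1
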