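# Default synthetic calibration study: four exposure groups with the
# record counts of the pooled calibration structure the score models use.
group_counts:
  powders_granules: 408
  comminuting: 112
  low_volatile: 256
  volatile: 176
companies_per_group: 12
workers_per_company: 3
n_strata: 3
sigma_bc: 0.5
sigma_bw: 0.3
measurement_gsd: 1.5
p_mis: 0.3
seed: 1
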