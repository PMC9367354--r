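# Breed calibration: Lithuanian Red open population (LR).
breed_id: LR
herd_size_target: 200
ecm_305d:
  "1": 6907
  "2": 7596
  "3+": 7469
fat_pct: 4.43
protein_pct: 3.50
calving_interval_days: 412
age_first_calving_months: 25.8
heat_obs_rate_cows_pct: 45.16
heat_obs_rate_heifers_pct: 55.08
conception_rate_cows_pct: 45       # = 100 / 2.2 inseminations, rounded
conception_rate_heifers_pct: 58.82
start_breeding_days: 46.67
incidence_per_100cy:
  milk_fever: 3.5
  dystocia: 1.3
  metritis: 7.0
  ketosis: 4.4
  mastitis: 26
  lameness: 19
stillbirth_rate: 5.2               # % of calvings
early_calf_mortality: 3.5          # package default (not recorded)
late_calf_mortality: 2.5           # package default (not recorded)
cow_mortality: 5.0                 # package default (not recorded)
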