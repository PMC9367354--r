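# Breed calibration: Lithuanian Red old genotype (LROG).
# Conception rate for cows is a simulated (model-reconciled) value.
breed_id: LROG
herd_size_target: 200
ecm_305d:
  "1": 4916
  "2": 5553
  "3+": 5949
fat_pct: 4.56
protein_pct: 3.48
calving_interval_days: 421
age_first_calving_months: 24.6
heat_obs_rate_cows_pct: 45.24
heat_obs_rate_heifers_pct: 55.56
conception_rate_cows_pct: 50
conception_rate_heifers_pct: 62.5
start_breeding_days: 45.62
incidence_per_100cy:
  milk_fever: 3.5
  dystocia: 1.3
  metritis: 7.0
  ketosis: 4.4
  mastitis: 26
  lameness: 19
stillbirth_rate: ~                 # not recorded ("-"): defaults to LR's 5.2
early_calf_mortality: 3.5          # package default (not recorded)
late_calf_mortality: 2.5           # package default (not recorded)
cow_mortality: 5.0                 # package default (not recorded)
feed_model:
  concentrate_share: 0.25          # lower concentrate use at the lower yield
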