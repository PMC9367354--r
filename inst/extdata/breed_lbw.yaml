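# Breed calibration: Lithuanian Black-and-White open population (LBW).
# Production and reproduction means from the 2016-2017 herd-recording
# productivity reports; disease treatment incidences per 100 cow-years.
# Rates printed as percent keep the percent scale here (keys *_pct).
breed_id: LBW
herd_size_target: 200          # cows (average herd size)
ecm_305d:                      # kg ECM per 305-d lactation, by parity class
  "1": 6741
  "2": 7648
  "3+": 7526
fat_pct: 4.31
protein_pct: 3.35
calving_interval_days: 424
age_first_calving_months: 27.2
heat_obs_rate_cows_pct: 43.16      # % of eligible oestruses detected
heat_obs_rate_heifers_pct: 59.91
conception_rate_cows_pct: 50       # % per insemination (= 100 / 2.0 inseminations)
conception_rate_heifers_pct: 62.5
start_breeding_days: 44.27         # voluntary waiting period, days postpartum
incidence_per_100cy:               # treated cases per 100 cow-years
  milk_fever: 3.5
  dystocia: 1.3
  metritis: 8.0
  ketosis: 4.4
  mastitis: 26
  lameness: 19
stillbirth_rate: 6.5               # % of calvings
# Rearing and cow mortality are not in the recording tables; package
# defaults (typical Northern-European herd-recording magnitudes):
early_calf_mortality: 3.5          # % dying, 3-14 d postpartum window
late_calf_mortality: 2.5           # % dying, 189-458 d postpartum window
cow_mortality: 5.0                 # % per cow-year
# disease_effects / feed_model / management omitted -> documented defaults
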