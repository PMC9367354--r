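# Price and cost book (EUR, year 2019) - LBW. Heifer, bull-calf and semen
# prices are the breed-specific (higher) levels.
milk_price_per_kg_ecm: 0.29        # EUR per kg ECM delivered to the dairy
slaughter_price_per_kg_live: 0.94  # EUR per kg live weight, slaughter cows
dead_cow_disposal: 33              # fallen-stock fee per dead cow
dead_heifer_disposal: 21
dead_calf_disposal: 9
pregnant_heifer_price: 1300
open_heifer_price: 800
bull_calf_price: 200
milk_powder_per_kg: 2.02
heifer_concentrate_per_sfu: 0.23
heifer_roughage_per_sfu: 0.10
# cow_feed_per_sfu omitted -> calibration default 0.2073 EUR/SFU
treatment_cost:                    # per treated case
  mastitis: 89
  milk_fever: 54
  dystocia: 69
  metritis: 72
  ketosis: 70
  lameness: 65                     # not in the price book; package default
semen_cost: 20                     # per insemination
other_costs_per_cow_year: 202      # calibration constant (statement anchor)
other_costs_per_heifer_year: 50    # calibration constant (statement anchor)
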