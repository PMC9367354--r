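# Translation of a herd_parameters object into the flat parameter list the
# C++ weekly-step engine consumes. All rate inputs are converted to weekly
# event probabilities here, in one place:
#   * hazard diseases: h = (I/100)/52 per cow-week, so that the expected case
#     count equals (I/100) x cow-years by construction (a 52-week year is the
#     unit of exposure throughout);
#   * dystocia: an at-calving event with a self-calibrating probability
#     q = (I/100) x cow-years/calvings (maintained inside the engine);
#   * mortality and voluntary culling: linear weekly hazards (annual/52);
#   * rearing mortality: window probabilities converted to per-week hazards
#     within the 3-14 d (weeks 1-2) and 189-458 d (weeks 27-65) windows.

# expected number of 3-week cycles to conception when at most n_cycles are
# available (truncated geometric); used to centre the heifer breeding age on
# the calibrated age at first calving
.mean_cycles_truncated <- function(p, n_cycles) {
  q <- 1 - p
  if (p <= 0) return(n_cycles)
  (1 / p) - n_cycles * q^n_cycles / (1 - q^n_cycles)
}

#' @keywords internal
engine_params <- function(p) {
  stopifnot(inherits(p, "herd_parameters"))
  mg <- p$management
  fm <- p$feed_model
  de <- p$disease_effects

  curve <- lactation_curve_weekly(p$ecm_305d)

  dur <- vapply(de[DISEASES], function(e) as.integer(e$effect_duration_weeks),
                integer(1))
  loss <- sapply(DISEASES, function(d)
    de[[d]]$milk_loss_frac_of_305d * unname(p$ecm_305d) / dur[[d]])  # 3 x 6

  hazard <- p$incidence_per_100cy / 100 / 52
  hazard[["dystocia"]] <- 0

  vwp_weeks <- p$start_breeding_days / 7
  elig_week_cow <- as.integer(ceiling(vwp_weeks + mg$anoestrus_weeks))

  # heifer breeding eligibility: fixed calibration constant of the breed,
  # frozen at herd_parameters() construction (see config_io.R)
  h_elig <- as.integer(mg$heifer_breeding_age_weeks)

  list(
    n_target = p$herd_size_target,
    yield_week = curve,
    loss_weekly = loss,
    conc_mult = vapply(de[DISEASES], function(e) e$conception_multiplier,
                       numeric(1)),
    add_mort = vapply(de[DISEASES], function(e) e$added_mortality_risk,
                      numeric(1)),
    add_cull = vapply(de[DISEASES], function(e) e$added_cull_risk, numeric(1)),
    hazard = unname(hazard[DISEASES]),
    duration = unname(dur),
    dyst_target = unname(p$incidence_per_100cy[["dystocia"]] / 100),
    ci_weeks_guess = p$calving_interval_days / 7,
    p_stillbirth = p$stillbirth_rate / 100,
    dyst_sb_mult = mg$dystocia_stillbirth_multiplier,
    dyst_cow_mort = mg$dystocia_cow_mortality_risk,
    h_cow_mort = p$cow_mortality / 100 / 52,
    h_cull = mg$base_cull_rate / 52,
    elig_week_cow = elig_week_cow,
    dnb_week = as.integer(mg$do_not_breed_week),
    cull_dnb_week = as.integer(mg$do_not_breed_cull_week),
    gestation = as.integer(mg$gestation_weeks),
    dry_wp = as.integer(mg$gestation_weeks - mg$dry_period_weeks),
    cycle = as.integer(mg$cycle_weeks),
    ho_cow = p$heat_obs_rate_cows,
    cr_cow = p$conception_rate_cows,
    ho_heif = p$heat_obs_rate_heifers,
    cr_heif = p$conception_rate_heifers,
    h_elig_week = h_elig,
    h_fail_week = as.integer(h_elig + mg$heifer_fail_cycles * mg$cycle_weeks),
    h_early = 1 - (1 - p$early_calf_mortality / 100)^(1 / 2),
    h_late = 1 - (1 - p$late_calf_mortality / 100)^(1 / 39),
    early_lo = 1L, early_hi = 2L, late_lo = 27L, late_hi = 65L,
    sex_ratio_female = 0.5,
    maint_sfu_day = fm$maintenance_sfu_per_day,
    sfu_per_kg = fm$sfu_per_kg_ecm,
    heifer_sfu_day = fm$heifer_sfu_per_day,
    powder_kg_day = fm$calf_milk_powder_kg_per_day,
    cow_weight = mg$cow_slaughter_weight_kg,
    heifer_weight = mg$heifer_slaughter_weight_kg,
    male_sale_age = 2L,
    powder_until_age = as.integer(fm$milk_powder_until_weeks),
    sell_decision_wp = as.integer(mg$heifer_sell_decision_wp)
  )
}
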