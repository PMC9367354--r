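# Breed calibration and price-book configuration.
#
# Configs are YAML files whose keys mirror the calibration table row labels:
# production means (305-d ECM per parity class, fat/protein %), reproduction
# means (calving interval, age at first calving, heat observation and
# conception rates, start of breeding), disease incidences per 100 cow-years,
# stillbirth (% of calvings), rearing/cow mortality, and three optional
# blocks (disease_effects, feed_model, management) that are filled with
# documented defaults when absent. Rates that the tables print as percent are
# stored in the files as percent (keys suffixed `_pct`) and held internally
# as probabilities.

#' Default per-disease effect assumptions
#'
#' The calibration tables give disease incidences but not the within-herd
#' consequences of a case. These defaults encode the assumed effect of one
#' case: milk loss as a fraction of the 305-d yield (spread uniformly over
#' the effect window), a multiplicative depression of the conception rate
#' while the episode is active, one-time added death/cull risks at onset,
#' and the episode duration in weeks. All values are overridable per breed
#' config and are logged at WARN level when defaulted.
#'
#' @return named list (one element per disease) of effect lists.
#' @export
default_disease_effects <- function() {
  eff <- function(loss, conc, mort, cull = 0, dur = 8L) {
    list(milk_loss_frac_of_305d = loss, conception_multiplier = conc,
         added_mortality_risk = mort, added_cull_risk = cull,
         effect_duration_weeks = dur)
  }
  list(
    milk_fever = eff(0.02, 1.00, 0.005),
    dystocia   = eff(0.00, 1.00, 0.000),
    metritis   = eff(0.02, 0.85, 0.000),
    ketosis    = eff(0.03, 0.85, 0.000),
    mastitis   = eff(0.05, 1.00, 0.005),
    lameness   = eff(0.03, 0.85, 0.000)
  )
}

#' Default feed model
#'
#' Energy requirements in Scandinavian feed units (SFU): cow maintenance per
#' day, marginal SFU per kg ECM produced, the concentrate share of the heifer
#' ration (used to blend the per-SFU heifer feed prices), heifer maintenance
#' per day, and the milk-powder allowance for pre-weaned calves.
#'
#' @return named list of feed parameters.
#' @export
default_feed_model <- function() {
  list(maintenance_sfu_per_day = 5.0,
       sfu_per_kg_ecm = 0.43,
       concentrate_share = 0.35,
       heifer_sfu_per_day = 4.7,
       calf_milk_powder_kg_per_day = 0.9,
       milk_powder_until_weeks = 9L)
}

#' Default management constants
#'
#' Herd-policy and biology constants that the calibration tables do not
#' print: the voluntary non-reproductive cull rate, the postpartum anoestrus
#' delay beyond the voluntary waiting period (the reproduction-calibration
#' constant that makes simulated calving intervals match the calibration
#' means), slaughter live weights, dystocia risk bumps, and the fixed weekly
#' time grid (40-week gestation, 7-week dry period, 3-week oestrus cycle).
#'
#' @return named list of management parameters.
#' @export
default_management <- function() {
  list(base_cull_rate = 0.20,            # voluntary culls per cow-year
       anoestrus_weeks = 3,              # weeks beyond VWP before first heat
       cow_slaughter_weight_kg = 550,
       heifer_slaughter_weight_kg = 480,
       dystocia_stillbirth_multiplier = 2.0,
       dystocia_cow_mortality_risk = 0.005,
       gestation_weeks = 40L,
       dry_period_weeks = 7L,
       cycle_weeks = 3L,
       do_not_breed_week = 44L,          # open past this week in milk -> cull
       do_not_breed_cull_week = 50L,
       heifer_sell_decision_wp = 36L,    # surplus sale point, weeks pregnant
       heifer_fail_cycles = 11L)         # open heifer cull after this many cycles
}

#' Construct and validate a herd parameter set
#'
#' @param breed_id breed label, e.g. `"LBW"`, `"LR"`, `"LROG"` or a custom tag.
#' @param herd_size_target target number of cows.
#' @param ecm_305d named numeric of 305-d ECM (kg) for parity classes
#'   `"1"`, `"2"`, `"3+"`.
#' @param fat_pct,protein_pct milk composition, percent.
#' @param calving_interval_days,age_first_calving_months,start_breeding_days
#'   reproduction means (days / months / days postpartum).
#' @param heat_obs_rate_cows,heat_obs_rate_heifers probability that an
#'   eligible oestrus is detected.
#' @param conception_rate_cows,conception_rate_heifers probability of
#'   pregnancy per insemination.
#' @param incidence_per_100cy named numeric of disease incidences per 100
#'   cow-years for milk_fever, dystocia, metritis, ketosis, mastitis,
#'   lameness.
#' @param stillbirth_rate percent of calvings.
#' @param early_calf_mortality percent dying in the 3-14 d window.
#' @param late_calf_mortality percent dying in the 189-458 d window.
#' @param cow_mortality percent per cow-year.
#' @param disease_effects,feed_model,management optional overrides of
#'   [default_disease_effects()], [default_feed_model()],
#'   [default_management()]; partial lists are merged over the defaults.
#' @param quiet suppress WARN logging of defaulted blocks.
#' @return object of class `herd_parameters`.
#' @export
herd_parameters <- function(breed_id, herd_size_target, ecm_305d, fat_pct,
                            protein_pct, calving_interval_days,
                            age_first_calving_months, heat_obs_rate_cows,
                            heat_obs_rate_heifers, conception_rate_cows,
                            conception_rate_heifers, start_breeding_days,
                            incidence_per_100cy, stillbirth_rate,
                            early_calf_mortality, late_calf_mortality,
                            cow_mortality, disease_effects = NULL,
                            feed_model = NULL, management = NULL,
                            quiet = FALSE) {
  if (is.null(disease_effects) && !quiet)
    ev_log("WARN", "disease_effects not supplied for ", breed_id,
           ": using package defaults (not calibration data)")
  de <- default_disease_effects()
  for (d in names(disease_effects))
    de[[d]] <- modifyList(de[[d]], disease_effects[[d]])
  fm <- modifyList(default_feed_model(), feed_model %||% list())
  mg <- modifyList(default_management(), management %||% list())
  if (is.null(mg$heifer_breeding_age_weeks)) {
    # back-calculate the heifer breeding eligibility age from the calibrated
    # age at first calving once, at construction time: it is a calibration
    # constant of the breed and must stay fixed when fertility parameters
    # are perturbed in scenario pairs
    afc_weeks <- as.numeric(age_first_calving_months) * 365.25 / 12 / 7
    p_cycle <- as.numeric(heat_obs_rate_heifers) *
      as.numeric(conception_rate_heifers)
    e_cycles <- .mean_cycles_truncated(p_cycle, mg$heifer_fail_cycles)
    mg$heifer_breeding_age_weeks <-
      max(40L, as.integer(round(afc_weeks - mg$gestation_weeks - 1 -
                                  (e_cycles - 1) * mg$cycle_weeks)))
  }

  p <- structure(list(
    breed_id = as.character(breed_id),
    herd_size_target = as.integer(herd_size_target),
    ecm_305d = unlist(ecm_305d)[c("1", "2", "3+")],
    fat_pct = as.numeric(fat_pct),
    protein_pct = as.numeric(protein_pct),
    calving_interval_days = as.numeric(calving_interval_days),
    age_first_calving_months = as.numeric(age_first_calving_months),
    heat_obs_rate_cows = as.numeric(heat_obs_rate_cows),
    heat_obs_rate_heifers = as.numeric(heat_obs_rate_heifers),
    conception_rate_cows = as.numeric(conception_rate_cows),
    conception_rate_heifers = as.numeric(conception_rate_heifers),
    start_breeding_days = as.numeric(start_breeding_days),
    incidence_per_100cy = unlist(incidence_per_100cy)[DISEASES],
    stillbirth_rate = as.numeric(stillbirth_rate),
    early_calf_mortality = as.numeric(early_calf_mortality),
    late_calf_mortality = as.numeric(late_calf_mortality),
    cow_mortality = as.numeric(cow_mortality),
    disease_effects = de,
    feed_model = fm,
    management = mg
  ), class = "herd_parameters")
  validate_herd_parameters(p)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a herd parameter set
#'
#' Checks the domain invariants: probabilities in \[0, 1\], incidences and
#' yields non-negative, percent rates in \[0, 100\], effect durations of at
#' least one week, concentrate share in \[0, 1\]. Throws a classed
#' `herdEV_validation_error` naming the offending field.
#'
#' @param p a `herd_parameters` object.
#' @return `p`, invisibly.
#' @export
validate_herd_parameters <- function(p) {
  fail <- function(field, msg)
    stop(structure(class = c("herdEV_validation_error", "error", "condition"),
                   list(message = sprintf("invalid %s: %s", field, msg),
                        call = NULL)))
  prob_fields <- c("heat_obs_rate_cows", "heat_obs_rate_heifers",
                   "conception_rate_cows", "conception_rate_heifers")
  for (f in prob_fields) {
    v <- p[[f]]
    if (!is.finite(v) || v < 0 || v > 1)
      fail(f, sprintf("probability %s outside [0, 1]", format(v)))
  }
  pct_fields <- c("stillbirth_rate", "early_calf_mortality",
                  "late_calf_mortality", "cow_mortality")
  for (f in pct_fields) {
    v <- p[[f]]
    if (!is.finite(v) || v < 0 || v > 100)
      fail(f, sprintf("percentage %s outside [0, 100]", format(v)))
  }
  if (anyNA(p$incidence_per_100cy) || any(p$incidence_per_100cy < 0))
    fail("incidence_per_100cy", "incidences must be present and >= 0")
  if (anyNA(p$ecm_305d) || any(p$ecm_305d <= 0))
    fail("ecm_305d", "305-d yields must be present and > 0")
  if (p$herd_size_target < 1) fail("herd_size_target", "must be >= 1")
  if (p$calving_interval_days <= 280)
    fail("calving_interval_days", "must exceed gestation length")
  for (d in names(p$disease_effects)) {
    e <- p$disease_effects[[d]]
    if (e$effect_duration_weeks < 1)
      fail(paste0("disease_effects$", d), "effect_duration_weeks must be >= 1")
    if (e$conception_multiplier < 0 || e$conception_multiplier > 1)
      fail(paste0("disease_effects$", d), "conception_multiplier outside [0, 1]")
    if (e$milk_loss_frac_of_305d < 0 || e$milk_loss_frac_of_305d > 1)
      fail(paste0("disease_effects$", d), "milk_loss_frac outside [0, 1]")
    if (e$added_mortality_risk < 0 || e$added_mortality_risk > 1 ||
        e$added_cull_risk < 0 || e$added_cull_risk > 1)
      fail(paste0("disease_effects$", d), "risk bump outside [0, 1]")
  }
  fm <- p$feed_model
  if (fm$concentrate_share < 0 || fm$concentrate_share > 1)
    fail("feed_model$concentrate_share", "outside [0, 1]")
  if (fm$maintenance_sfu_per_day <= 0 || fm$sfu_per_kg_ecm < 0)
    fail("feed_model", "SFU requirements must be positive")
  invisible(p)
}

#' Load a breed calibration config
#'
#' Reads a YAML breed file, converts percent-scaled keys (`*_pct`) to
#' probabilities, fills the optional `disease_effects` / `feed_model` /
#' `management` blocks with defaults, and validates the result. A missing
#' stillbirth rate (printed "-" in the LROG calibration) is defaulted to the
#' nearest-kin breed value 5.2 with a warning.
#'
#' @param path path to a breed YAML file.
#' @param quiet suppress WARN logging.
#' @return a [herd_parameters] object.
#' @export
load_breed_config <- function(path, quiet = FALSE) {
  if (!file.exists(path))
    stop(structure(class = c("herdEV_config_error", "error", "condition"),
                   list(message = paste0("breed config not found: ", path),
                        call = NULL)))
  y <- yaml::read_yaml(path)
  need <- c("breed_id", "herd_size_target", "ecm_305d", "fat_pct",
            "protein_pct", "calving_interval_days",
            "age_first_calving_months", "heat_obs_rate_cows_pct",
            "heat_obs_rate_heifers_pct", "conception_rate_cows_pct",
            "conception_rate_heifers_pct", "start_breeding_days",
            "incidence_per_100cy", "early_calf_mortality",
            "late_calf_mortality", "cow_mortality")
  missing <- setdiff(need, names(y))
  if (length(missing))
    stop(structure(class = c("herdEV_config_error", "error", "condition"),
                   list(message = paste0("breed config ", path,
                                         " missing mandatory key(s): ",
                                         paste(missing, collapse = ", ")),
                        call = NULL)))
  mis_dis <- setdiff(DISEASES, names(y$incidence_per_100cy))
  if (length(mis_dis))
    stop(structure(class = c("herdEV_config_error", "error", "condition"),
                   list(message = paste0("breed config ", path,
                                         " missing incidence_per_100cy key(s): ",
                                         paste(mis_dis, collapse = ", ")),
                        call = NULL)))
  sb <- y$stillbirth_rate
  if (is.null(sb) || !length(sb) || is.na(sb)) {
    if (!quiet)
      ev_log("WARN", "stillbirth_rate not given for ", y$breed_id,
             ": defaulting to 5.2 (nearest-kin breed value)")
    sb <- 5.2
  }
  herd_parameters(
    breed_id = y$breed_id,
    herd_size_target = y$herd_size_target,
    ecm_305d = y$ecm_305d,
    fat_pct = y$fat_pct,
    protein_pct = y$protein_pct,
    calving_interval_days = y$calving_interval_days,
    age_first_calving_months = y$age_first_calving_months,
    heat_obs_rate_cows = y$heat_obs_rate_cows_pct / 100,
    heat_obs_rate_heifers = y$heat_obs_rate_heifers_pct / 100,
    conception_rate_cows = y$conception_rate_cows_pct / 100,
    conception_rate_heifers = y$conception_rate_heifers_pct / 100,
    start_breeding_days = y$start_breeding_days,
    incidence_per_100cy = y$incidence_per_100cy,
    stillbirth_rate = sb,
    early_calf_mortality = y$early_calf_mortality,
    late_calf_mortality = y$late_calf_mortality,
    cow_mortality = y$cow_mortality,
    disease_effects = y$disease_effects,
    feed_model = y$feed_model,
    management = y$management,
    quiet = quiet
  )
}

#' Write a breed calibration config
#'
#' Inverse of [load_breed_config()]: a written file loads back to an
#' identical `herd_parameters` object.
#'
#' @param p a `herd_parameters` object.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_breed_config <- function(p, path) {
  y <- list(
    breed_id = p$breed_id,
    herd_size_target = p$herd_size_target,
    ecm_305d = as.list(p$ecm_305d),
    fat_pct = p$fat_pct,
    protein_pct = p$protein_pct,
    calving_interval_days = p$calving_interval_days,
    age_first_calving_months = p$age_first_calving_months,
    heat_obs_rate_cows_pct = 100 * p$heat_obs_rate_cows,
    heat_obs_rate_heifers_pct = 100 * p$heat_obs_rate_heifers,
    conception_rate_cows_pct = 100 * p$conception_rate_cows,
    conception_rate_heifers_pct = 100 * p$conception_rate_heifers,
    start_breeding_days = p$start_breeding_days,
    incidence_per_100cy = as.list(p$incidence_per_100cy),
    stillbirth_rate = p$stillbirth_rate,
    early_calf_mortality = p$early_calf_mortality,
    late_calf_mortality = p$late_calf_mortality,
    cow_mortality = p$cow_mortality,
    disease_effects = p$disease_effects,
    feed_model = p$feed_model,
    management = p$management
  )
  yaml::write_yaml(y, path, precision = 12)
  invisible(path)
}

PRICE_KEYS <- c("milk_price_per_kg_ecm", "slaughter_price_per_kg_live",
                "dead_cow_disposal", "dead_heifer_disposal",
                "dead_calf_disposal", "pregnant_heifer_price",
                "open_heifer_price", "bull_calf_price", "milk_powder_per_kg",
                "heifer_concentrate_per_sfu", "heifer_roughage_per_sfu",
                "cow_feed_per_sfu", "semen_cost", "other_costs_per_cow_year",
                "other_costs_per_heifer_year")

#' Load a price book
#'
#' Reads a YAML price file (EUR). `cow_feed_per_sfu` is a calibration
#' constant (the price book gives heifer feed prices only); when absent it
#' defaults to 0.2073 EUR/SFU, chosen so that the baseline cow feed cost of
#' the highest-yielding breed matches its income-statement anchor. A missing
#' lameness treatment cost defaults to EUR 65/case. Both defaults are logged.
#'
#' @param path path to a price YAML file.
#' @param quiet suppress WARN logging.
#' @return object of class `price_table` (named list).
#' @export
load_price_table <- function(path, quiet = FALSE) {
  if (!file.exists(path))
    stop(structure(class = c("herdEV_config_error", "error", "condition"),
                   list(message = paste0("price table not found: ", path),
                        call = NULL)))
  y <- yaml::read_yaml(path)
  if (is.null(y$cow_feed_per_sfu)) {
    if (!quiet)
      ev_log("WARN", "cow_feed_per_sfu not given: defaulting to 0.2073 ",
             "EUR/SFU (calibration constant, not a recorded price)")
    y$cow_feed_per_sfu <- 0.2073
  }
  if (is.null(y$treatment_cost$lameness)) {
    if (!quiet)
      ev_log("WARN", "treatment_cost$lameness not given: defaulting to ",
             "EUR 65/case (not in the price book)")
    y$treatment_cost$lameness <- 65
  }
  missing <- setdiff(PRICE_KEYS, names(y))
  if (length(missing))
    stop(structure(class = c("herdEV_config_error", "error", "condition"),
                   list(message = paste0("price table ", path,
                                         " missing key(s): ",
                                         paste(missing, collapse = ", ")),
                        call = NULL)))
  price_table(y)
}

#' Construct and validate a price table
#'
#' @param x named list with all `PRICE_KEYS` monetary fields plus a
#'   `treatment_cost` map over the six diseases.
#' @return object of class `price_table`.
#' @export
price_table <- function(x) {
  tc <- unlist(x$treatment_cost)[DISEASES]
  pt <- c(x[PRICE_KEYS], list(treatment_cost = tc))
  vals <- c(unlist(pt[PRICE_KEYS]), tc)
  if (anyNA(vals) || any(vals < 0))
    stop(structure(class = c("herdEV_validation_error", "error", "condition"),
                   list(message = paste0(
                     "negative or missing price: ",
                     paste(names(vals)[is.na(vals) | vals < 0], collapse = ", ")),
                     call = NULL)))
  structure(pt, class = "price_table")
}

#' Write a price book
#'
#' @param pt a `price_table` object.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_price_table <- function(pt, path) {
  y <- pt[PRICE_KEYS]
  y$treatment_cost <- as.list(pt$treatment_cost)
  yaml::write_yaml(y, path, precision = 12)
  invisible(path)
}

#' Conception rate from the mean number of inseminations
#'
#' The herd-recording convention: conception rate (percent) is
#' `(1 / number of inseminations) x 100`.
#'
#' @param n_inseminations mean number of inseminations per conception, > 0.
#' @param round_to_integer return the integer-rounded rate (the convention
#'   used when calibration tables print whole percent).
#' @return conception rate in percent.
#' @examples
#' conception_rate_from_inseminations(2.0)        # 50
#' conception_rate_from_inseminations(2.2, TRUE)  # 45
#' @export
conception_rate_from_inseminations <- function(n_inseminations,
                                               round_to_integer = FALSE) {
  if (!is.numeric(n_inseminations) || any(!is.finite(n_inseminations)) ||
      any(n_inseminations <= 0))
    stop(structure(class = c("herdEV_domain_error", "error", "condition"),
                   list(message = "n_inseminations must be > 0", call = NULL)))
  r <- (1 / n_inseminations) * 100
  if (round_to_integer) round(r) else r
}

#' Path to a shipped example config
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the shipped files.
#' @return full path (or vector of file names).
#' @export
herdEV_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "herdEV")))
  system.file("extdata", file, package = "herdEV", mustWork = TRUE)
}
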