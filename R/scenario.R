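# Paired high/low trait scenarios. Each of the 15 breeding-goal traits maps
# to one calibration parameter family; the scenario pair perturbs exactly
# that family (rate traits by +/- 1 absolute percentage point, ECM by +/- a
# kg delta applied proportionally to the parity classes) and leaves every
# other field bit-identical. Replicate i runs both scenarios with seed
# base_seed + i (common random numbers).

# trait registry: where the nominal level lives, its unit, and the realized
# column carrying the same quantity in the simulation output
.trait_registry <- function() {
  num <- function(get, set, unit, realized, rate = TRUE)
    list(get = get, set = set, unit = unit, realized = realized, rate = rate)
  reg <- list(
    ecm = num(
      function(p) mean(p$ecm_305d),
      function(p, v) { p$ecm_305d <- p$ecm_305d * (v / mean(p$ecm_305d)); p },
      "kg", "realized_ecm", rate = FALSE),
    stillbirth = num(
      function(p) p$stillbirth_rate,
      function(p, v) { p$stillbirth_rate <- v; p },
      "% point", "realized_stillbirth"),
    early_calf_mortality = num(
      function(p) p$early_calf_mortality,
      function(p, v) { p$early_calf_mortality <- v; p },
      "% point", "realized_early_calf_mortality"),
    late_calf_mortality = num(
      function(p) p$late_calf_mortality,
      function(p, v) { p$late_calf_mortality <- v; p },
      "% point", "realized_late_calf_mortality"),
    cow_mortality = num(
      function(p) p$cow_mortality,
      function(p, v) { p$cow_mortality <- v; p },
      "% point", "realized_cow_mortality"),
    cr_cows = num(
      function(p) 100 * p$conception_rate_cows,
      function(p, v) { p$conception_rate_cows <- v / 100; p },
      "% point", "realized_cr_cows"),
    cr_heifers = num(
      function(p) 100 * p$conception_rate_heifers,
      function(p, v) { p$conception_rate_heifers <- v / 100; p },
      "% point", "realized_cr_heifers"),
    ho_cows = num(
      function(p) 100 * p$heat_obs_rate_cows,
      function(p, v) { p$heat_obs_rate_cows <- v / 100; p },
      "% point", "realized_ho_cows"),
    ho_heifers = num(
      function(p) 100 * p$heat_obs_rate_heifers,
      function(p, v) { p$heat_obs_rate_heifers <- v / 100; p },
      "% point", "realized_ho_heifers")
  )
  for (d in HAZARD_DISEASES) {
    reg[[d]] <- local({
      dd <- d
      list(get = function(p) p$incidence_per_100cy[[dd]],
           set = function(p, v) { p$incidence_per_100cy[[dd]] <- v; p },
           unit = "% point", realized = paste0("realized_", dd), rate = TRUE)
    })
  }
  reg$dystocia <- list(
    get = function(p) p$incidence_per_100cy[["dystocia"]],
    set = function(p, v) { p$incidence_per_100cy[["dystocia"]] <- v; p },
    unit = "% point", realized = "realized_dystocia", rate = TRUE)
  reg[TRAITS]
}

#' Trait unit, as reported in the EV table
#' @param trait one of the 15 trait names in `TRAITS`.
#' @return unit string (`"kg"` for ECM, `"% point"` for rate traits).
#' @export
trait_unit <- function(trait) .trait_registry()[[.check_trait(trait)]]$unit

.check_trait <- function(trait) {
  if (!is.character(trait) || length(trait) != 1 || !trait %in% TRAITS)
    stop(structure(class = c("herdEV_domain_error", "error", "condition"),
                   list(message = paste0("unknown trait: ", trait,
                                         " (expected one of: ",
                                         paste(TRAITS, collapse = ", "), ")"),
                        call = NULL)))
  trait
}

#' Default scenario half-width for a trait
#'
#' Rate traits move by 1 absolute percentage point per scenario; ECM, a kg
#' trait to which the percentage-point convention cannot apply, moves by 250
#' kg of 305-d yield (the EV is per kg, so the estimate is delta-invariant
#' up to Monte-Carlo noise).
#'
#' @param trait trait name.
#' @return numeric delta in trait units.
#' @export
default_trait_delta <- function(trait) {
  if (.check_trait(trait) == "ecm") 250 else 1
}

#' Build a low/high scenario pair
#'
#' Returns the base calibration with the trait's parameter moved down and up
#' by `delta`; all other fields are bit-identical to `base`.
#'
#' @param trait trait name (see `TRAITS`).
#' @param base a [herd_parameters] object.
#' @param delta scenario half-width in trait units; see
#'   [default_trait_delta()].
#' @return list with elements `low`, `high` (herd_parameters) and
#'   `x_nominal` (named numeric: the two nominal trait levels).
#' @export
build_scenarios <- function(trait, base, delta = default_trait_delta(trait)) {
  trait <- .check_trait(trait)
  stopifnot(inherits(base, "herd_parameters"))
  reg <- .trait_registry()[[trait]]
  x0 <- reg$get(base)
  lo <- x0 - delta
  hi <- x0 + delta
  out <- tryCatch(
    list(low = validate_herd_parameters(reg$set(base, lo)),
         high = validate_herd_parameters(reg$set(base, hi)),
         x_nominal = c(low = lo, high = hi)),
    herdEV_validation_error = function(e)
      stop(structure(class = c("herdEV_scenario_error", "error", "condition"),
                     list(message = paste0(
                       "perturbation of ", trait, " by ", delta,
                       " leaves the valid range: ", conditionMessage(e)),
                       call = NULL))))
  out
}

# mediator columns extracted for every replicate x scenario row
MEDIATOR_COLS <- c(milk_yield = "realized_ecm",
                   mastitis = "realized_mastitis",
                   lameness = "realized_lameness",
                   ketosis = "realized_ketosis",
                   milk_fever = "realized_milk_fever",
                   metritis = "realized_metritis",
                   dystocia = "realized_dystocia",
                   stillbirth = "realized_stillbirth",
                   cow_mortality = "realized_cow_mortality",
                   cr_cows = "realized_cr_cows",
                   ho_cows = "realized_ho_cows",
                   cr_heifers = "realized_cr_heifers",
                   ho_heifers = "realized_ho_heifers")

# engine columns that pool across years by summation
.ENGINE_SUM_COLS <- c(
  "cow_weeks", "heifer_weeks", "kg_ecm_delivered",
  "cases_milk_fever", "cases_dystocia", "cases_metritis", "cases_ketosis",
  "cases_mastitis", "cases_lameness",
  "calvings", "first_calvings", "stillbirths",
  "live_calves_female", "live_calves_male",
  "calf_deaths_early", "calf_deaths_late",
  "cow_deaths", "cows_slaughtered", "slaughter_kg_cows",
  "heifers_slaughtered", "slaughter_kg_heifers",
  "heifers_sold_pregnant", "heifers_sold_open",
  "inseminations_cows", "inseminations_heifers",
  "conceptions_cows", "conceptions_heifers",
  "heats_eligible_cows", "heats_detected_cows",
  "heats_eligible_heifers", "heats_detected_heifers",
  "feed_sfu_cows", "feed_sfu_heifers", "milk_powder_kg", "bull_calves_sold",
  "ci_sum_days", "ci_n", "afc_sum_weeks", "afc_n")

# one replicate x scenario -> one row: net return is the mean annual
# contribution margin; realized levels are recomputed from pooled counts
# over the retained years (not means of annual ratios)
.summarize_replicate <- function(tech, econ) {
  pooled <- as.data.frame(t(colSums(tech[.ENGINE_SUM_COLS])))
  pooled$year <- 1
  pooled$cows_start <- tech$cows_start[1]
  pooled$cows_end <- tech$cows_end[nrow(tech)]
  lv <- finalize_annual(pooled, replicate_id = tech$replicate_id[1])
  out <- data.frame(net_return = mean(econ$contribution_margin))
  for (m in names(MEDIATOR_COLS)) out[[m]] <- lv[[MEDIATOR_COLS[[m]]]]
  out
}

#' Run a paired-scenario experiment for one trait
#'
#' For each replicate `i` in `1:n_replicates`, simulates the herd under the
#' low and the high scenario with seed `base_seed + i` (common random
#' numbers), prices each retained year, and collapses the replicate into
#' one row per scenario: mean annual net return (contribution margin per
#' cow-year), the realized level of the perturbed trait (`x_real`), and the
#' realized mediator levels. `x_diff` is the within-scenario centred
#' realized level, included in the EV regression to absorb independent
#' random variation of the trait around its nominal level.
#'
#' @param trait trait name.
#' @param base a [herd_parameters] object (baseline calibration).
#' @param prices a [price_table].
#' @param n_replicates paired replicates (rows = `2 * n_replicates`).
#' @param years,burn_in simulation horizon per replicate.
#' @param base_seed integer; replicate `i` uses `base_seed + i`.
#' @param delta scenario half-width; see [default_trait_delta()].
#' @return data.frame of class `experiment_result` with columns
#'   `replicate`, `scenario`, `x_nominal`, `x_real`, `x_diff`,
#'   `net_return` and one column per mediator.
#' @export
run_experiment <- function(trait, base, prices, n_replicates = 1000L,
                           years = 40L, burn_in = 10L, base_seed = 1L,
                           delta = default_trait_delta(trait)) {
  trait <- .check_trait(trait)
  sc <- build_scenarios(trait, base, delta)
  reg <- .trait_registry()[[trait]]
  share <- base$feed_model$concentrate_share
  rows <- vector("list", 2L * n_replicates)
  k <- 0L
  for (i in seq_len(n_replicates)) {
    for (j in c("low", "high")) {
      tech <- tryCatch(
        simulate_herd(sc[[j]], years = years, burn_in = burn_in,
                      seed = base_seed + i, replicate_id = i),
        herdEV_simulation_error = function(e)
          stop(structure(class = c("herdEV_simulation_error", "error",
                                   "condition"),
                         list(message = paste0("scenario '", j, "' of trait '",
                                               trait, "': ",
                                               conditionMessage(e)),
                              call = NULL))))
      econ <- compute_annual_economics(tech, prices, share)
      row <- .summarize_replicate(tech, econ)
      row$replicate <- i
      row$scenario <- j
      row$x_nominal <- sc$x_nominal[[j]]
      k <- k + 1L
      rows[[k]] <- row
    }
  }
  out <- do.call(rbind, rows)
  realized_col <- sub("^realized_", "", reg$realized)
  out$x_real <- if (realized_col %in% names(out)) out[[realized_col]] else {
    # ECM: realized kg delivered per cow-year
    out$milk_yield
  }
  out$x_diff <- out$x_real - ave(out$x_real, out$scenario)
  attr(out, "trait") <- trait
  attr(out, "delta") <- delta
  attr(out, "n_replicates") <- n_replicates
  class(out) <- c("experiment_result", "data.frame")
  out
}
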