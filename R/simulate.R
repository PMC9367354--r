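# Herd simulation front-end. The weekly-step engine is compiled (see
# src/herd_engine.cpp); simulate_herd() and step_week() both call the same
# C++ step function, so the fast whole-run path and the inspectable
# single-week path cannot diverge.

#' Simulate a dairy herd and return annual technical results
#'
#' Runs the stochastic weekly-step herd model for `years` simulated years of
#' 52 weeks and discards the first `burn_in` years (initialization
#' transient). The herd starts near `herd_size_target` with a steady-state
#' -like parity and lactation-stage mix and is maintained there by retaining
#' first-calving heifers and selling the surplus as pregnant heifers.
#'
#' All randomness is a pure function of `(params, seed)`: identical calls
#' give bit-identical results, and runs differing in a single calibration
#' parameter share the randomness of all events both evaluate (common random
#' numbers across paired scenarios).
#'
#' @param params a [herd_parameters] object.
#' @param years total simulated years.
#' @param burn_in initial years to discard; `years > burn_in >= 0`.
#' @param seed integer seed.
#' @param replicate_id identifier stored in the output rows.
#' @param weekly_log also return the per-week event log.
#' @return a data.frame of annual technical results, one row per retained
#'   year (class `annual_technical_result`), with counts, physical outputs
#'   and `realized_*` trait-level columns. If `weekly_log = TRUE`, the log
#'   is attached as attribute `"weekly"`.
#' @export
simulate_herd <- function(params, years = 40L, burn_in = 10L, seed = 1L,
                          replicate_id = 1L, weekly_log = FALSE) {
  stopifnot(inherits(params, "herd_parameters"))
  if (!(years > burn_in && burn_in >= 0))
    stop(structure(class = c("herdEV_domain_error", "error", "condition"),
                   list(message = "need years > burn_in >= 0", call = NULL)))
  ep <- engine_params(params)
  res <- tryCatch(
    .cpp_run_herd(ep, as.integer(years), as.integer(burn_in), as.double(seed),
                  weekly_log, FALSE),
    error = function(e)
      stop(structure(class = c("herdEV_simulation_error", "error", "condition"),
                     list(message = conditionMessage(e), call = NULL))))
  ann <- finalize_annual(as.data.frame(res$annual), replicate_id)
  if (weekly_log) attr(ann, "weekly") <- as.data.frame(res$weekly)
  ann
}

#' Initial herd state
#'
#' The documented starting configuration used by [simulate_herd()]: parity
#' mix 0.35 / 0.27 / 0.38 (parity 1 / 2 / 3+), lactation stage uniform, cows
#' past the modal conception stage pregnant, and a young-stock pipeline of
#' 0.9 heifers per cow with uniform ages.
#'
#' @param params a [herd_parameters] object.
#' @param seed integer seed.
#' @return a herd-state list (`week`, `cows`, `cow_disease_weeks`,
#'   `heifers`, exposure accumulators) accepted by [step_week()].
#' @export
init_herd_state <- function(params, seed = 1L) {
  .cpp_init_state(engine_params(params), as.double(seed))
}

#' Advance a herd state by whole weeks
#'
#' Applies the documented weekly event order (disease onset, yield accrual,
#' oestrus/insemination/conception, gestation and calving, mortality and
#' culling, episode expiry, young-stock aging and replacement entry) to a
#' herd state. Stochastic draws are keyed by `(seed, week, animal, event)`,
#' so stepping a state one week at a time or in blocks gives identical
#' trajectories.
#'
#' @param state a herd state from [init_herd_state()] or a previous call.
#' @param params a [herd_parameters] object.
#' @param seed integer seed (the replicate's random stream).
#' @param n_weeks number of weeks to advance.
#' @return list with the advanced `state` and `events`, a data.frame with
#'   one row per simulated week (same columns as the annual results' count
#'   fields).
#' @export
step_week <- function(state, params, seed = 1L, n_weeks = 1L) {
  stopifnot(inherits(params, "herd_parameters"))
  res <- .cpp_step_weeks(engine_params(params), state, as.integer(n_weeks),
                         as.double(seed))
  list(state = res$state, events = as.data.frame(res$weekly))
}

.safe_ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)

#' Aggregate a weekly event log into one annual technical result
#'
#' Sums the count and exposure columns of a weekly event log (as produced by
#' [step_week()] or the `weekly_log` attribute of [simulate_herd()]) and
#' derives the realized trait levels. An empty log (no cows) yields an
#' all-zero record with `cow_years = 0`.
#'
#' @param weekly data.frame of weekly event rows for one year.
#' @param replicate_id,year_index identifiers stored in the output.
#' @return one-row data.frame of class `annual_technical_result`.
#' @export
annual_aggregate <- function(weekly, replicate_id = 1L, year_index = 1L) {
  sums <- as.data.frame(t(colSums(weekly)))
  if (nrow(weekly)) {
    sums$cows_start <- weekly$cows_start[1]
    sums$cows_end <- weekly$cows_end[nrow(weekly)]
  }
  sums$year <- year_index
  sums$week <- 0
  finalize_annual(sums, replicate_id)
}

# Derived per-year quantities shared by the fast path and the event-log path.
finalize_annual <- function(df, replicate_id) {
  cy <- df$cow_weeks / 52
  hy <- df$heifer_weeks / 52
  inc <- function(cases) .safe_ratio(100 * cases, cy)
  out <- data.frame(
    replicate_id = replicate_id,
    year_index = df$year,
    cow_years = cy,
    heifer_years = hy,
    df[setdiff(names(df), c("year", "week"))],
    realized_ecm = .safe_ratio(df$kg_ecm_delivered, cy),
    realized_milk_fever = inc(df$cases_milk_fever),
    realized_dystocia = inc(df$cases_dystocia),
    realized_metritis = inc(df$cases_metritis),
    realized_ketosis = inc(df$cases_ketosis),
    realized_mastitis = inc(df$cases_mastitis),
    realized_lameness = inc(df$cases_lameness),
    realized_stillbirth = .safe_ratio(100 * df$stillbirths, df$calvings),
    realized_early_calf_mortality =
      .safe_ratio(100 * df$calf_deaths_early,
                  df$live_calves_female + df$live_calves_male),
    realized_late_calf_mortality =
      .safe_ratio(100 * df$calf_deaths_late, df$live_calves_female),
    realized_cow_mortality = inc(df$cow_deaths),
    realized_cr_cows =
      .safe_ratio(100 * df$conceptions_cows, df$inseminations_cows),
    realized_cr_heifers =
      .safe_ratio(100 * df$conceptions_heifers, df$inseminations_heifers),
    realized_ho_cows =
      .safe_ratio(100 * df$heats_detected_cows, df$heats_eligible_cows),
    realized_ho_heifers =
      .safe_ratio(100 * df$heats_detected_heifers, df$heats_eligible_heifers),
    realized_calving_interval_days = .safe_ratio(df$ci_sum_days, df$ci_n),
    realized_afc_months =
      .safe_ratio(df$afc_sum_weeks * 7 / (365.25 / 12), df$afc_n)
  )
  class(out) <- c("annual_technical_result", "data.frame")
  out
}
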