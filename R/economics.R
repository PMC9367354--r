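# Income/cost accounting: annual technical results are priced into the
# standard contribution-margin statement per cow-year with five income lines
# (milk, slaughter cows, calves, slaughter heifers, live heifers) and seven
# cost lines (feed cows/heifers, insemination cows/heifers, veterinary,
# other cows/heifers). Disposal fees for dead stock are netted into the
# corresponding income lines (negative contributions) so the statement keeps
# the conventional line structure.

INCOME_ITEMS <- c("milk", "slaughter_cows", "calves", "slaughter_heifers",
                  "heifers_live")
COST_ITEMS <- c("feed_cows", "feed_heifers", "insemination_cows",
                "insemination_heifers", "veterinary_cows", "other_cows",
                "other_heifers")

#' Assemble an income/cost statement
#'
#' Builds an `economic_result` from named income and cost items (EUR per
#' cow-year) and computes the exact accounting identities:
#' `total_income = sum(income)`, `variable_costs = sum(costs)`,
#' `contribution_margin = total_income - variable_costs`.
#'
#' @param income named numeric (or data.frame of such rows) with elements
#'   `r paste(INCOME_ITEMS, collapse = ", ")`.
#' @param costs named numeric (or data.frame) with elements
#'   `r paste(COST_ITEMS, collapse = ", ")`.
#' @return data.frame of class `economic_result` with one row per input row
#'   and columns `income_*`, `cost_*`, `total_income`, `variable_costs`,
#'   `contribution_margin`.
#' @examples
#' economic_result(
#'   income = c(milk = 2110, slaughter_cows = 143, calves = 100,
#'              slaughter_heifers = 16, heifers_live = 63),
#'   costs = c(feed_cows = 1027, feed_heifers = 247, insemination_cows = 35,
#'             insemination_heifers = 13, veterinary_cows = 105,
#'             other_cows = 202, other_heifers = 47))
#' @export
economic_result <- function(income, costs) {
  inc <- as.data.frame(as.list(income))[INCOME_ITEMS]
  cst <- as.data.frame(as.list(costs))[COST_ITEMS]
  if (anyNA(inc) || anyNA(cst))
    stop(structure(class = c("herdEV_domain_error", "error", "condition"),
                   list(message = "income/cost items missing or NA",
                        call = NULL)))
  out <- data.frame(
    setNames(inc, paste0("income_", INCOME_ITEMS)),
    setNames(cst, paste0("cost_", COST_ITEMS))
  )
  out$total_income <- rowSums(inc)
  out$variable_costs <- rowSums(cst)
  out$contribution_margin <- out$total_income - out$variable_costs
  class(out) <- c("economic_result", "data.frame")
  out
}

#' Price annual technical results into an economic statement
#'
#' Converts one or more annual technical result rows into EUR per cow-year:
#' milk income from kg ECM delivered; cow slaughter income from live weight
#' sold net of dead-cow disposal; calf income from bull-calf sales net of
#' stillborn/early-dead calf disposal; heifer slaughter income net of
#' dead-heifer disposal; live-heifer income from surplus pregnant (and open)
#' heifer sales; feed costs from SFU at the cow ration price and the
#' concentrate/roughage blend for heifers plus milk powder for calves;
#' insemination costs at the semen price; veterinary costs as cases times
#' per-case treatment costs; and the fixed other-cost constants per cow-year
#' and per heifer-year.
#'
#' @param tech an `annual_technical_result` data.frame (one or more rows).
#' @param prices a [price_table] object.
#' @param concentrate_share concentrate share of the heifer ration used to
#'   blend the two heifer feed prices; pass the breed's
#'   `feed_model$concentrate_share`.
#' @return an [economic_result] data.frame, one row per input row.
#' @export
compute_annual_economics <- function(tech, prices, concentrate_share = 0.35) {
  stopifnot(inherits(prices, "price_table"))
  cy <- tech$cow_years
  if (any(!is.finite(cy)) || any(cy <= 0))
    stop(structure(class = c("herdEV_domain_error", "error", "condition"),
                   list(message = "cow_years must be > 0", call = NULL)))
  tc <- prices$treatment_cost
  vet <- tech$cases_milk_fever * tc[["milk_fever"]] +
    tech$cases_dystocia * tc[["dystocia"]] +
    tech$cases_metritis * tc[["metritis"]] +
    tech$cases_ketosis * tc[["ketosis"]] +
    tech$cases_mastitis * tc[["mastitis"]] +
    tech$cases_lameness * tc[["lameness"]]
  heifer_sfu_price <- concentrate_share * prices$heifer_concentrate_per_sfu +
    (1 - concentrate_share) * prices$heifer_roughage_per_sfu
  income <- data.frame(
    milk = tech$kg_ecm_delivered * prices$milk_price_per_kg_ecm / cy,
    slaughter_cows =
      (tech$slaughter_kg_cows * prices$slaughter_price_per_kg_live -
         tech$cow_deaths * prices$dead_cow_disposal) / cy,
    calves = (tech$bull_calves_sold * prices$bull_calf_price -
                (tech$stillbirths + tech$calf_deaths_early) *
                  prices$dead_calf_disposal) / cy,
    slaughter_heifers =
      (tech$slaughter_kg_heifers * prices$slaughter_price_per_kg_live -
         tech$calf_deaths_late * prices$dead_heifer_disposal) / cy,
    heifers_live =
      (tech$heifers_sold_pregnant * prices$pregnant_heifer_price +
         tech$heifers_sold_open * prices$open_heifer_price) / cy
  )
  costs <- data.frame(
    feed_cows = tech$feed_sfu_cows * prices$cow_feed_per_sfu / cy,
    feed_heifers = (tech$feed_sfu_heifers * heifer_sfu_price +
                      tech$milk_powder_kg * prices$milk_powder_per_kg) / cy,
    insemination_cows = tech$inseminations_cows * prices$semen_cost / cy,
    insemination_heifers = tech$inseminations_heifers * prices$semen_cost / cy,
    veterinary_cows = vet / cy,
    other_cows = rep(prices$other_costs_per_cow_year, length(cy)),
    other_heifers = prices$other_costs_per_heifer_year * tech$heifer_years / cy
  )
  economic_result(income, costs)
}

#' Mean per-item differences between two scenario result sets
#'
#' For paired high/low scenario comparisons: returns `mean(high) -
#' mean(low)` for every income and cost item, the totals and the
#' contribution margin. By the accounting identity, the item deltas sum
#' exactly to the margin delta (income items positive, cost items entering
#' with a negative sign).
#'
#' @param high,low [economic_result] data.frames (any number of rows each).
#' @return one-row data.frame of deltas plus `delta_check` (the reassembled
#'   margin delta from the items).
#' @export
decompose_scenario_delta <- function(high, low) {
  stopifnot(inherits(high, "economic_result"), inherits(low, "economic_result"),
            nrow(high) > 0, nrow(low) > 0)
  cols <- c(paste0("income_", INCOME_ITEMS), paste0("cost_", COST_ITEMS),
            "total_income", "variable_costs", "contribution_margin")
  d <- as.data.frame(as.list(colMeans(high[cols]) - colMeans(low[cols])))
  d$delta_check <- sum(d[paste0("income_", INCOME_ITEMS)]) -
    sum(d[paste0("cost_", COST_ITEMS)])
  d
}
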