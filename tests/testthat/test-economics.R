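# Economics: exact accounting identities, pricing of technical results,
# scenario-delta additivity, and price monotonicity.

test_that("accounting identities are exact on the statement constructor", {
  r <- economic_result(
    income = c(milk = 2110, slaughter_cows = 143, calves = 100,
               slaughter_heifers = 16, heifers_live = 63),
    costs = c(feed_cows = 1027, feed_heifers = 247, insemination_cows = 35,
              insemination_heifers = 13, veterinary_cows = 105,
              other_cows = 202, other_heifers = 47))
  expect_equal(r$total_income, 2432)
  expect_equal(r$variable_costs, 1676)
  expect_equal(r$contribution_margin, 756)

  # all-zero record
  z <- economic_result(income = setNames(numeric(5), herdEV:::INCOME_ITEMS),
                       costs = setNames(numeric(7), herdEV:::COST_ITEMS))
  expect_equal(z$contribution_margin, 0)
})

test_that("identities hold to 1e-9 relative on simulated records", {
  p <- lbw_params()
  tech <- simulate_herd(p, years = 6, burn_in = 2, seed = 3)
  e <- compute_annual_economics(tech, lbw_prices(),
                                p$feed_model$concentrate_share)
  inc <- rowSums(e[paste0("income_", herdEV:::INCOME_ITEMS)])
  cst <- rowSums(e[paste0("cost_", herdEV:::COST_ITEMS)])
  expect_equal(e$total_income, inc, tolerance = 1e-9)
  expect_equal(e$variable_costs, cst, tolerance = 1e-9)
  expect_equal(e$contribution_margin, inc - cst, tolerance = 1e-9)
})

test_that("pricing formulas match direct arithmetic on a constructed record", {
  # one synthetic technical year, checked line by line against hand math
  tech <- data.frame(
    cow_years = 100, heifer_years = 80,
    kg_ecm_delivered = 700000,
    cases_milk_fever = 3, cases_dystocia = 1, cases_metritis = 8,
    cases_ketosis = 4, cases_mastitis = 26, cases_lameness = 19,
    stillbirths = 10, calf_deaths_early = 5, calf_deaths_late = 3,
    cow_deaths = 5, slaughter_kg_cows = 550 * 20,
    slaughter_kg_heifers = 480 * 2,
    heifers_sold_pregnant = 10, heifers_sold_open = 2,
    inseminations_cows = 170, inseminations_heifers = 60,
    feed_sfu_cows = 500000, feed_sfu_heifers = 120000,
    milk_powder_kg = 3000, bull_calves_sold = 45)
  pr <- lbw_prices()
  e <- compute_annual_economics(tech, pr, concentrate_share = 0.35)
  expect_equal(e$income_milk, 700000 * 0.29 / 100)
  expect_equal(e$income_slaughter_cows, (550 * 20 * 0.94 - 5 * 33) / 100)
  expect_equal(e$income_calves, (45 * 200 - 15 * 9) / 100)
  expect_equal(e$income_slaughter_heifers, (480 * 2 * 0.94 - 3 * 21) / 100)
  expect_equal(e$income_heifers_live, (10 * 1300 + 2 * 800) / 100)
  expect_equal(e$cost_feed_cows, 500000 * 0.2073 / 100)
  expect_equal(e$cost_feed_heifers,
               (120000 * (0.35 * 0.23 + 0.65 * 0.10) + 3000 * 2.02) / 100)
  expect_equal(e$cost_insemination_cows, 170 * 20 / 100)
  expect_equal(e$cost_veterinary_cows,
               (3 * 54 + 1 * 69 + 8 * 72 + 4 * 70 + 26 * 89 + 19 * 65) / 100)
  expect_equal(e$cost_other_cows, 202)
  expect_equal(e$cost_other_heifers, 50 * 80 / 100)

  tech$cow_years <- 0
  expect_error(compute_annual_economics(tech, pr),
               class = "herdEV_domain_error")
})

test_that("raising the milk price raises milk income and the margin", {
  p <- lbw_params()
  tech <- simulate_herd(p, years = 4, burn_in = 1, seed = 9)
  pr1 <- lbw_prices()
  pr2 <- pr1; pr2$milk_price_per_kg_ecm <- pr1$milk_price_per_kg_ecm + 0.05
  e1 <- compute_annual_economics(tech, pr1, 0.35)
  e2 <- compute_annual_economics(tech, pr2, 0.35)
  expect_true(all(e2$income_milk > e1$income_milk))
  expect_true(all(e2$contribution_margin > e1$contribution_margin))
})

test_that("scenario-delta decomposition is additive and zero on identity", {
  p <- lbw_params()
  tech <- simulate_herd(p, years = 5, burn_in = 2, seed = 5)
  e <- compute_annual_economics(tech, lbw_prices(), 0.35)
  d0 <- decompose_scenario_delta(e, e)
  expect_true(all(abs(unlist(d0)) < 1e-12))

  # constructed shift: milk up 6, feed up 2 -> margin delta 4, additive
  e2 <- e
  e2$income_milk <- e2$income_milk + 6
  e2$cost_feed_cows <- e2$cost_feed_cows + 2
  e2$total_income <- e2$total_income + 6
  e2$variable_costs <- e2$variable_costs + 2
  e2$contribution_margin <- e2$contribution_margin + 4
  d <- decompose_scenario_delta(e2, e)
  expect_equal(d$income_milk, 6)
  expect_equal(d$cost_feed_cows, 2)
  expect_equal(d$contribution_margin, 4)
  expect_equal(d$delta_check, d$contribution_margin, tolerance = 1e-9)
})
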