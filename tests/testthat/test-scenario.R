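# Scenario engine: pure perturbations, experiment structure, realized
# scenario separation, and the common-random-number variance reduction.

test_that("build_scenarios perturbs exactly one parameter family", {
  base <- lbw_params()
  sc <- build_scenarios("mastitis", base)
  expect_equal(sc$low$incidence_per_100cy[["mastitis"]], 25)
  expect_equal(sc$high$incidence_per_100cy[["mastitis"]], 27)
  expect_equal(sc$x_nominal, c(low = 25, high = 27))
  # every other field bit-identical
  strip <- function(p, tr) { p$incidence_per_100cy[[tr]] <- NA; p }
  expect_identical(strip(sc$low, "mastitis"), strip(base, "mastitis"))
  expect_identical(strip(sc$high, "mastitis"), strip(base, "mastitis"))

  sc2 <- build_scenarios("cr_cows", base)
  expect_equal(sc2$low$conception_rate_cows, 0.49)
  expect_equal(sc2$high$conception_rate_cows, 0.51)

  # ECM: +/- delta kg applied proportionally across parity classes
  sc3 <- build_scenarios("ecm", base, delta = 250)
  expect_equal(mean(sc3$high$ecm_305d), mean(base$ecm_305d) + 250)
  expect_equal(sc3$high$ecm_305d / base$ecm_305d,
               rep((mean(base$ecm_305d) + 250) / mean(base$ecm_305d), 3),
               ignore_attr = TRUE)

  # delta = 0 -> identical pair
  sc0 <- build_scenarios("metritis", base, delta = 0)
  expect_identical(sc0$low, sc0$high)

  # invalid perturbation leaves the valid range
  bad <- base
  bad$incidence_per_100cy[["dystocia"]] <- 0.5
  expect_error(build_scenarios("dystocia", bad, delta = 1),
               class = "herdEV_scenario_error")
  expect_error(build_scenarios("somatic_cells", base),
               class = "herdEV_domain_error")
})

test_that("run_experiment emits 2 rows per replicate with centred x_diff", {
  base <- lbw_params()
  ex <- run_experiment("mastitis", base, lbw_prices(), n_replicates = 6,
                       years = 6, burn_in = 2, base_seed = 50)
  expect_s3_class(ex, "experiment_result")
  expect_equal(nrow(ex), 12)
  expect_equal(sort(unique(ex$replicate)), 1:6)
  expect_setequal(unique(ex$scenario), c("low", "high"))
  # within-scenario centring: mean(x_diff) = 0 by construction
  expect_equal(as.numeric(tapply(ex$x_diff, ex$scenario, mean)), c(0, 0),
               tolerance = 1e-12)
  # mediator columns all present
  expect_true(all(names(herdEV:::MEDIATOR_COLS) %in% names(ex)))
  # deterministic under the same base seed
  ex2 <- run_experiment("mastitis", base, lbw_prices(), n_replicates = 6,
                        years = 6, burn_in = 2, base_seed = 50)
  expect_identical(ex, ex2)
})

test_that("realized disease levels separate by ~2 per 100 cow-years", {
  # oracle: the scenarios differ by 2 cases/100 cow-years in expectation
  # (difference of calibrated binomial means)
  base <- lbw_params()
  ex <- run_experiment("mastitis", base, lbw_prices(), n_replicates = 60,
                       years = 12, burn_in = 3, base_seed = 70)
  sep <- mean(ex$x_real[ex$scenario == "high"]) -
    mean(ex$x_real[ex$scenario == "low"])
  # 3 MC SEs of the mean difference
  sd_d <- sd(ex$x_real[ex$scenario == "high"] -
               ex$x_real[ex$scenario == "low"])
  expect_lt(abs(sep - 2), 3 * sd_d / sqrt(60))
})

test_that("common random numbers cut the variance of the paired contrast", {
  base <- lbw_params()
  pr <- lbw_prices()
  ex <- run_experiment("ecm", base, pr, n_replicates = 100,
                       years = 8, burn_in = 2, base_seed = 90)
  lo <- ex$net_return[ex$scenario == "low"]
  hi <- ex$net_return[ex$scenario == "high"]
  v_crn <- var(hi - lo)
  # independent pairing: same draws, shuffled partners
  v_ind <- var(hi - lo[c(2:length(lo), 1)])
  expect_lt(v_crn, v_ind)
  expect_gt(cor(lo, hi), 0.2)
})
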