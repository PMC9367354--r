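# Shared fixtures: shipped configs and a small fast herd for simulation
# tests. All stochastic tests use fixed seeds; simulation scale is kept
# small except where an acceptance criterion prescribes otherwise.

lbw_params <- function() {
  load_breed_config(herdEV_example("breed_lbw.yaml"), quiet = TRUE)
}
lr_params <- function() {
  load_breed_config(herdEV_example("breed_lr.yaml"), quiet = TRUE)
}
lrog_params <- function() {
  load_breed_config(herdEV_example("breed_lrog.yaml"), quiet = TRUE)
}
lbw_prices <- function() {
  load_price_table(herdEV_example("prices_lbw.yaml"), quiet = TRUE)
}
lr_prices <- function() {
  load_price_table(herdEV_example("prices_lr.yaml"), quiet = TRUE)
}

# a herd with every stochastic event switched off: no diseases, no deaths,
# no culling, no breeding detection -> pure yield accrual
null_hazard_params <- function(base = lbw_params()) {
  base$incidence_per_100cy[] <- 0
  base$stillbirth_rate <- 0
  base$early_calf_mortality <- 0
  base$late_calf_mortality <- 0
  base$cow_mortality <- 0
  base$heat_obs_rate_cows <- 0
  base$heat_obs_rate_heifers <- 0
  base$management$base_cull_rate <- 0
  base$management$dystocia_cow_mortality_risk <- 0
  # without breeding the do-not-breed and heifer-failure policy culls would
  # empty the herd; push them beyond the horizon
  base$management$do_not_breed_cull_week <- 100000L
  base$management$heifer_fail_cycles <- 30000L
  validate_herd_parameters(base)
  base
}

# independent OLS oracle: normal equations solved directly
ols_oracle <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  s2 <- sum(res^2) / (nrow(X) - ncol(X))
  list(beta = drop(beta), se = sqrt(diag(s2 * solve(XtX))))
}

# deterministic linear "experiment" generator for regression tests
synthetic_experiment <- function(n_pairs, beta_a = -1.8, beta_m = 0.2,
                                 sigma = 2, seed = 1) {
  set.seed(seed)
  x <- rep(c(25, 27), each = n_pairs)
  m <- rnorm(2 * n_pairs, mean = 7000, sd = 50)
  x_real <- x + rnorm(2 * n_pairs, sd = 0.5)
  x_diff <- x_real - ave(x_real, x)
  y <- 900 + beta_a * x + beta_m * (m - 7000) + 0.3 * x_diff +
    rnorm(2 * n_pairs, sd = sigma)
  data.frame(net_return = y, x_nominal = x, x_real = x_real, x_diff = x_diff,
             milk_yield = m, scenario = rep(c("low", "high"), each = n_pairs))
}
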