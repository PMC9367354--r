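# EV regression: mediator map, OLS against the independent normal-equations
# oracle, Frisch-Waugh, noiseless two-point slope, mediated-share shift,
# CI coverage, and the per-case cost rule.

test_that("mediator map reproduces the documented sets", {
  expect_equal(mediator_map("mastitis"), c("milk_yield", "cow_mortality"))
  expect_equal(mediator_map("metritis"),
               c("milk_yield", "ketosis", "cr_cows", "ho_cows"))
  expect_equal(mediator_map("ketosis"), c("milk_yield", "cr_cows"))
  expect_equal(mediator_map("milk_fever"),
               c("milk_yield", "metritis", "mastitis", "dystocia"))
  expect_equal(mediator_map("lameness"),
               c("milk_yield", "cr_cows", "cow_mortality"))
  expect_equal(mediator_map("dystocia"), c("stillbirth", "cow_mortality"))
  for (tr in c("ecm", "stillbirth", "cow_mortality", "cr_cows", "ho_heifers"))
    expect_length(mediator_map(tr), 0)
  expect_error(mediator_map("somatic_cells"), class = "herdEV_domain_error")
})

test_that("two noiseless scenarios give the connecting slope", {
  d <- data.frame(net_return = c(800, 794), x_nominal = c(25, 27),
                  x_real = c(25, 27), x_diff = c(0, 0))
  est <- derive_ev(d, trait = "mastitis", mediators = character(0),
                   include_x_diff = FALSE)
  expect_equal(est$ev, -3.0, tolerance = 1e-10)
})

test_that("derive_ev matches the normal-equations oracle to 1e-8", {
  for (seed in 1:5) {
    d <- synthetic_experiment(400, beta_a = -1.8, sigma = 4, seed = seed)
    est <- derive_ev(d, trait = "mastitis",
                     mediators = "milk_yield", include_x_diff = TRUE)
    X <- cbind(1, d$x_nominal, d$milk_yield - mean(d$milk_yield), d$x_diff)
    o <- ols_oracle(X, d$net_return)
    expect_equal(est$ev, o$beta[2], tolerance = 1e-8)
    expect_equal(est$se, o$se[2], tolerance = 1e-8)
    expect_true(est$ci95[["lower"]] < est$ev && est$ev < est$ci95[["upper"]])
  }
})

test_that("Frisch-Waugh: coefficient equals residualised slope", {
  d <- synthetic_experiment(300, seed = 42)
  est <- derive_ev(d, trait = "mastitis", mediators = "milk_yield")
  Z <- cbind(1, d$milk_yield, d$x_diff)
  rx <- d$x_nominal - Z %*% solve(crossprod(Z), crossprod(Z, d$x_nominal))
  ry <- d$net_return - Z %*% solve(crossprod(Z), crossprod(Z, d$net_return))
  expect_equal(est$ev, sum(rx * ry) / sum(rx^2), tolerance = 1e-8)
})

test_that("estimates are invariant to row order", {
  d <- synthetic_experiment(200, seed = 7)
  est1 <- derive_ev(d, trait = "ketosis", mediators = "milk_yield")
  perm <- sample(nrow(d))
  est2 <- derive_ev(d[perm, ], trait = "ketosis", mediators = "milk_yield")
  expect_equal(est1$ev, est2$ev, tolerance = 1e-12)
  expect_equal(est1$se, est2$se, tolerance = 1e-12)
})

test_that("omitting a mediator shifts the EV by the mediated share", {
  # constructed linear system: x -> m (slope g), m -> y (coef b_m); the
  # indirect path g*b_m moves into the x coefficient when m is omitted.
  # Oracle: path-analysis decomposition computed from the same constants.
  set.seed(99)
  n <- 4000
  x <- rep(c(25, 27), each = n / 2)
  g <- -50; b_m <- 0.2; b_x <- -0.9
  m <- 7000 + g * (x - 26) + rnorm(n, sd = 5)
  y <- 900 + b_x * x + b_m * (m - 7000) + rnorm(n, sd = 0.5)
  d <- data.frame(net_return = y, x_nominal = x, x_real = x,
                  x_diff = 0, milk_yield = m)
  with_m <- derive_ev(d, trait = "ketosis", mediators = "milk_yield",
                      include_x_diff = FALSE)
  without_m <- derive_ev(d, trait = "ketosis", mediators = character(0),
                         include_x_diff = FALSE)
  expect_equal(with_m$ev, b_x, tolerance = 0.1)
  expect_equal(without_m$ev - with_m$ev, g * b_m, tolerance = 0.1)
})

test_that("95% CI coverage over independent synthetic experiments", {
  hits <- 0L
  for (k in 1:50) {
    d <- synthetic_experiment(500, beta_a = -1.8, sigma = 4, seed = 1000 + k)
    est <- derive_ev(d, trait = "mastitis", mediators = "milk_yield")
    if (est$ci95[["lower"]] <= -1.8 && -1.8 <= est$ci95[["upper"]])
      hits <- hits + 1L
  }
  expect_gte(hits, 44L)  # empirical coverage within [0.88, 0.99] of nominal
  expect_lte(hits, 50L)
})

test_that("degenerate designs raise classed regression errors", {
  d <- synthetic_experiment(50, seed = 3)
  d$x_nominal <- 26  # one level only
  expect_error(derive_ev(d, trait = "mastitis", mediators = character(0)),
               class = "herdEV_regression_error")
  d2 <- synthetic_experiment(50, seed = 3)
  d2$dup <- d2$milk_yield  # perfectly collinear mediator
  expect_error(derive_ev(d2, trait = "mastitis",
                         mediators = c("milk_yield", "dup")),
               class = "herdEV_regression_error")
  expect_error(derive_ev(d2, trait = "mastitis",
                         mediators = c("milk_yield", "mastitis")),
               class = "herdEV_domain_error")  # trait among mediators
})

test_that("per-case cost is 100 x |EV| for rate traits only", {
  expect_equal(per_case_cost(-1.82, "mastitis"), 182)
  expect_equal(per_case_cost(-1.01, "ketosis"), 101)
  expect_equal(per_case_cost(0, "lameness"), 0)
  expect_error(per_case_cost(0.16, "ecm"), class = "herdEV_domain_error")
})
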