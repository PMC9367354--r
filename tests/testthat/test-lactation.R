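# Lactation curve: 305-d scaling against an independent fine-grid
# integration of the Wood curve, and the dry-period contract.

test_that("305-d cumulative weekly yield matches the calibrated totals", {
  for (mk in list(lbw_params, lrog_params)) {
    p <- mk()
    for (pc in c("1", "2", "3+")) {
      y <- lactation_yield(pc, 0:43, p)
      # weeks 0..42 full + 4/7 of week 43 cover exactly 305 days
      cum <- sum(y[1:43]) + y[44] * 4 / 7
      expect_equal(cum, unname(p$ecm_305d[[pc]]), tolerance = 1e-8)
    }
  }
})

test_that("weekly midpoint quadrature agrees with fine daily integration", {
  # independent oracle: integrate the same Wood shape on a fine daily grid
  p <- lbw_params()
  b <- herdEV:::WOOD_B; cc <- herdEV:::WOOD_C
  daily <- function(t) t^b * exp(-cc * t)
  t <- seq(0.005, 305, by = 0.01)
  total_fine <- sum(daily(t)) * 0.01
  scale <- p$ecm_305d[["1"]] / total_fine
  # compare cumulative curves at a few horizons (within 1%)
  for (days in c(105, 203, 305)) {
    fine <- scale * sum(daily(seq(0.005, days, by = 0.01))) * 0.01
    wk <- lactation_yield(1, 0:floor(days / 7), p)
    full <- floor(days / 7)
    pkg <- sum(wk[seq_len(full)]) + wk[full + 1] * (days - 7 * full) / 7
    expect_equal(pkg, fine, tolerance = 0.01)
  }
})

test_that("yield is zero beyond dry-off and support, errors on bad input", {
  p <- lbw_params()
  expect_equal(lactation_yield(2, 60, p, dry_off_week = 53), 0)
  expect_equal(lactation_yield(2, 300, p), 0)
  expect_gt(lactation_yield(2, 5, p), 0)
  # parity 3 and above share one class
  expect_equal(lactation_yield(3, 10, p), lactation_yield("3+", 10, p))
  expect_error(lactation_yield(5, 10, p), class = "herdEV_domain_error")
  expect_error(lactation_yield(1, -1, p), class = "herdEV_domain_error")
})

test_that("curve peaks after onset and declines late (shape sanity)", {
  p <- lbw_params()
  y <- lactation_yield(1, 0:50, p)
  peak <- which.max(y)
  expect_gt(peak, 2)     # rises first
  expect_lt(peak, 20)    # peaks in early lactation
  expect_true(all(diff(y[peak:45]) < 0))  # monotone decline after peak
})
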