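# Lactation yield. A Wood incomplete-gamma curve y(t) = a * t^b * exp(-c*t)
# (t in days) is used as the within-lactation shape; the scale a is set per
# parity class so that the cumulative yield over the first 305 days equals
# the calibrated 305-d ECM. Weekly yields are midpoint evaluations times 7.

WOOD_B <- 0.25   # rise exponent; peak at b/c = 62.5 days in milk
WOOD_C <- 0.004  # per-day decay

#' Weekly potential-yield matrix for the three parity classes
#'
#' @param ecm_305d numeric of length 3 (parity classes 1, 2, 3+), kg.
#' @param n_weeks number of weeks of support (yield beyond is zero).
#' @return 3 x `n_weeks` matrix of kg ECM per week, scaled so the first 305
#'   days sum to `ecm_305d` per class.
#' @keywords internal
lactation_curve_weekly <- function(ecm_305d, n_weeks = 90L) {
  stopifnot(length(ecm_305d) == 3, all(ecm_305d > 0))
  w <- seq_len(n_weeks) - 1L
  mid <- 7 * w + 3.5
  shape <- (mid^WOOD_B) * exp(-WOOD_C * mid) * 7
  # weight of each week inside the 305-d window (week 44 is partial: 4/7)
  full <- floor(305 / 7)                       # 43 full weeks
  win <- c(rep(1, full), (305 - 7 * full) / 7, rep(0, n_weeks - full - 1L))
  denom <- sum(shape * win)
  out <- outer(unname(ecm_305d), shape / denom)
  rownames(out) <- c("1", "2", "3+")
  out
}

#' Weekly milk yield of a healthy cow
#'
#' Potential ECM yield (kg) in a given week of lactation, before any
#' disease-related loss. The curve is scaled so that the cumulative yield
#' over the first 305 days equals the parity-class 305-d ECM of the
#' calibration (to well within 1%).
#'
#' @param parity_class `1`, `2` or `"3+"` (parity 3 and above).
#' @param week_in_milk week of lactation, 0-based; vectorised.
#' @param params a [herd_parameters] object.
#' @param dry_off_week optional week in milk at/after which the cow is dry
#'   (yield 0). In the simulation drying-off is driven by gestation stage;
#'   here it can be imposed directly.
#' @return kg ECM produced in that week.
#' @export
lactation_yield <- function(parity_class, week_in_milk, params,
                            dry_off_week = NULL) {
  pc <- as.character(parity_class)
  if (pc %in% c("3", "3+")) pc <- "3+"
  if (!pc %in% c("1", "2", "3+"))
    stop(structure(class = c("herdEV_domain_error", "error", "condition"),
                   list(message = paste0("unknown parity class: ",
                                         parity_class), call = NULL)))
  if (any(week_in_milk < 0))
    stop(structure(class = c("herdEV_domain_error", "error", "condition"),
                   list(message = "week_in_milk must be >= 0", call = NULL)))
  curve <- lactation_curve_weekly(params$ecm_305d)
  w <- as.integer(week_in_milk)
  y <- ifelse(w < ncol(curve), curve[pc, pmin(w + 1L, ncol(curve))], 0)
  if (!is.null(dry_off_week)) y[w >= dry_off_week] <- 0
  unname(y)
}
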