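# EV derivation by multiple regression with mediator variables. The net
# return of replicate i at scenario level j is modelled as
#
#   NetReturn_ij = mu + beta_a * x_ij + sum_k beta_bk * m_kij
#                     + beta_c * x_diff_ij + eps_ij
#
# where x_ij is the nominal trait level of the scenario, m_k are the
# mediator levels realized in the same replicate (traits that are
# themselves in the breeding goal and correlated with x: their economic
# consequences must not be double-counted in x's EV), and x_diff is the
# within-scenario centred realized trait level absorbing independent random
# variation of the trait around its nominal level. beta_a is the EV.

# mediator sets for the corrected traits; all other traits are fitted
# without mediators. "Cow insemination rate" is carried by the realized
# heat-observation rate (the detection probability that drives how often an
# eligible oestrus leads to an insemination).
MEDIATOR_MAP <- list(
  mastitis   = c("milk_yield", "cow_mortality"),
  metritis   = c("milk_yield", "ketosis", "cr_cows", "ho_cows"),
  ketosis    = c("milk_yield", "cr_cows"),
  milk_fever = c("milk_yield", "metritis", "mastitis", "dystocia"),
  lameness   = c("milk_yield", "cr_cows", "cow_mortality"),
  dystocia   = c("stillbirth", "cow_mortality")
)

#' Mediator variables for a trait's EV regression
#'
#' Returns the mediator list used to correct the trait's EV for double
#' counting; traits without a defined mediator set are fitted without
#' mediators (empty list).
#'
#' @param trait trait name (see `TRAITS`).
#' @return character vector of mediator names (possibly empty).
#' @examples
#' mediator_map("mastitis")  # milk_yield, cow_mortality
#' mediator_map("ecm")       # none
#' @export
mediator_map <- function(trait) {
  .check_trait(trait)
  MEDIATOR_MAP[[trait]] %||% character(0)
}

#' Derive the economic value of a trait from a paired-scenario experiment
#'
#' Fits the mediator regression by ordinary least squares on the
#' replicate-by-scenario rows of an experiment and returns the coefficient
#' on the nominal trait level as the EV (EUR per trait unit per cow-year),
#' with its standard error and 95% confidence interval. Mediators enter
#' centred on their pooled mean (pure conditioning; the EV coefficient is
#' unchanged).
#'
#' @param data an `experiment_result` from [run_experiment()], or any
#'   data.frame with columns `net_return`, `x_nominal`, `x_diff` and the
#'   mediator columns.
#' @param trait trait name; defaults to the experiment's trait.
#' @param mediators mediator names; defaults to [mediator_map()] of the
#'   trait. Must be distinct and exclude the trait itself.
#' @param include_x_diff include the `x_diff` regressor (default yes).
#' @return object of class `ev_estimate`: a list with `trait`, `unit`,
#'   `ev`, `se`, `ci95`, `intercept`, `mediator_coefficients`,
#'   `x_diff_coefficient`, `n_rows`, `per_case_cost` (rate traits) and the
#'   underlying `fit`.
#' @export
derive_ev <- function(data, trait = attr(data, "trait"),
                      mediators = mediator_map(trait),
                      include_x_diff = TRUE) {
  trait <- .check_trait(trait)
  if (anyDuplicated(mediators) || trait %in% mediators)
    stop(structure(class = c("herdEV_domain_error", "error", "condition"),
                   list(message = "mediators must be distinct and exclude the trait",
                        call = NULL)))
  if (length(unique(data$x_nominal)) < 2)
    stop(structure(class = c("herdEV_regression_error", "error", "condition"),
                   list(message = "need >= 2 distinct nominal trait levels",
                        call = NULL)))
  df <- data.frame(net_return = data$net_return, x = data$x_nominal)
  for (m in mediators) {
    if (!m %in% names(data))
      stop(structure(class = c("herdEV_regression_error", "error", "condition"),
                     list(message = paste0("mediator column missing: ", m),
                          call = NULL)))
    df[[m]] <- data[[m]] - mean(data[[m]])
  }
  if (include_x_diff) df$x_diff <- data$x_diff
  if (nrow(df) < ncol(df))  # params = predictors + intercept = ncol(df)
    stop(structure(class = c("herdEV_regression_error", "error", "condition"),
                   list(message = "fewer rows than regression columns",
                        call = NULL)))
  fit <- lm(net_return ~ ., data = df)
  cf <- coef(fit)
  if (anyNA(cf)) {
    bad <- names(cf)[is.na(cf)]
    stop(structure(class = c("herdEV_regression_error", "error", "condition"),
                   list(message = paste0("rank-deficient design; collinear: ",
                                         paste(bad, collapse = ", ")),
                        call = NULL)))
  }
  ev <- unname(cf[["x"]])
  if (fit$df.residual > 0) {
    se <- sqrt(diag(vcov(fit)))[["x"]]
    tq <- qt(0.975, df = fit$df.residual)
  } else {
    se <- NA_real_  # saturated fit: slope exact, no error estimate
    tq <- NA_real_
  }
  est <- list(
    trait = trait,
    unit = trait_unit(trait),
    ev = ev,
    se = se,
    ci95 = c(lower = ev - tq * se, upper = ev + tq * se),
    intercept = unname(cf[["(Intercept)"]]),
    mediator_coefficients = cf[intersect(names(cf), mediators)],
    x_diff_coefficient = if (include_x_diff) unname(cf[["x_diff"]]) else NA_real_,
    n_rows = nrow(df),
    per_case_cost = if (trait != "ecm") 100 * abs(ev) else NA_real_,
    fit = fit
  )
  class(est) <- "ev_estimate"
  est
}

#' @export
print.ev_estimate <- function(x, ...) {
  cat(sprintf("EV of %s: %.4f EUR per %s per cow-year (SE %.4f, 95%% CI [%.4f, %.4f], n = %d)\n",
              x$trait, x$ev, x$unit, x$se, x$ci95[["lower"]],
              x$ci95[["upper"]], x$n_rows))
  if (!is.na(x$per_case_cost))
    cat(sprintf("  total cost per case: %.1f EUR (= 100 x |EV|)\n",
                x$per_case_cost))
  invisible(x)
}

#' Total cost per case from a rate-trait EV
#'
#' An EV of a rate trait is EUR per percentage point of incidence per
#' cow-year; one percentage point is one case per 100 cow-years, so
#' multiplying the EV magnitude by 100 expresses the total cost per case.
#'
#' @param ev EV in EUR per percentage point per cow-year.
#' @param trait trait name; must be a rate trait (not `"ecm"`).
#' @return EUR per case (non-negative).
#' @examples
#' per_case_cost(-1.82, "mastitis")  # 182
#' @export
per_case_cost <- function(ev, trait) {
  trait <- .check_trait(trait)
  if (trait == "ecm")
    stop(structure(class = c("herdEV_domain_error", "error", "condition"),
                   list(message = "per-case cost is defined for rate traits only",
                        call = NULL)))
  100 * abs(ev)
}
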