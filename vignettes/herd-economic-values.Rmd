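---
title: "Deriving economic values from a stochastic herd model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving economic values from a stochastic herd model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model and its assumptions

`herdEV` estimates marginal economic values (EV) of dairy breeding-goal
traits by simulated comparative statics: simulate the same herd at a low and
a high level of one trait, price both, and attribute the profit difference
to the trait with a regression that strips out pathways already owned by
other breeding-goal traits.

## Herd simulation

The herd model is individual-based and advances in weekly steps on a
52-week year (a "cow-year" is 52 cow-weeks throughout; all rate inputs are
converted to weekly event probabilities against this grid). Its state is a
set of cows (parity, week in milk, reproductive status, gestation stage,
active disease episodes) and young stock (age, sex, reproductive status).
Weekly event order: disease onset; milk yield and feed accrual; oestrus,
insemination and conception; gestation and calving; mortality and culling;
episode expiry; young-stock aging and replacement entry.

**Milk.** Within-lactation shape is a Wood curve `y(t) = a t^b e^(-ct)`
(`b = 0.25`, `c = 0.004` per day, peak at ~63 days in milk), scaled per
parity class (1, 2, 3+) so the first 305 days integrate exactly to the
calibrated 305-d ECM. Drying-off happens seven weeks before expected
calving. Individual permanent yield variation is *not* modelled: replicate-
level variance comes from event stochasticity (disease, fertility,
survival), which is what the EV regression's error structure assumes.

**Reproduction.** Oestrus every 3 weeks after the voluntary waiting period
plus a postpartum anoestrus delay; detection with the breed's heat-
observation rate; conception with the conception rate times active disease
multipliers. Cows open past week 44 in milk are marked do-not-breed and
culled at week 50. Heifers breed from a fixed eligibility age
back-calculated once from the calibrated age at first calving (see
*Calibration constants*).

**Disease.** The five treated diseases with annual incidences (milk fever,
metritis, ketosis, mastitis, lameness) arise as weekly hazards
`h = (I/100)/52` per alive cow-week, so expected cases equal
`(I/100) x cow-years` *by construction*. A new case during an active
episode extends the episode and is still counted. We deliberately did not
use a survival-form hazard with a one-episode-per-lactation cap: at
mastitis-like incidences (26/100 cow-years) that construction is biased low
by ~1 case/100 cow-years, which is far outside the Monte-Carlo error of the
calibration checks the package enforces. Each case carries configurable
consequences (`disease_effects`): milk loss as a fraction of 305-d yield
spread over an 8-week window, a conception multiplier of 0.85 for
metritis/ketosis/lameness, and one-time added death risk of 0.5 %-points
for mastitis/milk fever. These magnitudes are package defaults, not
recorded data — the calibration tables give incidences only — and they are
the main lever behind EV magnitudes, which is why the package's tests
assert sign patterns and calibration properties rather than EV magnitudes.

**Dystocia and stillbirth.** Dystocia is drawn at calving. A fixed
per-calving probability cannot reproduce a per-100-cow-year incidence
(calvings per cow-year depend on fertility and culling), so the per-calving
probability self-calibrates as `q = (I/100) x cow-years/calvings` on the
run's own accumulating exposure; it converges during burn-in. Stillbirth is
a proportion of calvings (the trait definition), doubled under dystocia,
with the base rate compensated so the *marginal* stillbirth rate equals the
configured one.

**Replacement policy.** The herd targets 200 cows. Every female calf is
reared; pregnant heifers at week 36 of gestation are kept only if the herd
needs them, otherwise sold at the pregnant-heifer price; open heifers
failing 11 cycles are slaughtered. A voluntary cull hazard (default
0.20/cow-year, a management constant the calibration tables do not print)
tops up involuntary exits to a realistic ~30% annual exit rate.

## Economics

Annual technical results are priced into the conventional contribution-
margin statement per cow-year (milk; cow slaughter net of dead-stock
disposal; calf sales; heifer slaughter; live-heifer sales; cow and heifer
feed; inseminations; veterinary treatment; fixed "other costs"). The
identities `total income = Σ income`, `variable costs = Σ costs`,
`margin = income − costs` hold exactly, which is what makes the scenario
delta decomposition additive by construction.

## Scenario pairs and the EV regression

For trait *x*, two parameter sets are built that differ only in *x*: ±1
absolute percentage point for rate traits; for ECM — a kg trait to which the
percentage-point convention cannot apply — ±250 kg of 305-d yield applied
proportionally to the parity classes (the EV is per kg, so the estimate is
invariant to the delta up to Monte-Carlo noise; 250 kg clears the noise
floor). Replicate *i* runs both scenarios with seed `base_seed + i`.

Net return (mean annual contribution margin) is regressed on the nominal
trait level, the mediator levels of the replicate, and the within-scenario
centred realized trait level (`x_diff`), by OLS. The coefficient on the
nominal level is the EV. Mediator sets: every disease is mediated by milk
yield; mastitis adds cow mortality; metritis adds ketosis and the cow
conception/insemination rates; ketosis adds the cow conception rate; milk
fever adds metritis, mastitis and dystocia; lameness adds the cow
conception rate and cow mortality; dystocia is mediated by stillbirth and
cow mortality. Production, fertility, survival and stillbirth EVs are
fitted without mediators. Mediators enter centred on their pooled mean —
pure numerical conditioning; the EV coefficient is unchanged.

The "cow insemination rate" mediator is carried by the realized
heat-observation rate (detected/eligible oestruses): in this model the
probability that an oestrus leads to an insemination *is* the detection
probability, and the realized conception rate is a separate mediator.

# Randomness and common random numbers

All draws come from a counter-based RNG (a splitmix64 hash of seed, global
week, animal id, event purpose), not from a sequential stream. Two
consequences:

* identical `(params, seed)` give bit-identical results, stepping weekly or
  in blocks;
* a scenario pair differing in one parameter shares the randomness of every
  event both scenarios evaluate. Newborn ids are hashes of (dam id, parity),
  so cohorts stay aligned across the pair until trajectories genuinely
  diverge.

This makes the paired high-minus-low contrast far more precise than the
independence-based OLS standard error suggests; the package's
variance-reduction test verifies the effect empirically. Pairing still
decays over long horizons (herd composition drifts apart chaotically
through the replacement feedback), which is why the sign-pattern acceptance
test uses a 16-year horizon with a 4-year burn-in: at a fixed replicate
budget the shorter, better-correlated horizon gives a more precise paired
contrast than the full 40/10 design, and is flagged as scaled-down.

# Calibration constants

Three quantities are calibration constants fixed by matching a reported
statistic, in the model's own stated world, and never revisited per run:

* **Cow ration price** (EUR/SFU): the price book prices heifer feed only.
  Default 0.2073 EUR/SFU, solved from the baseline anchor "LBW cow feed
  ≈ EUR 1027/cow-year" given maintenance of 5 SFU/day and 0.43 SFU per kg
  ECM (1027 / (5×365 + 0.43×(2110/0.29))).
* **Postpartum anoestrus delay**: 3 weeks beyond the voluntary waiting
  period, set by matching the truncated-geometric expectation of days open
  to the calibrated calving intervals; simulated intervals land within
  ±10 days of the calibration means for all three breeds.
* **Heifer breeding eligibility age**: back-calculated from the calibrated
  age at first calving, gestation length and the expected cycles to
  conception. Crucially this constant is frozen when the parameter set is
  constructed: if it were re-derived after a fertility perturbation, the
  perturbation would be partially absorbed by recalibration and fertility
  EVs would be biased (this failure mode is real; we hit it).

Quantities the calibration tables omit entirely — rearing mortality (3.5%
early, 2.5% late), cow mortality (5%/cow-year), lameness treatment cost
(EUR 65/case), slaughter live weights (550/480 kg), dystocia risk bumps —
carry documented defaults, are configurable per breed file, and are logged
at WARN level when defaulted.

# What the generator does and does not emulate

The simulation reproduces: calibrated disease incidences (exactly in
expectation), breed reproduction means (calving interval, age at first
calving), the 305-d yield levels, a plausible herd turnover, and the
stochastic replicate-level structure the EV regression assumes. It does
*not* model seasonality, feed-ration optimisation, genetics or inheritance,
individual yield potential, milk withdrawal during treatment, or the
proprietary effect magnitudes of the reference engine. A green sign-pattern
test therefore establishes that the pipeline recovers the direction and
rough ordering of trait economics under a documented, self-consistent
calibration — not that EV magnitudes match any published table.

# Numerical choices and degenerate inputs

* OLS via QR (`lm`); rank deficiency is an error naming the collinear
  columns, not a silent drop. A saturated two-point fit returns the exact
  slope with `NA` standard error.
* Realized replicate-level rates are ratios of pooled counts over the
  retained years (not means of annual ratios), avoiding small-denominator
  noise; empty exposures yield `NA`, an empty year aggregates to an
  all-zero record with zero cow-years.
* A missing stillbirth calibration (one breed prints none) defaults to the
  nearest-kin breed value 5.2 with a warning.
* Herd extinction (no cows and no young stock) is a classed simulation
  error naming the simulated year.

# Known limitations

* EV magnitudes inherit the disease-effect defaults; treat them as
  order-of-magnitude unless `disease_effects` is calibrated to local data.
* The Table-style veterinary cost line reflects treatment costs only (no
  labour or discarded milk), so its level is below published statements
  that fold those in.
* Fertility-trait EVs have the weakest signal-to-noise; at 500 paired
  replicates their signs are stable but their magnitudes still carry
  ~0.15 EUR standard errors.
* One episode stream per disease: concurrent episodes of the same disease
  merge (the case is counted, the effect window restarts).
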