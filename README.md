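# eqtariff

Tools for the US EQ-5D-3L time trade-off tariff and its regression
specification, for health economists and HRQoL methodologists.

The EQ-5D-3L describes health on five dimensions (mobility, self-care,
usual activities, pain/discomfort, anxiety/depression) at three levels,
giving 243 states written as five-digit codes; a *tariff* maps each
state to a utility anchored at 1 (perfect health, state 11111) and 0
(death). The US tariff predicts the disutility `1 - U(s)` of an
impaired state additively from ten level dummies
(M2,...,A2, M3,...,A3), the counts-beyond-the-first terms
`I3 = max(n3 - 1, 0)` with squares `I22`, `I32`, and — in place of an
intercept — the ordinal variable

```
D1 = max(#impaired dimensions - 1, 0).
```

Because `1 = (M2 + ... + A3) - D1` holds exactly on every impaired
state, this "D1O" specification is algebraically equivalent to a
constant-term form ("D1C"): constant `= -` (D1 coefficient), each dummy
shifted by the D1 coefficient, identical predicted values for all 243
states. The package implements both (plus the "D1C_N3" variant with the
any-level-3 indicator), the exact transform between them, variance
inflation factors over the 242-state design space with an independent
matrix cross-check, calculation-step accounting, tied-state
enumeration, and a synthetic TTO valuation simulation with OLS
refitting for equivalence and coefficient-recovery checks.

## Worked example

```r
library(eqtariff)

t <- us_d1o_tariff()                  # published coefficients, 3 decimals
predict_value(t, c("11111", "21232"))
#> 11111 21232
#> 1.000 0.397

tc <- reparameterize(t)               # exact constant-term equivalent
round(tc$coefficients[1:6], 3)
#> (Intercept)     M2     S2     U2     P2     A2
#>      -0.140 -0.006 -0.035  0.000 -0.033 -0.016

v <- vif_all("D1O")                   # VIFs over the 242 impaired states
round(setNames(v$vif, v$predictor)[c("D1", "I3", "M2")], 3)
#>      D1      I3      M2
#> 113.184  38.529   5.336

nrow(find_tied_pairs(t))              # usual-activities 1->2 tied pairs
#> [1] 15
```

State 11111 always scores exactly 1 (axiomatic anchor, outside the
prediction scope). The re-parameterized usual-activities level-2
coefficient is exactly zero, which is why 15 state pairs differing only
in that move share a value; the D1 variable itself has VIF 113.2, the
headline collinearity finding. `reproduce_tables()` writes the full
coefficient/VIF table and the per-term worked examples as CSV;
`simulate_tto()` / `fit_ols()` / `recovery_experiment()` generate
synthetic respondent-level TTO data and verify by simulation that the
two specifications fit identically and recover their generating
coefficients. A thin CLI over these functions lives at
`inst/cli/eqtariff.R` (`tables`, `values`, `vif`, `compare`, `ties`,
`steps`, `simulate`).

See the vignette (`vignettes/tariff-reparameterization.Rmd`) for the
model, the R-squared conventions behind the VIFs, the step-counting
rule, and the simulation design.

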