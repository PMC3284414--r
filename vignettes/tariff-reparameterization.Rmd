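---
title: "The D1 specification of the US EQ-5D-3L tariff and its constant-term equivalent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The D1 specification of the US EQ-5D-3L tariff and its constant-term equivalent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqtariff)
```

## The model

The EQ-5D-3L descriptive system codes a health state as five digits, one
per dimension (mobility, self-care, usual activities, pain/discomfort,
anxiety/depression), each at level 1 (no problems), 2 (some problems) or
3 (extreme problems): 243 states in all, of which 242 are impaired in at
least one dimension. A *tariff* assigns each state a utility on the
scale anchored at 1 (perfect health, state 11111) and 0 (death). Values
come from regression models fitted to time trade-off (TTO) responses;
modelling is done on *disutilities*, `1 - TTO value`, so that state
11111 sits at disutility 0.

The US tariff predicts the disutility of an impaired state additively
from

* ten level dummies `M2, S2, U2, P2, A2, M3, S3, U3, P3, A3`;
* `I3 = max(n3 - 1, 0)`, the number of level-3 dimensions beyond the
  first, and the squares `I22`, `I32` of `I2` and `I3` (`I2` itself was
  dropped from the published model as nonsignificant);
* `D1 = max(n_impaired - 1, 0)`, the number of impaired dimensions
  beyond the first, used *in place of* an intercept.

The package calls this specification `D1O`. Because the identity

```
1 = (M2 + S2 + U2 + P2 + A2 + M3 + S3 + U3 + P3 + A3) - D1
```

holds exactly on every impaired state (each impaired dimension
contributes one dummy, and D1 is the impairment count minus one), the D1
term can be traded exactly for a constant. The re-parameterization
(`reparameterize()`) sets the constant to the negative of the D1
coefficient and shifts each dummy by the D1 coefficient; `I3`, `I22`,
`I32` are untouched. The resulting specification (`D1C`) predicts
identical values for all 243 states:

```{r equivalence}
t_d1o <- us_d1o_tariff()
t_d1c <- reparameterize(t_d1o)
max(abs(predict_all(t_d1o)$utility - predict_all(t_d1c)$utility))
```

A third specification, `D1C_N3`, replaces the `I3` count with the `N3`
any-level-3 indicator used by the UK model family.

### State 11111 and the scope of the constant

State 11111 carries the axiomatic value 1: it anchors the TTO exercise
and is never itself predicted. The package therefore treats the
intercept of `D1C`/`D1C_N3` as a constant *within the scope of the 242
impaired states*: `predict_value()` returns exactly 1 for 11111 under
every tariff, intercept or not, and `fit_ols()` drops 11111 rows before
fitting. This is the interpretation under which the constant-term and
D1 forms are exactly equivalent.

## Variance inflation factors

For a predictor `x_j`, the VIF is `1/(1 - R^2_j)` where `R^2_j` comes
from regressing `x_j` on all other predictors; `sqrt(VIF)` measures how
much the coefficient's standard error is inflated relative to a design
in which `x_j` were uncorrelated with the rest. The package computes
VIFs over the 242 impaired states with equal weight per state — the
definition space of the tariff, deliberately not any valuation study's
sampled subset — via `vif_all()`, and cross-checks every value against
an independent matrix route (`vif_oracle()`, the diagonal of the
inverse correlation or cosine-normalized cross-product matrix) to 1e-8.

Two R-squared conventions exist, and the choice is not cosmetic here:

* **centered with intercept** — the standard convention for intercept
  models; used for `D1C` and `D1C_N3`.
* **uncentered without intercept** — the convention statistical
  software applies to no-intercept models; used for `D1O`. With an
  *added* intercept the D1O design is exactly collinear (the identity
  above), so every centered auxiliary R-squared of its dummies and D1
  is exactly 1 and the VIFs are infinite. The finite published D1O
  VIFs only arise under the uncentered convention.

`method = "auto"` (the default) picks the convention matching the
specification; both are available explicitly. Under the defaults the
full published VIF table is reproduced at its printed precision:

```{r vifs}
vif_all("D1O")
vif_all("D1C")
```

The maximum VIF falls from 113.2 (the D1 variable itself) to 21.2
(`I3`) when the constant replaces D1; swapping `N3` for `I3` lowers the
maximum further (`N3` has VIF 3.01). One caveat the package's own
computation surfaces: that swap leaves the level-2 dummies and the
squared terms untouched but *does* move the level-3 dummy VIFs (3.591
to 3.245) — the two designs differ in a column correlated with the
level-3 dummies, so their auxiliary regressions cannot all be
invariant.

## Calculation steps and tied states

"Number of calculation steps" is informal in everyday tariff use; the
package fixes one rule and applies it uniformly: a step is either an
invoked additive term (nonzero predictor value; the constant counts
when the state is impaired and scoring starts from perfect health) or a
nontrivial multiplication (predictor value neither 0 nor 1). Under this
rule, scoring from perfect health, the constant-term form needs exactly
one extra step for the 10 single-impairment states, the same number for
the 40 double-impairment states, and strictly fewer for the 192 states
with three or more impairments; scoring impaired states from the common
value `1 - constant = 0.860` instead, it needs fewer steps for all 232
states with two or more impairments. These four claims are asserted
exhaustively in the test suite.

Because the re-parameterized usual-activities level-2 coefficient is
exactly zero (`-0.140 + 0.140`), moving usual activities from level 1
to level 2 costs nothing once the state is already impaired:
`find_tied_pairs()` enumerates the 16 candidate pairs (usual activities
1 vs 2, the other four dimensions free over levels 1 and 3) and finds
15 tied pairs; the sixteenth, (11111, 11211), differs by 0.140, the
magnitude of the constant. Ties are detected at printed precision
(tolerance 5e-4, half a unit in the last printed decimal; the printed
"-.000" is read as exactly zero), since the published coefficients are
3-decimal values treated as exact — the tolerance is a reading
convention for the published algorithm, not an estimate of the authors'
unrounded values.

## The synthetic valuation simulation

No respondent-level data from the original valuation study are
deposited, so the simulation module generates its own: each respondent
values each state, observing the tariff's true disutility plus iid
Gaussian noise. Defaults (`sim_config()`): the published tariff as
truth, all 242 impaired states, 50 respondents per state, noise sd 0.2
disutility units — individual TTO responses scatter widely around the
mean value, and 0.2 is a realistic per-response spread; 50 respondents
per state keeps a 200-replicate experiment desk-scale. Clipping to a
bounded disutility range is available but off by default; the published
model implies no particular bounds.

What the generator deliberately does *not* emulate: respondent random
effects, the original study's 13-states-per-respondent subset design,
its sampling and population weighting, and non-Gaussian TTO response
features (digit preference, censoring at the elicitation bounds).
Passing recovery tests therefore demonstrate properties of the
*specifications* under a clean generating process — equivalence, exact
coefficient mapping, OLS unbiasedness and SE calibration — not
robustness to real TTO data pathologies. In particular the printed
standard errors of the original study are not reproducible from any
simulation here and are out of scope.

`fit_ols()` fits a specification to simulated disutilities by OLS and
reports estimates back on the tariff's signed "add to 1" scale.
R-squared is centered for every specification, including the
no-intercept `D1O` — its column space contains the constant over the
impaired states, so the centered quantity is well defined and, like the
fitted values and residuals, identical between equivalent
specifications on the same data. `recovery_experiment()` repeats
simulate-and-fit with per-replicate seeds derived from the master seed
by counter (`seed + replicate index`), so the whole experiment is
reproducible from one integer.

### Standard errors and the two parameterizations

`prediction_se()` propagates a fit's coefficient covariance to a
state's predicted value in two modes. With the full covariance
(`sqrt(x' V x)`), equivalent parameterizations of the same fit give
*identical* prediction SEs for every state — re-parameterization cannot
change the distribution of fitted values. The claim that the D1 form
inflates the uncertainty of severe states (its SE "invoked four times"
where the constant's is invoked once) only materializes under
`diagonal_only` propagation, which ignores coefficient covariances;
both modes are provided and the tension is left visible rather than
adjudicated.

A related subtlety affects the `sqrt(VIF)` interpretation across
specifications. The exact design-based ratio of a dummy's SE under
`D1O` versus `D1C` equals `sqrt(VIF_D1O / VIF_D1C)` only when both
VIFs use the convention matching each estimator — uncentered on both
designs. With the mixed conventions of the published table (uncentered
for D1O, centered for D1C) the ratio is off by the centering factor
`sqrt(1/(1 - mean(x_j)))`, about 1.23 for the dummies here, and for the
level-3 dummies the D1O SEs on this design space are in fact slightly
*smaller*. The Monte-Carlo test of the SE-ratio relation therefore uses
the estimator-matched uncentered VIFs, under which the relation is an
identity up to simulation noise.

## Numerical choices

* Published coefficients are stored exactly as printed (3 decimals,
  signed "add to 1" scale) and never refitted; all worked examples are
  literal sums of these values. The per-term worked table for states
  11111, 22222, 33133, 33233 regenerated by `reproduce_tables()` sums
  to 1, 0.594, -0.095, -0.095 — the two severe states' totals follow
  from the printed per-term entries themselves, and the 33133/33233 tie
  (the usual-activities zero) is unaffected.
* Auxiliary R-squared values above `1 - 1e-12` are reported as infinite
  VIFs rather than errors; exact collinearity is a finding, not a
  failure.
* `fit_ols()` refuses rank-deficient designs, naming the dependent
  columns, rather than silently dropping them.
* Problem sizes: tests and the recovery experiment run at 242 states x
  50 respondents x 200 replicates (about 2.4 million simulated
  observations in total), chosen so that Monte-Carlo error on
  coefficient SDs is about 5% while the full suite stays desk-scale.

## Limitations

The package analyzes the published fixed-effect tariff algorithm as an
algebraic and design-theoretic object. It does not re-estimate the
tariff from valuation data, does not implement the UK value set (only
the N3 design idea), does not cover EQ-5D-5L, and makes no claims about
the statistical significance of the original coefficients — those
depend on the undeposited respondent data.
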