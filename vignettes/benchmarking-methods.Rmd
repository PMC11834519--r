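---
title: "Benchmarking community-care facilities: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking community-care facilities: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carebench)
```

## The problem and the measurement model

Community-care facilities (CCFs) provide day care, healthcare and
support services to older people. They consume resources — construction
and operating costs, subsidies, staff, a portfolio of service functions
— and produce outcomes — profitability, service volumes, coverage,
satisfaction and equity ratings. The 4E framework (Economy, Efficiency,
Effectiveness, Equity) organises these indicators: Economy and
Efficiency capture the economic side of provision, Effectiveness and
Equity the social side. Two perspectives are built in:

* **economic**: 4 inputs (self-raised construction and operating costs,
  employees, service functions) and 5 outputs (profitability, services
  completed, satisfaction, equity of delivery, complaint status);
* **social**: 4 inputs (government construction and operating
  subsidies, employees, service functions) and 8 outputs (adding
  re-employment, coverage rate, and quality-of-life improvement).

Efficiency is measured nonparametrically by data envelopment analysis
(DEA): the observed input–output points envelop a piecewise-linear
frontier, and each facility is scored against its projection onto that
frontier. We use a slacks-based measure with small data-derived
offsets (δ-SBM), which discriminates better among efficient units than
classical radial models and stays well defined when indicators contain
zeros — common in practice (a facility with no government subsidy, no
rehired workers, zero profit).

For facility $l$ the model maximises the weighted slack sum
$\sum_j w_j^- s_j^- + \sum_k w_k^+ s_k^+$ over the envelopment
technology with variable returns to scale (VRS):
$\sum_i \lambda_i x_{ij} \le x_{lj} - s_j^-$,
$\sum_i \lambda_i y_{ik} \ge y_{lk} + s_k^+$, $\sum_i \lambda_i = 1$,
all variables nonnegative. The published statement of the model lists
the objective, targets and score but not the constraint set; the
envelopment form above is the standard slacks-based VRS technology used
throughout the DEA literature this model family belongs to, and it is
isolated in a single formulation function so a variant (for example a
δ-perturbed constraint set) can be swapped in without touching the
solver. The VRS convexity constraint means a small facility is not
penalised merely for its scale.

Targets and scores follow the δ-SBM equations exactly: with scalar
offsets $\delta^- = \delta\,\min X$ and $\delta^+ = \delta\,\min Y$
(global minima over the whole panel),
$x^*_{lj} = x_{lj} - s^{-*}_{lj} + \delta^-_j$,
$y^*_{lk} = y_{lk} + s^{+*}_{lk} - \delta^+_k$, and
$\tau_l = (\sum w^+ y_l / \sum w^- x_l) \big/
(\sum w^+ y^*_l / \sum w^- x^*_l)$.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `delta` | 0.001 | scale of the data-derived target offsets (dimensionless; offsets inherit the data's units) |
| `input_weights`, `output_weights` | 1 | slack weights $w^-$, $w^+$ per indicator |
| `returns_to_scale` | `"vrs"` | convexity constraint on $\lambda$ (`"crs"` drops it) |
| `efficiency_tolerance` | 1e-6 | base tolerance for calling a score 1 |
| `tie_break` | `"lexicographic"` | canonicalisation of alternative optima |
| `min_mode` | `"literal"` | whether $\min X$ may be 0 or is the smallest positive entry |

The defaults `delta = 0.001`, unit weights and VRS are the model's
reference parameterisation. Two consequences of `delta > 0` deserve
note. First, a zero-slack facility's targets are δ-*worsened* copies of
its observations, so its raw score exceeds 1 slightly. We report the
raw score unmodified and classify with a per-facility tolerance equal
to `efficiency_tolerance` plus the exact score displacement the offsets
cause for that facility, so both readings — raw score and band — are
always available. Second, `min_mode = "literal"` follows the printed
offset formula even when the global minimum is 0 (offsets then vanish);
`"positive"` uses the smallest strictly positive entry as a safeguard
when zero-heavy data should still receive nonzero offsets.

Alternative optima are real in slack-maximisation (two different slack
splits can achieve the same objective, and they yield different targets
and scores for the projected unit's indicators). The default
`lexicographic` tie-break re-solves with the objective fixed at its
optimum and maximises each slack in column order, giving a canonical,
formulation-independent solution; `solver` accepts the first optimal
vertex found (roughly an order of magnitude faster, used internally
where only objectives or scores are needed).

## Projection diagnostics

Slack becomes interpretable as a percentage of the observed value: the
input *redundancy rate* and output *shortfall rate*, both
`slack / observed × 100`. Input rates cannot exceed 100% while targets
stay nonnegative (a 100% rate means the whole input is pure slack);
output rates are unbounded above — an output far below its projection
can show several hundred percent. The denominator choice reproduces
both behaviours. When an indicator is observed at exactly 0 with a
positive slack the ratio is undefined; we return an `NA` sentinel
rather than a silent infinity or an arbitrary convention, and the
report marks such cells. The projection report covers, by default, all
non-efficient bands, and tallies per indicator how many facilities
carry positive slack — the "k facilities show redundancy" diagnostic.

Two conservation properties tie the modules together and are enforced
by tests: the slacks in the report sum to the solver's objective per
facility, and replacing every reported facility by its δ = 0 targets
and re-evaluating empties the report (projections land exactly on the
frontier).

## Sensitivity analysis

The robustness check perturbs indicators and re-evaluates. The
perturbation scheme is not dictated by the model, so we chose the
simplest fully reproducible one: multiplicative, one column at a time
(`per-indicator`) or jointly (`all-inputs` / `all-outputs`), over a
signed grid defaulting to ±1%, ±2%, ±5%, ±10%, every cell an
independent full re-evaluation. Per-column (rather than per-facility)
perturbation is the default because it asks the managerially relevant
question — which *indicator* moves the scores; both are one flag apart.
The grid reports per-facility maximum absolute score change and a
per-indicator impact ranking. Score changes shrink continuously as the
magnitude shrinks (the LP value is continuous in its right-hand side),
which the tests check at 5%, 1% and 0.1%.

## The spatial stage

Facility performance is regressed on street-level GDP per capita:
first a univariate OLS fit $Y = \beta_0 + \beta_1 X + \varepsilon$ with
classical standard errors and two-sided t p-values, then a
geographically weighted regression
$y_i = \beta_0(u_i, v_i) + \sum_k \beta_k(u_i, v_i)\, x_{ik} +
\varepsilon_i$ to expose spatial heterogeneity in the slope. The GWR
weighting scheme is not part of the published model statement, so the
package uses the field's default: a Gaussian kernel
$w_{ij} = \exp(-\tfrac12 (d_{ij}/b)^2)$ on Euclidean distances in
projected planar coordinates, with bandwidth $b$ either fixed or
selected by leave-one-out cross-validation (golden-section search on
the log-bandwidth between half the smallest non-zero inter-point
distance and twice the coordinate range). Per-location fits are
weighted least squares via QR; rank-deficient locations are flagged and
skipped rather than aborting. The min–max interval of each coefficient
across locations summarises heterogeneity: a narrow interval (width
much smaller than the slope) means the association is spatially stable.
As $b \to \infty$ all weights become 1 and every local fit equals the
OLS fit — a limit the tests verify exactly. Geographic (lon/lat)
coordinates are deliberately not accepted; coordinates must already be
planar, and great-circle support is out of scope.

Which score (economic, social, or a composite) to regress is a study
choice, not a package choice: the response column is taken by name.

## The synthetic-data generator

Real facility surveys are rarely deposited, so the generator emulates a
survey cohort with known ground truth: 75 facilities by default, the
economic or social column structure, monetary columns in units of
10k CNY at facility-realistic magnitudes, counts at facility scale,
ratings on a 1–5 ordinal scale, and a street-level GDP covariate with a
planted association with performance (slope −0.321 per standardised GDP
unit, residual noise σ = 0.5 — values at which the slope is clearly
detectable but not trivially so at n = 75).

The frontier construction is geometric. `n_efficient` anchor facilities
sit on a concave increasing input–output surface: continuous columns
are proportional to a common size factor $r \in [0.3, 1]$ and
continuous outputs follow $g(r) = \sqrt{r}$. Every other facility is a
copy of a random anchor with all inputs multiplied by $1/u$ and all
outputs by $u$, $u \sim \mathrm{Beta}(2, 2)$ truncated to
$[0.05, 0.99]$ — strictly dominated by its parent by construction. The
Beta(2, 2) choice spreads δ = 0 scores (which equal $u^2$ against a
single anchor) across all four bands with most mass in the lower ones,
so band summaries structurally resemble an economic cohort with many
third-level facilities, without claiming to reproduce any particular
count. Jensen's inequality on the strictly concave continuous output
column guarantees every anchor keeps zero optimal slack, so at
`noise = 0` the planted set is *exactly* the DEA-efficient set — the
basis of the frontier-recovery tests. Ratings are rounded to the
ordinal scale and counts to integers; because rounding is monotone it
preserves parent dominance, and the continuous (monetary, ratio)
columns are left unrounded, which is what keeps the anchor guarantee
intact. Default measurement noise is 5% multiplicative on non-frontier
entries; with noise the planted labels are no longer guaranteed and no
test pretends otherwise.

What the generator does **not** emulate: the correlation structure of
real survey responses, non-frontier-generated inefficiency patterns,
district geography, or any interview content. Passing tests therefore
demonstrate that the method recovers structure it is mathematically
entitled to recover — not that it would reproduce any particular
empirical cohort's numbers.

The spatial response is generated on an unbounded latent scale
($0.6 + \beta_1 z_{\mathrm{GDP}} + \varepsilon$, with ε mixing white
and spatially smooth components) and deliberately not clamped to
$[0, 1]$, because clamping would bias slope recovery; the generator
documents this as a departure from bounded real scores.

## Numerical choices

The slack LPs are solved by a built-in dense two-phase simplex
(`lp_solve()`): Bland's rule for entering columns (finite termination
on these heavily degenerate programs and a deterministic pivot path), a
Harris-style ratio test that prefers the numerically largest pivot
among near-tied rows, a pivot-eligibility floor of 1e-7 on row-scaled
data (pivoting on smaller entries is pivoting on noise), redundant-row
elimination after phase 1, and a final re-solve of the basic system
against the original columns so the returned vertex is accurate to
machine precision. A terminal feasibility guard (1e-6 on the
standard-form residual) turns any silent corruption into an explicit
`numerical_failure` status, which `evaluate_panel()` records per
facility without aborting the batch. Problems are solved on data
rescaled by the panel's largest entry, making the whole procedure
invariant under a common rescaling of X and Y (verified to 1e-9 across
six orders of magnitude). Feasibility tolerance is 1e-9; score
comparisons use 1e-7; the efficient-band tolerance is 1e-6 plus the
exact δ displacement described above.

Determinism is end-to-end: fixed inputs and configuration give
byte-identical artifact files (numbers are written with the shortest
round-trip decimal representation, and the run manifest contains no
timestamps).

The test suite exercises the solver against an independent geometric
oracle (brute-force vertex enumeration of the one-input/one-output VRS
frontier) on hundreds of seeded panels, dominance soundness on a
thousand panels with a planted dominated facility, frontier recovery on
fifty 75-facility cohorts, and the closed-form $u^2$ score of a scaled
anchor copy. These problem sizes keep the full suite around a minute on
one core while covering every property at full stated scale.

## Design decisions on open points

* **Indicator screening scope.** Whether screening should compare
  indicators only within their role group (inputs with inputs, outputs
  with outputs) or across all candidates is genuinely open; the package
  defaults to within-role screening — cross-role correlation is
  expected (bigger facilities have more of everything) and is not by
  itself redundancy — and exposes `within_roles = FALSE` for the other
  reading. The screening threshold is configurable with default
  |ρ| ≥ 0.8, and both final schemas ship as built-in fixtures so the
  pipeline can bypass screening entirely.
* **Ordinal scales.** Rating indicators carry no canonical numeric
  scale; the generator uses 1–5 and downstream code treats ratings as
  ordinary numerics, as a DEA pipeline must. Real panels may use any
  nonnegative coding.
* **Exact-1 scores.** Whether an efficient unit's published score of
  exactly 1 reflects δ = 0 for those units or rounding cannot be
  settled from outside; the package persists both the raw score and the
  band so either reading is reproducible.
* **Negative data.** All built-in indicators are nonnegative, so
  negative entries are rejected at validation; the δ-SBM family can be
  extended to negative data, and the validation boundary is the single
  place to relax when such a variant is added.

## Known limitations

* The simplex is dense and pure R: comfortable up to a few hundred
  DMUs, not built for thousands (each facility is one LP with
  $n + m + p$ variables, plus $m + p$ re-solves under the
  lexicographic tie-break).
* CCR/BCC/additive models, Malmquist indices and window analysis are
  out of scope; `returns_to_scale = "crs"` exists but the reference
  analysis is VRS.
* GWR inference (local standard errors, effective degrees of freedom)
  is not implemented — the stage targets the coefficient-interval
  heterogeneity summary, not hypothesis testing; the OLS stage carries
  the inference.
* The ±grid sensitivity analysis perturbs one column (or group) at a
  time; joint random perturbation schemes are not included.
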