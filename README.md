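# carebench

Benchmarking the economic and social performance of community-care
facilities (CCFs) — day-care, healthcare and support centres for older
people — organised around the **4E framework** (Economy, Efficiency,
Effectiveness, Equity). The package is aimed at health-services
researchers who have a facility-level input–output panel (costs,
subsidies, staffing, service volumes, satisfaction ratings) and want to
know which facilities operate efficiently, by how much the others miss
the frontier, on which indicators, and how performance relates to the
economic context of the facility's location.

## The model

Each of the $n$ facilities is a decision-making unit (DMU) with
nonnegative inputs $\tilde{x}_{lj}$ ($j = 1,\dots,m$) and outputs
$\tilde{y}_{lk}$ ($k = 1,\dots,p$). For DMU $l$ the δ-SBM
(slacks-based measure) model maximises the weighted slack sum

$$\max \sum_{j=1}^{m} w_j^- \tilde{s}_{lj}^- + \sum_{k=1}^{p} w_k^+ \tilde{s}_{lk}^+$$

over the variable-returns-to-scale envelopment technology
$\sum_i \lambda_i \tilde{x}_{ij} \le \tilde{x}_{lj} - \tilde{s}_{lj}^-$,
$\sum_i \lambda_i \tilde{y}_{ik} \ge \tilde{y}_{lk} + \tilde{s}_{lk}^+$,
$\sum_i \lambda_i = 1$, $\lambda, s \ge 0$. Projection targets add small
data-derived offsets $\delta_j^- = \delta \cdot \min X$,
$\delta_k^+ = \delta \cdot \min Y$ (default $\delta = 0.001$):

$$\tilde{x}_{lj}^* = \tilde{x}_{lj} - \tilde{s}_{lj}^{-*} + \delta_j^-,
\qquad
\tilde{y}_{lk}^* = \tilde{y}_{lk} + \tilde{s}_{lk}^{+*} - \delta_k^+,$$

and the efficiency score is the ratio of aggregate output/input ratios
at observed versus target values:

$$\tilde{\tau}_l =
\frac{\sum_k w_k^+ \tilde{y}_{lk} \,/\, \sum_j w_j^- \tilde{x}_{lj}}
     {\sum_k w_k^+ \tilde{y}_{lk}^* \,/\, \sum_j w_j^- \tilde{x}_{lj}^*}.$$

Scores fall into four bands: DEA Efficient (score 1), First level
$[0.8, 1)$, Second level $[0.4, 0.8)$ and Third level $[0, 0.4)$.
Slacks become per-indicator diagnostics — the input **redundancy rate**
and output **shortfall rate**, each `slack / observed × 100` — and a
spatial stage regresses performance on street-level GDP per capita by
OLS and geographically weighted regression (GWR, Gaussian kernel,
cross-validated bandwidth).

Because facility surveys are rarely public, the package includes a
synthetic-data generator with known ground truth (planted frontier
members, planted regression slope) so the entire pipeline is runnable
and testable end to end.

## Worked example

```r
library(carebench)

spec <- synthetic_spec(n = 75, perspective = "economic",
                       n_efficient = 5, seed = 42)
gen <- generate_panel(spec)
ev  <- evaluate_panel(gen$panel)
ev
#> delta-SBM evaluation (economic perspective, VRS, delta = 0.001)
#>         score_range n_dmus                 evaluation
#>           Score = 1      5              DEA Efficient
#>    0.8 <= Score < 1      1  DEA Invalid / First level
#>  0.4 <= Score < 0.8     22 DEA Invalid / Second level
#>    0 <= Score < 0.4     47  DEA Invalid / Third level
```

The five facilities planted on the frontier are recovered exactly; the
remaining 70 spread over the three inefficient bands, most in the third
— the typical picture for economic performance, where public-welfare
facilities run high costs against limited profitability. Projection
turns their slacks into indicator-level diagnostics:

```r
projection_report(ev, gen$panel)
#> Projection report: 630 rows over 70 DMUs (bands: First level, Second level, Third level)
#>   DMUs with positive slack per indicator:
#>     E-Input1 (input): 68
#>     E-Input2 (input): 65
#>     ...
```

so e.g. 65 facilities carry staffing redundancy (`E-Input3`): they could
serve the same outputs with fewer employees. The spatial stage relates
scores to the local economy (the generator plants a slope of −0.321 per
standardised GDP unit):

```r
sp  <- generate_spatial(spec)
pts <- sp$points
pts$gdp_z <- scale(pts$gdp_per_capita)[, 1]
fit_ols(pts$gdp_z, pts$score)
#> OLS fit (n = 75): beta0 = 0.6574, beta1 = -0.3312 (se 0.0576, p = 1.973e-07)
fit_gwr(pts, response = "score", covariates = "gdp_z", bandwidth = "cv")
#> GWR fit (gaussian kernel, bandwidth 2.37473, CV score 18.8177)
#>   coefficient intervals across locations:
#>     (Intercept): [0.656953, 0.659137]
#>     gdp_z: [-0.332282, -0.329228]
```

The negative slope says facilities in wealthier streets tend to perform
worse; the narrow GWR interval says that association is spatially
stable. File-based workflows (`read_panel()` + schema sidecars,
`run_pipeline()` with a plain-text config, the `inst/cli/carebench.R`
wrapper) produce the same results as CSV artifacts plus a manifest that
reproduces any run bit-identically.

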