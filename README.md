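# sourcerisk

Soil surveys around mines and smelters ask three linked questions: how
polluted is the soil, where does each potentially toxic element (PTE) come
from, and what does that mean for the people living there — children in
particular. `sourcerisk` is an R package that answers all three on a single
samples × elements concentration table, and couples the source answer to
the health answer: every receptor-model factor gets its own risk estimate.

It is written for environmental geochemists and exposure analysts, in a
tidyverse idiom: tibbles in, tibbles out, `tidy()`/`glance()`/`autoplot()`
methods on every fitted object.

## What it computes

* **Pollution indices** — soil-property-adjusted target/intervention
  values `(SW,IW)_b = base · (A + B·clay + C·om)/(A + 25B + 10C)`,
  three-band sample classification, Hakanson ecological risk
  `Er = Tr · Cn / GB`, and per-element descriptive statistics with
  `CV = 100·sd/mean`.
* **Compositional data analysis** — closure, centred log-ratio transform
  `clr(x)_j = log(x_j / g(x))`, covariance-scaled clr biplot (ray length ∝
  clr standard deviation), and seeded k-means clustering in clr space.
* **Element networks** — Spearman/Pearson/partial association networks
  with BH-screened edges, and expected-influence centrality
  `EI(i) = Σ_j w_ij` (signed one-step sum, so antagonistic elements can
  score negative).
* **Receptor models** — varimax-rotated PCA with Kaiser retention, and a
  from-scratch weighted positive matrix factorisation: `X = GF + E`,
  `G, F ≥ 0`, minimising `Q = Σ_ij ((x_ij − Σ_k g_ik f_kj)/u_ij)²` by
  alternating exact non-negative least squares (Rcpp), with per-cell
  uncertainties `u_ij = √((σ·c)² + (0.5·MDL)²)` (5/6·MDL below detection),
  20 seeded restarts, and EPA-style diagnostics (scaled residuals, S/N,
  R², profile percentages).
* **Health risk** — USEPA multi-route hazard quotients
  (`HI = HQ_ing + HQ_der + HQ_inh`) and carcinogenic risks
  (`TCR = CR_ing + CR_der + CR_inh`) with age-adjusted intake factors IFS
  and DFS, per population (child / adult / age-adjusted resident).
* **Monte Carlo risk** — moment-matched lognormal concentration
  distributions, simulated HI/TCR distributions with percentile and
  exceedance reporting, and per-element contribution shares.
* **Source-oriented risk** — apportioned concentrations
  `C(k)_ij = g_ik f_kj` per PMF factor, pushed through the deterministic
  and Monte Carlo risk machinery; deterministic factor risks add up
  exactly to the risk of the full reconstruction.
* **Synthetic surveys** — a generator with a known non-negative
  source-mixing structure (`X = GF`, multiplicative lognormal noise,
  left-censoring at the detection limit), so every stage above is testable
  without any field data.

## Worked example

```r
library(sourcerisk)

ds <- generate_dataset(synthetic_config(seed = 42))   # 30 samples, 12 PTEs
summarize_elements(ds$samples, c("As", "Pb", "Sb"))
#>   element   mean median    max    min     sd    cv
#> 1 As       86.2   87.1   186.  28.6    40.4   46.9
#> 2 Pb      409.   294.   1424.  56.3   320.    78.2
#> 3 Sb        3.44   2.52   11.0  0.508   2.53  73.7
```

Mean As ≈ 86 mg/kg and Pb ≈ 409 mg/kg with CVs of 47–78% — the strongly
right-skewed marginals typical of a point-source-impacted district.

```r
X <- as.matrix(ds$samples[pte_elements])
u <- uncertainty_matrix(X, sigma = 0.05, mdl = default_mdl)
fit <- pmf_fit(X, u, n_factors = 3, n_runs = 20, seed = 1)
round(fit$profile_pct[, c("As", "Pb", "Sb")], 1)
#>      As   Pb   Sb
#> F1 27.6  9.5 11.1
#> F2 70.4 23.4 26.0
#> F3  2.0 67.2 62.9
```

The profile percentages (each column sums to 100% across factors) separate
an As-dominated factor (F2, the ore/tailings signature) from a Pb/Sb
factor (F3, the smelter signature).

```r
els <- c("As", "Pb", "Sb")
dists <- lapply(setNames(els, els),
                function(el) fit_concentration_distribution(ds$samples[[el]]))
rd <- monte_carlo_risk(dists, config = mc_config(n_iter = 1000, seed = 1))
dplyr::filter(tidy(rd), element == "total")
#>   population   quantity  mean        p      prob_hi_gt_1
#> 1 child        HI       4.04     6.91            1
#> 2 adult        HI       0.401    0.687           0.004
#> 3 age_adjusted TCR      0.000205 0.000386       NA

contribution_shares(rd, "HI", "child")
#>   element share_pct
#> 1 As          60.6
#> 2 Pb          36.5
#> 3 Sb           2.91
```

The simulated child hazard index has mean ≈ 4 (95th percentile ≈ 6.9) —
every draw above the HI = 1 threshold — while the adult mean stays below
1; the total carcinogenic risk mean of ≈ 2.1e-4 sits in the unacceptable
band (> 1e-4), with As contributing ~60% of the non-carcinogenic risk.
`apportion(fit)` followed by `source_health_risk()` repeats the same
summaries per PMF factor.

## Acceptance script

`scripts/acceptance.R` reruns the whole pipeline from scratch against the
installed package — synthetic survey, indices, CoDA, network, PCA, PMF,
deterministic/Monte Carlo risk and source-oriented risk — and writes its
result JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/soil-source-risk.Rmd`) describes the
models, the defaults and their units, what the synthetic generator does
and does not emulate, and the numerical choices made throughout.
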