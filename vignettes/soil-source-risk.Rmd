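---
title: "From soil geochemistry to source-oriented health risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From soil geochemistry to source-oriented health risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sourcerisk)
```

`sourcerisk` implements an integrated workflow for multi-element soil
surveys around industrial point sources: pollution indices, compositional
and network views of the element associations, two receptor models (PCA
and weighted PMF), and a USEPA-style health risk assessment evaluated
deterministically, by Monte Carlo, and per receptor-model factor. This
vignette is the package's account of the science behind each stage: the
models and their assumptions, the defaults and their units, and the
numerical choices that were genuinely open.

## The synthetic survey: a stated world

Soil surveys of this kind are small (a few dozen composite samples) and
their raw data are rarely published, so the package carries a generator
that emulates one: `generate_dataset()` draws from the same non-negative
source-mixing model the receptor stage fits,

$$X = GF + E,$$

with `G` the samples × sources activity matrix, `F` the sources ×
elements signature matrix (mg/kg per unit activity), and the error
entering multiplicatively.

The defaults describe one fixed world, chosen once:

* **30 samples, 12 elements** (As, Cd, Co, Cr, Cu, Fe, Mn, Ni, Pb, Sb,
  Zn, Hg) — the size and analyte suite of a typical composite topsoil
  survey of a mining settlement.
* **Three sources**: a battery-smelter / atmospheric signature (Pb, Sb,
  Hg, Cu, Zn), an ore-deposit/tailings signature dominated by As, and a
  geogenic signature (Fe, Mn, Cr, Ni, Co). The split of the
  anthropogenic burden into an As-carrier distinct from the Pb/Sb/Hg
  smelter reflects how antimony-district surveys actually decompose; it
  also matters mathematically — a source whose profile is a near-scalar
  multiple of another is unidentifiable in *any* mixing model, so a test
  world must keep its sources geochemically distinct. With unit mean
  activities the implied means are ≈ 85 mg/kg As, ≈ 360 mg/kg Pb,
  ≈ 3 mg/kg Sb — a heavily polluted district.
* **Source activities** lognormal with mean 1 and CV 1 (configurable
  gamma): activities are non-negative and strongly right-skewed, which
  reproduces the 45–130% per-element CVs such surveys report.
* **Noise** multiplicative lognormal with CV 0.05, matching a < 5%
  analytical relative standard deviation; a multiplicative error keeps
  concentrations strictly positive, which an additive Gaussian would not.
* **Censoring** at the ICP-OES-class detection limits in `default_mdl`;
  censored cells are reported at MDL/2 (configurable), the common
  substitution convention and consistent with the 0.5·MDL term of the
  uncertainty model below.
* **Clay and organic matter** from scaled Beta distributions (means 25%
  and 10% — the Dutch standard-soil reference point), because bounded
  percentages need bounded laws.

What the generator does *not* emulate: spatial autocorrelation (no
coordinates-driven structure), correlated analytical errors, and
source-profile variability in time. A green recovery test therefore
establishes that the estimators work on well-specified mixtures of known
richness — not that they resolve every field ambiguity.

`emulate_study_marginals()` serves the narrower task of reproducing an
element's *printed* moments: a lognormal matched in closed form to a
published mean/SD pair, for when only a summary table survives.

## Pollution indices

Target and intervention values are defined at a standard soil (25% clay,
10% organic matter) and corrected by element-specific constants A, B, C.
Two dialects are implemented because two readings of the correction
circulate: the conventional multiplicative form (default)

$$ (SW,IW)_b = \text{base}\cdot\frac{A + B\,\text{clay} + C\,\text{om}}
   {A + 25B + 10C}, $$

which is exact at the standard soil, and a "literal" variant in which the
base value multiplies only the A term. The literal form mixes units in
the numerator and does not return the base value at the standard soil, so
it is not the default, but it is retained for comparability with sources
that print it.

Band assignment is conservative: a concentration exactly at a threshold
falls in the *higher* band. The ecological risk categories
(low < 40 ≤ medium < 80 ≤ significant < 160 ≤ high < 320 ≤ very high)
are left-closed for the same reason. The `Tr` defaults (As 10, Pb 5,
Sb 7, Hakanson values elsewhere) are dimensionless toxicity weights;
background values `GB` are site property and have no meaningful default —
they are required inputs.

Statistics use the n−1 sample SD, and `CV = 100·sd/mean`; censored cells
enter at their substitute value, consistent with the PMF handling, so the
two stages never disagree about the data.

## Compositional data analysis

Concentrations are compositional: only relative information is
meaningful, and closure induces spurious correlation. The clr transform
$\mathrm{clr}(x)_j = \log(x_j/g(x))$ removes closure: rows sum to zero
and rescaling a sample leaves its coordinates unchanged. Zeros are
replaced multiplicatively at 0.65·MDL before transforming (standard
practice).

The clr biplot is the SVD of the column-centred clr matrix. The default
covariance scaling puts the singular values on the element rays, so a
ray's squared length is proportional to that element's clr variance —
the property that makes ray geometry readable as relative variability;
the form scaling is available for distance-faithful sample plots.
Clustering defaults to k = 3 (the typical geogenic / smelter / ore
decomposition of such districts) on the *full* clr coordinates rather
than the first two biplot axes: truncating to two axes discards real
variance and the choice of axis count would otherwise leak into the
cluster labels. A two-axis option exists for figure parity. k-means runs
25 seeded restarts; the number of biplot axes and the closure constant
(default 10^6, i.e. mg/kg) are configuration, not science.

## Element association networks

`build_network()` estimates pairwise associations (Spearman by default —
robust to the heavy-tailed marginals; Pearson and a ridge-regularised
partial correlation as options) and screens edges at BH-adjusted
p < 0.05. Expected influence is the *signed* one-step sum of a node's
edge weights. The signed sum — rather than the absolute ("strength")
variant — is the definition that lets an element anticorrelated with the
rest of the network carry negative influence, which is exactly the
feature that makes EI useful for flagging elements of exotic origin; the
absolute variant is exposed as an option. EI z-scores across nodes are
reported alongside raw values because the raw scale depends on network
density.

## Receptor models

**PCA.** Columns are z-scored (correlation-matrix PCA: element scales
differ by orders of magnitude), components retained by the Kaiser
criterion (eigenvalue > 1) unless a count is given, rotated by varimax
with Kaiser normalisation, and scored by the regression method. Rotation
is orthogonal, so per-element communalities are invariant — a tested
identity. A near-flat eigenvalue spectrum around 1 (the null case) makes
Kaiser retention unstable; the function warns rather than guesses.

**Weighted PMF.** The model `X = GF + E`, `G, F ≥ 0`, is fitted by
minimising

$$ Q = \sum_{ij}\left(\frac{x_{ij} - \sum_k g_{ik}f_{kj}}{u_{ij}}\right)^2 $$

with per-cell uncertainties

$$ u_{ij} = \sqrt{(\sigma_j c_{ij})^2 + (0.5\,\mathrm{MDL}_j)^2}, $$

replaced by $\tfrac{5}{6}\mathrm{MDL}_j$ for cells at or below the
detection limit. The printed trigger condition for that replacement is
circular as usually quoted (it conditions on the quantity it defines);
the default dialect triggers on concentration ≤ MDL — the receptor-model
convention — and a literal dialect (replace wherever MDL ≤ u) is kept for
fidelity.

The optimiser alternates *exact* non-negative weighted least-squares
solves of the rows of G and columns of F (Lawson–Hanson active set on the
normal equations, in C++; each subproblem is k-dimensional, k ≤ 7, so the
active set is tiny). Exact subproblem optima make Q non-increasing at
every sweep — an invariant the tests assert for every run. Convergence is
declared at relative ΔQ < 1e-8 (default `max_iter` 2000), with an
absolute floor at 1e-16 of the data's total scaled energy because an
exactly representable X drives Q geometrically toward zero and a purely
relative criterion would never fire. Twenty random restarts (the
conventional run count) start from uniform draws scaled to each element's
maximum, each on a deterministic child seed; the best-Q solution is kept
and all Q traces are retained for inspection. Factor count is a user
decision — `pmf_factor_scan()` reports Q against k but deliberately makes
no automatic choice, because Q always improves with k and the defensible
choice rests on diagnostics.

Diagnostics per element: share of scaled residuals within ±3, the
signal-to-noise ratio $\sqrt{\sum\max(x-u,0)^2 / \sum u^2}$ (cells whose
signal does not exceed its own uncertainty contribute no signal), and R²
between observed and reconstructed concentrations. Per-factor explained
variance is defined as the factor's share of the squared reconstruction,
$100\sum_{ij}(g_{ik}f_{kj})^2 / \sum_{ij}(\sum_k g_{ik}f_{kj})^2$; note
this metric is weight-dominated — factors carrying Fe and Mn absorb most
of it regardless of their trace-element content, which is why the profile
*percentages* (each element's column normalised to 100% across factors),
not the explained variances, are the interpretable source summary.

Recovered factors are only defined up to permutation and scale, so all
recovery tests first match factors to the truth by maximising total
cosine similarity over permutations (exhaustive — exact for k ≤ 8).
A caution that shaped the test design: a *noiseless* mixture is only
identifiable when the generating sources are separable (marker elements
and/or source-dominated samples); the test worlds are built that way, and
the realistic-noise worlds rely on the uncertainty weighting to make all
elements, not just the abundant ones, inform the fit.

## Health risk assessment

The three soil exposure routes for non-carcinogenic risk:

$$ HQ_{ing} = \frac{C\cdot IRS\cdot RBA\cdot EF\cdot ED}
   {BW\cdot AT\cdot RfDo}\times 10^{-6},\qquad
   HQ_{der} = \frac{C\cdot SA\cdot AF\cdot ABSd\cdot EF\cdot ED}
   {BW\cdot AT\cdot RfDo\cdot GIABS}\times 10^{-6}, $$

$$ HQ_{inh} = \frac{C\cdot EF\cdot ED}{AT\cdot RfC\cdot PEF},\qquad
   HI = HQ_{ing} + HQ_{der} + HQ_{inh}, $$

with the 10⁻⁶ factor converting mg of soil to kg and the particulate
emission factor (PEF, m³/kg) carrying the soil-to-air conversion for
inhalation. Carcinogenic risk uses the age-adjusted intake factors

$$ IFS = \frac{EF\cdot ED_a\cdot IRS_a}{BW_a} +
         \frac{EF\cdot ED_c\cdot IRS_c}{BW_c},\qquad
   DFS = \frac{EF\cdot ED_a\cdot SA_a}{BW_a} +
         \frac{EF\cdot ED_c\cdot SA_c\cdot AF_c}{BW_c}, $$

and `TCR = CRing + CRder + CRinh`, with the inhalation route carrying the
literal ×1000 mg→µg conversion for the inhalation unit risk. Two
formulation details were genuinely open and are worth recording. First,
the adult term of DFS above carries no adherence factor; that is the
formulation implemented by default, with `include_adult_af = TRUE`
switching to the screening-table convention that includes `AF_a`.
Second, in the dermal cancer route GIABS enters the denominator
(equivalently, the slope factor is adjusted by `CSFo/GIABS`), mirroring
its role in the dermal hazard quotient.

Additivity (`HI` and `TCR` equal their route sums bit-for-bit — the sums
are computed in a fixed order for that reason) and linearity in C are
exact identities, tested as such; linearity is also what makes the
source-risk decomposition below exact.

Routes whose reference value is missing are reported as *absent* (`NA`)
and excluded from HI with a named flag — never silently zeroed — because
a zero would masquerade as evidence of safety. An element with neither
slope factor nor unit risk is an error for `cancer_risks()`, not a zero.

Exposure defaults follow the USEPA RSL resident scenario (child: 200
mg/day ingestion, 6 yr, 15 kg; adult: 100 mg/day, 20 yr, 80 kg; EF 350
d/yr; PEF 1.36e9 m³/kg; carcinogenic averaging time 70 yr). The shipped
toxicity table is a screening-level placeholder set in the RSL style —
every site assessment should override it with its regulatory tables; the
engine is deliberately data-free, the numbers configuration.

Risk bands: HI ≥ 1 unacceptable; CR < 1e-6 ignorable, 1e-6–1e-4 notable
(boundaries inclusive — conservative where convention is silent), > 1e-4
unacceptable.

## Monte Carlo risk

Only concentrations are stochastic by default: exposure-factor
distributions are site-specific and rarely published, so varying them by
default would manufacture precision. Concentrations are fitted with a
lognormal matched in closed form to the sample mean and SD (positive
support, accommodates CV > 100%; the moment identity is exact and
tested), with maximum-likelihood and empirical-bootstrap alternatives.
Each element draws from an independent child stream of the config seed,
and the same concentration draws feed every population — the soil does
not change between receptors. Defaults: 1000 iterations, 95th percentile
reporting (linear interpolation between order statistics), exceedance
probabilities at the classification boundaries. The degenerate
(zero-variance) limit reproduces the deterministic result exactly, and a
single-element single-route HI — a linear map of a lognormal — has a
closed-form tail against which the simulation is tested.

## Source-oriented risk

`apportion()` splits the PMF reconstruction into per-factor concentration
matrices $C^{(k)}_{ij} = g_{ik}f_{kj}$; their sum is the reconstruction,
exactly. Factor risk uses the *per-sample* apportioned concentrations —
not mean profile × mean contribution — because the Monte Carlo needs the
between-sample variability that the mean-profile shortcut would destroy.
In deterministic mode, the linearity of every risk equation makes the
per-factor HI values sum exactly to the HI of the reconstruction (tested
to 1e-10), so "how much of the hazard is the smelter's" is a
well-defined, additive quantity. In MC mode each factor's concentrations
are refitted and simulated with the same machinery as the total-risk
pipeline, for comparability, plus a per-factor no-risk probability
(share of draws with HI ≤ 1).

## Orchestration and reproducibility

`run_pipeline()` executes the stages in dependency order from a single
config (list, JSON, or YAML), writing CSVs and a JSON manifest. One
global seed is expanded into per-stage child seeds by a fixed
deterministic scheme, so enabling or disabling one stage never shifts
another stage's random stream, and a rerun with the same config is
byte-identical — both are tested.

## Known limitations

* PMF rotational ambiguity is not quantified (no bootstrap/DISP-style
  error estimation); profile uncertainty is larger than a single best-Q
  fit suggests.
* The lognormal concentration model ignores cross-element correlation in
  the Monte Carlo; element shares of simulated totals are slightly
  smoother than correlated sampling would give.
* Left-censoring is handled by substitution (MDL/2; 0.65·MDL in clr
  space), not by likelihood-based imputation — adequate at the low
  censoring rates of the default world, biased at high ones.
* The shipped toxicity and exposure defaults are placeholders for
  screening-style demonstration, not regulatory values.
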