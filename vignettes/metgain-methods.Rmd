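---
title: "Models and methods behind metgain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metgain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

International wheat nursery networks distribute a fresh set of elite
lines every year to dozens of cooperating sites, each of which also
grows its own best local commercial variety as a check. Because the
entry list turns over annually, breeding progress cannot be read off any
single trial: it must be reconstructed by predicting every line's
genetic value across heterogeneous sites, summarizing each year by its
best lines, and regressing those summaries on the year of testing.
`metgain` implements that whole chain — per-site quality screening,
climate-based grouping of sites, a multi-site mixed model with
factor-analytic genotype-by-site covariance, and the gain and trait
regressions on top — together with a synthetic trial-network generator
that provides ground truth for every stage.

# Per-site model and the heritability screen

Each site-year is an $\alpha$-lattice: two replicates, each subdivided
into incomplete blocks. The single-site model is

$$ y_{ijk} = \mu + R_j + B_{k(j)} + G_i + \varepsilon_{ijk}, $$

with replicates $R_j$ and genotypes $G_i$ fixed and blocks
$B_{k(j)} \sim N(0, \sigma^2_{b})$ random; fitting is REML via `lme4`.
This fixed-genotype form yields the adjusted genotype means, but a
heritability needs a genotype variance, so the model is refit once with
genotypes random solely to obtain $\sigma^2_g$. We use the entry-mean
heritability

$$ H^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_\varepsilon / r}, $$

with $r$ the number of replicates, clamped to $[0,1]$; a plot-basis
variant is selectable. Sites with $H^2 < 0.05$ are excluded — strictly
below, so the boundary value is retained. Variance components are
constrained non-negative (boundary REML, as `lme4` does natively).

A caution established by simulation in this package's test suite: with
30–50 entries and two replicates, the sampling spread of
$\widehat{H^2}$ at a null site (no genetic variance) is wide enough
that only roughly half of truly uninformative sites fall below 0.05.
The screen is therefore a coarse filter against catastrophically noisy
sites, not a reliable classifier of null sites; expectations of
near-complete exclusion of null sites at this threshold are not
attainable at these trial dimensions.

# Climate classification

Retained sites are grouped by k-means ($k = 2$, 25 random restarts,
explicit seed) on standardized coolest-quarter precipitation, mean
minimum temperature and altitude. Standardization makes the clustering
invariant to affine rescaling of any covariate; restarts address
k-means' initialization sensitivity, which the source data pipeline
leaves unspecified. The cluster with the higher mean precipitation is
labeled `high_rainfall`; ties (possible only in degenerate data) are
broken by labeling the lower-altitude cluster `low_rainfall`, with a
warning. Each site is additionally checked against the conventional
150 mm precipitation rule and flagged when its label disagrees — the
flag reports, it never reassigns.

# The multi-site factor-analytic model

Within each (environment label, nursery year) group the model is

$$ y = \mathbf{1}\mu + X_s s + Z_r r + Z_b b + Z_g g + Z_{ge}\,ge + e, $$

with sites fixed and all listed random terms independent:
$\mathrm{var}(r) = \sigma^2_r I$, $\mathrm{var}(b) = \sigma^2_b I$,
$\mathrm{var}(g) = \sigma^2_g I_g$,
$\mathrm{var}(e) = \sigma^2_e I$, and the genotype-by-site term

$$ \mathrm{var}(ge) = \Sigma_s \otimes I_g, \qquad
   \Sigma_s = \Lambda \Lambda^\top + \Psi, $$

a factor-analytic (low-rank plus diagonal) covariance over sites.
The default order is FA(1) — the smallest model realizing the
structure; higher orders are selectable (with the conventional
rotation constraint fixing the upper-right triangle of $\Lambda$ at
zero) and AIC/BIC are reported for comparison. Loadings are
sign-canonicalized so the first nonzero loading of each factor is
positive, since the likelihood is invariant to a column sign flip.

## Estimation

No installed mixed-model package fits this covariance structure, so the
REML machinery is implemented here. The restricted likelihood is
evaluated through the sparse mixed-model-equation coefficient matrix
$C = W^\top R^{-1} W + \mathrm{diag}(0, G^{-1})$ using

$$ -2\,\ell_R = (n-p)\log 2\pi + \log|R| + \log|G| + \log|C|
   + y^\top P y, $$

with a sparse Cholesky factorization whose symbolic analysis is reused
across evaluations. Maximization is quasi-Newton (L-BFGS-B) on
transformed parameters — log variances, free loadings, log specific
variances — with the analytic gradient derived from the standard
identities $Z^\top P Z = G^{-1} - G^{-1} C^{uu} G^{-1}$ and
$\hat u = G Z^\top P y$; only the diagonal of $C^{-1}$ and its per-genotype
$s \times s$ blocks are needed. Starting values are method-of-moments:
the cross-site covariance matrix of genotype means seeds
$\sigma^2_g$, and its leading eigenvector seeds $\Lambda$. Convergence
is declared at a relative change in $-2\ell_R$ below $10^{-8}$ (or 300
iterations, flagged if hit); specific variances that pin to their lower
bound are flagged per site. Both the likelihood value and the MME
solutions are verified in the test suite against an independent dense
oracle that inverts the full marginal covariance directly.

## Identifiability

The genotype main effect and the common component of the FA term are
weakly identified: a loading vector proportional to $\mathbf{1}$
produces exactly the covariance $c^2 J$, indistinguishable from
genotype variance $\sigma^2_g$. The default keeps both terms, matching
the model's explicit form, and reports the *total* per-site genetic
covariance $\sigma^2_g + \Sigma_s$ for correlations. Quantities that
depend on the split — for example "how much GE variance is there?" —
should be read from the identifiable interaction component,
$\overline{\mathrm{diag}} - \overline{\mathrm{offdiag}}$ of the total
genetic covariance, which is what the package's recovery tests assert.

## Predictions

Solving the MME at the REML estimates gives BLUPs of $g$ and $ge$;
the total genetic prediction of line $i$ at site $j$ is
$\hat g_i + \widehat{ge}_{ij}$, defined for every genotype-site
combination including unobserved ones (information flows through
$\Sigma_s$). The across-site predicted mean is
$\hat\mu + \overline{\hat s} + \hat g_i + \overline{\widehat{ge}}_{i\cdot}$,
and the group's local-check mean (LCGY) averages the across-site
predictions of all local checks, which are site-specific genotypes and
enter the model as ordinary entry levels. Prediction error variances
come from the inverse coefficient matrix (computed densely up to 4000
equations, NA beyond).

# Gain regressions

For each environment, the five highest-yielding non-check lines (HYL)
of each year are selected by across-site predicted mean, ties broken
lexicographically by name. Two regressions on the centered nursery
year follow:

* **GYP** (gain per se): yearly HYL mean on year. The percentage rate
  divides the slope by the mean of the yearly HYL means over the
  period (a grand-mean denominator is selectable); the slope is also
  reported in kg/ha/yr.
* **GYLC** (gain relative to local checks): the percent series
  $100\,(\mathrm{HYL}-\mathrm{LC})/\mathrm{LC}$ regressed on year gives
  points/yr, and the absolute series $\mathrm{HYL}-\mathrm{LC}$ gives
  kg/ha/yr. Both are computed from their own series, never converted
  from each other.

Centering the year leaves slopes unchanged and puts intercepts at the
period mean. Yearly all-line densities (Silverman bandwidth,
configurable) summarize the whole nursery distribution, and the
overlap statistic reports the fraction of one environment's HYL that
also appear in the other's.

# Trait analysis

Secondary traits are derived on whatever scale the inputs are on:
grain-filling duration $\mathrm{DHM} = \mathrm{DM} - \mathrm{DH}$
(the convention implied by all reported values, under which DHM is
positive), grain number
$\mathrm{GN} = \mathrm{GY}\,[\mathrm{g\,m^{-2}}] /
(\mathrm{GW}\,[\mathrm{mg}]/1000)$, and
$\mathrm{GY}\,[\mathrm{t\,ha^{-1}}] = 0.01 \times
\mathrm{GY}\,[\mathrm{g\,m^{-2}}]$. Trait trends are OLS of yearly HYL
trait means (per-trait FA BLUPs) on the centered year.

The contribution analysis regresses GY on all traits and decomposes
$R^2$ sequentially: the partial $R^2$ of the $t$-th trait in the order
is the increment over the first $t-1$ (equivalently its sequential sum
of squares over the total), so partials telescope exactly to the total
$R^2$ and contributions are percentages of it. The default order is
greedy forward selection by incremental $R^2$, ties broken by trait
name, which makes the order invariant to input column order. Exact
collinearity (DHM with DM and DH all present) is detected; the aliased
trait is pivoted out with a warning and zero partial. The biplot is a
correlation biplot — columns standardized, SVD, singular values split
evenly between scores and loadings — because traits carry
incommensurate units.

# The synthetic generator

`simulate_program()` emulates the nursery structure: each year a fresh
set of 50 elite entries (nurseries carry 30–50) plus one distinct local
check per site; 8 sites per year drawn around two climate centres
(282 mm / 9.34 °C / 781 m vs 53 mm / 9.87 °C / 329 m, mixed
0.577 : 0.423); an $\alpha$-lattice layout with 2 replicates of 5
incomplete blocks (uneven block sizes are adjusted and recorded). A
plot's yield is $\mu$ + site effect + replicate + block + the entry's
genetic value + a rank-1 FA site deviation + residual.

Default generating values, fixed once as the study conditions:

* elite genetic trend 0.16 t/ha/yr, injected as a shift in the mean of
  each year's new-entry genetic values (entries turn over annually, so
  a trend in entry means is the only coherent encoding);
* the local-check mean trails the elite mean by 0.3 t/ha initially and
  the gap widens by 0.0651 t/ha/yr — a widening gap is required for a
  nonzero check-relative trend, since checks that improve at the elite
  rate would leave GYLC flat;
* $\sigma^2_g = 0.15$, $\Lambda = (0.3, \ldots, 0.8)$,
  $\Psi = 0.05 I$, $\sigma^2_r = \sigma^2_b = 0.05$,
  $\sigma^2_e = 0.4$, site variance 0.25 (all in (t/ha)²). These give
  per-site entry-mean heritabilities around 0.6–0.8 and between-site
  genetic correlations around 0.4–0.8, with interaction variance
  exceeding the genotype main effect — the pattern typical of
  international multi-environment wheat data;
* trait trends 1.08 mg/yr (GW), 4.10 d/yr (DM), 0 (DH, PH); traits are
  correlated with a genotype's yield deviation through fixed positive
  loadings for GW and DM (module constants, documented as arbitrary),
  so the contribution decomposition has signal to find.

All randomness flows from one seed through named substreams (climate,
design, genetics, traits, residual), so stages can be regenerated
independently and a fixed seed reproduces tables bit-identically.

What the generator does **not** emulate: spatial field trend within
sites, disease epidemics, pedigree structure among entries, missing
data patterns, or reporting errors. Passing recovery tests therefore
show that the estimators recover known truth under clean conditions at
realistic dimensions — not that real nursery data meet the model's
assumptions.

# Numerical and design choices

* Problem sizes: recovery simulations use one year of 8 sites × 40
  entries × 2 replicates per group (20 replicate groups), and 50
  ten-year programs for the slope recoveries, sizes at which the
  sampling distributions are informative while a full run of the suite
  stays interactive.
* The slope-recovery simulations feed the gain and trait stages with
  across-site adjusted genotype means as the predicted values: those
  stages are agnostic to how predictions were produced, top-line
  selection bias is constant across years (equal entry counts and
  noise), so the regression slope is the quantity under test either
  way. The BLUP route end-to-end is exercised by the pipeline run and
  the FA recovery tests.
* At 40 genotypes × 2 replicates per site, the element-wise precision
  of $\widehat\Sigma_s$ is limited by the data, not the optimizer: the
  REML estimate's agreement with truth closely tracks that of the raw
  cross-site method-of-moments covariance, and refitting from the
  generating parameters does not improve the likelihood. Recovery of
  $\Sigma_s$ element patterns to high fidelity needs more genotypes
  than a single nursery year carries.
* Degenerate inputs: constant responses return zero components and
  $H^2 = 0$; singular MMEs fall back to a minimum-norm solution with a
  warning; a singular $\Sigma_s$ during prediction is ridged by
  $10^{-8}\max(\mathrm{eig})$.
* Serialization is CSV at 10 significant digits, making repeated runs
  byte-identical across platforms.

# Limitations

Single residual variance across sites (heterogeneous residuals are a
common extension in MET practice but out of scope here); no spatial
row-column modeling; no pedigree or genomic relationships (genotypes
are iid by assertion); the FA order default of 1 is a parsimony choice,
not a claim about real networks.
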