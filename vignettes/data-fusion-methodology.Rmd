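---
title: "Fusing a clinical examination subsample into a health interview survey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing a clinical examination subsample into a health interview survey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Large health interview surveys collect self-reported information from many
respondents cheaply; clinical examinations (measured blood pressure, fasting
glucose, serum cholesterol, anthropometry) are accurate but affordable only
for a small subsample. Statistical matching — *data fusion* — imputes the
complete clinical block from the examined subsample (the **donor file**,
with common variables $X$ and specific variables $Y$) into the interview-only
respondents (the **recipient file**, with $X$ only), so that condition
prevalences can be estimated on the full fused file instead of the small
clinical subsample alone.

The fusion is only defensible when $X$ carries essentially all systematic
information about $Y$ (`predictive_relevance()` diagnoses this per
variable), and imputed records are estimates: they are meaningful only in
aggregate, never as individual measurements.

## The three imputation engines

All three engines are *stochastic*: the goal is to simulate plausible
instances of $f(Y \mid X)$, not to minimise per-record prediction error —
conditional-mean (deterministic) imputation is deliberately out of scope
because it shrinks the distribution of the imputed block.

* **k-nearest-neighbour hot deck** (`fit_knn_hotdeck()` / `impute_knn()`):
  each recipient receives the entire specific block of one real donor, so
  within-donor associations survive exactly. Similarity is a Gower-type
  distance over the common variables (range-normalised absolute difference
  for continuous, 0/1 mismatch for categorical, equal weights by default —
  the metric is a package choice; weights are configurable). Ties are broken
  uniformly at random under the seed. With $k>1$ a donor is drawn uniformly
  among the $k$ nearest, which is what makes repeated hot-deck imputation
  stochastic (the multiple-imputation variant defaults to $k = 10$).
* **Sequential regression** (`fit_sequential_regression()` /
  `impute_sequential()`): specific variables are modelled one at a time in a
  chain — linear submodels with residual SD for continuous outcomes, binary
  or multicategory logistic submodels for categorical ones, and derived
  variables (BMI) computed by formula. Candidate predictor sets are pruned
  by backward elimination (likelihood-ratio tests at `alpha = 0.05` by
  default) with a forced-in list for substantively required terms,
  operationalising the two chain-building rules: epidemiological sense and
  statistical significance. Imputation draws residuals; with
  `draw_parameters = TRUE` the coefficients are first drawn from their
  normal sampling approximation and the residual variance from its scaled
  inverse chi-square posterior, which is what makes repeated runs *proper*
  multiple imputations. Quasi-separation in a categorical submodel (a
  coefficient standard error above 50 on the logit scale) is reported as an
  engine error rather than silently producing absurd draws.
* **Data augmentation** (`da_impute()`): a Gibbs-type sampler under a joint
  latent-normal model for the specific block given the common design —
  I-steps draw the recipients' missing block given current parameters,
  P-steps draw the regression and scatter parameters from their
  normal-inverse-Wishart posterior given the completed data. Categorical
  specific variables enter as centred indicator columns and decode to the
  nearest indicator vertex (for a binary variable: the level whose latent
  indicator draw is closest, i.e. a 1/2 threshold). Defaults `burn_in =
  500`, `spacing = 100` are deliberately conservative; both are settings of
  the call and scaled-down values are used throughout the test suite and
  demo, where chains of a few hundred iterations mix perfectly well at
  these dimensions. A non-positive-definite scatter is repaired by a small
  ridge inflation (reported via a message) rather than aborting the chain.

## Validation suite

Eight statistics compare observed donor values with their re-imputed
counterparts, pairing rows by identifier. This family of statistics is
traditionally defined only by group labels, so the concrete
operationalisations are package choices, documented here with their orientation and kept pluggable:

| statistic | operationalisation | better |
|---|---|---|
| ASLm | mean achieved significance level of two-sample mean/proportion tests (Welch $t$ for continuous, chi-square for categorical) | high |
| ASLs | mean ASL of variance-ratio ($F$) tests, continuous variables | high |
| ACDi | mean absolute difference of pairwise associations within the specific block (Pearson $r$, correlation ratio $\eta$, Cramér's V by pair type) | low |
| ACDe | same, over specific-by-common pairs | low |
| WC | congruence $\langle S_o, S_i\rangle_F / (\|S_o\|_F \|S_i\|_F)$ of the centred cross-product matrices of the two specific blocks (indicator-expanded, continuous columns scaled by the observed spread); equals 1 iff proportional scatter | high |
| ASD | mean of Kolmogorov–Smirnov sup-distances (continuous) and total-variation distances (categorical) | low |
| TAU | mean of Cohen's kappa (categorical) and $1 - \mathrm{MSE}/\mathrm{var}$ floored at 0 (continuous) | high |
| RndRes | mean ASL of no-association tests of the residuals observed − imputed against every common variable (correlation test / one-way $F$) | high |

Averaging p-values (rather than combining them) follows the suite's original
design; under a faithful stochastic imputation RndRes therefore centres on
0.5, not 1, while exact reproduction of the donor block is flagged as
degenerate and reported as 1. ASD is fixed as a distance (lower = closer):
descriptions of this statistic sometimes flip its orientation between
contexts, so this package standardises on the distance reading and records
the orientation in every report.

## Multiple imputation and pooling

`multiply_impute()` repeats an engine $m$ times (donor redraws for the hot
deck, parameter draws for sequential regression, spaced chain draws for
data augmentation). `pool_estimates()` combines per-imputation estimates by
Rubin's rules: $\bar q$ the mean, $W$ the mean within-imputation sampling
variance, $B$ the between-imputation variance, $T = W + (1 + 1/m)B$.
Analyses are run per completed table and pooled; concatenating the $m$
tables into one long file (`tidy()` on a `multi_imputation`) is offered as
an export but pooled inference is the default, since concatenation gives
the same point estimate with no defensible variance bookkeeping. The
within-variance for a prevalence $p$ on $n$ rows is binomial, $p(1-p)/n$.

## The bootstrap comparison experiment

`run_comparison()` reproduces the method-comparison protocol: per
iteration, donor and recipient files are resampled with replacement, each
engine is fitted on the bootstrap donor, and the *donors'* specific block is
re-imputed from their common block and compared with their actual values —
only donors carry the truth, so validation is donor-based. MI cells compute
each statistic on each of the $m$ completed tables and record the mean
(per-imputation-then-mean, consistent with comparing per-statistic
densities). Two protocol details are package decisions worth knowing:

* **Self-donation is excluded.** A hot deck trained on a resample that
  contains the validated donor would return the donor's own row at distance
  zero and look artificially perfect; `impute_knn(exclude_self = TRUE)`
  bars donation between rows with the same identity during validation.
* **Degenerate resamples are redrawn.** If a categorical level present in
  the validation set vanishes from the bootstrap donor, the draw is
  rejected and redrawn (counted in the result) so that engine failures
  reflect the engines, not empty cells; residual engine failures are also
  logged and the run aborts past a configurable failure-rate ceiling.

The comparison is run on the continuous clinical block
(`clinical_fusion_spec()`): condition status is not fused directly but
predicted downstream from imputed risk factors, mirroring the two-phase
application design.

## Synthetic population

Because the motivating microdata are held under a research agreement, the
package ships a generator (`generate_population()`) that emulates their
structure with known ground truth: ~12 self-report common variables
(demographics, behaviour, declared conditions, self-reported height and
weight) and a clinical block generated by a chain of linear submodels with
two deliberate departures from textbook normality, both chosen to reflect
real clinical data:

* **Right-skewed residuals** (centred gamma; shapes per variable, strongest
  for fasting glucose) on the clinical variables that have no self-reported
  counterpart. Regression- and latent-normal-based engines draw normal
  residuals and therefore miss this shape; the hot deck, which transfers
  real values, does not — this is precisely the mechanism behind the
  classic finding that hot decks deliver the most realistic marginal
  distributions.
* **Metabolic cross-links** (waist into diastolic pressure and cholesterol,
  cholesterol and waist into glucose) that the curated epidemiological
  imputation scheme (`clinical_chain()`) deliberately omits, but a joint
  model captures — the mechanism behind data augmentation preserving
  multivariate structure best.
* **Gender-by-age interactions** in systolic pressure and waist, captured
  by both regression chains but not by a main-effects joint-normal design.
* **An undiagnosed-diabetes spike**: a small latent subpopulation (6%) with
  glucose shifted upwards, independent of everything self-reported —
  undiagnosed disease is the very reason examination surveys exist. The
  spike is mean-centred so every regression coefficient keeps its stated
  value.

The full generating chain, including those links, is exported as
`synthetic_generating_chain()`; fitting *it* is a correctly specified
problem, so parameter recovery within reported standard errors is a fair
implementation test (`generating_coefficients()` provides the truth in
fitted parameterization). Conditions (CVD, diabetes) are Bernoulli draws
from logistic models on the standard risk factors, with intercepts set so
global prevalences sit at realistic magnitudes (≈0.12 and ≈0.08). All
magnitudes are plausible fixtures — mean heights by gender, blood pressure
rising with age — and none are estimates of any real population. Continuous
age is generated and also banded into the five standard survey groups; the
default population size and examined fraction mirror the motivating design
(11614 respondents, 1508 examined).

What the generator does **not** emulate: survey design weights and
primary-sampling-unit structure (out of scope), item nonresponse in the
common block, measurement error in the behavioural variables, and real
nonlinear dose-response shapes. Tests passing on this synthetic world
therefore certify the machinery — engines, statistics, pooling, protocol —
not the fidelity of any particular real-world fusion.

## Application layer and numerical choices

`clinical_chain()` encodes the curated imputation scheme: clinical height
from self-reported height/weight and gender-by-age-group interactions,
clinical weight from imputed height and self-reported weight, BMI derived,
then abdominal perimeter, the two blood pressures, cholesterol and glucose (seven linear submodels in all) (each
from demographics, BMI and its declared-status variable; continuous age in
the metabolic and condition submodels, where banding would discard real
signal), and finally logistic submodels for CVD and diabetes on the
standard risk factors. `classify_conditions()` implements the clinical
threshold rules (glucose ≥ 126 mg/dL inclusive or medication; blood
pressure > 140/90 mmHg, 135/85 for persons meeting the hyperglycemia
definition, or medication; cholesterol > 250 mg/dL; BMI > 25 strictly;
waist > 102/88 cm by gender), and `classify_alcohol()` assigns intake at or
above the 280/170 g-per-week bounds to the risk category, because the
moderate category is defined strictly below the bound. Medication flags are
read from the declared-status variables ('with treat' levels) — the only
treatment information a self-report survey carries. Where a display
convention needs four activity levels folded into three, 'Light' merges
into 'Moderate' (configurable).

`estimate_prevalence()` produces the donor-only estimate (proportion with
binomial SD on $n_0$) and the fused estimate (per-imputation proportion
over donor + recipient rows, binomial within-variance, Rubin-pooled),
globally and by subgroup, with the **SD ratio** (donor SD / fused SD)
quantifying the precision gained by fusing. Empty subgroup cells are
reported as unavailable, never fabricated.

One variance subtlety deserves emphasis. The applied workflow is
two-phase: risk factors are multiply imputed (with parameter draws), and
condition status is then *predicted* from the fitted logistic submodels on
each completed table (`clinical_chain()` pins the two condition steps to
their fitted coefficients via `chain_step(draw_parameters = FALSE)`).
Under this scheme the between-variance reflects risk-factor imputation
variability only, and global SD ratios come out around 1.4–2. If the
condition-model parameters are redrawn as well (fully proper multiple
imputation, as in `synthetic_generating_chain()`), the between-variance
absorbs essentially the donor-side information bound for the condition
model and the SD ratio for a *global* prevalence hovers near 1 — proper
uncertainty propagation concedes that the donor file is the only source of
information about the condition given the risk factors. The coverage
checks use the fully proper chain; the headline precision gains use the
two-phase scheme. Users should choose per analysis and read the ratio
accordingly.

Problem sizes used by the shipped checks, chosen as a balance between
Monte-Carlo stability and desk-scale runtimes: comparison experiments run
on populations of 1600 with 600 donors at 50 bootstrap iterations and
$m = 5$ over 5 master seeds (DA at `burn_in = 60`, `spacing = 10`);
parameter recovery on donors of 2000 over 5 seeds; coverage on 200
replications of populations of 1500 with 350 donors and $m = 5$, with the
generator's skew disabled so the imputation model is exactly correct (the
premise of a coverage statement); the precision-gain analysis at the full
design scale (11614 / 1508, $m = 20$). The coverage check uses
`synthetic_generating_chain()` without significance pruning — selection
would reintroduce a small bias that a coverage statement about a correctly
specified model should not carry.

## Known limitations

* The validation statistics are one concrete operationalisation of a suite
  defined only by group labels; orientation metadata travels with every
  report so alternatives can be swapped in without touching the harness.
* The latent-normal DA treats categorical specifics by indicator rounding —
  adequate for binary flags, cruder for many-level variables; a general
  location model is the natural upgrade path.
* Rubin pooling assumes the per-imputation analysis is the one of interest;
  no small-sample degrees-of-freedom correction is applied.
* With a joint-transfer hot deck, the within-block scatter congruence (WC)
  is structurally near its ceiling, so WC separates model-based engines
  from each other better than it separates them from hot decks.
* No survey weights: all proportions are unweighted, by design.
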