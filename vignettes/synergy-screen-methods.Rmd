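---
title: "Methods: predicting synergistic drug combinations from single-agent screens"
author: "synergyscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting synergistic drug combinations from single-agent screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synergyscreen)
```

# The problem

Combination therapy is a central strategy against acquired drug resistance
in cancer, but the space of candidate pairs grows quadratically with the
drug panel while combination screening stays expensive. `synergyscreen`
implements a pipeline that learns to predict which drug pairs will be
synergistic, effective, or selectively effective in a genotype subgroup
(mutant BRAF, mutant RAS, or wild-type melanoma lines) using only
single-agent dose-response profiles as features and a limited combination
screen as training labels.

# The dose-response model

Single-agent data are fitted with the median-effect (mass-action) model.
With $f_a$ the fraction of growth inhibited at dose $D$ and
$f_u = 1 - f_a$,

$$\frac{f_a}{f_u} = \left(\frac{D}{D_m}\right)^m,$$

which is linear in log-log coordinates:
$\log_{10}\!\big(f_a/(1-f_a)\big) = m \log_{10} D - m \log_{10} D_m$.
`fit_median_effect()` estimates $(m, D_m)$ by ordinary least squares on
these coordinates and records the linear-fit correlation $r$ and the number
of points used. Inverting the curve gives the dose for any target effect:

$$D_x = D_m \left(\frac{x}{1-x}\right)^{1/m},$$

so $\mathrm{GI}_{50} = D_m$ and $\mathrm{GI}_{10}, \mathrm{GI}_{25}$ follow
from $x = 0.10, 0.25$.

Numerical choices:

* The log-odds transform is undefined at 0 and 1. Averaged responses
  outside the interior band $(\varepsilon, 1-\varepsilon)$ with
  $\varepsilon = 10^{-3}$ carry no usable information and are dropped; a
  series needs at least two interior points to be fittable.
* Replicates at the same dose are averaged before fitting, matching a
  triplicate screen design.
* A drug that never reaches 50% inhibition in its tested range has no
  in-range GI50. `gi50_matrix()` imputes such entries (and unfittable
  series) at 10 times the maximum tested dose and flags them. This keeps
  weak drugs in the feature space with a potency value that preserves their
  ordering, instead of discarding them.

# Synergy scoring

Combinations are scored with the Chou-Talalay combination index. At an
observed combination effect $f_a$ for doses $(d_1, d_2)$,

$$\mathrm{CI} = \frac{d_1}{D_{x,1}(f_a)} + \frac{d_2}{D_{x,2}(f_a)},$$

where $D_{x,i}(f_a)$ is each drug's own dose that would produce $f_a$
alone, from its median-effect fit. $\mathrm{CI} = 1$ is Loewe additivity,
$\mathrm{CI} < 1$ synergy, $\mathrm{CI} > 1$ antagonism. Screens work on
$\log_{10}(\mathrm{CI})$, and all cutoffs below are on that scale. The
mutually-nonexclusive variant with a third product term is deliberately not
computed. Bliss excess,
$e_{ab} - (e_a + e_b - e_a e_b)$, is available as a secondary effect-based
metric via `bliss_excess()`.

Two reliability rules apply during screen scoring
(`score_combination_screen()`):

* Observed effects at the interior-band boundary cannot be inverted
  reliably and are skipped with a logged count, following the same
  $\varepsilon$ convention as the fitter.
* The CI inherits the quality of the two single-agent fits. A fit backs a
  score only if it used at least `min_points = 3` interior dose points and
  achieved $|r| \ge 0.9$. Without this gate, poorly determined fits (two or
  three points plus noise) propagate large, drug-correlated errors into
  every CI involving that drug; the gate is the package's expression of the
  standard caveat that the Chou-Talalay method depends on well-defined
  dose-effect curves. Both thresholds are configurable.

# Label rules

Per-pair boolean outcomes are built from the combination screen:

* **Synergy** (training rule): the pair achieved
  $\log_{10}(\mathrm{CI}) < -1$ at *any* tested dose pair. The cutoff is
  strict. A companion validation rule (`label_synergy_validation()`) is
  inclusive at $-1$; the two variants are kept distinct on purpose and both
  are configurable. A raw CI can never be below $-1$, so the $-1$ threshold
  is only meaningful on the log scale.
* **Effectiveness**: mean percent growth inhibition across the cell-line
  group reaches 70% (boundary inclusive). For validation screens a
  third-quantile rule is provided (`label_effective_q3()`): Q3 of all
  observed inhibition values $\ge$ 70%, with Q3 computed by linear
  interpolation between order statistics (the `stats::quantile` type-7
  default).
* **Genotype selectivity**: the target genotype group's mean inhibition
  beats *every* other group's mean by at least 15 percentage points and
  reaches at least 50% within the target group. The group-mean reading of
  "within the genotypic group" is used; margin and floor are parameters, and
  setting both to zero reduces the rule to a pure mean comparison.

A dose grid gives several inhibition values per cell line; they are
collapsed to one value per (pair, cell line) before group means. The
default collapse is the mean over tested dose pairs; `dose_agg = "max"`
(the best inhibition achieved at any tested dose pair) is available where
"achieved" is read as a best-case statement.

# Features

For each pair $(a, b)$ and each cell line $c$, two features summarise the
single-agent profiles: the mean
$\mu_c = (t_{a,c} + t_{b,c})/2$ and the difference
$\Delta_c = |t_{a,c} - t_{b,c}|$ of the transformed GI50 values, giving
$2C$ features for $C$ cell lines — 54 for a 27-line panel. The transform
$t$ defaults to $\log_{10}$ of the GI50 dose in µM, because GI50s span
orders of magnitude; it is configurable since the original normalisation
("percent of concentration required to inhibit 50% of growth") admits more
than one reading. The absolute difference is forced by the requirement that
an unordered pair map to a single feature vector; a signed-difference mode
with canonical drug ordering exists behind a flag. Cell lines are ordered
by genotype block (BRAF, RAS, WT) then id, and the ordering is recorded in
the model bundle so prediction-time matrices align by name, never by
position.

A sham combination pairs a drug with itself: its $\Delta$ block is exactly
zero and its $\mu$ block is the drug's own profile. Shams are the natural
negative control for a synergy model — a drug cannot synergise with itself.

# Models and evaluation

One random forest is trained per outcome (synergy, general effectiveness,
each genotype selectivity), with 500 trees, $\sqrt{p}$ features per split
and unlimited depth — the standard defaults, all exposed in configuration.
Evaluation is 10-fold cross-validation with a plain seeded random
partition (stratified and drug-disjoint options exist but are off by
default; the drug-disjoint option addresses the train/test leakage
inherent in pair data, where both drugs of a test pair typically appear in
training pairs). AUC is the Mann-Whitney rank statistic over pooled
out-of-fold probabilities; accuracy, sensitivity, specificity and FDR
($\mathrm{FP}/(\mathrm{FP}+\mathrm{TP})$) come from the confusion matrix at
the 0.5 vote-fraction threshold. Robustness is measured by repeatedly
subsampling the training set at fractions of its size (stratified by
class), evaluating on the held-out remainder, and averaging. Feature
importances are mean-decrease-Gini values normalised to sum to one.

# The screen simulator

No public screen accompanies the pipeline, so `simulate_screen()` generates
one with known ground truth. Its defaults are the study conditions every
test and the acceptance script use.

* **Geometry**: 27 cell lines (15 BRAF / 6 RAS / 6 WT), combinations
  measured in a 19-line subset (8 / 6 / 5), 40 drugs, all 780 pairs tested.
* **Single-agent truth**: each drug has a slope $m \sim U(0.8, 2.5)$ and a
  base potency $\log_{10} D_m \sim U(-1, 1)$ (0.1-10 µM). Per-cell-line
  potency adds a latent structure:
  $\log_{10} D_{m,d,c} = b_d + \tau\, u_d v_c + \epsilon_{d,c}$ with a
  cell-line factor $v_c \sim N(0,1)$, drug loadings
  $u_d = \pm\, U(0.5, 1)$ (sign chosen at random), $\tau = 0.5$ and
  residual spread $0.15$. The bimodal loadings make pairwise profile
  correlations separate cleanly into "similar mechanism" (positive) and
  "opposing mechanism" (negative) groups; with continuous loadings near
  zero, profile correlation becomes noise-dominated and is invisible to the
  $\mu/\Delta$ features, which leaves the all-zero-$\Delta$ sham point in
  an ambiguous region of feature space.
* **Genotype selectivity**: 20% of drugs divide their $D_m$ by 8 in BRAF
  lines.
* **Dose design**: single agents on a four-point 1:10 dilution anchored at
  the drug's base potency, in simulated triplicate; combinations on a
  3\(\times\)3 grid anchored at each drug's GI10 / GI25 / GI50 in each cell
  line (low / medium / high).
* **Planted interactions**: the combination response at $(d_1, d_2)$ is the
  $f_a$ solving $d_1/D_{x,a}(f_a) + d_2/D_{x,b}(f_a) = 1/\gamma$, found by
  vectorised bisection on the log-odds scale (70 halvings of a $\pm 12$
  bracket, far beyond the $10^{-8}$ requirement; the left side is strictly
  decreasing, so the root is unique). By construction the true CI equals
  $1/\gamma$ at *every* dose pair, which makes CI recovery an exact oracle —
  a Bliss-style generator would not give that for this scorer.
* **The planted rule**: pairs in the lowest quartile of GI50-profile
  correlation across the BRAF lines are synergistic, with
  $\log_{10}\gamma \sim U(1.1, 1.5)$; all other pairs carry a 2% background
  synergy rate. This echoes the observation that predicted synergistic
  pairs tend to have weakly correlated efficacy profiles across mutant-BRAF
  lines, and it ties the label to a quantity the $\mu/\Delta$ features can
  express. The quartile, both probabilities and the $\gamma$ range are
  configuration fields.
* **Noise**: Gaussian with $\sigma = 0.05$ on the response scale — a
  typical ATP-assay replicate spread — simulated per replicate (3 by
  default), averaged, and clipped to $[0,1]$.

What the simulator does *not* emulate: plate and edge effects, correlated
(batch) noise, dose-dependent heteroscedasticity, drugs whose single-agent
curves are non-monotone or biphasic, antagonism ($\gamma < 1$), and any
mechanistic drug-target structure. Passing tests therefore demonstrate that
the pipeline recovers a planted, feature-expressible signal under
idealised independent noise — not that real screens carry such a signal.

## Degenerate and boundary behaviour

Three boundary situations deserve explicit mention:

* A combination that saturates ($f_a > 1 - \varepsilon$ at every tested
  dose pair) has no scorable dose pair, so its synergy label is undefined
  rather than false — consistent with the labelling contract that an empty
  score collection is an error, not a negative. On noiseless simulated
  screens these pairs are exactly the strongest planted synergists; they
  are excluded from label-recovery comparisons and counted.
* A planted $\gamma = 10$ places the true $\log_{10}(\mathrm{CI})$ exactly
  on the strict $-1$ training cutoff. The recovered score equals $-1$ to
  floating-point accuracy with arbitrary sign, so the *label* at this
  knife-edge is not a meaningful quantity; recovery at that point is
  asserted on the score itself.
* Seeded fold assignment, subsampling and forest growth make every
  evaluation a deterministic function of (data, hyperparameters, seed);
  rerunning the full pipeline with one seed reproduces every persisted
  stage file byte for byte.

# Problem sizes

The bundled tests and the acceptance script run the pipeline at the full
default geometry (40 drugs, 780 pairs, 27/19 cell lines) for classifier
evaluation — about half a minute per screen — and at a reduced geometry
(6 drugs, 8 lines) for the many structural and determinism checks, where
screen size is irrelevant to the property under test. Parameter-recovery
sweeps use 100 noiseless curves and 1,000 random combination-index cases.

# Known limitations

* The genotype-selectivity outcome is rare under the default generator
  (often a single class in 780 pairs); the corresponding model is then
  skipped with a message rather than trained.
* The GI50 imputation cap (10 times the maximum tested dose) is a
  convention; features built from capped values encode "weak drug", not a
  measured potency.
* Cross-validation folds are random over pairs, so the default evaluation
  shares drugs between train and test folds, as in the original design;
  use the drug-disjoint option to quantify that leakage.
* The pipeline predicts *screen* outcomes — dose-level growth inhibition
  and CI-derived labels — not clinical efficacy or tolerability.
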