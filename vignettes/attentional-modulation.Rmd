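---
title: "Measuring and modeling similarity-dependent attentional modulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modeling similarity-dependent attentional modulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attnshift)
```

## The scientific question

When two objects are superimposed and a person attends to one of them,
how strongly cortical responses are biased toward the attended object
turns out to depend on how *similar* the target and the distractor are
in their cortical representation. This package implements the full
analysis machinery for quantifying that dependence in multi-voxel fMRI
data, and a neural-population simulator for asking *which* neuron-level
attentional mechanism — response gain, tuning sharpening, or a labeled
line — can produce it.

The design has 16 conditions built from four object categories (bodies,
cars, cats, houses): 4 *isolated* conditions (one category shown and
attended) and 12 *paired* conditions (two superimposed categories, one
attended, one ignored). The data unit is a `voxel x condition x run`
table of GLM beta coefficients per participant and region
(`roi_dataset`), read from delimited text by `read_beta_table()` or
generated by `simulate_dataset()`.

## Univariate measures

For a category pair and a voxel, the category with the larger isolated
response is the voxel's more-preferred category $M$, the other is $L$
(`assign_preferences()`; exact ties break deterministically to the
alphabetically first category and are flagged). Averaging over voxels:

* **category distance** $= \bar R_{M^{at}} - \bar R_{L^{at}}$, the
  difference between the isolated responses (`univariate_distance()`);
* **attentional shift** $= \bar R_{M^{at}L} - \bar R_{ML^{at}}$, the
  drop in the paired-condition response when attention moves from $M$
  to $L$ (`univariate_shift()`). The stimuli are identical in the two
  paired conditions, so this difference isolates the attention effect.

Per participant and region, the six pairs give six (distance, shift)
points; their Pearson correlation (`shift_distance_correlation()`)
quantifies whether attention helps less when target and distractor are
more similar.

## Why split-half cross-validation

Preference labels are estimated from noisy data. Any quantity whose
sign convention depends on those labels and is computed from the *same*
noise is selection-biased: the same-half distance equals a mean of
absolute differences, which is positive even when the true distance is
zero. The pipeline therefore splits the runs into two halves
(`split_runs()`): labels (and distance) come from one half, the shift
from the left-out half. The default `odd_even` split interleaves the
halves across the session, balancing slow scanner/attentional drifts;
`first_last` is available. Which half carries the distance is an
option (`distance_half`), since the measurement sequence leaves room
for either; the default uses the preference half.

The bias and its removal are demonstrated in the test suite. One
subtlety is worth stating plainly: with noise that is independent
across conditions, the *shift* is unbiased even without
cross-validation, because labels come from the isolated cells and the
shift from the paired cells. The shift becomes selection-biased when
noise is shared between conditions with a common attention target —
as it is in real GLM betas estimated from common runs. The generator
exposes this as an optional attention-coupled noise component
(`att_noise_sd`, one Gaussian per voxel, run and attended category,
default 0); the demonstration enables it and shows that the same-half
shift inherits the bias while the cross-validated shift does not.

## Multivariate measures

Treating each condition's voxel pattern as a vector $V$, the paired
response is modeled as a linear combination of the two isolated
patterns:

$$V_{x^{at}y} = a_1 V_{x^{at}} + a_2 V_{y^{at}} + \epsilon_1,
\qquad V_{xy^{at}} = b_1 V_{x^{at}} + b_2 V_{y^{at}} + \epsilon_2.$$

`decompose_paired()` fits the weights by least squares *without an
intercept*: the construction is the orthogonal projection of the
paired pattern onto the plane spanned by the two isolated patterns,
and that plane passes through the origin; an intercept would turn the
projection into an affine fit that the construction never involves.
Weights are unconstrained in sign. The **weight shift**

$$\Delta w = \frac{a_1}{a_1 + a_2} - \frac{b_1}{b_1 + b_2}$$

is the change in the *normalized share* of the $x$ pattern when
attention moves from $x$ to $y$ (`weight_shift()`): 1 if attention
perfectly removes the distractor, 0 if attention does nothing.
Normalization makes pairs with different total weights comparable.
**Multivariate category distance** is $1 - \rho(V_{x^{at}},
V_{y^{at}})$, with a Euclidean variant as a robustness check
(`multivariate_distance()`). Cross-validation mirrors the univariate
scheme: weights from one half, distance from the other
(`pair_multivariate_result()`).

A reporting note: published group-average weights give a slightly
different share than averaging per-participant shares. For the
object-selective Body–Car example, group weights (0.79, 0.31) give an
attended share of 0.72 and a weight shift of 0.33, while
per-participant shares average to 0.72 and 0.38 with a shift of 0.34.
The report layer computes shares per participant before averaging,
and the discrepancy is documented rather than resolved.

## Numerical guards

* Near-collinear isolated patterns make the projection ill-posed; the
  decomposition is flagged degenerate when the design's condition
  number exceeds `1e6`. Distinct-category fMRI patterns sit orders of
  magnitude below this; the guard only catches pathological input.
* Near-cancelling weight sums make the share undefined; a sum below
  `1e-6 * (|w| + |w'| + eps)` yields a flagged `NA`, and degenerate
  pairs are dropped (and counted) from correlations.
* A constant pattern leaves the correlation distance undefined
  (`NA`), never an error; the same holds for a constant variable in
  the six-point correlations.
* Patterns are raw run-averaged coefficients; no voxel-wise
  normalization is applied, matching how the measures are defined.
* `voxel_filter_positive()` implements the robustness variant that
  keeps only voxels whose condition-mean response is significantly
  positive over runs (one-sided one-sample t, alpha 0.05).

## The population simulator

`build_population()` draws, per neuron, one baseline rate per category
i.i.d. from $N(30, 10)$ spikes/s truncated at 0, then swaps each
neuron's largest rate into its assigned preferred category's slot —
preserving the stated marginal moments while guaranteeing that every
neuron responds most to its preferred category and to the others "to
a lesser degree and with variation". (An optional `preference_boost`
instead raises the preferred category's mean before the swap.) Each
neuron gets an attention factor $\beta \sim U(1, 10)$. Two population
kinds: *object-selective* (the four preferences in equal proportions,
like LO/pFs) and *category-selective* (all neurons share one
preference, like EBA/PPA). Scale defaults are 4e5 neurons and voxels
of 1000 averaged same-preference neurons.

Attention multiplies a neuron's stimulus-driven response by a
mechanism-specific factor $g$ (`attended_rate()`):

* **response gain**: $g = \beta$ — enhancement independent of the
  stimulus;
* **tuning sharpening**: $g = \beta \, s$, with selectivity
  $s = R(\text{attended})/R_{max}$ — optimal stimuli strongly
  enhanced, weak ones suppressed (e.g. $\beta = 2$, $R = 10$,
  $R_{max} = 40$ gives $2 \cdot 0.25 \cdot 10 = 5 < 10$);
* **labeled line**: $g = \beta$ only if the attended stimulus is the
  neuron's preferred one, else $g = 1$.

For paired conditions (`condition_rate()`), the two stimulus drives
are combined — averaged by default, summed optionally (the combination
rule is a modeling choice; responses to multiple stimuli are known to
fall between the average and the sum of the isolated responses) — and
the factor earned by the *attended* stimulus multiplies the combined
response (`modulation = "response"`, the default). This is the reading
under which attention to either member of a pair enhances the
*neuron's response* by its factor: pure gain then modulates a pair
identically whichever member is attended (so the attention shift
between the two paired conditions is exactly zero), while tuning and
labeled-line factors depend on which member is attended. The
alternative reading (`modulation = "stimulus"`), where the factor
multiplies only the attended component and the ignored component
stays at baseline, is retained as an option; under pure gain it makes
the shift proportional to the distance in any population and so
predicts a similarity dependence that a content-independent mechanism
should not produce — which is why it is not the default.

Poisson spiking noise is applied per neuron and condition,
independently per run (`apply_noise()`); voxels average their sampled
neurons (`form_voxels()`); `simulate_dataset()` adds optional Gaussian
measurement noise (`run_noise_sd`, default 0 — Poisson spiking is the
simulator's stated noise source) and emits standard `roi_dataset`
objects, one independent population per simulated participant, fully
reproducible from the config seed.

## Mechanism signatures and problem sizes

The signature analyses in `analysis/` and the test suite use a
scaled-down population chosen to keep a full six-condition sweep
(3 mechanisms x 2 population kinds) within a couple of minutes on one
CPU: 4e4 neurons, 100 neurons per voxel, 200 voxels (a realistic ROI
voxel count; no canonical value exists), 12 runs (the lower end of a
typical session), 15 simulated participants. At these conditions:

* **response gain** leaves both the univariate shift-vs-distance and
  the weight-shift-vs-distance correlations indistinguishable from
  zero in both population kinds;
* **tuning sharpening** produces strongly positive univariate
  correlations in both kinds and a strongly positive weight-shift
  correlation in the category-selective kind;
* **labeled line** predicts the univariate effect only in the
  category-selective kind.

One signature does not replicate robustly at any feasible desk scale:
the weight-shift-vs-distance correlation under tuning in the
*object-selective* population. Because all four category rates are
i.i.d., the categories are exchangeable and that population has no
structural between-pair similarity differences; the weight shift is
then nearly constant across pairs (spread on the order of 1e-3), and
the finite-sampling coupling that remains (noiseless split halves
give a mean per-participant correlation near 0.5) is swamped by
Poisson noise at this scale. Reproducing it would require giving the
categories genuine similarity structure (correlated rates), which the
generator deliberately does not assume. The corresponding acceptance
check is left failing and documented rather than weakened.

## What the generator does and does not emulate

It emulates: per-voxel category preferences arising from averaging
selective neurons, attentional modulation with per-neuron variability,
spiking noise, multi-run sampling, and independent participants. It
does not emulate: hemodynamics, spatial correlation between voxels,
GLM estimation from time series, structural similarity between
categories (see above), or between-region differences beyond the two
population kinds. Passing signature tests therefore show that the
analysis pipeline distinguishes the mechanisms under the stated
population model — not that real cortical data were generated by one.

## Group-level inference

`group_shift_tests()` runs one-sample t tests (directional, against
zero) per ROI and pair, Bonferroni-corrected over the six pairs within
each ROI by default (Holm available; the family and the method are
explicit settings). `group_correlation_test()` tests per-participant
correlations against zero on raw r by default (mean r is what is
summarized), with a Fisher-z option. `build_report()` collates pair
summaries, correlations, group tests and degenerate counts into
deterministic tables.

## Known limitations

* The i.i.d.-rates population cannot express real category-similarity
  structure; simulated distances across pairs vary far less than
  empirical ones.
* The correlation over six pairs is a coarse statistic; per-participant
  r values are heavy-tailed at small voxel counts.
* The paired-condition combination rule and the modulation scope are
  modeling choices exposed as options; conclusions that depend on them
  should be checked under both settings.
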