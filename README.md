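# attnshift

Object-based attention biases cortical responses toward an attended
object, but the size of that bias depends on how similar the target and
the distractor are in their cortical representation. `attnshift` is an R
package for quantifying this similarity dependence in multi-voxel fMRI
data and for arbitrating, by simulation, between neuron-level
mechanisms of attentional enhancement.

It is aimed at cognitive/computational neuroscientists working with
voxel-wise GLM coefficients from designs in which four object
categories (bodies, cars, cats, houses) appear either isolated or
superimposed in attended/ignored pairs — 16 conditions in total, six
category pairs.

## The measures

For each category pair, each voxel's more-preferred category **M** and
less-preferred category **L** are assigned from its isolated responses.
Then, averaging over voxels:

- **univariate category distance** `= R(M_at) − R(L_at)`, the
  difference between the two isolated responses;
- **univariate attentional shift** `= R(M_at L) − R(M L_at)`, the drop
  in the paired response when attention moves from M to L (same stimuli
  in both conditions, so the difference is pure attention).

At the pattern level, each paired response vector is decomposed as a
no-intercept least-squares combination of the two isolated patterns,

    V_xy(att x) = a1·V_x + a2·V_y + e1
    V_xy(att y) = b1·V_x + b2·V_y + e2

and the **attentional weight shift**

    Δw = a1/(a1+a2) − b1/(b1+b2)

is the change in the normalized share of the x pattern when attention
moves from x to y (1 = distractor fully removed, 0 = no effect).
**Multivariate category distance** is `1 − ρ(V_x, V_y)` (Euclidean
variant available). All effect measures are split-half cross-validated:
voxel preferences and decomposition weights come from one half of the
runs, distances/shifts from the left-out half.

A built-in simulator generates fMRI-like datasets from spiking neural
populations (baseline rates ~ N(30, 10) sp/s, per-neuron attention
factor β ~ U(1, 10), Poisson noise, voxels averaging similarly
selective neurons) under three attentional mechanisms — response gain
(`β`), tuning sharpening (`β·R/Rmax`), labeled line (`β` only for the
preferred stimulus) — and two population kinds (object-selective,
category-selective), so the full pipeline is testable end to end
without any scanner data.

## Worked example

```r
library(attnshift)

cfg <- population_config(n_neurons = 2e4, neurons_per_voxel = 100,
                         n_voxels = 40, population_kind = "category_selective",
                         mechanism = "tuning", seed = 42)
sim <- simulate_dataset(cfg, n_participants = 8, n_runs = 8)

uni <- analyze_univariate(sim)          # distance & shift per pair
cors <- shift_distance_correlation(uni) # six-point r per participant
round(cors$r, 3)
#> [1] 1 1 1 1 1 1 1 1
group_correlation_test(cors)[, c("roi", "t_stat", "df", "p_raw")]
#>                  roi   t_stat df       p_raw
#> 1 category_selective 463392.9  7 2.87806e-38
```

In a tuning-sharpening world, every simulated participant of a
category-selective region shows a perfect rank relation between how
different two categories' responses are and how much attention shifts
the response — the similarity dependence the measures are built to
detect. The pattern-level analysis shows the same gradation, with the
weight shift growing with pattern distance:

```r
mv <- analyze_multivariate(sim)
subset(mv, participant == "sim01",
       select = c(distance, a1, a2, b1, b2, delta_w))
#>   distance    a1    a2    b1    b2 delta_w
#> 1    0.597 0.622 0.439 0.136 0.909   0.456
#> 2    0.508 0.648 0.383 0.144 0.889   0.489
#> 3    0.471 0.640 0.402 0.141 0.899   0.478
#> 4    0.722 0.721 0.237 0.212 0.748   0.532
#> 5    0.666 0.731 0.228 0.231 0.730   0.522
#> 6    0.952 0.732 0.230 0.231 0.730   0.521
```

The share arithmetic on reported group-average weights for the
object-selective Body–Car pair: attending bodies gives weights
(0.79, 0.31), so the body share is

```r
round(weight_share(0.79, 0.31), 2)
#> [1] 0.72
weight_shift(0.79, 0.31, 0.43, 0.68)
#> [1] 0.3307944
```

## The analysis workflow

The `analysis/` scripts run the full study on simulated data and write
their tables under `results/`:

1. `01_simulate_demo.R` — mechanism arithmetic on an example neuron and
   a demo beta table that round-trips through `read_beta_table()`;
2. `02_run_signature_simulations.R` — simulates all six mechanism ×
   population conditions (4e4 neurons, 100 per voxel, 200 voxels,
   12 runs, 15 participants) and runs both cross-validated analyses;
3. `03_mechanism_signatures.R` — per-condition group mean and 95% CI of
   the effect-vs-distance correlations (`results/mechanism_signatures.csv`);
4. `04_report_worked_example.R` — full report tables for the tuning
   condition and the worked share example.

Their bottom line: response gain predicts *no* relation between
attentional effects and category distance anywhere; tuning sharpening
predicts strongly positive relations (univariate in both population
kinds, multivariate in the category-selective kind); the labeled line
predicts the univariate effect only where all neurons share a
preference. See the methods vignette
(`vignettes/attentional-modulation.Rmd`) for the model, the numerical
guards, and the one signature that does not replicate at desk scale.

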