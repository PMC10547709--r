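# recursel

Behavioral-state-dependent recursive movement and step selection analysis
for GPS telemetry.

Animals do not sample their home ranges uniformly: they return to
profitable places. **recursel** quantifies that recursion conditional on
behavioral state and feeds it back into habitat selection models. It is
aimed at movement ecologists with hourly GPS relocations of central-place
or brood-rearing animals (its defaults describe wild-turkey broods tracked
for 28 days post-hatch) who want to go beyond landcover-only resource
selection.

The workflow, end to end:

1. **Clean** fixes (drop DOP > 7, drop roost-time fixes) and build step
   lengths `l` and turning angles `θ` in day-level bursts.
2. **Classify behavior** with a 3-state hidden Markov model with
   state-specific gamma × von Mises emissions,
   `f_k(l, θ) = Gamma(l; μ_k, σ_k) · vM(θ; m_k, κ_k)`,
   fitted by direct maximization of the forward log-likelihood and decoded
   with the Viterbi algorithm; the two slow states merge to *restricted*,
   the fast one is *mobile*.
3. **Measure recursion** per fix with a state-specific circular buffer
   (90 m restricted / 250 m mobile): revisitation (visit segments entering
   on other days), residence time (total time inside), return times
   (days between visits), with exact interpolated buffer crossings.
4. **Rasterize** recursion into per-animal, per-state 30-m intensity
   surfaces (movement-kernel smoothing along steps), rescaled to 0–100
   where **0 = strongest recursion**.
5. **Fit step-selection functions**: each used step versus 100 available
   steps drawn from the fitted movement distributions, by exact stratified
   conditional-logistic likelihood
   `ℓ(β) = Σ_s [x_used'β − log Σ_j exp(x_j'β)]`
   (equivalently, the fixed-large-variance conditional Poisson of Muff et
   al., which the package also implements as a cross-check), over a
   candidate set of landcover, recursion-only and composite
   (landcover × recursion) models.
6. **Select and validate** with AICc, ΔAICc, Akaike weights and rank-based
   AUC.

A synthetic-data module (landscape + state-switching trajectories with
patch attraction) provides known ground truth, so the whole pipeline is
testable offline.

## Worked example

```r
library(recursel)

cfg <- pipeline_config(outdir = "demo_run", seed = 1,
                       sim = sim_config(n_broods = 3, n_days = 28),
                       n_rows = 60, n_cols = 60)
res <- run_pipeline(cfg)
res$hmm_fit
```

```
<recursel_hmm_fit> 3 states, loglik -4013.36 on 638 steps (converged)
  stationary  gamma mean    24.1 m (sd    22.3), vm mean  -2.82, kappa  0.13
  restricted  gamma mean   145.6 m (sd   150.0), vm mean   2.73, kappa  0.45
  travelling  gamma mean   193.5 m (sd   435.2), vm mean  -0.04, kappa  0.60
```

The slow states land close to their generative values (step-length means of
27 and 150 m); the travelling state (generative mean 400 m, sd 1000 m) is
the hardest to pin down on a three-brood demo — its heavy-tailed gamma
produces many short steps, and the simulator's patch attraction shortens
steps near focal patches — so its fitted mean sits low at this sample size.
(At the 20,000-step scale the test suite uses, all three means are
recovered within 5%.) The travelling state is still the directed one: its
turning-angle concentration is the highest and centred on zero. Merged
state use and a model-selection block:

```r
res$state_props
#> # A tibble: 2 × 2
#>   state       prop
#>   <chr>      <dbl>
#> 1 restricted 0.531
#> 2 mobile     0.469

res$blocks[["ground.restricted.revisit"]]$table
#> # A tibble: 3 × 8
#>   model              K  AICc dAICc           w logLik   AUC n_strata
#> 1 recursion_only     1 1359.   0   1.000        -678. 0.533      149
#> 2 composite         17 1377.  18.6 0.0000928    -669. 0.556      149
#> 3 landcover          9 1390.  30.9 0.000000195  -685. 0.526      149
```

Each block (roosting period × behavioral state × recursion metric) ranks
the three candidate structures; `w` is the Akaike weight and AUC the pooled
used-vs-available discrimination of the linear predictor (0.5 = chance).
On this small simulated demo the recursion-only model wins the
ground/restricted block: the simulated broods revisit focal patches, and
the 0–100 revisitation raster carries that signal more parsimoniously than
seven landcover distances. Coefficients for models within 2 ΔAICc are in
`res$blocks[[...]]$coefficients`; `tidy()`, `glance()`, `autoplot()`,
`plot_track()` and `plot_recursion_raster()` cover inspection and figures.

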