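---
title: "Behavioral-state-dependent recursion and step selection: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral-state-dependent recursion and step selection: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

recursel implements a complete workflow for asking how *recursive movement*
— an animal's returns to previously visited places — interacts with
behavioral state to shape habitat selection. The intended data are
hourly GPS fixes on brood-rearing birds (the package's defaults describe
wild-turkey broods followed for 28 days post-hatch, with hourly fixes
0500–2000 and one nightly roost fix), but every stage takes plain tabular
inputs and is reusable for any hourly telemetry on a projected (meter)
coordinate system.

This vignette explains the models, the tunable parameters, the synthetic
data generator the test-suite rests on, and the numerical choices made where
the design was genuinely open.

## 1. Data model and preprocessing

A **fix table** has one row per GPS fix: `brood_id`, `timestamp`, `day`
(days since hatch, 1–28), projected `x`, `y` in meters, `dop`, and flags.
Cleaning applies two filters:

* `filter_dop()` drops fixes with dilution of precision strictly above 7;
  a fix at exactly 7 is kept. Missing DOP is an error, never a silent keep.
* `drop_roost_fixes()` removes the roost-associated fixes by time of day
  (23:58:58, 05:00, 06:00): roost sites are rarely revisited and the
  analysis targets foraging, loafing and travelling behavior.

`build_steps()` turns fixes into the observation stream of the movement
model: step length (Euclidean displacement between consecutive fixes) and
turning angle (signed heading change, wrapped to (-pi, pi]). Two conventions
needed fixing where the field has none:

* **Bursts.** Steps are only formed within *bursts* that break at
  calendar-day boundaries and at gaps longer than 1 h. Roost-fix removal
  leaves an overnight hole over which a "step" would conflate a night of
  roosting with an hour of movement; the burst rule makes that choice
  explicit and configurable (`max_gap_h`).
* **Ties and zeros.** A turning angle that lands exactly on ±pi is reported
  as +pi (a fixed convention, for reproducibility). Zero-length steps are
  legal — GPS jitter produces them — and carry a missing turning angle,
  since their heading is undefined.

Days 1–13 are the ground-roosting period and days 14–28 the tree-roosting
period (`split_periods()`); all selection models are fitted separately per
period.

## 2. The 3-state movement HMM

Behavioral states are inferred with a hidden Markov model whose per-state
emission is gamma (step length) × von Mises (turning angle). Gamma
distributions are parameterized by mean and standard deviation — the scale
practitioners report — and converted internally via shape = (mean/sd)²,
scale = sd²/mean. The canonical starting values (`default_hmm_init()`) are
a stationary state (27 m / 27 m; turning-angle mean pi, concentration 0.1),
a restricted state (150 m / 150 m; mean 2.5, concentration 0.5) and a
travelling state (400 m / 1000 m; mean 0.001, concentration 0.99). The 2.5
rad restricted-state center is unusual but is retained verbatim as a
starting value only; the optimizer is free to move it.

Estimation is by direct numerical maximization (BFGS with restarts) of the
exact forward log-likelihood, not EM: the composite gamma×von Mises
emission, the working-scale parameterization (log links for positive
parameters, multinomial-logit rows for the transition matrix) and the
Hessian-based confidence intervals all come out of one machinery. Each
burst restarts the chain from the initial distribution and bursts are
treated as independent; the default fits one pooled model across animals,
which is what a single reported parameter set implies (per-animal fitting is
just a `group_split()` away). Missing turning angles contribute no
turning-angle term. Exact-zero steps have no gamma density; unless a
zero-mass point component is configured (`zero_mass`), fitting jitters them
by U(0, 0.1) m and decoding scores them at the 0.05 m midpoint — both
documented fallbacks, chosen so the model never crashes on jittery data.

Label switching is resolved by sorting fitted states on the gamma mean, so
state 1 is always the slowest. `viterbi()` computes the jointly most
probable path per burst (ties toward the lower state index) and appends the
merged two-state labels used everywhere downstream: stationary and
restricted collapse to **restricted**, travelling becomes **mobile**. The
merge reflects that both slow states are short-distance, foraging-like
behavior, and it is applied after decoding, not inside the model.

Numerics: the forward and Viterbi inner loops are C++ (log-space with
per-burst renormalization); confidence intervals come from the inverse
numerical Hessian on the working scale, back-transformed, so gamma and
concentration intervals are always positive. Against exhaustive path
enumeration the forward likelihood is exact to 1e-8 on instances small
enough to enumerate.

## 3. Recursion statistics

Recursion is measured per fix with a circular buffer whose radius depends on
the fix's merged state: 90 m for restricted and 250 m for mobile movements
(`buffer_spec()`; the defaults are the merged states' mean step lengths, so
the buffer approximates the area used around a fix in one hour). For each
focal fix:

* **Visit segments** are maximal runs of the trajectory inside the closed
  disc (distance ≤ radius counts as inside). Entry and exit instants are
  interpolated linearly in space and time along the boundary inter-fix
  segments — an exact line–circle intersection — but never across a burst
  boundary: a visit in progress when a burst ends, ends with the burst.
* **Revisitation** is the number of visit segments whose entry day differs
  from the focal fix's day. Counting *segments* rather than fixes-inside
  keeps the statistic from inflating with fix frequency; the per-fix
  variant is available via `count_mode = "fixes"`.
* **Residence time** is the total duration of all visit segments over the
  whole monitoring window, the focal visit included.
* **Return times** are the day-valued gaps between consecutive segments.

Animals are evaluated independently; no shared-space recursion is computed.
The implementation is validated against an O(n²) brute-force oracle that
re-scans the whole track per focal fix and finds crossing times by
root-finding at 1-second bracketing resolution: revisit counts agree
exactly and residence times within one second.

## 4. Recursion rasters

To let recursion enter a selection model as a covariate, per-fix statistics
are converted to continuous surfaces on the 30-m landscape grid
(`recursion_intensity()`). Every fix of the requested state deposits an
isotropic Gaussian kernel weighted by its metric value (revisit count or
residence hours), with bandwidth equal to the state's buffer radius, and
the deposit is smeared along the fix's incoming step (5 interpolation
points by default, each carrying weight/5). This is a movement-informed
kernel in the spirit of biased-random-bridge utilization distributions:
intensity spreads along the path rather than sitting in point blobs. A
full BRB estimator needs diffusion and time-step parameters that are not
identifiable from hourly data without further assumptions, so the package
implements this fully specified approximation instead and exposes its two
knobs (`bandwidth`, `n_interp`). Consequences: surface *construct*
properties (mass conservation, linearity in the weights, maxima at
recursion hotspots) are testable and tested, but absolute map values are
estimator-specific.

`rescale_0_100()` then linearly inverts each surface to the reporting
scale: 0 marks the cells most strongly associated with the recursive
behavior, 100 the cells without it (v → 100·(1−v/vmax); an all-zero
surface maps to all-100; a monotone rank variant is available). Rasters are
built per animal, per merged state, per metric, all sharing the landscape's
grid registration.

## 5. Step selection with recursion covariates

`build_strata()` forms one stratum per observed step with a defined turning
angle: the observed endpoint (case 1) plus 100 available endpoints sampled
conditionally on the previous fix — step length from the *fitted* gamma of
the step's decoded state, direction relative to the previous heading with a
von Mises deviation from the same state (relative-heading sampling is
standard step-selection practice; at burst starts the direction is
uniform). Available points falling off the mapped landscape are redrawn,
i.e. availability is truncated to the mapped extent; with a landscape
generated to cover the tracks this affects a negligible fraction of draws.

Covariates are extracted by nearest-cell lookup (30-m raster semantics, no
interpolation): distance to each of the seven landcover classes and to
secondary roads (exact Euclidean distance transforms of the rasterized
features), NDVI, and the animal's own state-specific recursion rasters.
Distance covariates and the recursion covariates are scaled and centered
(mean 0, sd 1 with the n−1 convention) per period × state data set; the
movement-control covariates log step length and cos turning angle stay on
their natural scale by default (`scale_movement` switches this), since
standardizing them only rescales coefficients that are never interpreted as
selection. The log of a zero step uses a 0.1 m floor. Pairwise Pearson
correlations above 0.7 are flagged, never auto-dropped.

The candidate set per period × state × metric is: a **landcover** model
(distances to roads, hardwood, mixed pine-hardwood, open, pine,
shrub/scrub, plus NDVI, plus the movement terms), a **recursion-only**
model (the single recursion covariate), and a **composite** model
(landcover + recursion + all seven landcover × recursion interactions) —
24 fits over 2 periods × 2 states × 2 metrics.

Fitting maximizes the stratified conditional-logistic log-likelihood with
Newton–Raphson and analytic derivatives; standard errors come from the
inverse observed information. This is the exact infinite-variance limit of
the "conditional Poisson with stratum intercepts of fixed large variance"
formulation, which is also implemented (`method = "poisson"`, via glmmTMB
with the intercept variance pinned at 10^6) and agrees with the conditional
route to better than 1e-3 on the same data — a cross-check the test suite
performs. A covariate with no within-stratum contrast is inestimable and
is reported with coefficient 0 and missing SE; diverging coefficients are
diagnosed as quasi-complete separation and raised as an error naming the
covariate, rather than returned as a huge number.

Per-animal heterogeneity: the default (and the mode all acceptance checks
use) is fixed-effects-only. Where random slopes are wanted, the intended
estimator is two-stage — per-animal conditional fits pooled by
inverse-variance weighting — rather than a Laplace-approximated joint
mixed model; the joint model is out of scope. Interactions never get
per-animal slopes (they are the first victims of quasi-complete
separation in sparse strata).

## 6. Model selection and validation

Models within a block are ranked by AICc with n = number of strata (each
stratum contributes one conditional likelihood term; this choice is
configurable and documented rather than silent). Akaike weights use the
standard exp(−Δ/2) rule; AICc ties break by model name so a block always
has exactly one Δ = 0 row. Coefficient tables are emitted only for models
within 2 ΔAICc of the best.

Discrimination is summarized by the rank-based AUC of the linear predictor,
used points versus available points, pooled over strata with ties counting
one half. AUC on a conditional model is methodologically loose — the
stratum term cancels from the likelihood but not from pooled ranking — and
is reported as a descriptive validation statistic, not an inferential one.
An uninformative predictor scores 0.5 within sampling noise; the test suite
checks 0.5 ± 0.02 on 1,000 strata.

## 7. The synthetic data generator

Because suitable brood telemetry is not redistributable, the package ships
a generator that defines the study conditions everything is tested under:

* **Landscape** (`generate_landscape()`): seven landcover classes produced
  by smoothing independent noise fields and taking the per-cell argmax
  (contiguous patches, every class present or an explicit error), NDVI in
  [−1, 1] correlated with the forest classes, and 2 road polylines, all on
  a shared 30-m grid.
* **Trajectories** (`simulate_brood()`): 28 days of hourly fixes 0500–2000
  plus the 23:58:58 roost fix; a 3-state chain with self-transition 0.9
  emitting gamma steps and von Mises turns at the canonical values of
  §2; attraction to focal patches — with probability `p_return` (default
  0.3) a non-travelling animal steers toward the nearest previously used
  patch — which is what produces recursion; DOP with an 8% poor-quality
  component above 7; a 2% daily brood-loss (censoring) probability.
  Trajectories reflect at the landscape boundary, preserving the
  step-length distribution, rather than being clipped.

The patch-attraction mechanism is a deliberate, *labelled* stand-in: real
broods revisit profitable areas for reasons no emission model specifies, and
no claim is made that this mechanism matches the true one. What the
generator guarantees — and what passing tests therefore show — is known
ground truth: emission parameters, transition frequencies, true states, and
a recursion dose that rises with `p_return`. Tests confirm the pipeline
recovers these (parameter recovery within 5% on 20,000 steps, decoding
accuracy, revisitation increasing in `p_return`). What passing tests do
*not* show is robustness to the features real telemetry adds: irregular
fix success, spatially autocorrelated GPS error, habitat-driven movement,
and behavioral rhythms beyond the fitted emissions.

## 8. Problem sizes and reproducibility

The demo configuration (`pipeline_config()`: 3 broods × 28 days on a
60 × 60-cell landscape, 100 available points per stratum) runs the full
simulate → preprocess → HMM → recursion → rasters → strata → selection
workflow in well under ten minutes on one CPU, and the test suite exercises
parameter recovery at 20,000 steps and coefficient recovery at 2,000
strata. These sizes were chosen as the smallest at which the stochastic
checks are comfortably stable. Every stage derives its randomness from the
pipeline seed, and `run_pipeline()` writes a manifest of output files with
MD5 hashes: the same config and seed reproduce the hashes bit for bit,
which the test suite asserts.

Known limitations, beyond those noted above: no covariates on transition
probabilities; no interpolation of missing fixes; no geographic
(longitude/latitude) support — one planar metric projection is assumed
throughout; no joint mixed-effects selection model; and the recursion
rasters are an approximation to a full movement-based utilization
distribution estimator.
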