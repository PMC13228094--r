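---
title: "Individual-specific network metrics and Bayesian ordinal models for EMA: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual-specific network metrics and Bayesian ordinal models for EMA: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`emaconn` implements an analysis pipeline linking ecological momentary
assessment (EMA) ratings of motivation and pleasure — the negative-symptom
domain combining avolition and anhedonia, rated four times daily on a 1–5
ordinal scale — to individual-specific resting-state functional network
metrics. The pipeline has four analysis stages (time-series cleaning and
template-matching network mapping; network-level graph metrics; EMA
processing; Bayesian hierarchical cumulative-logit inference) plus a
synthetic-data stage that generates every input with known ground truth, so
each downstream stage can be validated against planted structure.

# The synthetic-data generator

## Surface and templates

Real analyses of this kind operate on a cortical surface mesh with tens of
thousands of vertices. The generator substitutes a rectangular lattice
(default 40×40 = 1600 vertices) with 4-neighbourhood adjacency and constant
vertex area (default 1 mm²). The lattice preserves everything the mapping
algorithm actually uses — contiguity, adjacency, and area thresholds — at
desk scale. Area-based rules (the 30 mm² small-patch threshold) scale with
`vertex_area`, so they keep their units.

Templates are grown by simultaneous seeded region growing: `K` random seed
vertices (default `K = 8`, labelled after the eight a-priori resting-state
networks: default mode, cingulo-opercular, dorsal attention, ventral
attention, salience, fronto-parietal, dorsal and ventral somato-motor) claim
unclaimed neighbours in round-robin passes until the lattice is partitioned
into `K` contiguous patches. Individual topography is emulated by
`perturb_individual()`, which relabels a configurable fraction (default 10%)
of boundary vertices to a neighbouring patch's label — individual network
layouts are perturbations of a shared group layout, which is exactly the
situation template matching is designed for.

## BOLD-like time series

Vertex `v` in network `s` follows a factor model

\[ x_v(t) = \sqrt{\rho_w}\, L_s(t) + \sqrt{\rho_b}\, G(t) +
   \sqrt{1 - \rho_w - \rho_b}\,\varepsilon_v(t) \]

with independent standard-normal latents, so the expected vertex-pair
correlation is \(\rho_w + \rho_b\) within a network and \(\rho_b\) between
networks. There is no hemodynamic convolution and, by default, no temporal
autocorrelation (an optional AR(1) recoloring flag exists); the mapping
algorithm depends only on the spatial correlation structure, which is what
the generator plants and the tests verify. The default run structure mirrors
a two-run resting-state protocol: 2 × 460 frames at TR = 0.8 s. Frame
censoring is independent Bernoulli per frame (default probability 0.1),
emulating motion scrubbing; mean framewise displacement is drawn from a
lognormal (median 0.15 mm) and acts purely as a participant-level covariate,
not as a mechanistic driver of censoring — the analysis only ever uses it as
a regressor.

Cohort defaults follow the transdiagnostic composition of the study design
the pipeline targets: 40 controls (CON), 38 bipolar (BD), 37 major
depressive (MDD) and 29 schizophrenia/schizoaffective (SZ) participants,
with group-specific age distributions (means 35.2/36.4/32.7/34.4 years, SDs
≈ 8) and female/non-binary rates (0.52/0.66/0.62/0.41). Gender is simulated
as a single binary code matching that grouping.

## Ordinal EMA responses

Responses follow a nested cumulative-logit model

\[ P(Y \le k) = \mathrm{logit}^{-1}(\tau_k - \eta), \qquad
   \eta = x^\top\beta + u_{\text{participant}} + u_{\text{day(participant)}} \]

with strictly increasing thresholds \(\tau_1 < \dots < \tau_4\) (default
\((-1.4, -0.4, 0.4, 1.4)\)), participant and day-within-participant random
intercepts (default SDs 0.5 and 0.3), and fixed effects on the per-SD
(standardized-predictor) log-odds scale. Default nonzero effects are a
positive SZ group effect (0.78 ≈ log 2.2, the magnitude of the elevated-MAP
group contrast such designs report), a small positive age effect (0.15) and
a positive question-type effect (0.3; pleasure questions are rated higher
than motivation questions). Metric and diagnosis×metric effects default to
zero and are switched on per simulation study. The protocol shape is 4
prompts/day × 14 days × 2 constructs (anticipatory, consummatory) × 2
questions (motivation, pleasure); both constructs share one linear predictor
and one set of random intercepts, since downstream models are fit per
construct anyway.

Missingness is independent Bernoulli per prompt (a skipped prompt drops all
four of its question rows), i.e. missing completely at random with default
rate 0.25. Real EMA missingness is unlikely to be MCAR; nothing is known
about its true mechanism in this design, so MCAR is an explicit modelling
assumption of the generator, and conclusions from passing tests extend to
real data only insofar as missingness is ignorable.

# Network mapping

Cleaning applies, in order: frame censoring, demeaning and linear
detrending, nuisance regression, and a 0.01–0.1 Hz band-pass. The order
matters and is fixed; all regression fits use retained frames only, and
retained frames are treated as contiguous for filtering. The band-pass is a
frequency-domain (FFT) filter with hard cut-offs — on synthetic white-noise
data there is no hemodynamic roll-off to preserve, and the hard window makes
the spectral test (a 0.2 Hz probe sinusoid must lose > 90% of its power)
exact. Nuisance columns collinear with the intercept/trend are dropped with
a warning rather than silently destabilizing the fit. Participants with
fewer than 375 retained frames (5 min at TR = 0.8 s) are excluded.

Template matching then proceeds per participant: dense vertex-by-vertex
Pearson correlation; per-vertex binarization of the strongest 5% of
connections; Dice comparison of that map against every template; assignment
to the argmax network; removal of contiguous same-label patches smaller than
30 mm²; parcellation into connected components by network identity and
proximity. Numerical decisions the published procedure leaves open are fixed
as follows, each chosen for determinism:

* the top-fraction count is `floor(fraction × (n − 1))` with the
  self-connection excluded (floor is conservative and deterministic);
* ties — at the binarization cut and at the Dice argmax — are broken by
  ascending index and counted in the assignment object;
* the Dice coefficient of two empty maps is defined as 0, so a vertex with
  no template overlap stays unassigned rather than being assigned on no
  evidence;
* no sign filter is applied to correlations: negative values can enter the
  top 5% only when fewer than 5% of a row's entries are positive;
* the 30 mm² rule uses a strict inequality (a patch of exactly 30 mm² is
  retained), and removed vertices become unassigned rather than being handed
  to the runner-up network;
* contiguity means lattice 4-neighbourhood (or whatever adjacency the
  surface object declares).

# Graph metrics

Parcel time series are unweighted member means. Parcel-pair Pearson
correlations are Fisher-Z transformed after clipping to ±(1 − 10⁻⁷) so the
transform stays finite. Within-network connectivity is the mean Z over
unordered parcel pairs sharing a label (undefined when a network has fewer
than two parcels — encoded as missing, never imputed); between-network
connectivity is the mean Z over spanning pairs. All 28 unordered pairs of
the eight networks are computed and written; model configurations select
subsets. (Published work sometimes reports 13 between-network metrics for
eight networks without stating the selection rule; this package does not
guess it, it exposes all 28 and lets the model spec choose.)

Participation coefficients are computed on binary graphs thresholded at tie
densities 1%–25% in 1% steps: at density `d` the top `floor(d × P)` of the
`P` off-diagonal pairs by signed Z are kept (ties by ascending pair index;
no absolute value — the ranking convention is configurable), and each
parcel's PC is \(1 - \sum_s (k_{is}/k_i)^2\). Isolated parcels contribute
PC 0 at that density, keeping the per-parcel average defined. "Averaged
across the first 10% of tie densities" is interpreted as the ten densities
1%–10% — the alternative reading (the first tenth of a 25-element list)
would be 2.5 graphs and is incoherent. Parcel averages are then averaged
within networks. Spatial extent is the exact vertex count per network label.

# EMA processing

Participants are retained when they answered at least 33% of issued prompts
— an inclusive threshold, with 33% read literally as the fraction 0.33
rather than 1/3, and applied to issued prompts (whether the original rule
counted issued or delivered prompts is unstated; issued is the reproducible
choice). Observations are split by construct and question type is coded
0 = motivation, 1 = pleasure. Within-prompt partial responses are retained
as single rows.

Model tables standardize every numeric predictor (age, mean FD, metrics)
using one value per participant — participants with more responses must not
dominate the scale — and broadcast the standardized value to their
observations. Diagnosis is dummy-coded with CON as reference; interaction
columns are the product of a dummy and a standardized metric, so they vanish
identically for the reference group.

# Ordinal inference

## Model and priors

The inference model mirrors the generator: cumulative logit link, ordered
thresholds, fixed effects, and random intercepts for participants and for
days nested in participants (random intercepts only; no random slopes).
Priors are weakly informative on the standardized scale and configurable:
Normal(0, 2.5) on coefficients, independent Normal(0, 2) on each threshold
subject to the ordering constraint, half-Normal(0, 1) on both
random-intercept SDs. No priors are prescribed by the designs this package
follows; these are the package's own defaults. All five outcome categories
are always modelled, even when a subgroup never uses one.

## Sampler

The posterior is sampled by a purpose-built blocked MCMC (implemented in
C++), designed around the structure of EMA designs: almost all covariates
are constant within participants, and only question type varies within a
day. Observations sharing a (participant, day, question) pattern are
aggregated into multinomial counts, which leaves the posterior unchanged and
shrinks the likelihood loop by the prompt count. The parameterization is
centered — the participant-level linear predictor is absorbed into the
participant intercept's prior mean — and the sweep combines:

* single-site adaptive Metropolis for day intercepts;
* exact conjugate draws for participant intercepts and for participant-level
  coefficients, the latter from the marginal with the intercepts integrated
  out analytically (the per-participant mean day intercept is normal in the
  coefficients with variance \(\sigma_p^2 + \sigma_d^2/D_i\));
* Metropolis on the log scale for \((\sigma_p, \sigma_d)\) against the
  compound-symmetric marginal likelihood of the day intercepts, followed by
  interweaved non-centered updates of both SDs (the classic
  centered/non-centered alternation that removes the variance–intercept
  coupling);
* per-coordinate and adaptive full-covariance Metropolis for the thresholds
  and observation-level coefficients (thresholds are strongly mutually
  correlated, so a spherical proposal mixes poorly);
* non-centered coordinate moves for the binary group-structure coefficients,
  which shift a whole group's intercept ensemble against the likelihood in
  one step;
* two likelihood-invariant location-shift moves (one carrying the diagnosis
  dummies along), which walk the threshold/intercept location ridge.

All proposal scales adapt only during warmup and are frozen afterwards, so
the post-warmup chain is a fixed-kernel Markov chain. Defaults are 4 chains
× 1000 post-warmup draws after 1000 warmup sweeps. Convergence is a
contract: potential scale reduction < 1.01 and effective sample size > 400
for every reported fixed effect, checked after every fit; by default a
violation is an error. Replicate simulation studies (20 fits per study in
the package's own checks) run at reduced sizes — 2 chains × 500 draws after
300 warmup — with the contract check relaxed to recorded-only, since only
posterior medians and interval endpoints are consumed there and their Monte
Carlo error at that size is far below the tolerances being tested. The
sampler was validated against an independent MCMC implementation of the
identical model (JAGS) on a small instance; posterior means agree within
Monte Carlo error, and that comparison is part of the test suite.

## Decision rules

Each reported term is summarized as an odds ratio `exp(median β)` with an
equal-tailed 95% credible interval, the probability of direction (PD), and
the percent of draws inside the region of practical equivalence (ROPE),
taken as the closed interval \([-0.10, 0.10]\) on the standardized log-odds
scale. PD is implemented literally as the percentage of draws strictly
greater than zero; because the common convention is `max(p, 1 − p)`, both
are reported (`pd` and `pd_max`), clearly labelled. A term is flagged
significant exactly when the odds-ratio interval excludes 1 (equivalently,
the log-odds interval excludes 0 — the equivalence is asserted in tests).
Simple slopes for diagnosis×metric interactions are computed per draw — the
reference group's conditional effect equals the main effect; each clinical
group adds its interaction draws — and summarized like any effect. Secondary
between-network models fit all requested between-network predictors plus
covariates within one diagnostic subgroup, and additionally flag "notable"
predictors whose directional probability exceeds 90 even when their interval
includes 1; near-collinear predictor blocks trigger a condition-number
warning.

# What the tests do and do not show

The test suite validates every stage against planted truth or an
independent oracle: exhaustive re-computation of template matching and
participation coefficients (agreement to 10⁻¹²), flood-fill component
enumeration, closed-form ordinal category probabilities, a spectral oracle
for the band-pass, the JAGS cross-check for the sampler, parameter recovery
(a planted 0.5 per-SD effect is recovered with nominal interval coverage
across 20 replicates), and null calibration (the significance flag fires at
the nominal rate under a zero effect). Problem sizes used in the checks —
a 40×40 lattice with 920 frames for recovery, a 10×10 lattice at 2000
frames for correlation calibration, 120 (recovery) and 60 (null)
participants for the ordinal studies — were chosen as the smallest sizes at
which the planted signal dominates sampling noise by a comfortable margin.

One calibration detail deserves emphasis: the connectivity calibration test
compares network-level Fisher-Z estimates against `atanh(0.5)` using one
parcel per vertex. Averaging time series over multi-vertex parcels
suppresses idiosyncratic vertex noise and drives parcel-pair correlations
toward 1 under the factor model — a real property of parcel averaging, not
an artifact — so the planted vertex-level correlation is only recoverable at
vertex resolution.

Passing these tests shows the machinery is correct on data from the stated
generative models. It does not show that real BOLD data satisfy those models
(no hemodynamics, no spatial noise correlation, no motion artifact
structure), nor that real EMA missingness is MCAR, nor anything about the
substantive neuroscience; with real data the pipeline's conclusions inherit
those assumptions in the usual way.

# Known limitations

* The surface is a lattice; mesh adjacency is supported by the data
  structures but no neuroimaging file-format adapter (e.g. CIFTI) is
  included, keeping the core free of neuroimaging I/O dependencies.
* The EMA generator shares one latent process across constructs; construct-
  specific effect profiles require two generator calls.
* The sampler's convergence contract covers reported fixed effects; the
  random-effect SDs mix more slowly (they are monitored and recorded, but
  not gated), which is immaterial for the effect summaries the pipeline
  reports.
* Command-line orchestration is provided through `run_all()` and
  `pipeline_config()` from R; the package's functions, scripts and this
  vignette are the interface, and a shell-level wrapper would add nothing
  beyond `Rscript -e`.
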