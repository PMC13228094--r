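# emaconn

Tools for linking **ecological momentary assessment (EMA)** ratings of
motivation and pleasure (MAP) to **individual-specific resting-state
functional network metrics**, for researchers studying negative symptoms
across psychotic and mood disorders.

Traditional group-atlas connectivity analyses blur individual differences in
where functional networks live on the cortex, and single-visit symptom scales
miss day-to-day fluctuation. This package implements the combined
alternative end to end:

1. **Template-matching network mapping.** From vertex×frame BOLD time series
   (cleaned by censoring → demean/detrend → nuisance regression → 0.01–0.1 Hz
   band-pass), compute dense vertex-to-vertex Pearson connectivity, binarize
   each vertex's top 5% of connections, match the resulting map to each of
   eight a-priori network templates by Dice coefficient
   ( \( D = 2|A\cap B| / (|A|+|B|) \) ), assign the argmax network, drop
   contiguous patches under 30 mm², and parcellate by network identity and
   contiguity.
2. **Network metrics per participant.** Fisher-Z within/between-network
   connectivity over parcel pairs, participation coefficients
   \( \mathrm{PC}_i = 1 - \sum_s (k_{is}/k_i)^2 \) on binary graphs
   thresholded across 1–25% tie densities (averaged over the first ten),
   and spatial extent (vertices per network).
3. **EMA processing.** Compliance filtering (≥ 33% of issued prompts),
   construct/question coding, and assembly of standardized model tables.
4. **Bayesian hierarchical cumulative-logit regression.**
   \( P(Y \le k) = \mathrm{logit}^{-1}(\tau_k - \eta) \),
   \( \eta = x^\top\beta + u_{\text{participant}} + u_{\text{day}} \),
   fit by a purpose-built blocked MCMC (C++), summarized as odds ratios with
   95% credible intervals, probability of direction (PD), and percent in the
   ROPE \([-0.10, 0.10]\); simple-slopes contrasts for diagnosis×metric
   interactions and secondary between-network models included.

A first-class **synthetic-data module** generates surface geometry,
contiguous network templates, individually perturbed assignments,
block-correlated BOLD-like series with motion censoring, covariates, and
ordinal EMA responses from a known generative model, so every stage is
testable against planted ground truth. See the methods vignette
(`vignettes/emaconn-methods.Rmd`) for models, priors, sampler design and
numerical conventions.

## Worked example

```r
library(emaconn)

cfg <- pipeline_config(
  master_seed = 7,
  n_per_group = c(CON = 2, BD = 2, MDD = 2, SZ = 2),
  rows = 12, cols = 12, K = 4,
  bold_cfg = bold_sim_config(frames_per_run = 230, n_runs = 2,
                             within_corr = 0.5, between_corr = 0.05,
                             censor_prob = 0.05),
  min_area = 4,
  fits = list(list(construct = "anticipatory", kind = "diagnostic",
                   network = NULL)),
  sampler = cl_model_spec(chains = 2, iter = 200, warmup = 200,
                          on_diagnostic_failure = "none"))
res <- run_all(cfg)
report(res)
```

```
construct      kind         network  term                     e^beta  95% CI                PD   %ROPE
anticipatory   diagnostic   -        dx_bd                      1.25  [ 0.40,  5.12]    63.0%   14.0%
anticipatory   diagnostic   -        dx_mdd                     1.00  [ 0.29,  3.85]    49.8%   15.5%
anticipatory   diagnostic   -        dx_sz                      0.87  [ 0.28,  3.69]    43.0%   10.5%
anticipatory   diagnostic   -        age_z                      1.12  [ 0.73,  1.78]    73.2%   30.8%
anticipatory   diagnostic   -        gender                     1.17  [ 0.33,  7.50]    59.8%   14.0%
anticipatory   diagnostic   -        question                   1.45  [ 1.10,  1.97]*   99.5%    3.0%
```

Each row is one fixed effect of the diagnostic-group model on this toy
cohort: the odds ratio `e^beta` (posterior median, per SD for numeric
predictors), its 95% credible interval, the probability of direction, and
the percent of posterior draws in the ROPE. The `*` marks the
significance rule — the credible interval excludes an odds ratio of 1. Here
only the question-type effect is flagged (the generator plants a +0.3
log-odds pleasure-vs-motivation effect; the tiny 8-participant cohort has no
power for the group contrasts, as the wide intervals show).

At study scale, `simulate_cohort()` defaults generate 144 participants
(40 CON, 38 BD, 37 MDD, 29 SZ) on a 40×40 surface with two 460-frame runs,
and `run_all()` carries them through mapping, metrics, EMA filtering and any
configured set of connectivity/extent model fits.

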