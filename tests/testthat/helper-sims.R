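# Shared simulation helpers for the ordinal-inference tests: generate a
# single-group cohort with one standardized participant-level metric driving
# the latent scale, and fit the matching cumulative-logit model.

make_metric_cohort <- function(n, data_seed) {
  set.seed(data_seed * 13 + 1)
  cov <- data.frame(participant_id = sprintf("P%03d", seq_len(n)),
                    diagnosis = "CON",
                    age = rnorm(n, 35, 8), gender = rbinom(n, 1, 0.5),
                    mean_fd = rlnorm(n, log(0.15), 0.4),
                    stringsAsFactors = FALSE)
  set.seed(data_seed * 13 + 2)
  met <- data.frame(participant_id = cov$participant_id, metric = rnorm(n),
                    stringsAsFactors = FALSE)
  list(cov = cov, met = met)
}

sim_metric_table <- function(n, beta_metric, data_seed, construct = "anticipatory") {
  ch <- make_metric_cohort(n, data_seed)
  cfg <- ema_sim_config(beta = c(age_z = 0.15, gender = 0, question = 0.3),
                        metric_effects = c(metric = beta_metric),
                        sigma_p = 0.5, sigma_d = 0.3, miss_prob = 0)
  ema <- simulate_ema(ch$cov, ch$met, cfg, seed = data_seed)
  enc <- encode_observations(ema)[[construct]]
  tab <- merge(enc, ch$cov[, c("participant_id", "age", "gender")],
               by = "participant_id")
  first <- match(unique(tab$participant_id), tab$participant_id)
  zp <- function(v) (v - mean(v[first])) / sd(v[first])
  tab$age_z <- zp(tab$age)
  m <- ch$met$metric[match(tab$participant_id, ch$met$participant_id)]
  tab$metric_z <- (m - mean(ch$met$metric)) / sd(ch$met$metric)
  tab
}

replicate_spec <- function(fit_seed, iter = 500, warmup = 300) {
  cl_model_spec(participant_terms = c("age_z", "gender", "metric_z"),
                observation_terms = "question",
                chains = 2, iter = iter, warmup = warmup, seed = fit_seed,
                on_diagnostic_failure = "none")
}

fit_metric_replicate <- function(n, beta_metric, data_seed, fit_seed, ...) {
  tab <- sim_metric_table(n, beta_metric, data_seed)
  fit <- fit_cumulative_logit(tab, replicate_spec(fit_seed, ...))
  summarize_effect(fit, "metric_z")
}
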