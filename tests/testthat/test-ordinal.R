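# build a minimal cl_fit around given draw matrices (one chain)
fake_fit <- function(draws_mat) {
  structure(list(draws = coda::mcmc.list(coda::mcmc(draws_mat)),
                 terms = colnames(draws_mat),
                 participant_terms = colnames(draws_mat),
                 observation_terms = character(0),
                 diagnostics = NULL, spec = NULL,
                 data_info = list()), class = "cl_fit")
}

test_that("probability of direction and ROPE follow their definitions", {
  expect_equal(prob_direction(c(0.2, 1, 3)), 100)
  expect_equal(prob_direction(c(-1, 1)), 50)
  expect_equal(prob_direction(c(-1, 0, 1)), 100 / 3)  # zero is not > 0

  expect_equal(rope_fraction(rep(0, 10)), 100)
  expect_equal(rope_fraction(c(-0.5, 0.5)), 0)
  expect_equal(rope_fraction(c(-0.10, 0.10)), 100)    # closed bounds
  expect_equal(rope_fraction(c(-0.100001, 0.100001)), 0)

  set.seed(1)
  d <- rnorm(1000)
  expect_equal(prob_direction(d) + 100 * mean(d <= 0), 100)
})

test_that("PD and ROPE match the normal CDF on a large sample", {
  set.seed(12)
  d <- rnorm(1e6, 0.3, 1)
  expect_lt(abs(prob_direction(d) - 100 * pnorm(0.3)), 0.3)
  want_rope <- 100 * (pnorm(-0.2) - pnorm(-0.4))
  expect_lt(abs(rope_fraction(d) - want_rope), 0.3)
})

test_that("effect summaries transform and flag correctly", {
  const <- matrix(0.7885, nrow = 50, ncol = 1, dimnames = list(NULL, "x"))
  s <- summarize_effect(fake_fit(const), "x")
  expect_equal(s$or, 2.2, tolerance = 1e-3)
  expect_equal(s$or_low, s$or_high)
  expect_equal(s$pd, 100)
  expect_equal(s$rope, 0)
  expect_true(s$significant)

  sym <- summarize_effect(c(-2, -1, 1, 2), "sym")
  expect_equal(sym$pd, 50)
  expect_equal(sym$pd_max, 50)

  # significance <=> CI of beta excludes 0 <=> CI of e^beta excludes 1
  set.seed(2)
  for (mu in c(-0.5, 0, 0.5)) {
    d <- rnorm(4000, mu, 0.2)
    s <- summarize_effect(d, "t")
    ci_beta <- stats::quantile(d, c(0.025, 0.975))
    expect_equal(s$significant, unname(ci_beta[1] > 0 || ci_beta[2] < 0))
    expect_equal(s$significant, s$or_low > 1 || s$or_high < 1)
    expect_true(s$or_low <= s$or && s$or <= s$or_high)
  }
  expect_error(summarize_effect(fake_fit(const), "nope"), "unknown term")
})

test_that("simple slopes combine main and interaction draws", {
  n <- 100
  draws <- cbind(pc_z = rep(0.2, n), pc_z_x_dx_bd = rep(-0.1, n),
                 pc_z_x_dx_mdd = rep(0, n), pc_z_x_dx_sz = rep(0.3, n))
  fit <- fake_fit(draws)
  sl <- simple_slopes(fit, "pc_z")
  expect_equal(sl$group, c("CON", "BD", "MDD", "SZ"))
  # reference group equals the main effect summary
  main <- summarize_effect(fit, "pc_z")
  expect_equal(sl$or[sl$group == "CON"], main$or)
  # constant draws: conditional effect is exp(0.2 + 0.3)
  expect_equal(sl$or[sl$group == "SZ"], exp(0.5), tolerance = 1e-12)
  expect_equal(sl$or[sl$group == "SZ"], 1.6487, tolerance = 1e-4)
  expect_error(simple_slopes(fit, "pc_z", groups = c(X = "dx_x")),
               "missing interaction")
})

test_that("the fit rejects degenerate inputs", {
  tab <- data.frame(response = rep(3L, 20), participant_id = rep("P1", 20),
                    day = rep(1:5, 4), question = rep(0:1, 10), x = 1)
  spec <- cl_model_spec(participant_terms = "x", observation_terms = "question")
  expect_error(fit_cumulative_logit(tab, spec), "constant")
  tab$response <- rep(c(1L, 5L), 10)
  spec2 <- cl_model_spec(participant_terms = "missing_term")
  expect_error(fit_cumulative_logit(tab, spec2), "not in table")
  expect_error(fit_cumulative_logit(tab[0, ], spec), "empty")
  # participant-level terms must be constant within participant
  tab$x <- seq_len(20)
  expect_error(fit_cumulative_logit(tab, spec), "varies within")
})

test_that("seeded fits are exactly reproducible", {
  tab <- sim_metric_table(20, 0.5, data_seed = 1)
  spec <- replicate_spec(77, iter = 150, warmup = 100)
  f1 <- fit_cumulative_logit(tab, spec)
  f2 <- fit_cumulative_logit(tab, spec)
  expect_identical(as.matrix(f1$draws[[1]]), as.matrix(f2$draws[[1]]))
  expect_identical(summarize_effects(f1), summarize_effects(f2))
  f3 <- fit_cumulative_logit(tab, replicate_spec(78, iter = 150, warmup = 100))
  expect_false(identical(as.matrix(f1$draws[[1]]), as.matrix(f3$draws[[1]])))
})

test_that("posterior agrees with an independent MCMC oracle on a small instance", {
  skip_if_not_installed("rjags")
  set.seed(42)
  n <- 30
  cov <- data.frame(participant_id = sprintf("P%02d", 1:n), diagnosis = "CON",
                    age = rnorm(n, 35, 8), gender = rbinom(n, 1, 0.5),
                    mean_fd = rlnorm(n, log(0.15), 0.4))
  cfg <- ema_sim_config(beta = c(age_z = 0.4, gender = -0.3, question = 0.5),
                        sigma_p = 0.5, sigma_d = 0.3, miss_prob = 0,
                        n_days = 6, prompts_per_day = 3)
  ema <- simulate_ema(cov, cfg = cfg, seed = 3)
  tab <- build_model_table(encode_observations(ema)$anticipatory, cov,
                           kind = "diagnostic")
  spec <- cl_model_spec(participant_terms = c("age_z", "gender"),
                        observation_terms = "question",
                        chains = 2, iter = 3000, warmup = 1000, seed = 5,
                        on_diagnostic_failure = "none")
  fit <- fit_cumulative_logit(tab, spec)
  mine <- colMeans(do.call(rbind, lapply(fit$draws, as.matrix)))

  # same model, independent sampler (JAGS), matching priors
  pid <- as.integer(factor(tab$participant_id))
  did <- as.integer(factor(paste(pid, tab$day)))
  data <- list(yy = tab$response, q = tab$question, age = tab$age_z,
               gen = tab$gender, pid = pid, did = did,
               N = nrow(tab), NP = max(pid), ND = max(did))
  m_str <- "model{
    for (i in 1:N) {
      eta[i] <- bage*age[i] + bgen*gen[i] + bq*q[i] + up[pid[i]] + ud[did[i]]
      for (k in 1:4) { Q[i,k] <- ilogit(tau[k] - eta[i]) }
      p[i,1] <- Q[i,1]
      for (k in 2:4) { p[i,k] <- Q[i,k] - Q[i,k-1] }
      p[i,5] <- 1 - Q[i,4]
      yy[i] ~ dcat(p[i,1:5])
    }
    bage ~ dnorm(0, 0.16); bgen ~ dnorm(0, 0.16); bq ~ dnorm(0, 0.16)
    tau0[1] ~ dnorm(0, 0.25)
    for (k in 2:4) { g[k] ~ dnorm(0, 0.25) T(0,); tau0[k] <- tau0[k-1] + g[k] }
    tau[1:4] <- tau0[1:4]
    sp ~ dnorm(0, 1) T(0,); sdd ~ dnorm(0, 1) T(0,)
    for (j in 1:NP) { up[j] ~ dnorm(0, 1/(sp*sp + 1e-9)) }
    for (j in 1:ND) { ud[j] ~ dnorm(0, 1/(sdd*sdd + 1e-9)) }
  }"
  jm <- rjags::jags.model(textConnection(m_str), data = data, n.chains = 1,
                          n.adapt = 500,
                          inits = list(.RNG.name = "base::Mersenne-Twister",
                                       .RNG.seed = 1),
                          quiet = TRUE)
  update(jm, 1000)
  js <- rjags::coda.samples(jm, c("bage", "bgen", "bq", "tau", "sp", "sdd"),
                            n.iter = 3000)
  jmean <- colMeans(as.matrix(js[[1]]))
  expect_lt(abs(mine["age_z"] - jmean["bage"]), 0.08)
  expect_lt(abs(mine["gender"] - jmean["bgen"]), 0.08)
  expect_lt(abs(mine["question"] - jmean["bq"]), 0.08)
  for (k in 1:4) {
    expect_lt(abs(mine[paste0("tau", k)] - jmean[paste0("tau[", k, "]")]), 0.1)
  }
  expect_lt(abs(mine["sigma_participant"] - jmean["sp"]), 0.1)
  expect_lt(abs(mine["sigma_day"] - jmean["sdd"]), 0.1)
})

test_that("a planted group-specific slope is recovered by simple slopes", {
  set.seed(31)
  n <- 400
  cov <- data.frame(participant_id = sprintf("P%03d", 1:n),
                    diagnosis = rep(c("CON", "BD", "MDD", "SZ"), each = 100),
                    age = rnorm(n, 35, 8), gender = rbinom(n, 1, 0.5),
                    mean_fd = rlnorm(n, log(0.15), 0.4))
  met <- data.frame(participant_id = cov$participant_id, mean_fd = cov$mean_fd,
                    within_DAN = rnorm(n), pc_DAN = rnorm(n))
  cfg <- ema_sim_config(metric_effects = c(pc_DAN = 0),
                        interaction_effects = c(pc_DAN_x_dx_sz = 0.5),
                        sigma_p = 0.5, sigma_d = 0.3, miss_prob = 0)
  ema <- simulate_ema(cov, met, cfg, seed = 17)
  tab <- build_model_table(encode_observations(ema)$anticipatory, cov, met,
                           kind = "connectivity", network = "DAN")
  fit <- fit_cumulative_logit(tab, cl_model_spec(chains = 2, iter = 400,
                                                 warmup = 300, seed = 21,
                                                 on_diagnostic_failure = "none"))
  sl <- simple_slopes(fit, "pc_z")
  sz <- sl[sl$group == "SZ", ]
  expect_true(log(sz$or_low) > 0)                 # SZ CI excludes 0
  expect_equal(sl$group[which.max(sl$beta_median)], "SZ")
  others <- sl[sl$group != "SZ", ]
  expect_true(all(abs(others$beta_median) < 0.35))
})

test_that("secondary between-network models surface the driving predictor", {
  set.seed(55)
  n <- 60
  cov <- data.frame(participant_id = sprintf("S%03d", 1:n), diagnosis = "SZ",
                    age = rnorm(n, 35, 8), gender = rbinom(n, 1, 0.5),
                    mean_fd = rlnorm(n, log(0.15), 0.4))
  bset <- c("between_VAN_DMN", "between_VAN_FPN", "between_VAN_SAL",
            "between_VAN_VSM", "between_VAN_DSM", "between_VAN_CON")
  met <- data.frame(participant_id = cov$participant_id, mean_fd = cov$mean_fd)
  for (b in bset) met[[b]] <- rnorm(n)
  cfg <- ema_sim_config(beta = c(question = 0.3),
                        metric_effects = c(between_VAN_FPN = 0.6),
                        sigma_p = 0.5, sigma_d = 0.3, miss_prob = 0)
  ema <- simulate_ema(cov, met, cfg, seed = 18)
  enc <- encode_observations(ema)$consummatory
  res <- secondary_between_model(enc, cov, met, group = "SZ",
                                 between_set = bset,
                                 spec = cl_model_spec(chains = 2, iter = 400,
                                                      warmup = 300, seed = 23,
                                                      on_diagnostic_failure = "none"))
  expect_equal(nrow(res$summary), length(bset))
  expect_equal(res$summary$term[which.max(res$summary$pd_max)],
               "between_VAN_FPN_z")
  expect_true(res$summary$notable[res$summary$term == "between_VAN_FPN_z"])
  # subgroup restriction really restricts
  expect_equal(res$fit$data_info$n_participants, n)
  # empty subgroup errors
  expect_error(build_model_table(enc, cov, met, kind = "secondary",
                                 between_set = bset, group = "BD"),
               "empty diagnostic subgroup")
  # collinear predictors trigger a condition-number warning
  met2 <- met
  met2$between_VAN_DMN <- met2$between_VAN_FPN + rnorm(n, 0, 1e-8)
  expect_warning(
    secondary_between_model(enc, cov, met2, group = "SZ", between_set = bset,
                            spec = cl_model_spec(chains = 1, iter = 50,
                                                 warmup = 50,
                                                 on_diagnostic_failure = "none")),
    "collinear")
})
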