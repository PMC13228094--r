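tiny_cov <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(participant_id = sprintf("P%02d", seq_len(n)),
             diagnosis = rep(c("CON", "BD", "MDD", "SZ"), length.out = n),
             age = rnorm(n, 35, 8), gender = rbinom(n, 1, 0.5),
             mean_fd = rlnorm(n, log(0.15), 0.4), stringsAsFactors = FALSE)
}

test_that("the EMA generator follows the protocol shape", {
  cov <- tiny_cov(3)
  cfg <- ema_sim_config(miss_prob = 0)
  ema <- simulate_ema(cov, cfg = cfg, seed = 2)
  # 4 prompts x 14 days x 2 questions = 112 rows per participant per construct
  counts <- table(ema$participant_id, ema$construct)
  expect_true(all(counts == 112L))
  expect_true(all(ema$response %in% 1:5))
  # determinism and seed sensitivity
  expect_identical(simulate_ema(cov, cfg = cfg, seed = 2)$response, ema$response)
  expect_false(identical(simulate_ema(cov, cfg = cfg, seed = 3)$response,
                         ema$response))
  # missingness removes whole prompts
  cfg_m <- ema_sim_config(miss_prob = 0.4)
  ema_m <- simulate_ema(cov, cfg = cfg_m, seed = 4)
  per_prompt <- table(paste(ema_m$participant_id, ema_m$day, ema_m$prompt))
  expect_true(all(per_prompt == 4L))          # 2 constructs x 2 questions
})

test_that("extreme thresholds force all mass into one category", {
  cov <- tiny_cov(2)
  cfg <- ema_sim_config(thresholds = c(20, 21, 22, 23),
                        beta = c(question = 0), sigma_p = 0, sigma_d = 0,
                        miss_prob = 0, n_days = 3)
  ema <- simulate_ema(cov, cfg = cfg, seed = 1)
  expect_true(all(ema$response == 1L))
  cfg2 <- ema_sim_config(thresholds = c(-23, -22, -21, -20),
                         beta = c(question = 0), sigma_p = 0, sigma_d = 0,
                         miss_prob = 0, n_days = 3)
  expect_true(all(simulate_ema(cov, cfg = cfg2, seed = 1)$response == 5L))
  expect_error(ema_sim_config(thresholds = c(0, -1, 1, 2)), "increasing")
})

test_that("ordinal category frequencies match the closed-form probabilities", {
  # uniform-fifths thresholds, no effects: each category has probability 0.2
  n <- 450                                   # ~1e5 draws over both constructs
  cov <- tiny_cov(n)
  cov$diagnosis <- "CON"
  cfg <- ema_sim_config(thresholds = stats::qlogis(c(0.2, 0.4, 0.6, 0.8)),
                        beta = c(question = 0), sigma_p = 0, sigma_d = 0,
                        miss_prob = 0)
  ema <- simulate_ema(cov, cfg = cfg, seed = 9)
  ndraw <- nrow(ema)
  expect_gte(ndraw, 1e5)
  freq <- as.numeric(table(factor(ema$response, levels = 1:5))) / ndraw
  mc_se <- sqrt(0.2 * 0.8 / ndraw)
  expect_true(all(abs(freq - 0.2) <= 3 * mc_se))
  # non-uniform case against the cumulative-logit closed form
  tau <- c(-1.386, -0.2, 0.9, 2.1)
  probs <- diff(c(0, stats::plogis(tau), 1))
  cfg2 <- ema_sim_config(thresholds = tau, beta = c(question = 0),
                         sigma_p = 0, sigma_d = 0, miss_prob = 0)
  ema2 <- simulate_ema(cov, cfg = cfg2, seed = 10)
  freq2 <- as.numeric(table(factor(ema2$response, levels = 1:5))) / nrow(ema2)
  se2 <- sqrt(probs * (1 - probs) / nrow(ema2))
  expect_true(all(abs(freq2 - probs) <= 3 * se2))
})

test_that("compliance filtering applies the inclusive 33% rule", {
  mk_records <- function(pid, n_prompts) {
    grid <- expand.grid(prompt = 1:4, day = 1:14)[seq_len(n_prompts), ]
    data.frame(participant_id = pid, day = grid$day, prompt = grid$prompt,
               construct = "anticipatory", question = "motivation",
               response = 3L, stringsAsFactors = FALSE)
  }
  records <- rbind(mk_records("A", 19), mk_records("B", 18))
  issued <- c(A = 56, B = 56, C = 56)        # C answered nothing
  res <- compliance_filter(records, issued)
  expect_identical(res$included, "A")        # 19/56 = 0.339 >= 0.33
  expect_setequal(res$excluded, c("B", "C")) # 18/56 = 0.321; 0/56
  expect_equal(unname(res$rate["A"]), 19 / 56)
  expect_error(compliance_filter(mk_records("ZZ", 5), issued), "unknown")
})

test_that("encoding splits constructs, codes questions and round-trips", {
  cov <- tiny_cov(4)
  ema <- simulate_ema(cov, cfg = ema_sim_config(miss_prob = 0.2), seed = 6)
  enc <- encode_observations(ema)
  expect_setequal(names(enc), c("anticipatory", "consummatory"))
  expect_true(all(enc$anticipatory$question %in% 0:1))
  # question text variants map onto the binary code
  txt <- data.frame(participant_id = "P01", day = 1, prompt = 1,
                    construct = c("consummatory", "consummatory"),
                    question = c("How interested are you in this activity?",
                                 "How much are you enjoying this activity?"),
                    response = c(2L, 4L), stringsAsFactors = FALSE)
  enc_txt <- encode_observations(txt)$consummatory
  expect_equal(enc_txt$question, c(0, 1))    # motivation = 0, pleasure = 1
  # round trip restores the observation table
  dec <- decode_observations(enc)
  ema_sorted <- ema[order(ema$participant_id, ema$day, ema$prompt,
                          ema$construct, ema$question), ]
  rownames(ema_sorted) <- NULL
  attr(ema_sorted, "truth") <- NULL
  expect_identical(dec, ema_sorted)
  # invalid responses are reported with their rows
  bad <- ema; bad$response[c(3, 9)] <- 7L
  expect_error(encode_observations(bad), "3, 9")
})

test_that("filtering and encoding commute", {
  cov <- tiny_cov(6)
  ema <- simulate_ema(cov, cfg = ema_sim_config(miss_prob = 0.5), seed = 8)
  issued <- stats::setNames(rep(56, 6), cov$participant_id)
  keep <- compliance_filter(ema, issued, threshold = 0.5)$included
  a <- encode_observations(ema[ema$participant_id %in% keep, ])
  enc_all <- encode_observations(ema)
  b <- lapply(enc_all, function(d) {
    d <- d[d$participant_id %in% keep, ]; rownames(d) <- NULL; d
  })
  expect_equal(a, b)
})

test_that("the model table standardizes at participant level and codes groups", {
  cov <- tiny_cov(12)
  ema <- simulate_ema(cov, cfg = ema_sim_config(miss_prob = 0), seed = 3)
  enc <- encode_observations(ema)$anticipatory
  met <- data.frame(participant_id = cov$participant_id, mean_fd = cov$mean_fd,
                    within_DAN = rnorm(12), pc_DAN = rnorm(12),
                    extent_SAL = rpois(12, 200))
  tab <- build_model_table(enc, cov, met, kind = "connectivity",
                           network = "DAN")
  first <- match(unique(tab$participant_id), tab$participant_id)
  # reference coding: controls carry all-zero dummies
  con_rows <- tab$participant_id %in% cov$participant_id[cov$diagnosis == "CON"]
  expect_true(all(tab[con_rows, c("dx_bd", "dx_mdd", "dx_sz")] == 0))
  # standardized participant-level predictors have mean 0, sd 1
  for (col in c("age_z", "fd_z", "within_z", "pc_z")) {
    expect_lt(abs(mean(tab[[col]][first])), 1e-8)
    expect_lt(abs(stats::sd(tab[[col]][first]) - 1), 1e-8)
  }
  # interaction columns vanish for the reference group
  expect_true(all(tab$within_z_x_dx_sz[con_rows] == 0))
  sz_rows <- tab$participant_id %in% cov$participant_id[cov$diagnosis == "SZ"]
  expect_equal(tab$within_z_x_dx_sz[sz_rows], tab$within_z[sz_rows])
  # standardizing an already standardized column is a no-op
  z <- tab$within_z[first]
  expect_lt(max(abs((z - mean(z)) / stats::sd(z) - z)), 1e-12)
  # extent model shape
  tab_e <- build_model_table(enc, cov, met, kind = "extent", network = "SAL")
  expect_true(all(c("extent_z", "extent_z_x_dx_bd") %in%
                    attr(tab_e, "participant_terms")))
  # participants without metrics are excluded with a log entry
  expect_message(
    tab_d <- build_model_table(enc, cov, met[-1, ], kind = "connectivity",
                               network = "DAN"),
    "excluding 1")
  expect_identical(attr(tab_d, "dropped"), cov$participant_id[1])
})
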