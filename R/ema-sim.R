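#' Configuration for the ordinal EMA generator
#'
#' Responses are drawn from a nested cumulative-logit model:
#' `P(Y <= k) = logistic(tau_k - eta)` with
#' `eta = x' beta + u_participant + u_day(participant)`, five ordered response
#' categories, participant and day-within-participant random intercepts, and
#' prompt-level missingness (a skipped prompt drops all of its questions,
#' missing completely at random).
#'
#' Numeric participant-level predictors (age, mean FD, network metrics) enter
#' the linear predictor standardized across participants, so every effect in
#' `beta`, `metric_effects` and `interaction_effects` is a per-SD log-odds.
#'
#' @param thresholds Strictly increasing latent thresholds `tau_1 < ... <
#'   tau_4`.
#' @param beta Named log-odds for covariate terms; recognized names are
#'   `dx_bd`, `dx_mdd`, `dx_sz` (diagnosis dummies vs the control reference),
#'   `age_z`, `gender`, `fd_z`, and `question` (0 = motivation, 1 = pleasure).
#' @param metric_effects Named log-odds per standardized metric column (names
#'   must match columns of the metrics table, e.g. `within_DAN`).
#' @param interaction_effects Named log-odds for diagnosis-by-metric
#'   interactions, names of the form `<metric>_x_<dx>` (e.g.
#'   `pc_VAN_x_dx_sz`).
#' @param sigma_p,sigma_d Random-intercept SDs (participant;
#'   day-in-participant), both `>= 0`.
#' @param prompts_per_day,n_days EMA protocol shape (defaults: 4 prompts a day
#'   for 14 days).
#' @param miss_prob Probability that a prompt goes unanswered.
#' @return A list of class `ema_sim_config`.
#' @export
ema_sim_config <- function(thresholds = c(-1.4, -0.4, 0.4, 1.4),
                           beta = c(dx_bd = 0, dx_mdd = 0, dx_sz = 0.78,
                                    age_z = 0.15, gender = 0, question = 0.3),
                           metric_effects = numeric(0),
                           interaction_effects = numeric(0),
                           sigma_p = 0.5, sigma_d = 0.3,
                           prompts_per_day = 4, n_days = 14,
                           miss_prob = 0.25) {
  if (any(diff(thresholds) <= 0)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  stopifnot(sigma_p >= 0, sigma_d >= 0, miss_prob >= 0, miss_prob < 1,
            prompts_per_day >= 1, n_days >= 1)
  structure(list(thresholds = thresholds, beta = beta,
                 metric_effects = metric_effects,
                 interaction_effects = interaction_effects,
                 sigma_p = sigma_p, sigma_d = sigma_d,
                 prompts_per_day = as.integer(prompts_per_day),
                 n_days = as.integer(n_days), miss_prob = miss_prob),
            class = "ema_sim_config")
}

# cumulative-logit category probabilities for one linear predictor
cl_category_probs <- function(eta, thresholds) {
  cum <- stats::plogis(outer(-eta, thresholds, "+"))  # P(Y <= k)
  cbind(cum, 1)[, c(1, seq_along(thresholds) + 1), drop = FALSE] -
    cbind(0, cum)
}

#' Simulate ordinal EMA responses
#'
#' Draws motivation-and-pleasure ratings (1-5) for every participant, day,
#' prompt, construct (anticipatory / consummatory) and question (motivation /
#' pleasure) from the generative model described in [ema_sim_config()]. The
#' same linear predictor and random intercepts apply to both constructs; the
#' two constructs are analyzed in separate models downstream.
#'
#' @param covariates Data frame with columns `participant_id`, `diagnosis`
#'   (`CON`, `BD`, `MDD`, `SZ`), `age`, `gender` (0/1), `mean_fd`.
#' @param metrics Optional data frame with `participant_id` and the metric
#'   columns named by `cfg$metric_effects` / `cfg$interaction_effects`.
#' @param cfg An [ema_sim_config()].
#' @param seed Integer seed.
#' @return Data frame of EMA observations (`participant_id`, `day`, `prompt`,
#'   `construct`, `question`, `response`), with attribute `truth` recording
#'   the per-participant linear predictor contributions.
#' @export
simulate_ema <- function(covariates, metrics = NULL, cfg = ema_sim_config(),
                         seed = 1) {
  stopifnot(inherits(cfg, "ema_sim_config"),
            all(c("participant_id", "diagnosis", "age", "gender", "mean_fd")
                %in% names(covariates)))
  covariates$diagnosis <- factor(covariates$diagnosis,
                                 levels = c("CON", "BD", "MDD", "SZ"))
  if (anyNA(covariates$diagnosis)) stop("unknown diagnosis label", call. = FALSE)
  n_p <- nrow(covariates)
  # participant-level design on the standardized scale
  xp <- data.frame(
    dx_bd = as.numeric(covariates$diagnosis == "BD"),
    dx_mdd = as.numeric(covariates$diagnosis == "MDD"),
    dx_sz = as.numeric(covariates$diagnosis == "SZ"),
    age_z = standardize(covariates$age),
    gender = as.numeric(covariates$gender),
    fd_z = standardize(covariates$mean_fd))
  metric_terms <- union(names(cfg$metric_effects),
                        sub("_x_dx_(bd|mdd|sz)$", "",
                            names(cfg$interaction_effects)))
  if (length(metric_terms)) {
    if (is.null(metrics)) stop("metric effects configured but no metrics given",
                               call. = FALSE)
    m <- metrics[match(covariates$participant_id, metrics$participant_id), ,
                 drop = FALSE]
    for (term in metric_terms) {
      if (!term %in% names(m)) stop(sprintf("metric column '%s' missing", term),
                                    call. = FALSE)
      xp[[term]] <- standardize(m[[term]])
    }
  }
  eta_p <- numeric(n_p)
  for (term in names(cfg$beta)) {
    if (term == "question") next
    if (term %in% names(xp)) eta_p <- eta_p + cfg$beta[[term]] * xp[[term]]
  }
  for (term in names(cfg$metric_effects)) {
    eta_p <- eta_p + cfg$metric_effects[[term]] * xp[[term]]
  }
  for (term in names(cfg$interaction_effects)) {
    parts <- strsplit(term, "_x_", fixed = TRUE)[[1]]
    eta_p <- eta_p + cfg$interaction_effects[[term]] * xp[[parts[1]]] * xp[[parts[2]]]
  }
  beta_q <- if ("question" %in% names(cfg$beta)) cfg$beta[["question"]] else 0
  local_rng(seed, {
    u_p <- stats::rnorm(n_p, 0, cfg$sigma_p)
    grid <- expand.grid(prompt = seq_len(cfg$prompts_per_day),
                        day = seq_len(cfg$n_days),
                        p = seq_len(n_p))
    u_d_key <- paste(grid$p, grid$day)
    days <- unique(u_d_key)
    u_d <- stats::setNames(stats::rnorm(length(days), 0, cfg$sigma_d), days)
    answered <- stats::runif(nrow(grid)) >= cfg$miss_prob
    grid <- grid[answered, , drop = FALSE]
    u_d_key <- u_d_key[answered]
    rows <- vector("list", 4L)
    i <- 0L
    for (construct in c("anticipatory", "consummatory")) {
      for (question in c("motivation", "pleasure")) {
        i <- i + 1L
        eta <- eta_p[grid$p] + u_p[grid$p] + u_d[u_d_key] +
          beta_q * (question == "pleasure")
        pr <- cl_category_probs(eta, cfg$thresholds)
        u <- stats::runif(length(eta))
        cum <- t(apply(pr, 1L, cumsum))
        resp <- 1L + as.integer(rowSums(u > cum[, -ncol(cum), drop = FALSE]))
        rows[[i]] <- data.frame(
          participant_id = covariates$participant_id[grid$p],
          day = grid$day, prompt = grid$prompt,
          construct = construct, question = question, response = resp,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$participant_id, out$day, out$prompt,
                     out$construct, out$question), ]
    rownames(out) <- NULL
    attr(out, "truth") <- list(eta_participant = eta_p, u_p = u_p,
                               design = xp)
    out
  })
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}
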