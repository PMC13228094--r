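#' Specify a hierarchical cumulative-logit model
#'
#' Captures the fixed-effect structure, priors and sampler settings for
#' [fit_cumulative_logit()]. The random-intercept structure is fixed:
#' participant intercepts with day-within-participant intercepts nested
#' inside, matching the repeated-measurement structure of EMA data.
#'
#' Priors are weakly informative on the standardized-predictor scale:
#' Normal(0, `prior_sd_beta`) on coefficients, independent Normal(0,
#' `prior_sd_tau`) on each ordered threshold, half-Normal(0,
#' `prior_sd_sigma`) on the random-intercept SDs.
#'
#' @param participant_terms Character vector of fixed-effect columns constant
#'   within participants; defaults to the model table's recorded terms.
#' @param observation_terms Fixed-effect columns that vary within
#'   participants (normally just the question-type code).
#' @param chains,iter,warmup Sampler size: number of chains, post-warmup
#'   draws per chain, warmup sweeps per chain.
#' @param seed Integer seed controlling all sampler randomness.
#' @param prior_sd_beta,prior_sd_tau,prior_sd_sigma Prior scales (see above).
#' @param rhat_limit,ess_limit Convergence contract for reported fixed
#'   effects: potential scale reduction below `rhat_limit` and effective
#'   sample size above `ess_limit`.
#' @param on_diagnostic_failure `"error"` to fail loudly when the contract is
#'   violated, `"warn"` to continue with a warning (used for large replicate
#'   simulation studies), `"none"` to only record diagnostics.
#' @return A list of class `cl_model_spec`.
#' @export
cl_model_spec <- function(participant_terms = NULL, observation_terms = NULL,
                          chains = 4, iter = 1000, warmup = 1000, seed = 1,
                          prior_sd_beta = 2.5, prior_sd_tau = 2,
                          prior_sd_sigma = 1,
                          rhat_limit = 1.01, ess_limit = 400,
                          on_diagnostic_failure = c("error", "warn", "none")) {
  stopifnot(chains >= 1, iter >= 10, warmup >= 10)
  structure(list(participant_terms = participant_terms,
                 observation_terms = observation_terms,
                 chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 prior_sd_beta = prior_sd_beta, prior_sd_tau = prior_sd_tau,
                 prior_sd_sigma = prior_sd_sigma,
                 rhat_limit = rhat_limit, ess_limit = ess_limit,
                 on_diagnostic_failure = match.arg(on_diagnostic_failure)),
            class = "cl_model_spec")
}

#' Fit a Bayesian hierarchical cumulative-logit model
#'
#' Fits `P(Y <= k) = logistic(tau_k - eta)` with
#' `eta = x' beta + u_participant + u_day(participant)` to an ordinal
#' observation table by blocked MCMC (see the package vignette for the
#' sampler design). Observations sharing a participant, day and
#' observation-level covariate pattern are aggregated into multinomial
#' counts, which leaves the posterior unchanged.
#'
#' @param table A `model_table` (or data frame with `response`,
#'   `participant_id`, `day` and the predictor columns).
#' @param spec A [cl_model_spec()]; term lists default to the table's
#'   attributes.
#' @return An object of class `cl_fit`: posterior draws as a
#'   [coda::mcmc.list] (fixed effects, thresholds `tau1..tau4`, random-effect
#'   SDs `sigma_participant`, `sigma_day`), a `diagnostics` data frame (Rhat
#'   and effective sample size per parameter), the spec, and data shape info.
#' @export
fit_cumulative_logit <- function(table, spec = cl_model_spec()) {
  stopifnot(is.data.frame(table),
            all(c("response", "participant_id", "day") %in% names(table)))
  if (nrow(table) == 0L) stop("empty model table", call. = FALSE)
  if (!all(table$response %in% 1:5)) {
    stop("responses must be integers in 1..5", call. = FALSE)
  }
  if (length(unique(table$response)) < 2L) {
    stop("outcome is constant: cannot fit an ordinal model", call. = FALSE)
  }
  pt <- spec$participant_terms %||% attr(table, "participant_terms")
  ot <- spec$observation_terms %||% attr(table, "observation_terms")
  if (is.null(pt)) stop("no participant-level terms specified", call. = FALSE)
  missing_terms <- setdiff(c(pt, ot), names(table))
  if (length(missing_terms)) {
    stop(sprintf("term(s) not in table: %s",
                 paste(missing_terms, collapse = ", ")), call. = FALSE)
  }

  pid <- factor(table$participant_id)
  did <- factor(paste(as.integer(pid), table$day, sep = ":"),
                levels = unique(paste(as.integer(pid), table$day, sep = ":")[
                  order(as.integer(pid), table$day)]))
  # participant-level design: verify constancy within participant
  Xp <- matrix(0, nlevels(pid), length(pt), dimnames = list(levels(pid), pt))
  first <- match(levels(pid), pid)
  for (j in seq_along(pt)) {
    v <- table[[pt[j]]]
    rng <- tapply(v, pid, function(x) diff(range(x)))
    if (any(rng > 1e-8)) {
      stop(sprintf("term '%s' varies within participants; move it to observation_terms",
                   pt[j]), call. = FALSE)
    }
    Xp[, j] <- v[first]
  }
  # cell aggregation: (day, observation-covariate pattern) x category counts
  ot <- ot %||% character(0)
  obs_key <- if (length(ot)) {
    do.call(paste, c(lapply(ot, function(tm) table[[tm]]), sep = "|"))
  } else rep("", nrow(table))
  cell <- factor(paste(as.integer(did), obs_key, sep = "#"))
  y <- t(vapply(split(factor(table$response, levels = 1:5), cell),
                function(r) as.integer(base::table(r)), integer(5)))
  cell_first <- match(levels(cell), cell)
  cell_day <- as.integer(did)[cell_first]
  Xo <- if (length(ot)) {
    as.matrix(stats::setNames(table[cell_first, ot, drop = FALSE], ot))
  } else matrix(0, length(cell_first), 0)
  ord <- order(cell_day)
  y <- y[ord, , drop = FALSE]
  cell_day <- cell_day[ord]
  Xo <- Xo[ord, , drop = FALSE]
  day_first <- match(seq_len(nlevels(did)), as.integer(did))
  day_pid <- as.integer(pid)[day_first]

  # threshold initialization from marginal cumulative frequencies
  freq <- cumsum(base::table(factor(table$response, levels = 1:5))) / nrow(table)
  tau_init <- stats::qlogis(pmin(pmax(freq[1:4], 0.02), 0.98))

  # exclusive diagnosis dummies, used by the sampler's group-shift move;
  # binary group-structure columns additionally get the non-centered
  # coefficient move (continuous predictors mix well through the conjugate
  # block alone)
  dummy_cols <- which(pt %in% c("dx_bd", "dx_mdd", "dx_sz")) - 1L
  ncb_cols <- which(pt %in% c("dx_bd", "dx_mdd", "dx_sz", "gender")) - 1L

  par_names <- c(pt, ot, paste0("tau", 1:4), "sigma_participant", "sigma_day")
  chains <- vector("list", spec$chains)
  local_rng(spec$seed, {
    for (ch in seq_len(spec$chains)) {
      res <- .cl_sampler_chain(y, cell_day - 1L, Xo, day_pid - 1L, Xp,
                               spec$warmup, spec$iter,
                               spec$prior_sd_beta, spec$prior_sd_tau,
                               spec$prior_sd_sigma, tau_init, dummy_cols,
                               ncb_cols)
      d <- res$draws
      colnames(d) <- par_names
      chains[[ch]] <- coda::mcmc(d, start = spec$warmup + 1L)
    }
  })
  draws <- coda::mcmc.list(chains)

  reported <- c(pt, ot)
  ess <- tryCatch(coda::effectiveSize(draws), error = function(e) NULL)
  rhat <- if (spec$chains >= 2) {
    g <- coda::gelman.diag(draws, autoburnin = FALSE, multivariate = FALSE)
    g$psrf[, 1L]
  } else stats::setNames(rep(NA_real_, length(par_names)), par_names)
  diagnostics <- data.frame(parameter = par_names,
                            rhat = unname(rhat[par_names]),
                            ess = unname(ess[par_names]),
                            row.names = NULL)
  bad <- diagnostics$parameter %in% reported &
    ((!is.na(diagnostics$rhat) & diagnostics$rhat > spec$rhat_limit) |
       (!is.na(diagnostics$ess) & diagnostics$ess < spec$ess_limit))
  if (any(bad)) {
    msg <- sprintf(
      "convergence contract violated for: %s (Rhat limit %.3f, ESS limit %d)",
      paste(diagnostics$parameter[bad], collapse = ", "),
      spec$rhat_limit, as.integer(spec$ess_limit))
    switch(spec$on_diagnostic_failure,
           error = stop(msg, call. = FALSE),
           warn = warning(msg, call. = FALSE),
           none = invisible(NULL))
  }
  structure(list(draws = draws, terms = reported,
                 participant_terms = pt, observation_terms = ot,
                 diagnostics = diagnostics, spec = spec,
                 data_info = list(n_obs = nrow(table),
                                  n_participants = nlevels(pid),
                                  n_days = nlevels(did),
                                  n_cells = nrow(y))),
            class = "cl_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cl_fit <- function(x, ...) {
  cat(sprintf(paste0("cl_fit: hierarchical cumulative-logit model\n",
                     "  %d observations, %d participants, %d participant-days, %d cells\n",
                     "  %d chains x %d draws; terms: %s\n"),
              x$data_info$n_obs, x$data_info$n_participants, x$data_info$n_days,
              x$data_info$n_cells, length(x$draws), nrow(x$draws[[1]]),
              paste(x$terms, collapse = ", ")))
  print(summarize_effects(x))
  invisible(x)
}

# pooled draws of one parameter across chains
pooled_draws <- function(fit, term) {
  stopifnot(inherits(fit, "cl_fit"))
  if (!term %in% colnames(fit$draws[[1]])) {
    stop(sprintf("unknown term '%s'", term), call. = FALSE)
  }
  unlist(lapply(fit$draws, function(m) as.numeric(m[, term])), use.names = FALSE)
}
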