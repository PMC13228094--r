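#' Probability of direction
#'
#' Percentage of posterior draws strictly greater than zero (zero itself is
#' not counted). Note this is the literal directional definition; the common
#' convention `max(p, 1 - p)` is reported alongside it by
#' [summarize_effect()] as `pd_max`.
#'
#' @param draws Numeric vector of posterior draws for one coefficient.
#' @return Percentage in \[0, 100\].
#' @export
prob_direction <- function(draws) {
  stopifnot(length(draws) >= 1)
  100 * mean(draws > 0)
}

#' Fraction of draws inside the region of practical equivalence
#'
#' Percentage of posterior draws inside the closed interval (default
#' \[-0.10, 0.10\] on the standardized log-odds scale), treated as a
#' practically null effect size.
#'
#' @param draws Numeric vector of posterior draws for one coefficient.
#' @param interval Closed ROPE bounds, `lower < upper`.
#' @return Percentage in \[0, 100\].
#' @export
rope_fraction <- function(draws, interval = c(-0.10, 0.10)) {
  stopifnot(length(draws) >= 1, interval[1] < interval[2])
  100 * mean(draws >= interval[1] & draws <= interval[2])
}

#' Summarize one coefficient as an effect table row
#'
#' Computes the posterior odds ratio `exp(median(beta))`, an equal-tailed 95%
#' credible interval on the odds-ratio scale, probability of direction and
#' percent in the ROPE (both on the log-odds scale), and the significance
#' flag (credible interval for the odds ratio excludes 1, equivalently the
#' interval for the log-odds excludes 0).
#'
#' @param draws A `cl_fit`, or a numeric vector of log-odds draws.
#' @param term Term name (required when `draws` is a `cl_fit`; used as a
#'   label otherwise).
#' @param rope Closed ROPE bounds on the log-odds scale.
#' @param level Credible level.
#' @return One-row data.frame: `term`, `or` (odds ratio), `or_low`,
#'   `or_high`, `pd`, `pd_max`, `rope`, `significant`, `beta_median`.
#' @export
summarize_effect <- function(draws, term = NULL, rope = c(-0.10, 0.10),
                             level = 0.95) {
  if (inherits(draws, "cl_fit")) {
    if (is.null(term)) stop("'term' is required for a cl_fit", call. = FALSE)
    draws <- pooled_draws(draws, term)
  }
  stopifnot(is.numeric(draws), length(draws) >= 1)
  alpha <- (1 - level) / 2
  qs <- stats::quantile(draws, c(alpha, 0.5, 1 - alpha), names = FALSE, type = 7)
  pd <- prob_direction(draws)
  data.frame(term = term %||% "effect",
             or = exp(qs[2]), or_low = exp(qs[1]), or_high = exp(qs[3]),
             pd = pd, pd_max = max(pd, 100 - pd),
             rope = rope_fraction(draws, rope),
             significant = qs[1] > 0 | qs[3] < 0,
             beta_median = qs[2],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize all fixed effects of a fit
#'
#' @param fit A `cl_fit`.
#' @param rope,level Passed to [summarize_effect()].
#' @return Data frame with one row per fixed-effect term.
#' @export
summarize_effects <- function(fit, rope = c(-0.10, 0.10), level = 0.95) {
  stopifnot(inherits(fit, "cl_fit"))
  do.call(rbind, lapply(fit$terms, function(tm)
    summarize_effect(fit, tm, rope = rope, level = level)))
}

#' Simple-slopes analysis of a diagnosis-by-metric interaction
#'
#' Summarizes the conditional (per-group) effect of a metric: for the
#' reference group the conditional draws equal the main-effect draws; for
#' each diagnostic group they are the per-draw sum of the main effect and the
#' corresponding interaction coefficient. Significance uses the same
#' credible-interval rule as any effect.
#'
#' @param fit A `cl_fit` containing the metric main effect and its diagnosis
#'   interactions (columns named `<term>_x_<dummy>`).
#' @param term Metric term name (e.g. `"pc_z"`).
#' @param groups Named character vector mapping group labels to diagnosis
#'   dummy terms; the reference group maps to `NA`.
#' @param rope,level Passed to [summarize_effect()].
#' @return Data frame with one row per group (`group` column plus the usual
#'   effect-summary columns).
#' @export
simple_slopes <- function(fit, term,
                          groups = c(CON = NA, BD = "dx_bd", MDD = "dx_mdd",
                                     SZ = "dx_sz"),
                          rope = c(-0.10, 0.10), level = 0.95) {
  stopifnot(inherits(fit, "cl_fit"))
  main <- pooled_draws(fit, term)
  rows <- lapply(names(groups), function(g) {
    dummy <- groups[[g]]
    d <- if (is.na(dummy)) main else {
      int_term <- paste0(term, "_x_", dummy)
      if (!int_term %in% fit$terms) {
        stop(sprintf("missing interaction term '%s'", int_term), call. = FALSE)
      }
      main + pooled_draws(fit, int_term)
    }
    out <- summarize_effect(d, term = term, rope = rope, level = level)
    cbind(group = g, out, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Secondary between-network connectivity model
#'
#' Fits, within one diagnostic subgroup, a hierarchical cumulative-logit
#' model containing a set of between-network connectivity predictors plus
#' the standard covariates (age, gender, question type, mean FD), and
#' summarizes every between-network predictor. Predictors whose directional
#' posterior probability `pd_max` exceeds `notable_pd` are flagged as notable
#' even when their credible interval includes 1.
#'
#' @param encoded One construct's encoded EMA table
#'   ([encode_observations()]).
#' @param covariates Participant covariate data frame.
#' @param metrics Metrics table (`$table` from [metrics_table()]).
#' @param group Diagnostic subgroup label (e.g. `"SZ"`).
#' @param between_set Character vector of `between_<a>_<b>` metric columns to
#'   include as predictors.
#' @param spec A [cl_model_spec()] (term lists are filled in automatically).
#' @param notable_pd Directional-probability threshold for the notable flag.
#' @param kappa_limit Condition-number threshold above which predictor
#'   collinearity triggers a warning.
#' @return A list with `fit` (the `cl_fit`), `summary` (effect rows for the
#'   between-network predictors with a `notable` flag) and `kappa` (condition
#'   number of the between-network predictor block).
#' @export
secondary_between_model <- function(encoded, covariates, metrics, group,
                                    between_set, spec = cl_model_spec(),
                                    notable_pd = 90, kappa_limit = 30) {
  table <- build_model_table(encoded, covariates, metrics, kind = "secondary",
                             between_set = between_set, group = group)
  bz <- paste0(between_set, "_z")
  first <- match(unique(table$participant_id), table$participant_id)
  block <- as.matrix(table[first, bz, drop = FALSE])
  kappa <- if (length(bz) > 1L) kappa(block, exact = TRUE) else 1
  if (is.finite(kappa) && kappa > kappa_limit) {
    warning(sprintf(
      "between-network predictors are nearly collinear (condition number %.1f)",
      kappa), call. = FALSE)
  }
  fit <- fit_cumulative_logit(table, spec)
  summary <- do.call(rbind, lapply(bz, function(tm) summarize_effect(fit, tm)))
  summary$notable <- summary$pd_max > notable_pd
  list(fit = fit, summary = summary, kappa = kappa)
}
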