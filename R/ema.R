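#' Compliance filtering of EMA participants
#'
#' A participant is included when the fraction of issued prompts they
#' responded to is at least `threshold` (inclusive, reading "at least 33%"
#' literally as the fraction 0.33). A prompt counts as responded when at
#' least one of its questions has a response.
#'
#' @param records EMA observation data frame (`participant_id`, `day`,
#'   `prompt`, ...).
#' @param prompts_issued Named integer vector: prompts issued per participant
#'   (e.g. 56 for 4 prompts a day over 14 days). Its names define the known
#'   participant set.
#' @param threshold Minimum response fraction.
#' @return A list with `included` and `excluded` participant-id vectors and
#'   `rate` (named response fractions).
#' @export
compliance_filter <- function(records, prompts_issued, threshold = 0.33) {
  stopifnot(all(prompts_issued > 0), !is.null(names(prompts_issued)))
  unknown <- setdiff(unique(records$participant_id), names(prompts_issued))
  if (length(unknown)) {
    stop(sprintf("records contain unknown participant(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  key <- unique(records[, c("participant_id", "day", "prompt")])
  responded <- table(factor(key$participant_id, levels = names(prompts_issued)))
  rate <- as.numeric(responded) / as.numeric(prompts_issued)
  names(rate) <- names(prompts_issued)
  list(included = names(prompts_issued)[rate >= threshold],
       excluded = names(prompts_issued)[rate < threshold],
       rate = rate)
}

# Table-style question texts accepted alongside the short codes
question_texts <- c(
  "How much are you enjoying this activity?" = "pleasure",
  "How interested are you in this activity?" = "motivation",
  "How much do you think you will enjoy this activity?" = "pleasure",
  "How interested do you think you will be in this activity?" = "motivation")

#' Encode EMA observations for modeling
#'
#' Splits the observation table by construct (anticipatory vs consummatory)
#' and codes the question type as a binary variable (0 = motivation,
#' 1 = pleasure). Question entries may be the short codes or the full prompt
#' texts.
#'
#' @param records EMA observation data frame (`participant_id`, `day`,
#'   `prompt`, `construct`, `question`, `response`).
#' @return A list with one data frame per construct (`anticipatory`,
#'   `consummatory`), each carrying a numeric `question` code (0/1) and a
#'   `question_label` column preserving the original label.
#' @export
encode_observations <- function(records) {
  req <- c("participant_id", "day", "prompt", "construct", "question", "response")
  stopifnot(all(req %in% names(records)))
  bad <- which(!(records$response %in% 1:5))
  if (length(bad)) {
    stop(sprintf("responses outside 1..5 in row(s): %s",
                 paste(utils::head(bad, 10L), collapse = ", ")), call. = FALSE)
  }
  q <- as.character(records$question)
  q_std <- ifelse(q %in% names(question_texts), unname(question_texts[q]), q)
  if (!all(q_std %in% c("motivation", "pleasure"))) {
    stop("unrecognized question label", call. = FALSE)
  }
  records$question_label <- q
  records$question <- as.numeric(q_std == "pleasure")
  out <- split(records, records$construct)
  stopifnot(all(names(out) %in% c("anticipatory", "consummatory")))
  lapply(out, function(d) { rownames(d) <- NULL; d })
}

#' Decode an encoded observation table
#'
#' Inverse of [encode_observations()]: re-binds the construct tables and
#' restores the original question labels.
#'
#' @param encoded List of encoded construct tables.
#' @return The reassembled observation data frame.
#' @export
decode_observations <- function(encoded) {
  out <- do.call(rbind, unname(encoded))
  out$question <- out$question_label
  out$question_label <- NULL
  out <- out[order(out$participant_id, out$day, out$prompt,
                   out$construct, out$question), ]
  rownames(out) <- NULL
  attributes(out) <- attributes(out)[c("names", "class", "row.names")]
  out
}

#' Assemble a model-ready observation table
#'
#' Joins one construct's encoded EMA observations to participant covariates
#' and (for connectivity / extent / secondary models) network metrics.
#' Diagnosis is dummy-coded with the control group as reference; numeric
#' predictors (age, mean FD, metrics) are standardized using one value per
#' participant across the included participants, then broadcast to
#' observations; interaction columns are the product of a diagnosis dummy and
#' a standardized metric.
#'
#' @param encoded One construct's encoded data frame from
#'   [encode_observations()].
#' @param covariates Covariate data frame (`participant_id`, `diagnosis`,
#'   `age`, `gender`, `mean_fd`).
#' @param metrics Metrics table from [metrics_table()] (`$table`), required
#'   for all but the diagnostic model.
#' @param kind Model family: `"diagnostic"` (diagnosis + covariates),
#'   `"connectivity"` (adds one network's within-network Z and PC with
#'   diagnosis interactions), `"extent"` (adds one network's vertex count
#'   with interactions), or `"secondary"` (a between-network predictor set on
#'   one diagnostic subgroup, no diagnosis terms).
#' @param network Network id for connectivity/extent models.
#' @param between_set Character vector of `between_<a>_<b>` columns for
#'   secondary models.
#' @param group Diagnostic subgroup (e.g. `"SZ"`) to restrict to for
#'   secondary models.
#' @return A data.frame of class `model_table` with attributes
#'   `participant_terms` (fixed effects constant within participant),
#'   `observation_terms` (fixed effects varying within participant) and
#'   `dropped` (participants excluded for missing covariates or metrics).
#' @export
build_model_table <- function(encoded, covariates, metrics = NULL,
                              kind = c("diagnostic", "connectivity", "extent",
                                       "secondary"),
                              network = NULL, between_set = NULL, group = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(encoded), "question" %in% names(encoded))
  ids <- unique(encoded$participant_id)
  have_cov <- ids %in% covariates$participant_id
  need_metrics <- kind != "diagnostic"
  if (need_metrics && is.null(metrics)) stop("metrics table required", call. = FALSE)
  have_met <- if (need_metrics) ids %in% metrics$participant_id else rep(TRUE, length(ids))
  dropped <- ids[!(have_cov & have_met)]
  if (length(dropped)) {
    message(sprintf("excluding %d participant(s) with missing covariates/metrics",
                    length(dropped)))
  }
  ids <- ids[have_cov & have_met]
  cov <- covariates[match(ids, covariates$participant_id), , drop = FALSE]
  cov$diagnosis <- factor(cov$diagnosis, levels = c("CON", "BD", "MDD", "SZ"))
  if (kind == "secondary") {
    if (is.null(group)) stop("secondary models need a diagnostic subgroup",
                             call. = FALSE)
    keep <- cov$diagnosis == group
    if (!any(keep)) stop("empty diagnostic subgroup", call. = FALSE)
    ids <- ids[keep]; cov <- cov[keep, , drop = FALSE]
  }
  # participant-level predictor frame (one row per participant)
  pp <- data.frame(participant_id = ids,
                   dx_bd = as.numeric(cov$diagnosis == "BD"),
                   dx_mdd = as.numeric(cov$diagnosis == "MDD"),
                   dx_sz = as.numeric(cov$diagnosis == "SZ"),
                   age_z = standardize(cov$age),
                   gender = as.numeric(cov$gender),
                   stringsAsFactors = FALSE)
  terms <- c("dx_bd", "dx_mdd", "dx_sz", "age_z", "gender")
  dx_terms <- c("dx_bd", "dx_mdd", "dx_sz")
  if (need_metrics) {
    met <- metrics[match(ids, metrics$participant_id), , drop = FALSE]
    pp$fd_z <- standardize(met$mean_fd)
    terms <- c(terms, "fd_z")
    add_metric <- function(pp, col, name) {
      if (!col %in% names(met)) stop(sprintf("metric column '%s' missing", col),
                                     call. = FALSE)
      pp[[name]] <- standardize(met[[col]])
      pp
    }
    if (kind == "connectivity") {
      stopifnot(!is.null(network))
      pp <- add_metric(pp, paste0("within_", network), "within_z")
      pp <- add_metric(pp, paste0("pc_", network), "pc_z")
      for (m in c("within_z", "pc_z")) for (d in dx_terms) {
        pp[[paste0(m, "_x_", d)]] <- pp[[m]] * pp[[d]]
      }
      terms <- c(terms, "within_z", "pc_z",
                 as.vector(outer(c("within_z", "pc_z"), dx_terms,
                                 function(m, d) paste0(m, "_x_", d))))
    } else if (kind == "extent") {
      stopifnot(!is.null(network))
      pp <- add_metric(pp, paste0("extent_", network), "extent_z")
      for (d in dx_terms) pp[[paste0("extent_z_x_", d)]] <- pp$extent_z * pp[[d]]
      terms <- c(terms, "extent_z", paste0("extent_z_x_", dx_terms))
    } else if (kind == "secondary") {
      stopifnot(!is.null(between_set))
      bz <- paste0(between_set, "_z")
      for (j in seq_along(between_set)) pp <- add_metric(pp, between_set[j], bz[j])
      terms <- c(setdiff(terms, dx_terms), bz)
      pp[dx_terms] <- NULL
    }
  }
  obs <- encoded[encoded$participant_id %in% ids, , drop = FALSE]
  out <- merge(obs, pp, by = "participant_id", sort = FALSE)
  out <- out[order(out$participant_id, out$day, out$prompt, out$question), ]
  rownames(out) <- NULL
  structure(out, participant_terms = setdiff(terms, "question"),
            observation_terms = "question", dropped = dropped,
            kind = kind, class = c("model_table", "data.frame"))
}
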