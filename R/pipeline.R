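#' Build a pipeline run configuration
#'
#' Collects every stage's settings in one validated list. All protocol
#' constants are surfaced as named keys with their standard defaults: top
#' connection fraction 0.05, minimum patch area 30 mm^2, tie densities
#' 1-25% averaged over the first ten, compliance threshold 0.33, minimum
#' retained frames 375, ROPE bounds +/- 0.10.
#'
#' @param master_seed Master seed; all stage seeds derive from it.
#' @param n_per_group Cohort group sizes.
#' @param rows,cols,vertex_area,K,swap_frac Surface / template settings.
#' @param bold_cfg,ema_cfg Generator configs.
#' @param fraction Top connection fraction for template matching.
#' @param min_area Minimum patch area (mm^2).
#' @param min_frames Frame-count QC minimum.
#' @param compliance EMA compliance threshold.
#' @param densities,avg_over Participation-coefficient grid.
#' @param rope ROPE bounds (log-odds scale).
#' @param clean Logical: run time-series cleaning (demean/detrend + band-pass)
#'   before connectivity.
#' @param band Band-pass limits (Hz) when `clean = TRUE`.
#' @param fits List of fits to run; each element is a list with `construct`
#'   (`"anticipatory"` or `"consummatory"`), `kind` (`"diagnostic"`,
#'   `"connectivity"` or `"extent"`) and `network` (required unless
#'   diagnostic).
#' @param sampler A [cl_model_spec()] used for every fit (its seed is
#'   re-derived per fit from the master seed).
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(master_seed = 1,
                            n_per_group = c(CON = 40, BD = 38, MDD = 37, SZ = 29),
                            rows = 40, cols = 40, vertex_area = 1, K = 8,
                            swap_frac = 0.1,
                            bold_cfg = bold_sim_config(),
                            ema_cfg = ema_sim_config(),
                            fraction = 0.05, min_area = 30, min_frames = 375,
                            compliance = 0.33,
                            densities = seq(0.01, 0.25, by = 0.01),
                            avg_over = 1:10, rope = c(-0.10, 0.10),
                            clean = TRUE, band = c(0.01, 0.1),
                            fits = list(list(construct = "anticipatory",
                                             kind = "diagnostic",
                                             network = NULL)),
                            sampler = cl_model_spec()) {
  structure(list(master_seed = master_seed, n_per_group = n_per_group,
                 rows = rows, cols = cols, vertex_area = vertex_area, K = K,
                 swap_frac = swap_frac, bold_cfg = bold_cfg, ema_cfg = ema_cfg,
                 fraction = fraction, min_area = min_area,
                 min_frames = min_frames, compliance = compliance,
                 densities = densities, avg_over = avg_over, rope = rope,
                 clean = clean, band = band, fits = fits, sampler = sampler),
            class = "run_config")
}

validate_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ids <- if (config$K == 8) c("DMN", "CON", "DAN", "VAN", "SAL", "FPN",
                              "DSM", "VSM") else sprintf("NET%02d", seq_len(config$K))
  for (f in config$fits) {
    if (!f$kind %in% c("diagnostic", "connectivity", "extent")) {
      stop(sprintf("unknown model kind '%s'", f$kind), call. = FALSE)
    }
    if (!f$construct %in% c("anticipatory", "consummatory")) {
      stop(sprintf("unknown construct '%s'", f$construct), call. = FALSE)
    }
    if (f$kind != "diagnostic" && !isTRUE(f$network %in% ids)) {
      stop(sprintf("fit references unknown network '%s'",
                   as.character(f$network %||% "NULL")), call. = FALSE)
    }
  }
  invisible(ids)
}

#' Run the full pipeline
#'
#' Orchestrates simulate, map-networks, metrics, EMA processing and model
#' fitting under a single configuration: cohort generation, optional
#' time-series cleaning, dense connectivity, template matching, small-patch
#' removal, parcellation, the per-participant metric table, compliance
#' filtering, model-table assembly, cumulative-logit fits, and effect-table
#' assembly. A stage failure aborts with the stage name; the manifest
#' reconciles participant counts surviving each filter.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, results tables and the run
#'   manifest are written there as TSV/JSON.
#' @return A list of class `run_result`: `metrics` (per-participant metric
#'   table), `qc`, `compliance`, `effects` (effect rows across fits, shaped
#'   like a key-effects table: construct, kind, network, term, odds ratio,
#'   CI, PD, ROPE, significance), `slopes` (per-group conditional effects for
#'   interaction models), `fits` (the `cl_fit` objects) and `manifest`.
#' @export
run_all <- function(config = pipeline_config(), out_dir = NULL) {
  validate_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  bundle <- stage("simulate", simulate_cohort(
    n_per_group = config$n_per_group, rows = config$rows, cols = config$cols,
    vertex_area = config$vertex_area, K = config$K,
    swap_frac = config$swap_frac, bold_cfg = config$bold_cfg,
    ema_cfg = config$ema_cfg, master_seed = config$master_seed))

  participants <- stage("map-networks", {
    lapply(stats::setNames(nm = bundle$covariates$participant_id), function(pid) {
      ts <- bundle$ts[[pid]]
      ts_clean <- if (config$clean) clean_timeseries(ts, band = config$band) else ts
      conn <- vertex_connectivity(ts_clean)
      asg <- assign_vertices(conn, bundle$templates, fraction = config$fraction)
      asg <- remove_small_patches(asg, bundle$surface, min_area = config$min_area)
      parc <- parcellate(asg, bundle$surface)
      list(ts = ts, ts_clean = ts_clean, assignment = asg, parcellation = parc)
    })
  })
  # metric extraction uses the cleaned series; QC counts the original mask
  met <- stage("metrics", {
    inputs <- lapply(participants, function(p) {
      list(ts = vertex_ts(p$ts_clean$data,
                          censor_mask = rep(TRUE, ncol(p$ts_clean$data)),
                          tr = p$ts_clean$tr, mean_fd = p$ts$mean_fd),
           parcellation = p$parcellation, assignment = p$assignment)
    })
    qc_mask <- vapply(participants, function(p) sum(p$ts$censor_mask), 1)
    m <- metrics_table(inputs, min_frames = 0,
                       densities = config$densities, avg_over = config$avg_over)
    m$qc$retained_frames <- as.integer(qc_mask[m$qc$participant_id])
    m$qc$included <- m$qc$retained_frames >= config$min_frames
    m$table <- m$table[m$table$participant_id %in%
                         m$qc$participant_id[m$qc$included], , drop = FALSE]
    m
  })
  ema_ready <- stage("ema", {
    issued <- stats::setNames(
      rep(config$ema_cfg$prompts_per_day * config$ema_cfg$n_days,
          nrow(bundle$covariates)), bundle$covariates$participant_id)
    comp <- compliance_filter(bundle$ema, issued, threshold = config$compliance)
    records <- bundle$ema[bundle$ema$participant_id %in% comp$included, ,
                          drop = FALSE]
    list(compliance = comp, encoded = encode_observations(records))
  })
  effects <- list(); slopes <- list(); fit_objs <- list()
  stage("fit", for (i in seq_along(config$fits)) {
    f <- config$fits[[i]]
    tab <- build_model_table(ema_ready$encoded[[f$construct]],
                             bundle$covariates,
                             metrics = if (f$kind == "diagnostic") NULL else met$table,
                             kind = f$kind, network = f$network)
    spec <- config$sampler
    spec$seed <- derive_seed(config$master_seed, 20000L + i)
    fit <- fit_cumulative_logit(tab, spec)
    key <- paste(f$construct, f$kind, f$network %||% "", sep = ".")
    fit_objs[[key]] <- fit
    su <- summarize_effects(fit, rope = config$rope)
    effects[[key]] <- cbind(construct = f$construct, kind = f$kind,
                            network = f$network %||% NA_character_, su,
                            stringsAsFactors = FALSE)
    metric_terms <- switch(f$kind, connectivity = c("within_z", "pc_z"),
                           extent = "extent_z", NULL)
    for (tm in metric_terms) {
      sl <- simple_slopes(fit, tm, rope = config$rope)
      slopes[[paste(key, tm, sep = ".")]] <-
        cbind(construct = f$construct, network = f$network, sl,
              stringsAsFactors = FALSE)
    }
  })
  effects <- if (length(effects)) do.call(rbind, c(effects, make.row.names = FALSE)) else NULL
  slopes <- if (length(slopes)) do.call(rbind, c(slopes, make.row.names = FALSE)) else NULL
  manifest <- list(
    config_hash = config_hash(config),
    master_seed = config$master_seed,
    counts = list(simulated = nrow(bundle$covariates),
                  frame_qc_included = sum(met$qc$included),
                  compliance_included = length(ema_ready$compliance$included),
                  ema_rows = nrow(bundle$ema),
                  fits = length(config$fits)),
    bundle_manifest = bundle$manifest)
  result <- structure(list(metrics = met$table, qc = met$qc,
                           compliance = ema_ready$compliance,
                           effects = effects, slopes = slopes,
                           fits = fit_objs, manifest = manifest),
                      class = "run_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(met$table, file.path(out_dir, "metrics.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    jsonlite::write_json(met$qc, file.path(out_dir, "qc.json"), digits = NA)
    if (!is.null(effects)) {
      utils::write.table(effects, file.path(out_dir, "effects.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
    if (!is.null(slopes)) {
      utils::write.table(slopes, file.path(out_dir, "slopes.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

# stable hash of the configuration via its canonical JSON serialization
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(rapply(unclass(config), unclass, how = "replace"),
                              auto_unbox = TRUE, digits = NA, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Render a human-readable effect report
#'
#' Formats the effect rows of a pipeline run the way a key-effects table is
#' printed: odds ratio with 95% CI, PD and %ROPE, with `*` marking terms
#' whose credible interval excludes 1.
#'
#' @param result A `run_result` from [run_all()] (or a data frame shaped like
#'   its `effects` component).
#' @return Character vector of report lines, invisibly; the report is also
#'   printed.
#' @export
report <- function(result) {
  eff <- if (is.data.frame(result)) result else result$effects
  if (is.null(eff) || !nrow(eff)) {
    lines <- "No fits were run."
    cat(lines, sep = "\n")
    return(invisible(lines))
  }
  lines <- c(sprintf("%-14s %-12s %-8s %-22s %8s  %-16s %7s %7s",
                     "construct", "kind", "network", "term", "e^beta",
                     "95% CI", "PD", "%ROPE"))
  for (i in seq_len(nrow(eff))) {
    r <- eff[i, ]
    lines <- c(lines, sprintf(
      "%-14s %-12s %-8s %-22s %8.2f  [%5.2f, %5.2f]%s %6.1f%% %6.1f%%",
      r$construct, r$kind, ifelse(is.na(r$network), "-", r$network), r$term,
      r$or, r$or_low, r$or_high, ifelse(r$significant, "*", " "),
      r$pd, r$rope))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
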