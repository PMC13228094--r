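#' Simulate a full synthetic cohort
#'
#' Generates one self-consistent bundle: a lattice surface with contiguous
#' network templates, an individually perturbed vertex assignment and
#' block-correlated BOLD-like time series per participant, participant
#' covariates, and ordinal EMA responses from the nested cumulative-logit
#' generative model. Default group sizes are 40 controls, 38 bipolar, 37
#' major depressive and 29 schizophrenia/schizoaffective participants (144
#' total); ages and gender rates are drawn per group from distributions
#' matching a transdiagnostic clinical sample.
#'
#' Every sub-generator seed is derived deterministically from `master_seed`
#' and recorded in the bundle manifest, so a fixed master seed reproduces the
#' bundle bit-identically.
#'
#' @param n_per_group Named counts for `CON`, `BD`, `MDD`, `SZ`.
#' @param rows,cols,vertex_area Surface lattice shape.
#' @param K Number of networks.
#' @param swap_frac Boundary-relabel fraction for individual topography.
#' @param bold_cfg A [bold_sim_config()].
#' @param ema_cfg An [ema_sim_config()].
#' @param metrics Optional metrics table passed to [simulate_ema()] when the
#'   EMA config includes metric effects.
#' @param master_seed Integer master seed.
#' @return A list of class `cohort_bundle` with `surface`, `templates`,
#'   `truth`, `covariates`, `assignments` (list of `vertex_labels`), `ts`
#'   (list of `vertex_ts`), `ema` (observation data frame) and `manifest`.
#' @export
simulate_cohort <- function(n_per_group = c(CON = 40, BD = 38, MDD = 37, SZ = 29),
                            rows = 40, cols = 40, vertex_area = 1, K = 8,
                            swap_frac = 0.1,
                            bold_cfg = bold_sim_config(),
                            ema_cfg = ema_sim_config(),
                            metrics = NULL, master_seed = 1) {
  stopifnot(all(c("CON", "BD", "MDD", "SZ") %in% names(n_per_group)),
            all(n_per_group >= 1))
  n_per_group <- n_per_group[c("CON", "BD", "MDD", "SZ")]
  surface <- make_surface(rows, cols, vertex_area)
  tpl <- make_templates(surface, K = K, seed = derive_seed(master_seed, 1L))
  # group-specific age and gender distributions typical of a transdiagnostic
  # clinical sample (means/SDs in years; gender = P(female/non-binary))
  age_mean <- c(CON = 35.15, BD = 36.43, MDD = 32.65, SZ = 34.42)
  age_sd <- c(CON = 7.62, BD = 8.03, MDD = 8.21, SZ = 8.32)
  gender_p <- c(CON = 0.52, BD = 0.66, MDD = 0.62, SZ = 0.41)
  groups <- rep(names(n_per_group), times = n_per_group)
  n <- length(groups)
  ids <- sprintf("P%03d", seq_len(n))
  covariates <- local_rng(derive_seed(master_seed, 2L), {
    data.frame(participant_id = ids, diagnosis = groups,
               age = round(stats::rnorm(n, age_mean[groups], age_sd[groups]), 1),
               gender = stats::rbinom(n, 1, gender_p[groups]),
               mean_fd = NA_real_, stringsAsFactors = FALSE)
  })
  assignments <- vector("list", n); ts <- vector("list", n)
  seeds <- data.frame(participant_id = ids,
                      perturb_seed = derive_seed(master_seed, 100L + seq_len(n)),
                      bold_seed = derive_seed(master_seed, 10000L + seq_len(n)))
  for (i in seq_len(n)) {
    assignments[[i]] <- perturb_individual(tpl$truth, surface, swap_frac,
                                           seed = seeds$perturb_seed[i])
    ts[[i]] <- simulate_bold(surface, assignments[[i]], bold_cfg,
                             seed = seeds$bold_seed[i])
    covariates$mean_fd[i] <- ts[[i]]$mean_fd
  }
  names(assignments) <- names(ts) <- ids
  ema <- simulate_ema(covariates, metrics = metrics, cfg = ema_cfg,
                      seed = derive_seed(master_seed, 3L))
  manifest <- list(master_seed = master_seed,
                   template_seed = derive_seed(master_seed, 1L),
                   covariate_seed = derive_seed(master_seed, 2L),
                   ema_seed = derive_seed(master_seed, 3L),
                   participant_seeds = seeds,
                   n_per_group = as.list(n_per_group),
                   surface = list(rows = rows, cols = cols,
                                  vertex_area = vertex_area),
                   K = K, swap_frac = swap_frac,
                   bold_cfg = unclass(bold_cfg),
                   ema_cfg = lapply(unclass(ema_cfg), unclass))
  structure(list(surface = surface, templates = tpl$templates,
                 truth = tpl$truth, covariates = covariates,
                 assignments = assignments, ts = ts, ema = ema,
                 manifest = manifest),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("cohort_bundle: %d participants, %d x %d surface, %d networks, %d EMA rows\n",
              nrow(x$covariates), x$surface$rows, x$surface$cols,
              length(x$templates$network_ids), nrow(x$ema)))
  invisible(x)
}

#' Write a cohort bundle to a directory
#'
#' Plain-text layout: `manifest.json` (seeds and configs), `surface.json`
#' (lattice shape and adjacency list), `templates.json` (network ids, label
#' maps, ground-truth labels), `covariates.csv`, `ema.csv`,
#' `assignments.tsv` (participant, vertex, network label), and per
#' participant `ts/<id>_data.tsv` (vertices x frames) plus
#' `ts/<id>_mask.tsv` (censor mask).
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(file.path(dir, "ts"), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  s <- bundle$surface
  jsonlite::write_json(list(rows = s$rows, cols = s$cols,
                            vertex_area = s$vertex_area,
                            edges = unname(apply(s$edges, 1L, as.list))),
                       file.path(dir, "surface.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(list(network_ids = bundle$templates$network_ids,
                            maps = apply(bundle$templates$maps, 2L, function(m)
                              which(m == 1L), simplify = FALSE),
                            truth = as.integer(bundle$truth)),
                       file.path(dir, "templates.json"), digits = NA)
  utils::write.csv(bundle$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$ema, file.path(dir, "ema.csv"), row.names = FALSE)
  asg <- do.call(rbind, lapply(names(bundle$assignments), function(pid) {
    data.frame(participant_id = pid,
               vertex_id = seq_along(bundle$assignments[[pid]]),
               network = as.integer(bundle$assignments[[pid]]))
  }))
  utils::write.table(asg, file.path(dir, "assignments.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (pid in names(bundle$ts)) {
    utils::write.table(bundle$ts[[pid]]$data,
                       file.path(dir, "ts", paste0(pid, "_data.tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(mask = as.integer(bundle$ts[[pid]]$censor_mask),
                                  tr = bundle$ts[[pid]]$tr,
                                  mean_fd = bundle$ts[[pid]]$mean_fd),
                       file.path(dir, "ts", paste0(pid, "_mask.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Read a cohort bundle from a directory
#'
#' @param dir Directory written by [write_bundle()].
#' @return A `cohort_bundle`.
#' @export
read_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  sj <- jsonlite::read_json(file.path(dir, "surface.json"), simplifyVector = TRUE)
  surface <- make_surface(sj$rows, sj$cols, sj$vertex_area)
  tj <- jsonlite::read_json(file.path(dir, "templates.json"), simplifyVector = TRUE)
  n <- surface$n_vertices
  ids <- as.character(tj$network_ids)
  maps <- matrix(0L, n, length(ids), dimnames = list(NULL, ids))
  for (k in seq_along(ids)) maps[tj$maps[[k]], k] <- 1L
  templates <- structure(list(network_ids = ids, maps = maps),
                         class = "network_templates")
  truth <- structure(as.integer(tj$truth), network_ids = ids,
                     class = "vertex_labels")
  covariates <- utils::read.csv(file.path(dir, "covariates.csv"),
                                stringsAsFactors = FALSE)
  ema <- utils::read.csv(file.path(dir, "ema.csv"), stringsAsFactors = FALSE)
  asg <- utils::read.table(file.path(dir, "assignments.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  assignments <- lapply(split(asg, asg$participant_id), function(d) {
    structure(d$network[order(d$vertex_id)], network_ids = ids,
              class = "vertex_labels")
  })
  pids <- covariates$participant_id
  ts <- lapply(pids, function(pid) {
    dat <- as.matrix(utils::read.table(
      file.path(dir, "ts", paste0(pid, "_data.tsv")), sep = "\t"))
    dimnames(dat) <- NULL
    meta <- utils::read.table(file.path(dir, "ts", paste0(pid, "_mask.tsv")),
                              sep = "\t", header = TRUE)
    vertex_ts(dat, censor_mask = meta$mask == 1L, tr = meta$tr[1],
              mean_fd = meta$mean_fd[1])
  })
  names(ts) <- pids
  structure(list(surface = surface, templates = templates, truth = truth,
                 covariates = covariates, assignments = assignments[pids],
                 ts = ts, ema = ema, manifest = manifest),
            class = "cohort_bundle")
}
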