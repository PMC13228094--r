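#' Average parcel time series
#'
#' Unweighted mean over member vertices, retained frames only.
#'
#' @param ts A `vertex_ts`.
#' @param parcellation A `parcellation`.
#' @return A parcels x frames numeric matrix.
#' @export
parcel_timeseries <- function(ts, parcellation) {
  stopifnot(inherits(ts, "vertex_ts"), inherits(parcellation, "parcellation"))
  if (!length(parcellation$parcels)) stop("empty parcellation", call. = FALSE)
  keep <- which(ts$censor_mask)
  x <- ts$data[, keep, drop = FALSE]
  out <- t(vapply(parcellation$parcels, function(vs) {
    if (!length(vs)) stop("empty parcel", call. = FALSE)
    colMeans(x[vs, , drop = FALSE])
  }, numeric(ncol(x))))
  out
}

#' Fisher Z transform
#'
#' `atanh` of the correlation, variance-stabilizing before averaging.
#' Correlations are clipped to +/- (1 - 1e-7) so the transform stays finite.
#'
#' @param r Correlation value(s), `|r| <= 1`.
#' @return Fisher-Z value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) stop("|r| must be <= 1", call. = FALSE)
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' Parcel-level Fisher-Z connectivity
#'
#' Pearson correlations between all parcel time series, Fisher-Z transformed.
#'
#' @param parcel_ts Parcels x frames matrix from [parcel_timeseries()].
#' @param network Integer network index per parcel.
#' @param network_ids Character network labels.
#' @return A `parcel_connectivity` object: symmetric parcels x parcels Z
#'   matrix plus parcel network labels.
#' @export
parcel_connectivity <- function(parcel_ts, network, network_ids) {
  stopifnot(nrow(parcel_ts) == length(network))
  z <- fisher_z(stats::cor(t(parcel_ts)))
  diag(z) <- 0
  structure(list(z = z, network = as.integer(network),
                 network_ids = network_ids),
            class = "parcel_connectivity")
}

#' Within- and between-network connectivity
#'
#' Averages parcel-pair Fisher-Z values within each network (over unordered
#' parcel pairs sharing the label; missing when the network has fewer than
#' two parcels) and between each network pair (over pairs spanning the two
#' labels; missing when either network has no parcel). The diagonal is never
#' included.
#'
#' @param pc_mat A `parcel_connectivity`.
#' @return A list with `within` (named numeric, one entry per network id) and
#'   `between` (named numeric over unordered pairs, names `"<a>_<b>"` in
#'   network-id order).
#' @export
within_between <- function(pc_mat) {
  stopifnot(inherits(pc_mat, "parcel_connectivity"))
  ids <- pc_mat$network_ids
  K <- length(ids)
  net <- pc_mat$network
  z <- pc_mat$z
  within <- stats::setNames(rep(NA_real_, K), ids)
  for (k in seq_len(K)) {
    p <- which(net == k)
    if (length(p) >= 2L) {
      sub <- z[p, p, drop = FALSE]
      within[k] <- mean(sub[upper.tri(sub)])
    }
  }
  pairs <- utils::combn(K, 2L)
  between <- stats::setNames(rep(NA_real_, ncol(pairs)),
                             apply(pairs, 2L, function(ab) paste(ids[ab], collapse = "_")))
  for (j in seq_len(ncol(pairs))) {
    pa <- which(net == pairs[1L, j]); pb <- which(net == pairs[2L, j])
    if (length(pa) && length(pb)) {
      between[j] <- mean(z[pa, pb, drop = FALSE])
    }
  }
  list(within = within, between = between)
}

#' Participation coefficients over a tie-density grid
#'
#' Binarizes the parcel graph at each tie density (top `d` fraction of
#' off-diagonal edges by signed Z, ties broken by ascending pair index; edge
#' count `floor(d * P)` for `P` unordered pairs), computes each parcel's
#' participation coefficient `1 - sum_s (k_is / k_i)^2` (isolated parcels get
#' 0), averages each parcel across the averaging densities, and finally
#' averages parcels within each network.
#'
#' @param pc_mat A `parcel_connectivity`.
#' @param densities Tie densities (fractions) to threshold at.
#' @param avg_over Indices into `densities` averaged for the stable estimate;
#'   the default uses densities 1 through 10 percent.
#' @return A list with `network` (named per-network mean PC), `node`
#'   (parcels x densities PC matrix), and `node_mean` (per-parcel average over
#'   the averaging densities).
#' @export
participation_coefficients <- function(pc_mat,
                                       densities = seq(0.01, 0.25, by = 0.01),
                                       avg_over = 1:10) {
  stopifnot(inherits(pc_mat, "parcel_connectivity"))
  n <- nrow(pc_mat$z)
  if (n < 2L) stop("need at least 2 parcels", call. = FALSE)
  net <- pc_mat$network
  ids <- pc_mat$network_ids
  K <- length(ids)
  up <- which(upper.tri(pc_mat$z), arr.ind = TRUE)
  w <- pc_mat$z[up]
  P <- nrow(up)
  ord <- order(-w, seq_len(P))  # descending Z, ties by ascending pair index
  node_pc <- matrix(0, n, length(densities))
  for (di in seq_along(densities)) {
    m <- floor(densities[di] * P)
    if (m < 1L) { node_pc[, di] <- 0; next }
    sel <- up[ord[seq_len(m)], , drop = FALSE]
    # degree and per-network edge counts
    deg <- numeric(n)
    kis <- matrix(0, n, K)
    a <- sel[, 1L]; b <- sel[, 2L]
    for (e in seq_len(m)) {
      deg[a[e]] <- deg[a[e]] + 1
      deg[b[e]] <- deg[b[e]] + 1
      kis[a[e], net[b[e]]] <- kis[a[e], net[b[e]]] + 1
      kis[b[e], net[a[e]]] <- kis[b[e], net[a[e]]] + 1
    }
    has <- deg > 0
    pcv <- numeric(n)
    if (any(has)) {
      pcv[has] <- 1 - rowSums((kis[has, , drop = FALSE] / deg[has])^2)
    }
    node_pc[, di] <- pcv
  }
  node_mean <- rowMeans(node_pc[, avg_over, drop = FALSE])
  network <- stats::setNames(rep(NA_real_, K), ids)
  for (k in seq_len(K)) {
    p <- which(net == k)
    if (length(p)) network[k] <- mean(node_mean[p])
  }
  list(network = network, node = node_pc, node_mean = node_mean)
}

#' Spatial extent of each network
#'
#' Number of vertices assigned to each network; unassigned vertices are
#' excluded and networks absent from the assignment count 0.
#'
#' @param assignment A `vertex_assignment`.
#' @return Named integer vector, one entry per network id.
#' @export
spatial_extent <- function(assignment) {
  stopifnot(inherits(assignment, "vertex_assignment"))
  K <- length(assignment$network_ids)
  counts <- tabulate(assignment$label[!is.na(assignment$label)], nbins = K)
  stats::setNames(as.integer(counts), assignment$network_ids)
}

#' Per-participant network metric table
#'
#' Runs the metric stage for each participant: frame-count QC, parcel time
#' series, Fisher-Z parcel connectivity, within/between-network averages,
#' participation coefficients and spatial extent, joined into one row per
#' included participant. Excluded participants are listed in the QC report.
#'
#' @param participants Named list; each element is a list with components
#'   `ts` (a `vertex_ts`), `parcellation`, and `assignment`.
#' @param min_frames Minimum retained frames for inclusion.
#' @param densities,avg_over Passed to [participation_coefficients()].
#' @return A list with `table` (data.frame, one row per included participant:
#'   `participant_id`, `mean_fd`, `within_<net>`, `between_<a>_<b>`,
#'   `pc_<net>`, `extent_<net>`) and `qc` (data.frame of participant id,
#'   retained frame count and inclusion flag).
#' @export
metrics_table <- function(participants, min_frames = 375,
                          densities = seq(0.01, 0.25, by = 0.01),
                          avg_over = 1:10) {
  stopifnot(is.list(participants), length(participants) > 0,
            !is.null(names(participants)))
  rows <- list(); qc <- list()
  for (pid in names(participants)) {
    p <- participants[[pid]]
    retained <- sum(p$ts$censor_mask)
    include <- qc_retained_frames(p$ts$censor_mask, min_frames)
    qc[[pid]] <- data.frame(participant_id = pid, retained_frames = retained,
                            included = include, stringsAsFactors = FALSE)
    if (!include) next
    pts <- parcel_timeseries(p$ts, p$parcellation)
    pcm <- parcel_connectivity(pts, p$parcellation$network,
                               p$parcellation$network_ids)
    wb <- within_between(pcm)
    pc <- participation_coefficients(pcm, densities, avg_over)
    ext <- spatial_extent(p$assignment)
    row <- c(list(participant_id = pid, mean_fd = p$ts$mean_fd),
             as.list(stats::setNames(wb$within, paste0("within_", names(wb$within)))),
             as.list(stats::setNames(wb$between, paste0("between_", names(wb$between)))),
             as.list(stats::setNames(pc$network, paste0("pc_", names(pc$network)))),
             as.list(stats::setNames(ext, paste0("extent_", names(ext)))))
    rows[[pid]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  table <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else NULL
  list(table = table, qc = do.call(rbind, c(qc, make.row.names = FALSE)))
}
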