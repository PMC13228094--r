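#' Dense vertex-to-vertex connectivity
#'
#' Pearson correlations between all vertex pairs over retained frames only.
#' Vertices with zero variance are flagged: their rows and columns are set to
#' `NA` and they are skipped by downstream template matching.
#'
#' @param ts A `vertex_ts`.
#' @return A symmetric vertices x vertices correlation matrix with attribute
#'   `zero_variance` (integer vertex indices).
#' @export
vertex_connectivity <- function(ts) {
  stopifnot(inherits(ts, "vertex_ts"))
  keep <- which(ts$censor_mask)
  if (length(keep) < 2L) stop("need at least 2 retained frames", call. = FALSE)
  x <- t(ts$data[, keep, drop = FALSE])
  sds <- apply(x, 2L, stats::sd)
  zv <- which(sds == 0)
  conn <- suppressWarnings(stats::cor(x))
  if (length(zv)) {
    warning(sprintf("%d zero-variance vertices flagged", length(zv)), call. = FALSE)
    conn[zv, ] <- NA_real_
    conn[, zv] <- NA_real_
  }
  attr(conn, "zero_variance") <- zv
  conn
}

#' Binarize the strongest fraction of a connectivity row
#'
#' Retains exactly `floor(fraction * length(row))` strongest entries (the row
#' must already exclude the self-connection). Ties at the cut are broken by
#' ascending vertex index, with a warning.
#'
#' @param conn_row Numeric vector of connectivity values for one vertex,
#'   self-connection excluded.
#' @param fraction Fraction of connections to retain, in (0, 1).
#' @return Integer 0/1 vector of the same length.
#' @export
binarize_top_fraction <- function(conn_row, fraction = 0.05) {
  stopifnot(is.numeric(conn_row), fraction > 0, fraction < 1)
  m <- floor(fraction * length(conn_row))
  if (m < 1) stop("fewer than one retained entry at this fraction", call. = FALSE)
  # order by descending value, ties by ascending index
  ord <- order(-conn_row, seq_along(conn_row))
  cut_val <- conn_row[ord[m]]
  if (m < length(conn_row) && conn_row[ord[m + 1L]] == cut_val) {
    warning("tie at the top-fraction cut; broken by ascending vertex index",
            call. = FALSE)
  }
  out <- integer(length(conn_row))
  out[ord[seq_len(m)]] <- 1L
  out
}

#' Dice coefficient of two binary maps
#'
#' `2 |a intersect b| / (|a| + |b|)`; defined as 0 when both maps are empty.
#'
#' @param a,b Binary (0/1 or logical) vectors of equal length.
#' @return Overlap similarity in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (length(a) != length(b)) stop("maps must have equal length", call. = FALSE)
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(0)
  2 * sum(a & b) / denom
}

#' Assign vertices to networks by Dice template matching
#'
#' For each vertex, the strongest `fraction` of its connections is binarized
#' into a spatial map; the map is compared to every network template by Dice
#' coefficient and the vertex is assigned to the network with the highest
#' Dice. A vertex whose map overlaps no template (all Dice zero), or that was
#' flagged as zero-variance, is left unassigned. Exact Dice ties go to the
#' lowest-index network and are counted.
#'
#' @param conn Dense connectivity matrix from [vertex_connectivity()].
#' @param templates A `network_templates` object on the same surface.
#' @param fraction Top fraction of connections retained per vertex.
#' @return A `vertex_assignment` object: list with `label` (integer network
#'   index or `NA`), `dice` (winning Dice value per vertex), `network_ids`,
#'   and `n_ties` (count of exact argmax ties).
#' @export
assign_vertices <- function(conn, templates, fraction = 0.05) {
  stopifnot(inherits(templates, "network_templates"),
            nrow(conn) == ncol(conn), nrow(conn) == nrow(templates$maps))
  n <- nrow(conn)
  maps <- templates$maps
  tsize <- colSums(maps)
  m <- floor(fraction * (n - 1L))
  if (m < 1) stop("fewer than one retained entry at this fraction", call. = FALSE)
  zv <- attr(conn, "zero_variance")
  label <- rep(NA_integer_, n)
  best <- rep(NA_real_, n)
  n_ties <- 0L
  # row-wise top-m selection; B[v, ] is the binarized map of vertex v
  bin <- matrix(0L, n, n)
  idx_seq <- seq_len(n)
  for (v in idx_seq) {
    if (length(zv) && v %in% zv) next
    row <- conn[v, ]
    row[v] <- -Inf  # exclude self-connection
    ord <- order(-row, idx_seq)
    bin[v, ord[seq_len(m)]] <- 1L
  }
  inter <- bin %*% maps                      # n x K intersection counts
  dice_mat <- 2 * inter / outer(rowSums(bin), tsize, "+")
  dice_mat[!is.finite(dice_mat)] <- 0
  for (v in idx_seq) {
    if (length(zv) && v %in% zv) next
    d <- dice_mat[v, ]
    if (all(d == 0)) next
    w <- which(d == max(d))
    if (length(w) > 1L) n_ties <- n_ties + 1L
    label[v] <- w[1L]
    best[v] <- d[w[1L]]
  }
  structure(list(label = label, dice = best,
                 network_ids = templates$network_ids, n_ties = n_ties),
            class = "vertex_assignment")
}

#' @export
print.vertex_assignment <- function(x, ...) {
  cat(sprintf("vertex_assignment: %d vertices, %d assigned, %d network ids, %d ties\n",
              length(x$label), sum(!is.na(x$label)), length(x$network_ids), x$n_ties))
  invisible(x)
}

# connected components of same-labelled vertices under surface adjacency;
# returns a list of integer vertex sets with a 'label' attribute each
same_label_components <- function(label, surface) {
  assigned <- which(!is.na(label))
  if (!length(assigned)) return(list())
  e <- surface$edges
  keep_e <- !is.na(label[e[, 1L]]) & !is.na(label[e[, 2L]]) &
    label[e[, 1L]] == label[e[, 2L]]
  g <- igraph::graph_from_edgelist(e[keep_e, , drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, surface$n_vertices - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  comps <- split(assigned, comp[assigned])
  lapply(comps, function(vs) structure(vs, label = label[vs[1L]]))
}

#' Remove small contiguous patches from an assignment
#'
#' Connected components of same-labelled vertices whose total surface area is
#' strictly less than `min_area` are set to unassigned; components at or above
#' the threshold are untouched.
#'
#' @param assignment A `vertex_assignment`.
#' @param surface The `surface_model` providing adjacency and vertex area.
#' @param min_area Minimum component area in mm^2.
#' @return The cleaned `vertex_assignment`, with attribute `n_removed`
#'   (number of removed components).
#' @export
remove_small_patches <- function(assignment, surface, min_area = 30) {
  stopifnot(inherits(assignment, "vertex_assignment"),
            inherits(surface, "surface_model"),
            length(assignment$label) == surface$n_vertices)
  comps <- same_label_components(assignment$label, surface)
  removed <- 0L
  for (comp in comps) {
    if (length(comp) * surface$vertex_area < min_area) {
      assignment$label[comp] <- NA_integer_
      assignment$dice[comp] <- NA_real_
      removed <- removed + 1L
    }
  }
  attr(assignment, "n_removed") <- removed
  assignment
}

#' Parcellate an assignment by network identity and contiguity
#'
#' One parcel per connected component of same-labelled vertices; unassigned
#' vertices are excluded. The parcel count varies per participant.
#'
#' @param assignment A `vertex_assignment` (after any small-patch cleanup).
#' @param surface The `surface_model`.
#' @return A `parcellation` object: list with `parcels` (list of integer
#'   vertex sets), `network` (integer network index per parcel) and
#'   `network_ids`.
#' @export
parcellate <- function(assignment, surface) {
  stopifnot(inherits(assignment, "vertex_assignment"),
            inherits(surface, "surface_model"))
  comps <- same_label_components(assignment$label, surface)
  if (!length(comps)) warning("zero parcels: no assigned vertices", call. = FALSE)
  # deterministic ordering: by smallest member vertex
  if (length(comps)) comps <- comps[order(vapply(comps, min, 1L))]
  structure(list(parcels = unname(lapply(comps, as.integer)),
                 network = vapply(comps, function(p) attr(p, "label"), 1L),
                 network_ids = assignment$network_ids),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("parcellation: %d parcels over %d networks\n",
              length(x$parcels), length(unique(x$network))))
  invisible(x)
}
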