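#' Build a lattice surface model
#'
#' Creates a rectangular lattice stand-in for a cortical surface mesh:
#' `rows * cols` vertices with 4-neighbourhood adjacency and a constant
#' per-vertex area. Area-based rules (such as small-patch removal) scale with
#' `vertex_area`, so the lattice preserves the contiguity and mm^2 semantics
#' of a real surface at desk scale.
#'
#' @param rows,cols Lattice dimensions; both must be at least 3 so that every
#'   vertex has at least two neighbours.
#' @param vertex_area Area attributed to each vertex, in mm^2.
#' @return An object of class `surface_model`: a list with `n_vertices`,
#'   `rows`, `cols`, `vertex_area`, `edges` (two-column integer matrix of
#'   adjacent vertex pairs, each unordered pair once) and `neighbors` (list of
#'   integer vectors, one per vertex).
#' @examples
#' surf <- make_surface(5, 5)
#' surf$n_vertices
#' @export
make_surface <- function(rows, cols, vertex_area = 1) {
  if (!is.numeric(rows) || !is.numeric(cols) || length(rows) != 1L ||
      length(cols) != 1L || rows < 3 || cols < 3 ||
      rows != as.integer(rows) || cols != as.integer(cols)) {
    stop("'rows' and 'cols' must be integers >= 3", call. = FALSE)
  }
  if (!is.numeric(vertex_area) || length(vertex_area) != 1L || vertex_area <= 0) {
    stop("'vertex_area' must be a positive scalar (mm^2)", call. = FALSE)
  }
  rows <- as.integer(rows); cols <- as.integer(cols)
  n <- rows * cols
  # vertex id = (r - 1) * cols + c, row-major
  id <- matrix(seq_len(n), nrow = rows, ncol = cols, byrow = TRUE)
  horiz <- cbind(as.vector(id[, -cols, drop = FALSE]), as.vector(id[, -1, drop = FALSE]))
  vert  <- cbind(as.vector(id[-rows, , drop = FALSE]), as.vector(id[-1, , drop = FALSE]))
  edges <- rbind(horiz, vert)
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  storage.mode(edges) <- "integer"
  nb <- vector("list", n)
  both <- rbind(edges, edges[, 2:1])
  split_nb <- split(both[, 2L], both[, 1L])
  nb[as.integer(names(split_nb))] <- lapply(split_nb, function(x) sort(as.integer(x)))
  structure(
    list(n_vertices = n, rows = rows, cols = cols, vertex_area = vertex_area,
         edges = edges, neighbors = nb),
    class = "surface_model"
  )
}

#' @export
print.surface_model <- function(x, ...) {
  cat(sprintf("surface_model: %d x %d lattice (%d vertices, %.3g mm^2/vertex)\n",
              x$rows, x$cols, x$n_vertices, x$vertex_area))
  invisible(x)
}

#' Generate contiguous network templates on a surface
#'
#' Partitions the surface into `K` contiguous patches by simultaneous seeded
#' region growing and returns both the template set (one binary map per
#' network) and the matching ground-truth vertex assignment. The default
#' `K = 8` mirrors the a-priori resting-state networks used throughout the
#' package (default mode, cingulo-opercular, dorsal attention, ventral
#' attention, salience, fronto-parietal, dorsal and ventral somato-motor).
#'
#' @param surface A `surface_model`.
#' @param K Number of networks (`2 <= K <= n_vertices`; `K = 1` is allowed and
#'   yields a single all-vertex map).
#' @param seed Integer seed; identical seeds give identical partitions.
#' @param network_ids Optional character vector of `K` labels.
#' @return A list with `templates` (class `network_templates`: `network_ids`
#'   and `maps`, a vertices-by-K 0/1 matrix) and `truth` (integer vector of
#'   network indices per vertex, class `vertex_labels`).
#' @export
make_templates <- function(surface, K = 8, seed = 1,
                           network_ids = NULL) {
  stopifnot(inherits(surface, "surface_model"))
  n <- surface$n_vertices
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K > n) {
    stop("'K' must satisfy 1 <= K <= n_vertices", call. = FALSE)
  }
  K <- as.integer(K)
  if (is.null(network_ids)) {
    network_ids <- if (K == 8L) {
      c("DMN", "CON", "DAN", "VAN", "SAL", "FPN", "DSM", "VSM")
    } else {
      sprintf("NET%02d", seq_len(K))
    }
  }
  stopifnot(length(network_ids) == K, !anyDuplicated(network_ids))
  label <- integer(n)  # 0 = unclaimed
  res <- local_rng(seed, {
    seeds <- sample.int(n, K)
    label[seeds] <- seq_len(K)
    # round-robin frontier growth: each network claims unclaimed neighbours of
    # its current frontier in turn, giving roughly balanced contiguous patches
    frontiers <- as.list(seeds)
    while (any(label == 0L)) {
      grew <- FALSE
      for (k in seq_len(K)) {
        fr <- frontiers[[k]]
        if (!length(fr)) next
        cand <- unique(unlist(surface$neighbors[fr], use.names = FALSE))
        cand <- cand[label[cand] == 0L]
        if (length(cand)) {
          # claim one shuffled neighbour per frontier pass to keep growth even
          take <- cand[sample.int(length(cand))]
          label[take] <- k
          frontiers[[k]] <- take
          grew <- TRUE
        } else {
          frontiers[[k]] <- integer(0)
        }
      }
      if (!grew && any(label == 0L)) {
        # disconnected leftovers cannot occur on a lattice, but guard anyway
        label[label == 0L] <- 1L
      }
    }
    label
  })
  maps <- matrix(0L, nrow = n, ncol = K, dimnames = list(NULL, network_ids))
  maps[cbind(seq_len(n), res)] <- 1L
  templates <- structure(list(network_ids = network_ids, maps = maps),
                         class = "network_templates")
  truth <- structure(res, network_ids = network_ids, class = "vertex_labels")
  list(templates = templates, truth = truth)
}

#' @export
print.network_templates <- function(x, ...) {
  cat(sprintf("network_templates: %d networks over %d vertices (%s)\n",
              length(x$network_ids), nrow(x$maps),
              paste(x$network_ids, collapse = ", ")))
  invisible(x)
}

#' Perturb a vertex assignment to emulate individual topography
#'
#' Relabels a fraction of boundary vertices (vertices adjacent to a different
#' network) to a neighbouring network's label, emulating inter-individual
#' variability in the location and extent of functional networks around a
#' shared group-level layout.
#'
#' @param truth Integer `vertex_labels` vector (network index per vertex,
#'   `NA` allowed for unassigned).
#' @param surface The `surface_model` the labels live on.
#' @param swap_frac Fraction of boundary vertices to relabel, in `[0, 0.5)`.
#' @param seed Integer seed.
#' @return A perturbed `vertex_labels` vector.
#' @export
perturb_individual <- function(truth, surface, swap_frac = 0.1, seed = 1) {
  stopifnot(inherits(surface, "surface_model"),
            length(truth) == surface$n_vertices)
  if (!is.numeric(swap_frac) || length(swap_frac) != 1L ||
      swap_frac < 0 || swap_frac >= 0.5) {
    stop("'swap_frac' must lie in [0, 0.5)", call. = FALSE)
  }
  lab <- as.integer(truth)
  if (swap_frac == 0) return(structure(lab, network_ids = attr(truth, "network_ids"),
                                       class = "vertex_labels"))
  # boundary vertex: has a neighbour carrying a different (non-NA) label
  other <- lapply(seq_along(lab), function(v) {
    nb <- lab[surface$neighbors[[v]]]
    unique(nb[!is.na(nb) & !is.na(lab[v]) & nb != lab[v]])
  })
  boundary <- which(lengths(other) > 0L)
  if (!length(boundary)) return(structure(lab, network_ids = attr(truth, "network_ids"),
                                          class = "vertex_labels"))
  n_swap <- max(1L, as.integer(round(swap_frac * length(boundary))))
  local_rng(seed, {
    pick <- boundary[sample.int(length(boundary), n_swap)]
    for (v in pick) {
      opts <- other[[v]]
      lab[v] <- if (length(opts) == 1L) opts else opts[sample.int(length(opts), 1L)]
    }
  })
  structure(lab, network_ids = attr(truth, "network_ids"), class = "vertex_labels")
}

# Run an expression under a temporary RNG state so generators are
# deterministic under their own seed without disturbing the caller's stream.
local_rng <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic derivation of stage seeds from one master seed (documented
# splitting scheme: multiply-and-offset modulo the 32-bit integer range).
derive_seed <- function(master, stage) {
  as.integer((as.double(master) * 7919 + 104729 * stage) %% 2147483647)
}
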