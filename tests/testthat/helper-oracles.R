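# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals: plain loops,
# direct formulas.

# exhaustive template matching: per-vertex top-m map, full Dice table, argmax
oracle_assign <- function(conn, maps, fraction = 0.05) {
  n <- nrow(conn)
  K <- ncol(maps)
  m <- floor(fraction * (n - 1))
  label <- rep(NA_integer_, n)
  best <- rep(NA_real_, n)
  for (v in seq_len(n)) {
    row <- conn[v, ]
    row[v] <- -Inf
    ord <- order(-row, seq_len(n))
    bmap <- rep(0L, n)
    bmap[ord[seq_len(m)]] <- 1L
    dv <- numeric(K)
    for (k in seq_len(K)) {
      den <- sum(bmap) + sum(maps[, k])
      dv[k] <- if (den == 0) 0 else 2 * sum(bmap == 1 & maps[, k] == 1) / den
    }
    if (any(dv > 0)) {
      label[v] <- which.max(dv)
      best[v] <- max(dv)
    }
  }
  list(label = label, dice = best)
}

# direct summation participation coefficients over a density grid
oracle_pc <- function(z, net, densities, avg_over) {
  n <- nrow(z)
  K <- max(net)
  up <- which(upper.tri(z), arr.ind = TRUE)
  w <- z[up]
  ord <- order(-w, seq_len(nrow(up)))
  node <- matrix(0, n, length(densities))
  for (di in seq_along(densities)) {
    m <- floor(densities[di] * nrow(up))
    if (m < 1) next
    sel <- up[ord[seq_len(m)], , drop = FALSE]
    for (v in seq_len(n)) {
      nb <- c(sel[sel[, 1] == v, 2], sel[sel[, 2] == v, 1])
      if (!length(nb)) next
      s <- 0
      for (k in seq_len(K)) s <- s + (sum(net[nb] == k) / length(nb))^2
      node[v, di] <- 1 - s
    }
  }
  rowMeans(node[, avg_over, drop = FALSE])
}

# two-pass Pearson correlation from the covariance formula
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# connected components of same-labelled vertices by explicit flood fill
oracle_components <- function(label, neighbors) {
  n <- length(label)
  seen <- logical(n)
  comps <- list()
  for (v in seq_len(n)) {
    if (seen[v] || is.na(label[v])) next
    queue <- v
    seen[v] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      members <- c(members, u)
      for (w in neighbors[[u]]) {
        if (!seen[w] && !is.na(label[w]) && label[w] == label[u]) {
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}

# random binary template partition over n vertices (not contiguous; used
# only where contiguity is irrelevant)
random_partition_templates <- function(n, K) {
  lab <- sample(K, n, TRUE)
  maps <- matrix(0L, n, K, dimnames = list(NULL, sprintf("N%d", seq_len(K))))
  maps[cbind(seq_len(n), lab)] <- 1L
  structure(list(network_ids = colnames(maps), maps = maps),
            class = "network_templates")
}
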