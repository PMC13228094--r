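make_parc <- function(parcels, network, ids) {
  structure(list(parcels = parcels, network = as.integer(network),
                 network_ids = ids), class = "parcellation")
}

test_that("parcel time series are plain member averages over retained frames", {
  x <- rbind(a = rep(2, 10), b = rep(2, 10), c = 1:10, d = -(1:10))
  ts <- vertex_ts(x, tr = 0.8)
  parc <- make_parc(list(c(1, 2), c(3, 4)), c(1, 2), c("A", "B"))
  pts <- parcel_timeseries(ts, parc)
  expect_equal(pts[1, ], rep(2, 10))          # identical members
  expect_equal(pts[2, ], rep(0, 10))          # x and -x cancel

  set.seed(4)
  y <- matrix(rnorm(8 * 30), 8)
  parc4 <- make_parc(list(1:2, 3:4, 5:6, 7:8), 1:4, sprintf("N%d", 1:4))
  pts4 <- parcel_timeseries(vertex_ts(y), parc4)
  for (p in 1:4) {
    expect_equal(pts4[p, ], colMeans(y[parc4$parcels[[p]], ]), tolerance = 1e-12)
  }
  # retained frames only
  mask <- c(rep(TRUE, 20), rep(FALSE, 10))
  pts_m <- parcel_timeseries(vertex_ts(y, censor_mask = mask), parc4)
  expect_equal(ncol(pts_m), 20L)
})

test_that("Fisher Z is the clipped atanh and is odd", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  r <- seq(0.1, 0.9, by = 0.1)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(is.finite(fisher_z(1)))
  expect_error(fisher_z(1.2), "<= 1")
})

test_that("within/between averaging matches explicit pair enumeration", {
  # a network with exactly two parcels reports their Z
  z2 <- matrix(0, 3, 3); z2[1, 2] <- z2[2, 1] <- 0.8
  pcm2 <- structure(list(z = z2, network = c(1L, 1L, 2L),
                         network_ids = c("A", "B")),
                    class = "parcel_connectivity")
  wb2 <- within_between(pcm2)
  expect_equal(unname(wb2$within["A"]), 0.8)
  expect_true(is.na(wb2$within["B"]))         # single-parcel network

  set.seed(5)
  n <- 10
  z <- matrix(rnorm(n * n), n); z <- (z + t(z)) / 2; diag(z) <- 0
  net <- c(1, 1, 1, 2, 2, 2, 2, 3, 3, 3)
  pcm <- structure(list(z = z, network = as.integer(net),
                        network_ids = c("A", "B", "C")),
                   class = "parcel_connectivity")
  wb <- within_between(pcm)
  for (k in 1:3) {
    idx <- which(net == k)
    pairs <- utils::combn(idx, 2)
    expect_equal(unname(wb$within[k]),
                 mean(z[cbind(pairs[1, ], pairs[2, ])]), tolerance = 1e-12)
  }
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    vals <- as.vector(z[net == pair[1], net == pair[2]])
    nm <- paste(c("A", "B", "C")[pair], collapse = "_")
    expect_equal(unname(wb$between[nm]), mean(vals), tolerance = 1e-12)
  }
  # invariant to parcel ordering
  perm <- sample(n)
  pcm_p <- structure(list(z = z[perm, perm], network = as.integer(net[perm]),
                          network_ids = c("A", "B", "C")),
                     class = "parcel_connectivity")
  wb_p <- within_between(pcm_p)
  expect_equal(wb_p$within, wb$within, tolerance = 1e-12)
  expect_equal(wb_p$between, wb$between, tolerance = 1e-12)
})

test_that("participation coefficients follow the direct-summation formula", {
  # node with every edge inside its own network has PC 0
  z <- matrix(0, 4, 4)
  z[1, 2] <- z[2, 1] <- 0.9; z[1, 3] <- z[3, 1] <- 0.8
  pcm <- structure(list(z = z, network = c(1L, 1L, 1L, 2L),
                        network_ids = c("A", "B")),
                   class = "parcel_connectivity")
  pc <- participation_coefficients(pcm, densities = 1/3, avg_over = 1)
  expect_equal(pc$node[1, 1], 0)              # both edges stay inside A

  # 4 edges into 4 distinct networks: PC = 1 - 4 * (1/4)^2 = 0.75
  z5 <- matrix(0, 5, 5)
  z5[1, 2:5] <- z5[2:5, 1] <- c(0.9, 0.8, 0.7, 0.6)
  pcm5 <- structure(list(z = z5, network = c(1L, 2L, 3L, 4L, 5L),
                         network_ids = sprintf("N%d", 1:5)),
                    class = "parcel_connectivity")
  pc5 <- participation_coefficients(pcm5, densities = 0.4, avg_over = 1)
  expect_equal(pc5$node[1, 1], 0.75)

  # brute-force oracle agreement on seeded 20-node graphs
  set.seed(6)
  for (i in 1:5) {
    zz <- stats::cor(t(matrix(rnorm(20 * 40), 20))); diag(zz) <- 0
    netp <- sample(3, 20, TRUE)
    pcmz <- structure(list(z = zz, network = netp,
                           network_ids = c("A", "B", "C")),
                      class = "parcel_connectivity")
    got <- participation_coefficients(pcmz)
    want <- oracle_pc(zz, netp, seq(0.01, 0.25, by = 0.01), 1:10)
    expect_equal(got$node_mean, want, tolerance = 1e-12)
    # PC is invariant to permuting network labels
    relab <- c(2L, 3L, 1L)[netp]
    pcm_r <- structure(list(z = zz, network = relab,
                            network_ids = c("A", "B", "C")),
                       class = "parcel_connectivity")
    expect_equal(participation_coefficients(pcm_r)$node_mean, got$node_mean,
                 tolerance = 1e-12)
    # increasing tie density never decreases any node's degree
    up <- which(upper.tri(zz), arr.ind = TRUE)
    ord <- order(-zz[up], seq_len(nrow(up)))
    degs <- sapply(seq(0.01, 0.25, by = 0.01), function(d) {
      m <- floor(d * nrow(up))
      sel <- up[ord[seq_len(m)], , drop = FALSE]
      tabulate(c(sel), nbins = 20)
    })
    expect_true(all(apply(degs, 1, function(k) all(diff(k) >= 0))))
    # bound: PC <= 1 - 1/S for S available networks
    expect_true(all(got$node <= 1 - 1/3 + 1e-12))
    expect_true(all(got$node >= 0))
  }
})

test_that("spatial extent counts labels exactly and conserves vertices", {
  asg <- structure(list(label = c(rep(1L, 1600)), dice = rep(1, 1600),
                        network_ids = sprintf("N%d", 1:4), n_ties = 0L),
                   class = "vertex_assignment")
  expect_equal(unname(spatial_extent(asg)), c(1600L, 0L, 0L, 0L))

  set.seed(7)
  lab <- sample(c(1:4, NA), 500, TRUE)
  asg2 <- structure(list(label = as.integer(lab), dice = rep(1, 500),
                         network_ids = sprintf("N%d", 1:4), n_ties = 0L),
                    class = "vertex_assignment")
  ext <- spatial_extent(asg2)
  expect_equal(sum(ext) + sum(is.na(lab)), 500L)
})

test_that("the metric table has the documented shape and applies frame QC", {
  surf <- make_surface(10, 10)
  tpl <- make_templates(surf, K = 8, seed = 2)
  cfg <- bold_sim_config(frames_per_run = 100, n_runs = 2, within_corr = 0.6,
                         between_corr = 0, censor_prob = 0)
  mk <- function(seed, retained) {
    asg <- perturb_individual(tpl$truth, surf, 0.15, seed = seed)
    ts <- simulate_bold(surf, asg, cfg, seed = seed)
    ts$censor_mask[seq_len(ncol(ts$data) - retained)] <- FALSE
    asg_obj <- structure(list(label = as.integer(asg), dice = rep(1, 100),
                              network_ids = tpl$templates$network_ids,
                              n_ties = 0L), class = "vertex_assignment")
    list(ts = ts, parcellation = parcellate(asg_obj, surf),
         assignment = asg_obj)
  }
  participants <- list(P1 = mk(1, 150), P2 = mk(2, 150), P3 = mk(3, 80))
  mt <- metrics_table(participants, min_frames = 100)
  expect_equal(nrow(mt$table), 2L)
  expect_false("P3" %in% mt$table$participant_id)
  expect_true("P3" %in% mt$qc$participant_id)
  expect_false(mt$qc$included[mt$qc$participant_id == "P3"])
  cols <- names(mt$table)
  expect_equal(sum(startsWith(cols, "within_")), 8L)
  expect_equal(sum(startsWith(cols, "between_")), choose(8, 2))  # 28 pairs
  expect_equal(sum(startsWith(cols, "pc_")), 8L)
  expect_equal(sum(startsWith(cols, "extent_")), 8L)
  expect_true("mean_fd" %in% cols)
})
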