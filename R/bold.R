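#' Configuration for the BOLD-like time-series generator
#'
#' The generator plants a block correlation structure: every vertex in
#' network s follows `sqrt(rho_w) * L_s(t) + sqrt(rho_b) * G(t) +
#' sqrt(1 - rho_w - rho_b) * eps_v(t)` with independent standard-normal
#' latents, so the expected vertex-pair correlation is `rho_w + rho_b` within
#' a network and `rho_b` between networks. Frame censoring is independent
#' Bernoulli per frame; mean framewise displacement is drawn from a lognormal
#' and used only as a participant-level covariate.
#'
#' @param frames_per_run,n_runs Run structure; defaults mirror two six-minute
#'   runs of 460 frames each.
#' @param within_corr,between_corr Planted correlations (`0 <= between_corr
#'   <= within_corr < 1`, `within_corr + between_corr < 1`).
#' @param censor_prob Per-frame probability of motion censoring.
#' @param fd_meanlog,fd_sdlog Lognormal parameters for mean framewise
#'   displacement (mm).
#' @param ar1 Optional AR(1) coefficient applied to every latent series
#'   (0 disables temporal autocorrelation; marginal variances are preserved).
#' @param tr Frame duration in seconds.
#' @return A list of class `bold_sim_config`.
#' @export
bold_sim_config <- function(frames_per_run = 460, n_runs = 2,
                            within_corr = 0.4, between_corr = 0.05,
                            censor_prob = 0.1,
                            fd_meanlog = log(0.15), fd_sdlog = 0.4,
                            ar1 = 0, tr = 0.8) {
  stopifnot(frames_per_run >= 1, n_runs >= 1,
            within_corr >= 0, within_corr < 1,
            between_corr >= 0, between_corr <= within_corr,
            censor_prob >= 0, censor_prob < 1,
            ar1 >= 0, ar1 < 1, tr > 0)
  if (within_corr + between_corr >= 1) {
    stop("'within_corr' + 'between_corr' must be < 1", call. = FALSE)
  }
  structure(list(frames_per_run = as.integer(frames_per_run),
                 n_runs = as.integer(n_runs),
                 within_corr = within_corr, between_corr = between_corr,
                 censor_prob = censor_prob,
                 fd_meanlog = fd_meanlog, fd_sdlog = fd_sdlog,
                 ar1 = ar1, tr = tr),
            class = "bold_sim_config")
}

#' Simulate vertex time series with planted network structure
#'
#' @param surface A `surface_model`.
#' @param assignment Integer network label per vertex (`vertex_labels`).
#' @param cfg A [bold_sim_config()].
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A `vertex_ts` object: list with `data` (vertices x frames matrix),
#'   `censor_mask` (logical, TRUE = frame retained), `tr`, and `mean_fd`.
#' @export
simulate_bold <- function(surface, assignment, cfg = bold_sim_config(), seed = 1) {
  stopifnot(inherits(surface, "surface_model"),
            inherits(cfg, "bold_sim_config"),
            length(assignment) == surface$n_vertices)
  lab <- as.integer(assignment)
  if (anyNA(lab)) stop("assignment must cover the surface", call. = FALSE)
  n_v <- surface$n_vertices
  t_total <- cfg$frames_per_run * cfg$n_runs
  nets <- sort(unique(lab))
  local_rng(seed, {
    latents <- matrix(stats::rnorm(length(nets) * t_total), length(nets), t_total)
    global <- stats::rnorm(t_total)
    if (cfg$ar1 > 0) {
      latents <- t(apply(latents, 1L, ar1_filter, phi = cfg$ar1))
      global <- ar1_filter(global, cfg$ar1)
    }
    noise <- matrix(stats::rnorm(n_v * t_total), n_v, t_total)
    if (cfg$ar1 > 0) noise <- t(apply(noise, 1L, ar1_filter, phi = cfg$ar1))
    w <- sqrt(cfg$within_corr); b <- sqrt(cfg$between_corr)
    e <- sqrt(1 - cfg$within_corr - cfg$between_corr)
    dat <- w * latents[match(lab, nets), , drop = FALSE] +
      b * matrix(global, n_v, t_total, byrow = TRUE) + e * noise
    mask <- stats::runif(t_total) >= cfg$censor_prob
    fd <- stats::rlnorm(1, cfg$fd_meanlog, cfg$fd_sdlog)
    vertex_ts(dat, censor_mask = mask, tr = cfg$tr, mean_fd = fd)
  })
}

# stationary AR(1) recoloring that preserves unit marginal variance
ar1_filter <- function(x, phi) {
  y <- numeric(length(x))
  y[1] <- x[1]
  for (t in seq_along(x)[-1]) y[t] <- phi * y[t - 1] + sqrt(1 - phi^2) * x[t]
  y
}

#' Construct a vertex time-series object
#'
#' @param data Numeric vertices x frames matrix.
#' @param censor_mask Logical vector, one entry per frame; `TRUE` marks a
#'   retained (low-motion) frame.
#' @param tr Frame duration in seconds.
#' @param mean_fd Participant mean framewise displacement (mm), carried as a
#'   covariate.
#' @return An object of class `vertex_ts`.
#' @export
vertex_ts <- function(data, censor_mask = rep(TRUE, ncol(data)), tr = 0.8,
                      mean_fd = NA_real_) {
  data <- as.matrix(data)
  if (length(censor_mask) != ncol(data)) {
    stop("censor mask length must equal the frame count", call. = FALSE)
  }
  structure(list(data = data, censor_mask = as.logical(censor_mask),
                 tr = tr, mean_fd = mean_fd),
            class = "vertex_ts")
}

#' @export
print.vertex_ts <- function(x, ...) {
  cat(sprintf("vertex_ts: %d vertices x %d frames (%d retained), TR = %.3g s\n",
              nrow(x$data), ncol(x$data), sum(x$censor_mask), x$tr))
  invisible(x)
}

#' Frame-count quality control
#'
#' A participant's scan is usable only if enough low-motion frames survive
#' censoring; the default minimum of 375 frames corresponds to five minutes
#' of data at TR = 0.8 s.
#'
#' @param mask Logical censor mask (TRUE = retained frame).
#' @param minimum Minimum retained-frame count for inclusion.
#' @return `TRUE` (include) or `FALSE` (exclude).
#' @export
qc_retained_frames <- function(mask, minimum = 375) {
  sum(as.logical(mask)) >= minimum
}

#' Clean vertex time series
#'
#' Applies, in order: frame censoring, per-vertex demeaning and linear
#' detrending, nuisance regression, and band-pass filtering. All regression
#' fits use retained frames only; censored frames are dropped and the
#' retained frames are treated as contiguous for filtering. The band-pass is
#' a frequency-domain (FFT) filter that zeroes Fourier components outside
#' `(band[1], band[2])` Hz.
#'
#' @param ts A `vertex_ts`.
#' @param nuisance Optional numeric matrix of nuisance regressors, one row
#'   per original frame (motion parameters, global signals, ...). Columns
#'   collinear with the intercept/trend or with earlier columns are dropped
#'   with a warning.
#' @param band Band-pass limits in Hz, `0 <= low < high < ` Nyquist; `NULL`
#'   skips filtering.
#' @return A cleaned `vertex_ts` containing retained frames only (its mask is
#'   all-TRUE).
#' @export
clean_timeseries <- function(ts, nuisance = NULL, band = c(0.01, 0.1)) {
  stopifnot(inherits(ts, "vertex_ts"))
  keep <- which(ts$censor_mask)
  if (length(keep) < 2L) stop("fewer than 2 retained frames", call. = FALSE)
  x <- ts$data[, keep, drop = FALSE]
  t_idx <- seq_along(keep)
  basis <- cbind(intercept = 1, trend = t_idx - mean(t_idx))
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != length(ts$censor_mask)) {
      stop("nuisance rows must align with frames", call. = FALSE)
    }
    nuisance <- nuisance[keep, , drop = FALSE]
    full <- cbind(basis, nuisance)
    qr_full <- qr(full)
    if (qr_full$rank < ncol(full)) {
      drop_cols <- qr_full$pivot[seq.int(qr_full$rank + 1L, ncol(full))]
      warning(sprintf("dropping %d collinear nuisance column(s)",
                      length(drop_cols)), call. = FALSE)
      full <- full[, -drop_cols, drop = FALSE]
    }
    basis <- full
  }
  # residualize: demean + detrend + nuisance in one least-squares projection
  fit <- qr(basis)
  resid <- t(qr.resid(fit, t(x)))
  if (!is.null(band)) {
    nyq <- 1 / (2 * ts$tr)
    if (!(band[1] >= 0 && band[1] < band[2] && band[2] < nyq)) {
      stop(sprintf("band must satisfy 0 <= low < high < Nyquist (%.3g Hz)", nyq),
           call. = FALSE)
    }
    resid <- bandpass_fft(resid, ts$tr, band[1], band[2])
  }
  vertex_ts(resid, censor_mask = rep(TRUE, ncol(resid)), tr = ts$tr,
            mean_fd = ts$mean_fd)
}

# zero Fourier components with frequency outside (low, high); operates on a
# vertices x frames matrix
bandpass_fft <- function(x, tr, low, high) {
  n <- ncol(x)
  freq <- c(0, seq_len(n - 1)) / (n * tr)
  freq <- pmin(freq, 1 / tr - freq)  # fold to physical frequency
  keep <- freq > low & freq < high
  xf <- t(stats::mvfft(t(x)))
  xf[, !keep] <- 0
  Re(t(stats::mvfft(t(xf), inverse = TRUE))) / n
}
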