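#' Ground-truth tuning curves for a simulated place-cell population
#'
#' Draws Gaussian-bump place fields: centres uniform over the environment,
#' a common tuning width, per-cell peak rates, and a low spatially uniform
#' baseline. Cells flagged as non-place cells get a flat tuning curve at the
#' baseline rate. Defaults emulate dorsal CA1 ensembles of a few dozen
#' pyramidal cells with mean rates around 1-1.5 Hz.
#'
#' @param env A [spatial_env()].
#' @param n_cells Number of cells.
#' @param n_nonplace How many of them are non-place (flat-tuned) cells.
#' @param peak_rate Range (length-2) the per-cell peak rates are drawn from
#'   uniformly, Hz.
#' @param width Tuning-curve SD in cm.
#' @param baseline Baseline rate in Hz, added everywhere.
#' @param seed RNG seed.
#'
#' @return An object of class `ground_truth_fields`: list with `centers`
#'   (cells x dims matrix), `widths`, `peak_rates`, `baseline`,
#'   `is_place_cell`, and the environment.
#' @export
make_ground_truth_fields <- function(env, n_cells = 49, n_nonplace = 0,
                                     peak_rate = c(5, 15), width = 12,
                                     baseline = 0.1, seed = NULL) {
  stopifnot(n_cells >= 1, n_nonplace >= 0, n_nonplace <= n_cells)
  with_seed(seed, {
    d <- if (env$is2d) 2L else 1L
    centers <- matrix(stats::runif(n_cells * d), n_cells, d)
    centers <- centers * matrix(rep(env$extent, length.out = d),
                                n_cells, d, byrow = TRUE)
    peaks <- stats::runif(n_cells, peak_rate[1], peak_rate[2])
    isp <- rep(TRUE, n_cells)
    if (n_nonplace > 0) {
      np <- sample.int(n_cells, n_nonplace)
      isp[np] <- FALSE
      peaks[np] <- baseline
    }
    structure(list(centers = centers, widths = rep(width, n_cells),
                   peak_rates = peaks, baseline = baseline,
                   is_place_cell = isp, env = env),
              class = "ground_truth_fields")
  })
}

#' Evaluate ground-truth firing rates at given positions
#'
#' Gaussian tuning: `baseline + (peak - baseline) * exp(-d^2 / (2 w^2))`
#' where `d` is the (environment-appropriate) distance from the field
#' centre. Non-place cells return their flat baseline rate everywhere.
#'
#' @param fields A [make_ground_truth_fields()] object.
#' @param pos Positions: vector (1-D) or 2-column matrix (2-D), cm.
#' @return Rate matrix, cells x positions, Hz.
#' @export
field_rates <- function(fields, pos) {
  env <- fields$env
  pos <- as.matrix(pos)
  C <- length(fields$peak_rates)
  out <- matrix(fields$baseline, C, nrow(pos))
  for (c in seq_len(C)) {
    if (!fields$is_place_cell[c]) {
      out[c, ] <- fields$peak_rates[c]  # flat tuning
      next
    }
    d <- position_distance(pos,
                           matrix(fields$centers[c, ], nrow(pos), ncol(pos),
                                  byrow = TRUE), env)
    out[c, ] <- fields$baseline +
      (fields$peak_rates[c] - fields$baseline) * exp(-d^2 / (2 * fields$widths[c]^2))
  }
  out
}

#' Simulate an animal trajectory
#'
#' Linear track: back-and-forth laps at a jittered speed. Circular track:
#' unidirectional laps. Open field: a smooth random walk (Ornstein-Uhlenbeck
#' speed around `mean_speed`, slowly drifting heading) with reflecting
#' boundaries. Sampled at `fs` Hz (default 60, the usual video-tracking
#' rate).
#'
#' @param env A [spatial_env()].
#' @param duration Duration in seconds.
#' @param mean_speed Mean running speed, cm/s.
#' @param fs Sampling rate, Hz.
#' @param seed RNG seed.
#' @return A [trajectory()].
#' @export
simulate_trajectory <- function(env, duration, mean_speed = 25, fs = 60,
                                seed = NULL) {
  if (!is.numeric(duration) || duration <= 0)
    stop("`duration` must be positive", call. = FALSE)
  if (!is.numeric(mean_speed) || mean_speed <= 0)
    stop("`mean_speed` must be positive", call. = FALSE)
  with_seed(seed, {
    n <- max(2L, floor(duration * fs))
    t <- (seq_len(n) - 1L) / fs
    dt <- 1 / fs
    # jittered speed, mean-reverting, floored at 0
    sp <- numeric(n)
    sp[1] <- mean_speed
    sig <- 0.3 * mean_speed
    for (i in 2:n)
      sp[i] <- max(0, sp[i - 1] + 0.05 * (mean_speed - sp[i - 1]) +
                     sig * sqrt(dt) * stats::rnorm(1))
    if (env$kind == "linear_track") {
      # fold cumulative arc distance into back-and-forth laps
      s <- cumsum(sp * dt) %% (2 * env$extent)
      x <- ifelse(s <= env$extent, s, 2 * env$extent - s)
      trajectory(t, x, env = env)
    } else if (env$kind == "circular_track") {
      x <- cumsum(sp * dt) %% env$extent
      trajectory(t, x, env = env)
    } else {
      w <- env$extent[1]; h <- env$extent[2]
      x <- numeric(n); y <- numeric(n)
      x[1] <- w / 2; y[1] <- h / 2
      th <- stats::runif(1, 0, 2 * pi)
      for (i in 2:n) {
        th <- th + 0.8 * sqrt(dt) * stats::rnorm(1)
        nx <- x[i - 1] + sp[i] * cos(th) * dt
        ny <- y[i - 1] + sp[i] * sin(th) * dt
        # reflecting boundaries
        if (nx < 0) { nx <- -nx; th <- pi - th }
        if (nx > w) { nx <- 2 * w - nx; th <- pi - th }
        if (ny < 0) { ny <- -ny; th <- -th }
        if (ny > h) { ny <- 2 * h - ny; th <- -th }
        x[i] <- min(max(nx, 0), w); y[i] <- min(max(ny, 0), h)
      }
      trajectory(t, x, y, env = env)
    }
  })
}

#' Sample Poisson spike counts along a trajectory
#'
#' The generative twin of the decoding likelihood: within each temporal bin
#' of width `delta`, the count of cell `c` is Poisson with mean
#' `lambda_c(pos) * delta`, where `pos` is the mean trajectory position in
#' the bin; counts are independent across cells and bins given position.
#'
#' @param fields A [make_ground_truth_fields()] object.
#' @param traj A [trajectory()].
#' @param delta Bin width, s.
#' @param seed RNG seed.
#' @return A [spike_matrix()], with the per-bin positions attached as
#'   attribute `"bin_pos"`.
#' @export
sample_spike_counts <- function(fields, traj, delta, seed = NULL) {
  if (delta <= 0) stop("`delta` must be positive", call. = FALSE)
  span <- traj$t[nrow(traj)] - traj$t[1]
  n <- floor(span / delta + 1e-9)
  if (n < 1L) stop("trajectory shorter than one bin", call. = FALSE)
  t0 <- traj$t[1]
  pos <- bin_trajectory(traj, delta = delta, t0 = t0, n = n)
  lam <- field_rates(fields, pos_matrix(pos))
  with_seed(seed, {
    counts <- matrix(stats::rpois(length(lam), lam * delta),
                     nrow(lam), ncol(lam))
    sm <- spike_matrix(counts, delta = delta, t0 = t0)
    attr(sm, "bin_pos") <- pos
    sm
  })
}

#' Synthesise a time-compressed replay event
#'
#' Builds a sharp-wave-ripple-like event: the population traverses a spatial
#' `path` at one path point per 20-ms bin, with firing rates scaled up by
#' `gain` to mimic the compressed-timescale population burst, sampled
#' through the same Poisson model as behaviour. A multi-unit activity (MUA)
#' trace is also returned: baseline population counts with the event
#' superimposed at a known onset, for exercising the candidate-event
#' detector.
#'
#' @param fields A [make_ground_truth_fields()] object.
#' @param path Positions (vector or 2-column matrix, >= 2 rows) visited by
#'   the virtual traversal, one per temporal bin.
#' @param delta Bin width, s (default 0.02, the ripple timescale).
#' @param gain Multiplicative rate gain during the event.
#' @param direction `"forward"` or `"reverse"`; reverse flips the path.
#' @param baseline_bins Number of baseline bins padded on each side of the
#'   event in the MUA trace.
#' @param baseline_rate Per-cell baseline rate during non-event bins, Hz.
#' @param seed RNG seed.
#'
#' @return List with `event` (a [spike_matrix()] covering only the event
#'   bins), `mua` (integer vector: population counts for baseline + event +
#'   baseline), `onset_bin` (first event bin within the MUA trace),
#'   `direction`, and `path` (the traversed positions, after any reversal).
#' @export
make_replay_event <- function(fields, path, delta = 0.02, gain = 5,
                              direction = c("forward", "reverse"),
                              baseline_bins = 250, baseline_rate = 0.5,
                              seed = NULL) {
  direction <- match.arg(direction)
  path <- as.matrix(path)
  if (nrow(path) < 2L) stop("`path` needs at least 2 positions", call. = FALSE)
  if (direction == "reverse") path <- path[nrow(path):1, , drop = FALSE]
  lam <- field_rates(fields, path) * gain
  C <- nrow(lam)
  with_seed(seed, {
    ev <- matrix(stats::rpois(length(lam), lam * delta), C, ncol(lam))
    base_pre <- matrix(stats::rpois(C * baseline_bins, baseline_rate * delta),
                       C, baseline_bins)
    base_post <- matrix(stats::rpois(C * baseline_bins, baseline_rate * delta),
                        C, baseline_bins)
    mua <- c(colSums(base_pre), colSums(ev), colSums(base_post))
    list(event = spike_matrix(ev, delta = delta),
         mua = as.integer(mua),
         onset_bin = baseline_bins + 1L,
         direction = direction,
         path = path)
  })
}
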