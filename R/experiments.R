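#' Idealised place-field map from ground-truth tuning curves
#'
#' Evaluates the generator's tuning curves at the spatial bin centres,
#' yielding the noiseless encoder a simulation study can hand to the
#' supervised decoder (uniform occupancy, every bin visited).
#'
#' @param fields A [make_ground_truth_fields()] object.
#' @param env A [spatial_env()] (default: the fields' environment).
#' @return A `place_field_map`.
#' @export
true_field_map <- function(fields, env = fields$env) {
  bins <- spatial_bins(env)
  lambda <- field_rates(fields, bins$centers)
  structure(list(lambda = lambda,
                 occupancy = rep(1 / bins$n, bins$n),
                 occupancy_time = rep(1, bins$n),
                 mask = rep(TRUE, bins$n),
                 bins = bins, env = env,
                 cell_ids = seq_len(nrow(lambda)),
                 smoothing = "none (analytic)"),
            class = "place_field_map")
}

#' Monte-Carlo sweep of representation power
#'
#' For each run, simulates a fresh behavioural session from fixed
#' ground-truth tuning curves, bins and speed-filters it, estimates place
#' fields (encoding phase), then for every grid condition builds the
#' sleep-like epoch structure and scores both decoders by their median
#' decoding error. Grid conditions within a run share the same simulated
#' substrate, so conditions are compared pairwise across runs.
#'
#' @param fields Ground-truth tuning curves ([make_ground_truth_fields()]).
#' @param grid Data frame of conditions with any of the columns `T0`, `rho`,
#'   `delta` (s), `per_epoch`, `thin` (missing columns get defaults
#'   `T0 = 10`, `rho = 1`, `delta = 0.25`, `per_epoch = FALSE`,
#'   `thin = FALSE`).
#' @param duration Session duration, s.
#' @param mean_speed Mean running speed, cm/s.
#' @param speed_threshold Speed filter, cm/s.
#' @param decoders Subset of `c("rf", "norf")`.
#' @param cell_subset Optional cell indices restricting the population
#'   before any other manipulation (used for information-partition
#'   contrasts).
#' @param n_runs Monte Carlo runs.
#' @param base_seed Run `i` is seeded with `base_seed + i`.
#' @param min_cells Active-set floor for [subsample_cells()].
#' @param hmm_control List of [fit_hdp_hmm()] arguments for the
#'   unsupervised decoder (desk-scale defaults: truncation 30, 60 sweeps,
#'   30 burn-in).
#' @param reverse_prob,shuffle_order Passed to [split_into_epochs()].
#' @param verbose Report per-run progress?
#'
#' @return Data frame of class `result_table`: one row per run x condition
#'   x decoder with `median_error` (cm; `NA` with a `reason` when the
#'   condition is infeasible) and, for the unsupervised decoder, the
#'   inferred state count `m`. Summarise with [summarise_results()].
#' @export
run_representation_experiment <- function(fields, grid,
                                          duration = 300, mean_speed = 25,
                                          speed_threshold = 15,
                                          decoders = c("rf", "norf"),
                                          cell_subset = NULL,
                                          n_runs = 50, base_seed = 1,
                                          min_cells = 10,
                                          hmm_control = list(L = 30,
                                                             n_iter = 60,
                                                             burn_in = 30),
                                          reverse_prob = 0.5,
                                          shuffle_order = TRUE,
                                          verbose = FALSE) {
  decoders <- match.arg(decoders, c("rf", "norf"), several.ok = TRUE)
  defaults <- list(T0 = 10, rho = 1, delta = 0.25, per_epoch = FALSE,
                   thin = FALSE)
  for (nm in names(defaults)) if (is.null(grid[[nm]])) grid[[nm]] <- defaults[[nm]]
  env <- fields$env
  rows <- list()
  for (run in seq_len(n_runs)) {
    seed <- base_seed + run
    traj <- simulate_trajectory(env, duration, mean_speed, seed = seed)
    for (dl in unique(grid$delta)) {
      sm <- sample_spike_counts(fields, traj, delta = dl, seed = seed + 1)
      smf <- apply_speed_filter(sm, traj, threshold = speed_threshold)
      if (!is.null(cell_subset)) {
        sub <- spike_matrix(smf$counts[cell_subset, , drop = FALSE], smf$delta,
                            smf$t0, smf$cell_ids[cell_subset])
        attr(sub, "bin_pos") <- attr(smf, "bin_pos")
        smf <- sub
      }
      pfm <- estimate_place_fields(smf, env = env)
      gsub <- grid[grid$delta == dl, , drop = FALSE]
      for (g in seq_len(nrow(gsub))) {
        cond <- gsub[g, ]
        T0 <- min(cond$T0, n_bins(smf))
        res <- tryCatch({
          eps <- split_into_epochs(smf, T0, reverse_prob = reverse_prob,
                                   shuffle_order = shuffle_order,
                                   seed = seed + 2)
          if (cond$rho < 1 || cond$per_epoch)
            eps <- subsample_cells(eps, cond$rho, per_epoch = cond$per_epoch,
                                   min_cells = min_cells, seed = seed + 3)
          if (cond$thin)
            eps$epochs <- lapply(eps$epochs, thin_spikes)
          out <- list()
          if ("rf" %in% decoders) {
            dec <- decode_epochs_rf(eps, pfm)
            out$rf <- c(err = dec$median_error, m = NA_real_)
          }
          if ("norf" %in% decoders) {
            fit_args <- c(list(epochs = eps, seed = seed + 4), hmm_control)
            model <- suppressWarnings(do.call(fit_hdp_hmm, fit_args))
            ssm <- build_state_space_map(model, eps, env = env)
            err <- decode_position_from_states(model, ssm, eps)
            out$norf <- c(err = as.numeric(err), m = model$m)
          }
          out
        }, error = function(e) e)
        for (d in decoders) {
          rows[[length(rows) + 1L]] <- data.frame(
            run = run, T0 = cond$T0, rho = cond$rho, delta = cond$delta,
            per_epoch = cond$per_epoch, thin = cond$thin, decoder = d,
            median_error = if (inherits(res, "error")) NA_real_
                           else res[[d]]["err"],
            m = if (inherits(res, "error")) NA_real_ else res[[d]]["m"],
            reason = if (inherits(res, "error")) conditionMessage(res) else "")
        }
      }
    }
    if (verbose) message(sprintf("run %d/%d done", run, n_runs))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("result_table", "data.frame")
  out
}

#' Monte-Carlo sweep of replay detection power
#'
#' Builds, per run, a fresh time-compressed traversal event from the
#' ground-truth tuning curves, degrades it per condition (cell removal at
#' ratio `rho`, or emptying `removed_bins` random time bins at `rho = 1`),
#' runs the full shuffle-based significance pipeline with the supervised
#' decoder over the idealised field map, and records `|R|`, the Z-score and
#' the significance call.
#'
#' @param fields Ground-truth tuning curves.
#' @param rho Active-cell ratios to test (each with no bin removal).
#' @param removed_bins Numbers of emptied bins to test (each at `rho = 1`).
#' @param T0 Event length in bins.
#' @param delta Bin width, s.
#' @param gain Event rate gain.
#' @param n_runs Monte Carlo runs per condition.
#' @param n_shuffle Shuffles per event.
#' @param base_seed Seed; run `i` uses `base_seed + i`.
#' @param min_cells Active-set floor for the cell-removal conditions.
#' @return Data frame of class `result_table`: one row per run x condition
#'   with `abs_R`, `Z`, `significant`.
#' @export
run_detection_experiment <- function(fields, rho = c(0.2, 0.4, 0.6, 0.8, 1),
                                     removed_bins = c(2, 4, 6, 8, 10),
                                     T0 = 20, delta = 0.02, gain = 5,
                                     n_runs = 100, n_shuffle = 1000,
                                     base_seed = 1, min_cells = 10) {
  env <- fields$env
  pfm <- true_field_map(fields)
  decoder <- replay_decoder_rf(pfm)
  conds <- rbind(data.frame(rho = rho, removed = 0),
                 data.frame(rho = 1, removed = removed_bins))
  conds <- unique(conds)
  rows <- list()
  for (run in seq_len(n_runs)) {
    seed <- base_seed + run
    path <- event_path(env, T0, seed = seed)
    ev <- make_replay_event(fields, path, delta = delta, gain = gain,
                            seed = seed + 1)
    for (g in seq_len(nrow(conds))) {
      cond <- conds[g, ]
      sm <- ev$event
      if (cond$rho < 1) {
        eps <- subsample_cells(sm, cond$rho, min_cells = min_cells,
                               seed = seed + 2 + g)
        sm <- eps$epochs[[1]]
      }
      if (cond$removed > 0)
        sm <- remove_time_bins(sm, cond$removed, seed = seed + 2 + g)
      res <- assess_replay(sm, decoder, n_shuffle = n_shuffle,
                           seed = seed + 100 + g)
      rows[[length(rows) + 1L]] <- data.frame(
        run = run, rho = cond$rho, removed_bins = cond$removed,
        R = res$R, abs_R = res$abs_R, Z = res$Z,
        significant = res$significant)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("result_table", "data.frame")
  out
}

# A straight traversal across the environment, one position per bin: the
# canonical "clean sequential structure" reference event.
event_path <- function(env, n_bins, seed = NULL) {
  with_seed(seed, {
    f <- seq(0.1, 0.9, length.out = n_bins)
    if (env$is2d) {
      # random straight chord through the field
      th <- stats::runif(1, 0, 2 * pi)
      cx <- env$extent / 2
      r <- 0.4 * min(env$extent)
      cbind(cx[1] + r * cos(th) * (2 * f - 1),
            cx[2] + r * sin(th) * (2 * f - 1))
    } else {
      cbind(f * env$extent)
    }
  })
}

#' Summarise a Monte-Carlo result table as mean +/- SEM
#'
#' Groups by every non-run, non-response column and reports
#' `mean`, `sem = sd / sqrt(n)` and `n` of the chosen response across runs.
#'
#' @param results A `result_table`.
#' @param response Column to summarise (default `"median_error"` if present,
#'   else `"abs_R"`).
#' @return Data frame with one row per condition (and decoder, if present).
#' @export
summarise_results <- function(results, response = NULL) {
  if (is.null(response))
    response <- if ("median_error" %in% names(results)) "median_error" else "abs_R"
  drop_cols <- c("run", "median_error", "m", "reason", "R", "abs_R", "Z",
                 "significant")
  keys <- setdiff(names(results), drop_cols)
  f <- interaction(results[keys], drop = TRUE)
  agg <- function(v, g) {
    n <- tapply(!is.na(v), g, sum)
    mu <- tapply(v, g, mean, na.rm = TRUE)
    sdv <- tapply(v, g, stats::sd, na.rm = TRUE)
    data.frame(mean = as.numeric(mu), sem = as.numeric(sdv / sqrt(n)),
               n = as.numeric(n))
  }
  first <- !duplicated(f)
  out <- cbind(results[first, keys, drop = FALSE][order(f[first]), , drop = FALSE],
               agg(results[[response]], f))
  names(out)[names(out) == "mean"] <- paste0("mean_", response)
  rownames(out) <- NULL
  out
}
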