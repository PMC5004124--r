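#' Weighted correlation of a decoded event
#'
#' Pearson correlation between time-bin index and decoded position,
#' weighted by the posterior probability mass: with weights
#' `w_tx = post[t, x]`, `R = cov_w(t, x) / sqrt(var_w(t) var_w(x))`. A
#' positive R indicates a forward sweep across the support, a negative R a
#' reverse sweep; `|R| > 0.5` is the usual first replay criterion.
#'
#' @param post A `posterior_matrix` (rows = time bins, columns = ordered
#'   support positions; rows normalised).
#' @param x Support coordinate per column; defaults to the first column of
#'   the posterior's `support` attribute, else the column index.
#' @return R in `[-1, 1]`, or `NA` (flagged non-significant downstream) when
#'   a weighted variance vanishes (e.g. a single time bin or the mass stuck
#'   on one position).
#' @export
weighted_correlation <- function(post, x = NULL) {
  W <- unclass(post)
  if (is.null(x)) {
    sup <- attr(post, "support")
    x <- if (!is.null(sup)) sup[, 1] else seq_len(ncol(W))
  }
  t_idx <- seq_len(nrow(W))
  tot <- sum(W)
  wt <- rowSums(W); wx <- colSums(W)
  mt <- sum(wt * t_idx) / tot
  mx <- sum(wx * x) / tot
  var_t <- sum(wt * (t_idx - mt)^2) / tot
  var_x <- sum(wx * (x - mx)^2) / tot
  if (var_t <= 0 || var_x <= 0) return(NA_real_)
  cov_tx <- as.numeric(t(t_idx - mt) %*% W %*% (x - mx)) / tot
  cov_tx / sqrt(var_t * var_x)
}

#' Shuffle null distribution of the weighted correlation
#'
#' Builds `n_shuffle` surrogate events by permuting the spike-count matrix
#' and re-decoding each with the same decoder. The default composes the two
#' standard operations: a temporal shuffle (whole population time bins,
#' i.e. column vectors, permuted together) and a cell shuffle (row
#' identities permuted). A per-cell independent temporal shuffle is
#' available behind `per_cell`.
#'
#' @param event A [spike_matrix()] with at least 2 bins.
#' @param decoder Function `spike_matrix -> posterior_matrix` (see
#'   [replay_decoder_rf()] / [replay_decoder_states()]).
#' @param n_shuffle Number of surrogates (>= 100).
#' @param kinds Character subset of `c("temporal", "cell")`.
#' @param per_cell Permute time bins independently per cell?
#' @param seed RNG seed.
#' @return An object of class `shuffle_null`: list with `R_shuffle`
#'   (length `n_shuffle`; `NA` where degenerate), `kinds`, `per_cell`.
#' @export
shuffle_null <- function(event, decoder, n_shuffle = 1000,
                         kinds = c("temporal", "cell"), per_cell = FALSE,
                         seed = NULL) {
  stopifnot(inherits(event, "spike_matrix"))
  kinds <- match.arg(kinds, c("temporal", "cell"), several.ok = TRUE)
  if (n_bins(event) < 2L) stop("event has fewer than 2 bins", call. = FALSE)
  if (n_shuffle < 100) stop("`n_shuffle` must be at least 100", call. = FALSE)
  C <- n_cells(event); T <- n_bins(event)
  with_seed(seed, {
    Rs <- vapply(seq_len(n_shuffle), function(i) {
      m <- event$counts
      if ("temporal" %in% kinds) {
        if (per_cell) {
          for (c in seq_len(C)) m[c, ] <- m[c, sample.int(T)]
        } else m <- m[, sample.int(T), drop = FALSE]
      }
      if ("cell" %in% kinds) m <- m[sample.int(C), , drop = FALSE]
      sh <- spike_matrix(m, event$delta, event$t0, event$cell_ids)
      attr(sh, "active_cells") <- attr(event, "active_cells")
      weighted_correlation(decoder(sh))
    }, numeric(1))
    structure(list(R_shuffle = Rs, kinds = kinds, per_cell = per_cell),
              class = "shuffle_null")
  })
}

#' Z-score and p-value of a weighted correlation against its shuffle null
#'
#' Computed on the absolute correlation so forward and reverse events are
#' treated symmetrically: `Z = (|R| - mean |R_shuffle|) / sd |R_shuffle|`.
#' The null's normality is tested (Shapiro-Wilk, alpha = 0.05, on up to
#' 5000 samples); when rejected -- or when the null is degenerate -- the
#' Monte Carlo p-value `(1 + #\{|R_s| >= |R|\}) / (n + 1)` is reported
#' instead of the one-sided normal tail.
#'
#' @param R_raw Raw weighted correlation (signed).
#' @param null A [shuffle_null()] (or a bare numeric vector of shuffle
#'   statistics).
#' @return List with `Z`, `p`, `p_method` (`"normal"` or `"monte_carlo"`),
#'   `normal_null`, `null_mean`, `null_sd`.
#' @export
zscore_pvalue <- function(R_raw, null) {
  Rs <- if (inherits(null, "shuffle_null")) null$R_shuffle else as.numeric(null)
  Rs <- abs(Rs[!is.na(Rs)])
  if (length(Rs) < 3) stop("null distribution too small", call. = FALSE)
  a <- abs(R_raw)
  mu <- mean(Rs); sdv <- stats::sd(Rs)
  Z <- if (sdv > 0) (a - mu) / sdv else NA_real_
  sw <- Rs
  if (length(sw) > 5000) sw <- sw[seq(1, length(sw), length.out = 5000)]
  normal <- if (stats::sd(sw) > 0)
    tryCatch(stats::shapiro.test(sw)$p.value >= 0.05, error = function(e) FALSE)
  else FALSE
  if (normal && is.finite(Z)) {
    p <- stats::pnorm(Z, lower.tail = FALSE)
    method <- "normal"
  } else {
    p <- (1 + sum(Rs >= a)) / (length(Rs) + 1)
    method <- "monte_carlo"
  }
  list(Z = Z, p = p, p_method = method, normal_null = normal,
       null_mean = mu, null_sd = sdv)
}

#' Three-criteria replay significance classification
#'
#' An event is significant iff (1) `|R| > 0.5`; (2) it spans at least 5
#' temporal bins (100 ms at the 20-ms ripple timescale) and its average MAP
#' probability score exceeds the chance level `5 / n_support_bins`; (3) its
#' Z-score exceeds 1.65 (one-sided 5%), or, when the Monte Carlo branch was
#' used, `p < 0.05`.
#'
#' @param R Signed weighted correlation (`NA` fails criterion 1).
#' @param Z Z-score of `|R|` against the shuffle null.
#' @param n_bins Temporal bins in the event.
#' @param avg_map_score Average MAP probability score.
#' @param n_support_bins Size of the decoding support (position or state
#'   bins).
#' @param p,p_method Optional p-value and its method; when
#'   `p_method = "monte_carlo"` criterion 3 uses `p < 0.05`.
#' @return List of flags: `r_pass`, `length_pass`, `map_pass`, `z_pass`,
#'   `significant` (their conjunction), and `direction` (`"forward"` /
#'   `"reverse"` by the sign of R).
#' @export
classify_significance <- function(R, Z, n_bins, avg_map_score, n_support_bins,
                                  p = NULL, p_method = "normal") {
  r_pass <- !is.na(R) && abs(R) > 0.5
  length_pass <- n_bins >= 5
  map_pass <- avg_map_score > 5 / n_support_bins
  z_pass <- if (identical(p_method, "monte_carlo")) {
    !is.null(p) && p < 0.05
  } else {
    !is.na(Z) && Z > 1.65
  }
  list(r_pass = r_pass, length_pass = length_pass, map_pass = map_pass,
       z_pass = z_pass,
       significant = r_pass && length_pass && map_pass && z_pass,
       direction = if (!is.na(R) && R < 0) "reverse" else "forward")
}

#' Receptive-field decoder closure for replay assessment
#'
#' @param field A [estimate_place_fields()] map.
#' @param prior,P Passed to [decode_posterior()].
#' @return Function `spike_matrix -> posterior_matrix`.
#' @export
replay_decoder_rf <- function(field, prior = "uniform", P = NULL) {
  force(field); force(prior); force(P)
  function(sm) decode_posterior(sm, field, prior = prior, P = P)
}

#' State-space decoder closure for replay assessment
#'
#' Smoothed state posteriors restricted to the states with a state-space-map
#' position (rows renormalised), with the mapped positions as the support
#' coordinates -- so the weighted correlation measures time versus mapped
#' position exactly as in the supervised decoder.
#'
#' @param model An [fit_hdp_hmm()] model.
#' @param map A [build_state_space_map()].
#' @return Function `spike_matrix -> posterior_matrix`.
#' @export
replay_decoder_states <- function(model, map) {
  force(model); force(map)
  keep <- which(map$mapped)
  sup <- if ("y" %in% names(map)) cbind(map$x[keep], map$y[keep])
         else cbind(map$x[keep])
  function(sm) {
    gm <- state_posteriors(model, sm)
    g <- unclass(gm)[, keep, drop = FALSE]
    g <- g / pmax(rowSums(g), .Machine$double.eps)
    structure(g, support = sup, support_index = keep,
              env = attr(map, "env"),
              class = c("posterior_matrix", "matrix"))
  }
}

#' Full replay assessment of one candidate event
#'
#' Decodes the event, computes the weighted correlation, builds the shuffle
#' null, derives the Z-score / p-value, and applies the three significance
#' criteria.
#'
#' @param event A [spike_matrix()] at the ripple timescale.
#' @param decoder Decoder closure ([replay_decoder_rf()] or
#'   [replay_decoder_states()]).
#' @param n_shuffle Shuffles for the null.
#' @param kinds,per_cell Passed to [shuffle_null()].
#' @param seed RNG seed (drives the shuffles).
#' @return An object of class `replay_result`: list with `R`, `abs_R`, `Z`,
#'   `p`, `p_method`, `avg_map_score`, `n_bins`, `n_support_bins`, `rho`
#'   (active-cell fraction of the event), the criterion `flags`,
#'   `significant`, `direction`, and the `null`.
#' @export
assess_replay <- function(event, decoder, n_shuffle = 1000,
                          kinds = c("temporal", "cell"), per_cell = FALSE,
                          seed = NULL) {
  post <- decoder(event)
  R <- weighted_correlation(post)
  mp <- map_path(post)
  null <- shuffle_null(event, decoder, n_shuffle = n_shuffle, kinds = kinds,
                       per_cell = per_cell, seed = seed)
  zp <- zscore_pvalue(if (is.na(R)) 0 else R, null)
  flags <- classify_significance(R, zp$Z, n_bins = n_bins(event),
                                 avg_map_score = mp$avg_map_score,
                                 n_support_bins = ncol(post),
                                 p = zp$p, p_method = zp$p_method)
  structure(list(R = R, abs_R = abs(R), Z = zp$Z, p = zp$p,
                 p_method = zp$p_method,
                 avg_map_score = mp$avg_map_score,
                 n_bins = n_bins(event), n_support_bins = ncol(post),
                 rho = mean(rowSums(event$counts) > 0),
                 flags = flags[c("r_pass", "length_pass", "map_pass", "z_pass")],
                 significant = flags$significant,
                 direction = flags$direction,
                 null = null),
            class = "replay_result")
}

#' @export
print.replay_result <- function(x, ...) {
  cat(sprintf("<replay_result> R = %.3f (%s), Z = %.2f, p = %.3g (%s), map %.3f, %d bins -> %s\n",
              x$R, x$direction, x$Z, x$p, x$p_method, x$avg_map_score,
              x$n_bins, if (x$significant) "SIGNIFICANT" else "not significant"))
  invisible(x)
}

#' Screen a multi-unit activity trace for ripple candidate events
#'
#' Finds intervals where the Gaussian-smoothed MUA exceeds mean + 3 SD
#' (optionally requiring the ripple-band power trace to cross the same
#' threshold), expands each to the nearest sub-mean crossings, and applies
#' the minimum cell-activation criterion: at least `max(min_cells,
#' ceiling(min_frac * C))` cells firing within the event.
#'
#' @param mua Population multi-unit count trace (one value per temporal
#'   bin).
#' @param counts Optional [spike_matrix()] aligned bin-for-bin with `mua`,
#'   used for the cell-activation criterion and the per-event matrices.
#' @param ripple_power Optional ripple-band power trace, same length.
#' @param delta Bin width, s.
#' @param threshold_sd Core detection threshold in SDs above the mean.
#' @param edge_sd Expansion stops where the trace falls below mean +
#'   `edge_sd` SD.
#' @param smooth_sd Gaussian smoothing SD in bins (0 = none).
#' @param min_cells,min_frac Cell-activation floor and fraction.
#' @return List of `candidate_event` objects (`interval` bins, `t_start`/
#'   `t_end` s, `counts`, `rho`, `T0`, `n_active`), with attributes
#'   `"n_detected"` (supra-threshold intervals) and `"n_retained"`.
#' @export
detect_candidate_events <- function(mua, counts = NULL, ripple_power = NULL,
                                    delta = 0.02, threshold_sd = 3,
                                    edge_sd = 0, smooth_sd = 1,
                                    min_cells = 6, min_frac = 0.10) {
  x <- as.numeric(mua)
  smooth1d <- function(v, sd) {
    if (sd <= 0) return(v)
    half <- max(1L, ceiling(3 * sd))
    k <- stats::dnorm(-half:half, sd = sd)
    n <- length(v)
    out <- numeric(n); wsum <- numeric(n)
    for (o in -half:half) {            # edge-renormalised convolution
      w <- k[o + half + 1L]
      src <- seq_len(n) - o
      ok <- src >= 1L & src <= n
      out[ok] <- out[ok] + w * v[src[ok]]
      wsum[ok] <- wsum[ok] + w
    }
    out / wsum
  }
  xs <- smooth1d(x, smooth_sd)
  # relative tolerance: edge renormalisation of a constant trace leaves
  # rounding-level wiggle that must not register as structure
  if (stats::sd(xs) <= 1e-12 * max(abs(xs), 1)) {
    warning("flat MUA trace; no events detected", call. = FALSE)
    return(structure(list(), n_detected = 0L, n_retained = 0L))
  }
  z <- (xs - mean(xs)) / stats::sd(xs)
  above <- z > threshold_sd
  if (!is.null(ripple_power)) {
    rp <- smooth1d(as.numeric(ripple_power), smooth_sd)
    if (stats::sd(rp) > 0) {
      zr <- (rp - mean(rp)) / stats::sd(rp)
      above <- above & (zr > threshold_sd)
    }
  }
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cores <- cbind(starts[runs$values], ends[runs$values])
  events <- list()
  n_det <- nrow(cores)
  if (n_det > 0) {
    # expand to nearest sub-edge crossings and merge overlaps
    lo <- integer(n_det); hi <- integer(n_det)
    for (i in seq_len(n_det)) {
      a <- cores[i, 1]
      while (a > 1L && z[a - 1L] > edge_sd) a <- a - 1L
      b <- cores[i, 2]
      while (b < length(z) && z[b + 1L] > edge_sd) b <- b + 1L
      lo[i] <- a; hi[i] <- b
    }
    keep <- !duplicated(lo)
    lo <- lo[keep]; hi <- hi[keep]
    for (i in seq_along(lo)) {
      ev <- list(interval = c(lo[i], hi[i]),
                 t_start = (lo[i] - 1) * delta, t_end = hi[i] * delta,
                 T0 = hi[i] - lo[i] + 1L)
      if (!is.null(counts)) {
        sub <- counts$counts[, lo[i]:hi[i], drop = FALSE]
        n_active <- sum(rowSums(sub) > 0)
        C <- nrow(sub)
        if (n_active < max(min_cells, ceiling(min_frac * C))) next
        ev$counts <- spike_matrix(sub, counts$delta,
                                  counts$t0 + (lo[i] - 1) * counts$delta,
                                  counts$cell_ids)
        ev$n_active <- n_active
        ev$rho <- n_active / C
      }
      events[[length(events) + 1L]] <- structure(ev, class = "candidate_event")
    }
  }
  structure(events, n_detected = n_det, n_retained = length(events))
}

#' Compare two populations of replay results
#'
#' Builds the standard summary-table columns per set (total events, events
#' with >= 10% active cells, events with `|R| > 0.5`, with `Z > 1.65`, and
#' fully significant), the medians of `|R|` and `Z` among significant
#' events, and Wilcoxon rank-sum tests between the sets on `rho`, `|R|` and
#' `Z`.
#'
#' @param results_a,results_b Lists of [assess_replay()] results.
#' @param labels Length-2 character labels.
#' @return List with `table` (one row per set) and `tests` (rank-sum
#'   p-values; `NA` when a set is empty).
#' @export
compare_epoch_populations <- function(results_a, results_b,
                                      labels = c("A", "B")) {
  summarise <- function(res) {
    if (length(res) == 0L)
      return(data.frame(n_total = 0L, n_active10 = 0L, n_r = 0L, n_z = 0L,
                        n_sig = 0L, median_absR = NA_real_, median_Z = NA_real_))
    absR <- vapply(res, function(r) r$abs_R, numeric(1))
    Z <- vapply(res, function(r) r$Z, numeric(1))
    rho <- vapply(res, function(r) r$rho %||% NA_real_, numeric(1))
    sig <- vapply(res, function(r) r$significant, logical(1))
    data.frame(n_total = length(res),
               n_active10 = sum(rho >= 0.10, na.rm = TRUE),
               n_r = sum(absR > 0.5, na.rm = TRUE),
               n_z = sum(Z > 1.65, na.rm = TRUE),
               n_sig = sum(sig),
               median_absR = if (any(sig)) stats::median(absR[sig]) else NA_real_,
               median_Z = if (any(sig)) stats::median(Z[sig]) else NA_real_)
  }
  tab <- rbind(summarise(results_a), summarise(results_b))
  rownames(tab) <- labels
  pull <- function(res, f) vapply(res, f, numeric(1))
  tests <- list(rho = NA_real_, absR = NA_real_, Z = NA_real_)
  if (length(results_a) > 0 && length(results_b) > 0) {
    wt <- function(a, b) {
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (length(a) < 1 || length(b) < 1) return(NA_real_)
      suppressWarnings(stats::wilcox.test(a, b)$p.value)
    }
    tests$rho <- wt(pull(results_a, function(r) r$rho %||% NA_real_),
                    pull(results_b, function(r) r$rho %||% NA_real_))
    tests$absR <- wt(pull(results_a, function(r) r$abs_R),
                     pull(results_b, function(r) r$abs_R))
    tests$Z <- wt(pull(results_a, function(r) r$Z),
                  pull(results_b, function(r) r$Z))
  }
  list(table = tab, tests = tests)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
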