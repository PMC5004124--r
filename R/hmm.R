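#' @useDynLib sleepreplay, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) { g <- rep(0, length(alpha)); g[which.max(alpha)] <- 1 }
  g / sum(g)
}

# Stationary distribution of a row-stochastic matrix (left eigenvector for
# eigenvalue 1); falls back to uniform for defective cases.
stationary_dist <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  if (sum(v) <= 0 || any(!is.finite(v))) return(rep(1 / nrow(P), nrow(P)))
  v / sum(v)
}

# Emission log-likelihood matrix (T x L) for one epoch, restricted to the
# epoch's active cells; the -log(y!) term, constant in the state, is
# dropped (log-joint traces therefore omit the same additive constant).
epoch_loglik <- function(counts, active, Lambda, delta, rate_floor = 1e-3) {
  lamd <- pmax(Lambda[, active, drop = FALSE], rate_floor) * delta  # L x Ca
  ll <- t(counts[active, , drop = FALSE]) %*% t(log(lamd))          # T x L
  sweep(ll, 2, rowSums(lamd), "-")
}

#' Fit an HDP-HMM with Poisson emissions to ensemble spike epochs
#'
#' Unsupervised decoder: a hierarchical-Dirichlet-process hidden Markov
#' model, sampled by a weak-limit Gibbs sampler at truncation `L`. Each
#' epoch is treated as an independent chain sharing the transition matrix
#' and state rate vectors; its initial distribution is the stationary
#' distribution of the current transition matrix. Per sweep: state paths are
#' block-sampled by forward-filter/backward-sampling; state firing rates get
#' conjugate gamma-Poisson updates; the shared stick-breaking weights and
#' the transition rows get the usual HDP auxiliary-table updates (with an
#' optional sticky self-transition bonus `kappa`). The number of states `m`
#' is read off the selected sample as the number of states occupying at
#' least `occupancy_frac` of the bins.
#'
#' The returned model is the single post-burn-in sample with the highest
#' complete-data log joint (states + data given parameters), keeping the
#' transition matrix and rate matrix coherent, restricted and row-
#' renormalised to the occupied states.
#'
#' @param epochs An `epoch_set` or [spike_matrix()].
#' @param L Weak-limit truncation level (upper bound on the state count).
#' @param n_iter,burn_in Gibbs sweeps in total / discarded.
#' @param gamma_conc,alpha_conc HDP concentration parameters (top-level /
#'   per-row).
#' @param kappa Sticky self-transition mass (0 = plain HDP-HMM).
#' @param rate_shape Gamma prior shape on rates; the prior rate is matched
#'   so the prior mean equals the data's grand mean rate.
#' @param occupancy_frac Minimum fraction of bins a state must occupy to be
#'   counted in `m`.
#' @param seed RNG seed.
#' @param verbose Print sweep progress?
#'
#' @return An object of class `hmm_model`: `m`, `P` (m x m), `Lambda`
#'   (m x C, Hz), `pi0` (stationary distribution of `P`), `delta`,
#'   `active_states` (their labels at truncation level), `occupancy` (bins
#'   per kept state in the selected sample), `full` (untruncated `P`,
#'   `Lambda`, `beta`), `hyper`, and `diagnostics` (log-joint trace, Geweke
#'   z of the post-burn-in trace, selected sweep).
#' @export
fit_hdp_hmm <- function(epochs, L = 100, n_iter = 200, burn_in = 100,
                        gamma_conc = 5, alpha_conc = 5, kappa = 0,
                        rate_shape = 1, occupancy_frac = 0.005, seed = NULL,
                        verbose = FALSE) {
  epochs <- as_epoch_set(epochs)
  eps <- epochs$epochs
  C <- length(epochs$cell_ids)
  delta <- epochs$delta
  Ts <- vapply(eps, n_bins, integer(1))
  Ttot <- sum(Ts)
  if (Ttot < L)
    stop(sprintf("total bins (%d) below truncation level L = %d", Ttot, L),
         call. = FALSE)
  active <- lapply(eps, function(e) {
    a <- attr(e, "active_cells"); if (is.null(a)) seq_len(C) else a
  })
  tot_spikes <- sum(vapply(eps, function(e) sum(e$counts), numeric(1)))
  if (tot_spikes == 0) stop("no spikes in any epoch", call. = FALSE)
  grand_rate <- tot_spikes / (Ttot * delta)
  rate_rate <- rate_shape / grand_rate      # prior mean = grand mean rate

  with_seed(seed, {
    beta_w <- rep(1 / L, L)
    ## initial segmentation: k-means on sqrt counts keeps distinct firing
    ## patterns in distinct states from the first sweep on (random fallback)
    allY <- sqrt(t(do.call(cbind, lapply(eps, function(e) e$counts))))
    km <- tryCatch(stats::kmeans(allY, centers = min(L, nrow(unique(allY))),
                                 iter.max = 25, nstart = 1)$cluster,
                   error = function(e) sample.int(L, Ttot, replace = TRUE))
    paths <- split(as.integer(km), rep(seq_along(Ts), Ts))
    logjoint <- rep(NA_real_, n_iter)
    best <- NULL
    for (it in seq_len(n_iter)) {
      ## 1. sufficient statistics of the current paths
      trans <- matrix(0, L, L)
      occ <- numeric(L)
      spikes <- matrix(0, L, C)
      exposure <- matrix(0, L, C)
      for (e in seq_along(eps)) {
        s <- paths[[e]]; T <- length(s)
        if (T > 1) {
          flat <- (s[-1] - 1L) * L + s[-T]     # column-major (from, to) cell
          trans <- trans + matrix(tabulate(flat, nbins = L * L), L, L)
        }
        so <- rowsum(rep(1, T), s)
        ii <- as.integer(rownames(so))
        occ[ii] <- occ[ii] + so
        sp <- rowsum(t(eps[[e]]$counts[active[[e]], , drop = FALSE]) + 0, s)
        spikes[ii, active[[e]]] <- spikes[ii, active[[e]]] + sp
        exposure[ii, active[[e]]] <- exposure[ii, active[[e]]] + so[, 1] * delta
      }
      ## 2. conjugate rate updates
      Lambda <- matrix(stats::rgamma(L * C, rate_shape + spikes,
                                     rate_rate + exposure), L, C)
      ## 3. HDP auxiliary table counts and stick weights
      m_tab <- matrix(0, L, L)
      nz <- which(trans > 0, arr.ind = TRUE)
      for (r in seq_len(nrow(nz))) {
        j <- nz[r, 1]; k <- nz[r, 2]
        conc <- alpha_conc * beta_w[k] + if (j == k) kappa else 0
        n <- trans[j, k]
        m_tab[j, k] <- sum(stats::runif(n) < conc / (conc + seq_len(n) - 1))
      }
      mbar <- m_tab
      if (kappa > 0) {
        rho_c <- kappa / (alpha_conc + kappa)
        for (j in seq_len(L)) {
          if (m_tab[j, j] > 0) {
            pr <- rho_c / (rho_c + beta_w[j] * (1 - rho_c))
            mbar[j, j] <- m_tab[j, j] - stats::rbinom(1, m_tab[j, j], pr)
          }
        }
      }
      beta_w <- rdirichlet1(gamma_conc / L + colSums(mbar))
      ## 4. transition rows
      P <- matrix(0, L, L)
      for (j in seq_len(L)) {
        a <- alpha_conc * beta_w + trans[j, ]
        if (kappa > 0) a[j] <- a[j] + kappa
        P[j, ] <- rdirichlet1(a)
      }
      ## 5. block-sample state paths
      pi0 <- stationary_dist(P)
      lj <- 0
      occ <- numeric(L)
      for (e in seq_along(eps)) {
        ll <- epoch_loglik(eps[[e]]$counts, active[[e]], Lambda, delta)
        s <- as.integer(ffbs_cpp(ll, P, pi0))
        paths[[e]] <- s
        T <- length(s)
        lj <- lj + log(pi0[s[1]]) + sum(ll[cbind(seq_len(T), s)])
        if (T > 1) lj <- lj + sum(log(P[cbind(s[-T], s[-1])]))
        so <- rowsum(rep(1, T), s)
        ii <- as.integer(rownames(so))
        occ[ii] <- occ[ii] + so
      }
      logjoint[it] <- lj
      if (it > burn_in && (is.null(best) || lj > best$logjoint)) {
        best <- list(P = P, Lambda = Lambda, beta = beta_w, paths = paths,
                     occ = occ, logjoint = lj, iter = it)
      }
      if (verbose && it %% 20 == 0)
        message(sprintf("sweep %d/%d  log-joint %.1f", it, n_iter, lj))
    }
    ## reduce to occupied states of the selected sample
    keep <- which(best$occ >= occupancy_frac * Ttot)
    if (length(keep) == 0L) keep <- which.max(best$occ)
    Pred <- best$P[keep, keep, drop = FALSE]
    Pred <- sweep(Pred, 1, rowSums(Pred), "/")
    post <- logjoint[(burn_in + 1):n_iter]
    gz <- geweke_z(post)
    diag <- list(logjoint = logjoint, geweke_z = gz,
                 selected_iter = best$iter,
                 converged = is.finite(gz) && abs(gz) <= 3)
    if (!diag$converged)
      warning("log-joint trace still trending after n_iter sweeps (Geweke |z| > 3)",
              call. = FALSE)
    structure(list(m = length(keep),
                   P = Pred,
                   Lambda = best$Lambda[keep, , drop = FALSE],
                   pi0 = stationary_dist(Pred),
                   delta = delta,
                   cell_ids = epochs$cell_ids,
                   active_states = keep,
                   occupancy = best$occ[keep],
                   full = list(P = best$P, Lambda = best$Lambda,
                               beta = best$beta, L = L),
                   hyper = list(gamma_conc = gamma_conc,
                                alpha_conc = alpha_conc, kappa = kappa,
                                rate_shape = rate_shape,
                                rate_rate = rate_rate,
                                occupancy_frac = occupancy_frac),
                   diagnostics = diag),
              class = "hmm_model")
  })
}

# Crude Geweke-style convergence score on a scalar trace: standardised
# difference between the means of the first 10% and last 50% of samples.
geweke_z <- function(x) {
  n <- length(x)
  if (n < 20) return(NA_real_)
  a <- x[seq_len(max(2, floor(0.1 * n)))]
  b <- x[(floor(0.5 * n) + 1):n]
  (mean(a) - mean(b)) / sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf("<hmm_model> m = %d states (truncation %d), %d cells, delta = %g s\n",
              x$m, x$full$L, ncol(x$Lambda), x$delta))
  invisible(x)
}

# Emission loglik of a spike matrix under the reduced model, honouring the
# matrix's active-cell subset if recorded.
model_loglik <- function(model, sm, cells = NULL) {
  if (n_cells(sm) != ncol(model$Lambda))
    stop("spike matrix and model disagree on the cell population", call. = FALSE)
  if (is.null(cells)) cells <- attr(sm, "active_cells")
  if (is.null(cells)) cells <- seq_len(n_cells(sm))
  epoch_loglik(sm$counts, cells, model$Lambda, sm$delta)
}

#' Smoothed state posteriors under a fitted HMM
#'
#' Forward-backward posterior `p(S_t = j | y_{1:T})` over the model's
#' occupied states.
#'
#' @param model An [fit_hdp_hmm()] model.
#' @param sm A [spike_matrix()] over the same cell population.
#' @return A `posterior_matrix` (time bins x states, rows summing to 1) with
#'   attribute `support` = state labels.
#' @export
state_posteriors <- function(model, sm) {
  ll <- model_loglik(model, sm)
  fb <- forward_backward_cpp(ll, model$P, model$pi0)
  structure(fb$gamma, support = cbind(model$active_states),
            support_index = seq_len(model$m), env = NULL,
            loglik = fb$loglik,
            class = c("posterior_matrix", "matrix"))
}

#' Viterbi state path and MAP probability score
#'
#' Max-product decoding of the most probable state sequence, with the
#' average MAP probability score (mean over bins of the smoothed posterior
#' mass at the Viterbi state).
#'
#' @param model An [fit_hdp_hmm()] model.
#' @param sm A [spike_matrix()].
#' @return List with `path` (state index per bin, into the model's reduced
#'   state set), `logprob` (joint log probability of the path, up to the
#'   count-factorial constant), `avg_map_score`, and `gamma` (the smoothed
#'   posteriors).
#' @export
viterbi_path <- function(model, sm) {
  ll <- model_loglik(model, sm)
  vt <- viterbi_cpp(ll, log(model$P), log(model$pi0))
  gm <- state_posteriors(model, sm)
  path <- as.integer(vt$path)
  list(path = path, logprob = vt$logprob,
       avg_map_score = mean(gm[cbind(seq_along(path), path)]),
       gamma = gm)
}

#' Map latent states to physical space
#'
#' Evaluation-only step: assigns each occupied state the occupancy-weighted
#' centroid (circular mean on circular tracks) of the true positions of its
#' Viterbi-assigned bins. Positions are used here and nowhere else in the
#' unsupervised pipeline.
#'
#' @param model An [fit_hdp_hmm()] model.
#' @param epochs An `epoch_set` or [spike_matrix()] whose epochs carry
#'   per-bin positions (attribute `"bin_pos"`).
#' @param env The [spatial_env()]; defaults to the one attached to the
#'   positions.
#' @return An object of class `state_space_map`: data frame with one row per
#'   model state (`state`, `x` (, `y`), `dispersion_cm`, `n_bins`,
#'   `mapped`); states with no assigned bins are masked (`mapped = FALSE`).
#' @export
build_state_space_map <- function(model, epochs, env = NULL) {
  epochs <- as_epoch_set(epochs)
  states <- integer(0); xs <- numeric(0); ys <- numeric(0)
  for (ep in epochs$epochs) {
    bp <- attr(ep, "bin_pos")
    if (is.null(bp)) stop("epochs carry no per-bin positions", call. = FALSE)
    if (is.null(env)) env <- attr(bp, "env")
    vt <- viterbi_path(model, ep)
    states <- c(states, vt$path)
    xs <- c(xs, bp$x)
    if ("y" %in% names(bp)) ys <- c(ys, bp$y)
  }
  is2d <- length(ys) > 0
  out <- data.frame(state = seq_len(model$m), x = NA_real_)
  if (is2d) out$y <- NA_real_
  out$dispersion_cm <- NA_real_
  out$n_bins <- 0L
  for (j in seq_len(model$m)) {
    idx <- which(states == j)
    out$n_bins[j] <- length(idx)
    if (length(idx) == 0L) next
    if (!is.null(env) && env$kind == "circular_track") {
      th <- xs[idx] * 2 * pi / env$extent
      cx <- (atan2(mean(sin(th)), mean(cos(th))) %% (2 * pi)) *
        env$extent / (2 * pi)
      out$x[j] <- cx
    } else {
      out$x[j] <- mean(xs[idx])
      if (is2d) out$y[j] <- mean(ys[idx])
    }
    ctr <- if (is2d) cbind(out$x[j], out$y[j]) else cbind(out$x[j])
    pts <- if (is2d) cbind(xs[idx], ys[idx]) else cbind(xs[idx])
    out$dispersion_cm[j] <-
      sqrt(mean(position_distance(pts, ctr[rep(1, length(idx)), , drop = FALSE],
                                  env)^2))
  }
  out$mapped <- out$n_bins > 0L
  attr(out, "env") <- env
  class(out) <- c("state_space_map", "data.frame")
  out
}

#' Decode positions through the state-space map and score them
#'
#' Viterbi state per bin, mapped to its state-space-map position, scored by
#' the median distance to the true position. Bins landing in unmapped states
#' are excluded and their fraction reported.
#'
#' @param model An [fit_hdp_hmm()] model.
#' @param map A [build_state_space_map()] (normally built on held-in data).
#' @param epochs An `epoch_set` or [spike_matrix()] carrying per-bin
#'   positions.
#' @return Median error in cm, with attributes `"errors"` (per scored bin)
#'   and `"excluded_fraction"`.
#' @export
decode_position_from_states <- function(model, map, epochs) {
  epochs <- as_epoch_set(epochs)
  env <- attr(map, "env")
  errs <- numeric(0); n_excl <- 0L; n_tot <- 0L
  for (ep in epochs$epochs) {
    bp <- attr(ep, "bin_pos")
    if (is.null(bp)) stop("epochs carry no per-bin positions", call. = FALSE)
    vt <- viterbi_path(model, ep)
    ok <- map$mapped[vt$path]
    n_tot <- n_tot + length(ok); n_excl <- n_excl + sum(!ok)
    if (!any(ok)) next
    dec <- if ("y" %in% names(map)) cbind(map$x[vt$path[ok]], map$y[vt$path[ok]])
           else cbind(map$x[vt$path[ok]])
    tru <- pos_matrix(bp)[ok, , drop = FALSE]
    errs <- c(errs, position_distance(dec, tru, env))
  }
  if (length(errs) == 0L) stop("all bins fell in unmapped states", call. = FALSE)
  structure(stats::median(errs), errors = errs,
            excluded_fraction = n_excl / n_tot)
}

#' Force-directed topology graph of the transition structure
#'
#' Symmetrises the transition matrix into pairwise connectivity strengths
#' `w_ij = P_ij + P_ji` (i != j) and lays the states out with the
#' Fruchterman-Reingold algorithm (fixed seed), normalised to the unit
#' bounding box so the layout is scale-invariant.
#'
#' @param model An [fit_hdp_hmm()] model (or a bare transition matrix).
#' @param strength_threshold Connectivity threshold for counting a node's
#'   neighbours; default the 60th percentile of the nonzero strengths.
#' @param seed Layout seed.
#' @return An object of class `topology_graph`: list with `graph` (igraph),
#'   `layout` (nodes x 2, unit bounding box), `strengths` (nonzero w_ij,
#'   upper triangle), `strength_stats` (mean, sd), `degree_above_threshold`
#'   (per node), `threshold`.
#' @export
topology_layout <- function(model, strength_threshold = NULL, seed = 1) {
  P <- if (inherits(model, "hmm_model")) model$P else as.matrix(model)
  W <- P + t(P)
  diag(W) <- 0
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  lay <- with_seed(seed, {
    if (nrow(W) == 1L) matrix(0.5, 1, 2)
    else igraph::layout_with_fr(g, weights = igraph::E(g)$weight)
  })
  rng <- apply(lay, 2, function(v) diff(range(v)))
  lay <- sweep(lay, 2, apply(lay, 2, min), "-")
  lay <- sweep(lay, 2, pmax(rng, .Machine$double.eps), "/")
  up <- W[upper.tri(W)]
  strengths <- up[up > 0]
  if (is.null(strength_threshold))
    strength_threshold <- if (length(strengths)) unname(stats::quantile(strengths, 0.6)) else 0
  deg <- rowSums(W > strength_threshold)
  structure(list(graph = g, layout = lay, strengths = strengths,
                 strength_stats = c(mean = mean(strengths), sd = stats::sd(strengths)),
                 degree_above_threshold = deg,
                 threshold = strength_threshold),
            class = "topology_graph")
}

#' @export
print.topology_graph <- function(x, ...) {
  cat(sprintf("<topology_graph> %d nodes, %d nonzero strengths (mean %.3f, sd %.3f), threshold %.3f\n",
              nrow(x$layout), length(x$strengths), x$strength_stats["mean"],
              x$strength_stats["sd"], x$threshold))
  invisible(x)
}
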