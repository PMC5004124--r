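# Shared synthetic fixtures for the test suite. Everything is generated on
# the fly from fixed seeds; no binary fixtures are stored.

# A K-state Poisson HMM with a dominant diagonal and a weak ring structure:
# the parameter-recovery oracle for the unsupervised decoder.
gen_hmm_data <- function(T, seed, K = 4, C = 20, delta = 0.25,
                         rate_hi = 15, rate_lo = 0.5) {
  set.seed(seed)
  P <- matrix(0.05 / 3, K, K)
  diag(P) <- 0.85
  for (k in seq_len(K)) P[k, k %% K + 1L] <- 0.10
  Lam <- matrix(rate_lo, K, C)
  blk <- floor(C / K)
  for (k in seq_len(K)) Lam[k, ((k - 1) * blk + 1):(k * blk)] <- rate_hi
  s <- integer(T)
  s[1] <- 1L
  for (t in 2:T) s[t] <- sample.int(K, 1L, prob = P[s[t - 1], ])
  Y <- matrix(stats::rpois(C * T, t(Lam[s, ]) * delta), C, T)
  list(sm = spike_matrix(Y, delta), P = P, Lam = Lam, states = s)
}

# All permutations of a small vector (used instead of a Hungarian solver:
# K! is tiny for the K used in tests).
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# Best-permutation (one-to-one) Frobenius distance between an inferred and a
# true transition matrix; NA when the state counts differ.
frob_perm <- function(fit, Ptrue) {
  K <- nrow(Ptrue)
  if (fit$m != K) return(NA_real_)
  best <- Inf
  for (p in all_perms(seq_len(K)))
    best <- min(best, sqrt(sum((fit$P[p, p] - Ptrue)^2)))
  best
}

# Many-to-one evaluation tolerant of over-segmentation: each inferred state
# is assigned to the nearest true state by its rate vector, and the inferred
# transition matrix is aggregated with occupancy weights before comparison.
frob_aggregated <- function(fit, Ptrue, LamTrue) {
  K <- nrow(Ptrue)
  asg <- apply(fit$Lambda, 1, function(l)
    which.min(colSums((t(LamTrue) - l)^2)))
  if (length(unique(asg)) < K) return(NA_real_)
  occ <- fit$occupancy
  Pa <- matrix(0, K, K)
  for (k in seq_len(K)) {
    ik <- which(asg == k)
    w <- occ[ik] / sum(occ[ik])
    for (l in seq_len(K))
      Pa[k, l] <- sum(w * rowSums(fit$P[ik, asg == l, drop = FALSE]))
  }
  sqrt(sum((Pa - Ptrue)^2))
}

# Small open-field ground truth shared by several tests.
test_env_2d <- function() spatial_env("open_field", c(100, 100), 15)
test_env_1d <- function(kind = "linear_track") spatial_env(kind, 200, 10)

test_fields_2d <- function(n_cells = 40, seed = 42)
  make_ground_truth_fields(test_env_2d(), n_cells = n_cells, seed = seed)

test_fields_1d <- function(n_cells = 40, seed = 42, kind = "linear_track")
  make_ground_truth_fields(test_env_1d(kind), n_cells = n_cells, seed = seed)

# Straight 1-D traversal positions for replay events.
line_path <- function(env, n_bins) cbind(seq(0.1, 0.9, length.out = n_bins) * env$extent)
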