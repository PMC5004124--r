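test_that("single-state data is recovered as m = 1", {
  set.seed(20)
  sm <- spike_matrix(matrix(rpois(10 * 400, 0.5), 10, 400), 0.25)
  # duplicate-state modes on unstructured data take a while to merge, so
  # this degenerate case gets a longer chain than the structured fixtures
  fit <- suppressWarnings(fit_hdp_hmm(sm, L = 10, n_iter = 300, burn_in = 150,
                                      seed = 1))
  expect_equal(fit$m, 1)
  expect_equal(fit$P, matrix(1, 1, 1))
  g <- state_posteriors(fit, sm)
  expect_true(all(g == 1))
})

test_that("the sampler validates its inputs", {
  sm <- spike_matrix(matrix(0L, 3, 50), 0.25)
  expect_error(fit_hdp_hmm(sm, L = 10, n_iter = 10, burn_in = 5), "no spikes")
  sm2 <- spike_matrix(matrix(1L, 3, 50), 0.25)
  expect_error(fit_hdp_hmm(sm2, L = 100), "below truncation")
})

test_that("state posteriors are normalised and match the emission structure", {
  d <- gen_hmm_data(600, seed = 21)
  fit <- suppressWarnings(fit_hdp_hmm(d$sm, L = 10, n_iter = 80, burn_in = 40,
                                      seed = 2))
  g <- state_posteriors(fit, d$sm)
  expect_true(all(abs(rowSums(g) - 1) < 1e-9))
  expect_true(all(g >= 0))
  wrong <- spike_matrix(matrix(1L, 5, 10), 0.25)
  expect_error(state_posteriors(fit, wrong), "cell population")
})

test_that("viterbi recovers labels for near-deterministic emissions", {
  # 2 states with disjoint active cells, sticky transitions
  model <- structure(list(m = 2,
                          P = matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2),
                          Lambda = rbind(c(20, 20, 0.01, 0.01),
                                         c(0.01, 0.01, 20, 20)),
                          pi0 = c(0.5, 0.5), delta = 0.25, cell_ids = 1:4,
                          active_states = 1:2, occupancy = c(1, 1),
                          full = list(L = 2)),
                     class = "hmm_model")
  truth <- rep(c(1L, 2L), each = 10)
  set.seed(22)
  Y <- matrix(rpois(4 * 20, t(model$Lambda[truth, ]) * 0.25), 4, 20)
  sm <- spike_matrix(Y, 0.25)
  vt <- viterbi_path(model, sm)
  expect_identical(vt$path, truth)
  expect_gte(vt$avg_map_score, 1 / model$m)
  expect_lte(vt$avg_map_score, 1)
})

test_that("viterbi equals exhaustive enumeration on small instances", {
  set.seed(23)
  m <- 3; T <- 6
  grid <- as.matrix(expand.grid(rep(list(1:m), T)))
  for (rep_i in 1:5) {
    P <- matrix(rgamma(m * m, 1), m, m); P <- P / rowSums(P)
    pi0 <- rgamma(m, 1); pi0 <- pi0 / sum(pi0)
    ll <- matrix(log(runif(T * m)), T, m)
    brute <- apply(grid, 1, function(s)
      log(pi0[s[1]]) + sum(ll[cbind(1:T, s)]) +
        sum(log(P[cbind(s[-T], s[-1])])))
    vt <- sleepreplay:::viterbi_cpp(ll, log(P), log(pi0))
    expect_equal(vt$logprob, max(brute), tolerance = 1e-10)
    expect_equal(as.integer(vt$path), as.integer(grid[which.max(brute), ]))
  }
})

test_that("transition recovery improves with more data", {
  # best-permutation match at the sizes where m is recovered exactly, and a
  # many-to-one rate-vector match (tolerant of state splitting) overall:
  # the aggregated error must shrink monotonically over the T grid
  errs <- numeric(0)
  for (T in c(500, 2000, 8000)) {
    d <- gen_hmm_data(T, seed = 11)
    fit <- suppressWarnings(fit_hdp_hmm(d$sm, L = 15, n_iter = 300,
                                        burn_in = 150, seed = 3))
    errs <- c(errs, frob_aggregated(fit, d$P, d$Lam))
  }
  expect_true(all(is.finite(errs)))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[length(errs)], 0.15)
})

test_that("state-space decoding is equivariant under label permutation", {
  d <- gen_hmm_data(1000, seed = 24)
  fit <- suppressWarnings(fit_hdp_hmm(d$sm, L = 12, n_iter = 120, burn_in = 60,
                                      seed = 4))
  # attach synthetic positions: one location per generating state
  env <- test_env_1d()
  posx <- c(25, 75, 125, 175)[d$states]
  bp <- data.frame(bin = seq_along(posx), x = posx, speed = 20)
  attr(bp, "env") <- env
  attr(d$sm, "bin_pos") <- bp
  err1 <- decode_position_from_states(fit, build_state_space_map(fit, d$sm, env),
                                      d$sm)
  # permute the model's state labels
  perm <- rev(seq_len(fit$m))
  fit2 <- fit
  fit2$P <- fit$P[perm, perm]
  fit2$Lambda <- fit$Lambda[perm, , drop = FALSE]
  fit2$pi0 <- fit$pi0[perm]
  fit2$occupancy <- fit$occupancy[perm]
  err2 <- decode_position_from_states(fit2, build_state_space_map(fit2, d$sm, env),
                                      d$sm)
  expect_equal(as.numeric(err1), as.numeric(err2), tolerance = 1e-9)
  expect_equal(fit2$m, fit$m)
})

test_that("states inherit the location of their assigned bins", {
  d <- gen_hmm_data(1500, seed = 25)
  fit <- suppressWarnings(fit_hdp_hmm(d$sm, L = 12, n_iter = 150, burn_in = 75,
                                      seed = 5))
  env <- test_env_1d()
  segs <- c(25, 75, 125, 175)
  bp <- data.frame(bin = seq_along(d$states), x = segs[d$states], speed = 20)
  attr(bp, "env") <- env
  attr(d$sm, "bin_pos") <- bp
  map <- build_state_space_map(fit, d$sm, env)
  # every mapped state's centroid sits essentially on one of the segments
  cen <- map$x[map$mapped]
  expect_true(all(vapply(cen, function(x) min(abs(x - segs)), 0) < 15))
  err <- decode_position_from_states(fit, map, d$sm)
  expect_lt(as.numeric(err), 15)
  expect_lt(attr(err, "excluded_fraction"), 0.05)
})

test_that("the topology graph of a ring transition matrix is a cycle", {
  K <- 8
  P <- matrix(0.001, K, K)
  for (k in seq_len(K)) {
    P[k, k %% K + 1L] <- 0.45
    P[k, (k - 2L) %% K + 1L] <- 0.45
  }
  P <- P / rowSums(P)
  topo <- topology_layout(P, strength_threshold = 0.2)
  expect_true(all(topo$degree_above_threshold == 2))
  expect_true(all(topo$layout >= 0 & topo$layout <= 1))
  # symmetric strengths: w_ij = P_ij + P_ji
  W <- igraph::as_adjacency_matrix(topo$graph, attr = "weight", sparse = FALSE)
  expect_equal(unname(W), P + t(P) - diag(diag(P + t(P))), tolerance = 1e-12)
  # single-node graph degenerates gracefully
  single <- topology_layout(matrix(1, 1, 1))
  expect_equal(nrow(single$layout), 1)
})
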