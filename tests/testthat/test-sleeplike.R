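test_that("make_nonplace_cells conserves each cell's total count exactly", {
  set.seed(1)
  sm <- spike_matrix(matrix(rpois(5 * 400, 0.8), 5, 400), 0.25)
  before <- rowSums(sm$counts)
  out <- make_nonplace_cells(sm, c(2, 4), seed = 7)
  expect_identical(rowSums(out$counts), before)
  expect_identical(out$counts[c(1, 3, 5), ], sm$counts[c(1, 3, 5), ])
  expect_identical(make_nonplace_cells(sm, integer(0)), sm)
  expect_error(make_nonplace_cells(sm, 9), "invalid")
})

test_that("non-place conversion flattens the tuning curve in the limit", {
  # T = 50,000 bins on a two-position trajectory with uniform occupancy:
  # after conversion the max/min tuning ratio approaches 1
  env <- test_env_1d()
  T <- 50000
  pos <- data.frame(bin = seq_len(T), x = rep(c(25, 175), T / 2),
                    speed = rep(20, T))
  lam <- ifelse(pos$x < 100, 8, 0.5)           # strongly tuned cell
  set.seed(2)
  sm <- spike_matrix(matrix(rpois(T, lam * 0.25), 1, T), 0.25)
  attr(sm, "bin_pos") <- pos
  out <- make_nonplace_cells(sm, 1, seed = 3)
  rate_left <- mean(out$counts[1, pos$x < 100])
  rate_right <- mean(out$counts[1, pos$x >= 100])
  expect_lt(max(rate_left, rate_right) / min(rate_left, rate_right), 1.05)
})

test_that("speed filter keeps exactly the fast bins", {
  env <- test_env_1d()
  # alternating fast/immobile 250-ms bins: positions chosen so consecutive
  # trajectory samples move 7.5 cm (30 cm/s at 4 Hz) or stay put
  t <- seq(0, 99.75, by = 0.25)
  x <- rep(c(50, 57.5), length.out = length(t))
  x[rep(c(FALSE, TRUE), each = 2, length.out = length(t))] <- 50  # immobile pairs
  tr <- trajectory(t, x, env = env)
  sm <- spike_matrix(matrix(1L, 2, 399), delta = 0.25, t0 = 0)
  out <- apply_speed_filter(sm, tr, threshold = 15)
  expect_lt(abs(ncol(out$counts) / 399 - 0.5), 0.05)
  expect_identical(attr(out, "kept_bins"), which(bin_trajectory(tr, sm)$speed >= 15))
  # constant fast speed: unchanged
  tr2 <- trajectory(seq(0, 10, by = 0.05), seq(0, 200, length.out = 201),
                    env = env)
  sm2 <- spike_matrix(matrix(1L, 1, 40), delta = 0.25)
  expect_equal(ncol(apply_speed_filter(sm2, tr2)$counts), 40)
  # constant slow speed: error
  tr3 <- trajectory(seq(0, 10, by = 0.05), seq(0, 10, length.out = 201),
                    env = env)
  expect_error(apply_speed_filter(sm2, tr3), "no data above speed threshold")
})

test_that("epoch splitting partitions the bins and honours its flags", {
  set.seed(4)
  sm <- spike_matrix(matrix(rpois(3 * 100, 1), 3, 100), 0.25)
  eps <- split_into_epochs(sm, 10, seed = 1)
  expect_equal(length(eps$epochs), 10)
  expect_true(all(vapply(eps$epochs, function(e) ncol(e$counts), 0L) == 10))
  # all source bins appear exactly once
  idx <- sort(unlist(lapply(eps$epochs, attr, "bin_index")))
  expect_identical(idx, 1:100)
  # T0 = T, no reversal, no shuffling: identity
  one <- split_into_epochs(sm, 100, reverse_prob = 0, shuffle_order = FALSE)
  expect_identical(one$epochs[[1]]$counts, sm$counts)
  # remainder dropped
  eps2 <- split_into_epochs(sm, 30, seed = 2)
  expect_equal(length(eps2$epochs), 3)
  expect_error(split_into_epochs(sm, 101), "T0")
})

test_that("epoch reversal is an involution", {
  set.seed(5)
  sm <- spike_matrix(matrix(rpois(2 * 20, 1), 2, 20), 0.25)
  eps <- split_into_epochs(sm, 20, reverse_prob = 1, shuffle_order = FALSE)
  rev1 <- eps$epochs[[1]]
  expect_identical(rev1$counts, sm$counts[, 20:1])
  eps2 <- split_into_epochs(rev1, 20, reverse_prob = 1, shuffle_order = FALSE)
  expect_identical(eps2$epochs[[1]]$counts, sm$counts)
})

test_that("cell subsampling sizes follow round-half-up with a floor", {
  set.seed(6)
  sm <- spike_matrix(matrix(rpois(50 * 40, 1), 50, 40), 0.25)
  eps <- split_into_epochs(sm, 10, seed = 1)
  sub <- subsample_cells(eps, 0.3, seed = 2)
  expect_equal(length(sub$meta$active_cells[[1]]), 15)       # 0.3 * 50
  # all epochs share the subset when per_epoch = FALSE
  expect_true(all(vapply(sub$meta$active_cells, identical,
                         logical(1), sub$meta$active_cells[[1]])))
  # floor at min_cells
  sm20 <- spike_matrix(matrix(rpois(20 * 40, 1), 20, 40), 0.25)
  sub20 <- subsample_cells(split_into_epochs(sm20, 10, seed = 1), 0.3, seed = 2)
  expect_equal(length(sub20$meta$active_cells[[1]]), 10)
  # rho = 1 keeps every cell active
  all50 <- subsample_cells(eps, 1, seed = 3)
  expect_equal(length(all50$meta$active_cells[[1]]), 50)
  expect_error(subsample_cells(eps, 0), "rho")
  # per-epoch subsets differ (with overwhelming probability at these sizes)
  pe <- subsample_cells(eps, 0.3, per_epoch = TRUE, seed = 4)
  expect_gt(length(unique(pe$meta$active_cells)), 1)
})

test_that("thinning clips to one spike per bin", {
  sm <- spike_matrix(matrix(c(0L, 1L, 3L, 7L), 2, 2), 0.02)
  th <- thin_spikes(sm)
  expect_identical(as.integer(th$counts), c(0L, 1L, 1L, 1L))
  z <- spike_matrix(matrix(0L, 2, 2), 0.02)
  expect_identical(thin_spikes(z)$counts, z$counts)
  # clipped Poisson(1): active fraction -> 1 - exp(-1)
  set.seed(7)
  big <- spike_matrix(matrix(rpois(2e5, 1), 1), 0.02)
  frac <- mean(thin_spikes(big)$counts)
  expect_lt(abs(frac - (1 - exp(-1))), 0.005)
})

test_that("bin removal empties exactly n bins and never adds spikes", {
  set.seed(8)
  sm <- spike_matrix(matrix(rpois(4 * 20, 2), 4, 20), 0.02)
  out <- remove_time_bins(sm, 10, seed = 9)
  expect_equal(ncol(out$counts), 20)
  killed <- attr(out, "removed_bins")
  expect_equal(length(killed), 10)
  expect_true(all(out$counts[, killed] == 0L))
  expect_identical(out$counts[, -killed], sm$counts[, -killed])
  expect_lte(sum(out$counts), sum(sm$counts))
  expect_identical(remove_time_bins(sm, 0), sm)
  expect_error(remove_time_bins(sm, 21), "n_bins")
})
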