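# One-bin-per-position toy session over a linear track with uniform
# occupancy: positions cycle through the bin centres.
toy_session <- function(n_cycles = 50, counts_fn, delta = 0.25) {
  env <- test_env_1d()                 # 200 cm, 10-cm bins -> 20 spatial bins
  centers <- (seq_len(20) - 0.5) * 10
  x <- rep(centers, n_cycles)
  T <- length(x)
  pos <- data.frame(bin = seq_len(T), x = x, speed = rep(20, T))
  sm <- spike_matrix(counts_fn(x), delta)
  attr(sm, "bin_pos") <- pos
  list(sm = sm, env = env, centers = centers)
}

test_that("a cell spiking in a single bin peaks there", {
  s <- toy_session(10, function(x) matrix(as.integer(x > 40 & x < 50), 1))
  pfm <- estimate_place_fields(s$sm, env = s$env)
  expect_equal(which.max(pfm$lambda[1, ]), 5)    # bin covering (40, 50]
  pfm_raw <- estimate_place_fields(s$sm, env = s$env, smooth = FALSE)
  expect_equal(which.max(pfm_raw$lambda[1, ]), 5)
  expect_equal(sum(pfm_raw$lambda[1, ] > 0), 1)
})

test_that("a homogeneous 2 Hz cell estimates a flat 2 Hz field", {
  set.seed(10)
  s <- toy_session(500, function(x) matrix(rpois(length(x), 2 * 0.25), 1))
  pfm <- estimate_place_fields(s$sm, env = s$env)
  # each bin holds 125 s of data; SE of the rate is sqrt(2/125) ~ 0.13 Hz
  se <- sqrt(2 / 125)
  expect_true(all(abs(pfm$lambda[1, ] - 2) < 4 * se))
})

test_that("smoothing conserves each cell's total spike mass", {
  env <- test_env_2d()
  f <- test_fields_2d()
  tr <- simulate_trajectory(env, 120, seed = 1)
  sm <- sample_spike_counts(f, tr, 0.25, seed = 2)
  pfm <- estimate_place_fields(sm, env = env)
  tot <- as.numeric(pfm$lambda[, pfm$mask] %*% pfm$occupancy_time[pfm$mask])
  expect_equal(tot, rowSums(sm$counts + 0), tolerance = 1e-9)
  expect_equal(sum(pfm$occupancy[pfm$mask]), 1, tolerance = 1e-12)
  # positivity preserved
  expect_true(all(pfm$lambda[, pfm$mask] >= 0))
  # unvisited bins masked, not zero
  if (any(!pfm$mask)) expect_true(all(is.na(pfm$lambda[, !pfm$mask])))
})

test_that("field estimation is invariant to permuting the time bins", {
  env <- test_env_1d()
  f <- test_fields_1d()
  tr <- simulate_trajectory(env, 120, seed = 3)
  sm <- sample_spike_counts(f, tr, 0.25, seed = 4)
  pos <- attr(sm, "bin_pos")
  set.seed(5)
  perm <- sample.int(ncol(sm$counts))
  smp <- spike_matrix(sm$counts[, perm], sm$delta)
  posp <- pos[perm, ]
  a <- estimate_place_fields(sm, pos = pos, env = env)
  b <- estimate_place_fields(smp, pos = posp, env = env)
  expect_equal(a$lambda, b$lambda, tolerance = 1e-12)
  expect_equal(a$occupancy, b$occupancy, tolerance = 1e-12)
})

test_that("information-rate closed forms hold", {
  env <- test_env_1d()
  mk_pfm <- function(lam) {
    n <- length(lam)
    structure(list(lambda = matrix(lam, 1), occupancy = rep(1 / n, n),
                   occupancy_time = rep(1, n), mask = rep(TRUE, n),
                   bins = list(n = n), env = env, cell_ids = 1,
                   smoothing = "none"),
              class = "place_field_map")
  }
  flat <- spatial_information_rate(mk_pfm(rep(3, 20)))
  expect_equal(flat$bits_per_sec, 0, tolerance = 1e-12)
  # two equal-occupancy bins at (2, 0) Hz: mean 1 Hz, 1 bit/s, 1 bit/spike
  two <- spatial_information_rate(mk_pfm(c(2, 0)))
  expect_equal(two$mean_rate_hz, 1)
  expect_equal(two$bits_per_sec, 1, tolerance = 1e-12)
  expect_equal(two$bits_per_spike, 1, tolerance = 1e-12)
  # one active bin of N: log2(N) bits/spike, exactly
  for (N in c(4, 16, 25)) {
    lam <- c(N, rep(0, N - 1))                 # mean rate 1 Hz
    one <- spatial_information_rate(mk_pfm(lam))
    expect_equal(one$bits_per_spike, log2(N), tolerance = 1e-12)
  }
  # silent cell: zero with a warning
  expect_warning(sil <- spatial_information_rate(mk_pfm(rep(0, 5))), "no spikes")
  expect_equal(sil$bits_per_sec, 0)
})

test_that("the information split matches its worked examples", {
  env <- test_env_1d()
  # 4 cells firing in 1, 2, 4, 8 of 16 uniform bins (decreasing bits/spike)
  lam <- rbind(c(16, rep(0, 15)),
               c(rep(8, 2), rep(0, 14)),
               c(rep(4, 4), rep(0, 12)),
               c(rep(2, 8), rep(0, 8)))
  pfm <- structure(list(lambda = lam, occupancy = rep(1 / 16, 16),
                        occupancy_time = rep(1, 16), mask = rep(TRUE, 16),
                        bins = list(n = 16), env = env, cell_ids = 1:4,
                        smoothing = "none"),
                   class = "place_field_map")
  sp <- partition_by_information(pfm)
  expect_equal(sp$high_ids, c(1, 2))
  expect_equal(sp$low_ids, c(3, 4))
  # all-equal information: split by index, extra cell to the low group
  lam5 <- matrix(rep(c(16, rep(0, 15)), 5), 5, 16, byrow = TRUE)
  pfm5 <- pfm; pfm5$lambda <- lam5; pfm5$cell_ids <- 1:5
  sp5 <- partition_by_information(pfm5)
  expect_equal(sp5$high_ids, c(4, 5))
  expect_equal(sp5$low_ids, c(1, 2, 3))
})
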