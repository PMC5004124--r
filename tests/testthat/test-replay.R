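mk_post <- function(m, x = NULL) {
  m <- m / rowSums(m)
  structure(m, support = if (is.null(x)) NULL else cbind(x),
            class = c("posterior_matrix", "matrix"))
}

test_that("weighted correlation reproduces its closed-form cases", {
  expect_equal(weighted_correlation(mk_post(diag(3))), 1)
  expect_equal(weighted_correlation(mk_post(diag(3)[3:1, ])), -1)
  expect_equal(weighted_correlation(mk_post(matrix(1, 4, 5))), 0)
  hand <- mk_post(rbind(c(0.7, 0.3), c(0.3, 0.7)))
  expect_equal(weighted_correlation(hand), 0.4, tolerance = 1e-12)
  # degenerate: a single time bin has zero weighted time variance
  expect_true(is.na(weighted_correlation(mk_post(matrix(c(0.5, 0.5), 1)))))
})

test_that("weighted correlation equals Pearson correlation on one-hot rows", {
  set.seed(30)
  for (i in 1:20) {
    T <- sample(5:30, 1); S <- sample(4:15, 1)
    idx <- sample.int(S, T, replace = TRUE)
    m <- matrix(0, T, S)
    m[cbind(seq_len(T), idx)] <- 1
    r_ref <- suppressWarnings(stats::cor(seq_len(T), idx))
    r_w <- weighted_correlation(mk_post(m))
    if (is.na(r_ref) || stats::sd(idx) == 0) expect_true(is.na(r_w))
    else expect_equal(r_w, r_ref, tolerance = 1e-12)
  }
})

test_that("weighted correlation stays within [-1, 1] on random posteriors", {
  set.seed(31)
  for (i in 1:200) {
    m <- matrix(rgamma(8 * 6, 0.5), 8, 6)
    r <- weighted_correlation(mk_post(m))
    expect_true(is.na(r) || (r >= -1 - 1e-12 && r <= 1 + 1e-12))
  }
})

test_that("shuffles conserve the multiset of matrix entries", {
  env <- test_env_1d()
  f <- test_fields_1d()
  ev <- make_replay_event(f, line_path(env, 10), seed = 1)
  decoder <- replay_decoder_rf(true_field_map(f))
  # a decoder that records the shuffled matrices
  seen <- list()
  spy <- function(sm) { seen[[length(seen) + 1]] <<- sm$counts; decoder(sm) }
  null <- shuffle_null(ev$event, spy, n_shuffle = 100, seed = 2)
  expect_length(null$R_shuffle, 100)
  orig_cells <- sort(rowSums(ev$event$counts))
  orig_bins <- sort(colSums(ev$event$counts))
  for (m in seen) {
    expect_identical(sort(as.integer(m)), sort(as.integer(ev$event$counts)))
    expect_identical(sort(rowSums(m)), orig_cells)    # cell totals permuted
    expect_identical(sort(colSums(m)), orig_bins)     # bin totals permuted
  }
  expect_error(shuffle_null(ev$event, decoder, n_shuffle = 10), "at least 100")
})

test_that("a strong forward event beats its shuffle null", {
  env <- test_env_1d()
  f <- test_fields_1d()
  ev <- make_replay_event(f, line_path(env, 10), gain = 5, seed = 3)
  decoder <- replay_decoder_rf(true_field_map(f))
  R <- weighted_correlation(decoder(ev$event))
  null <- shuffle_null(ev$event, decoder, n_shuffle = 200, seed = 4)
  expect_gt(abs(R), stats::quantile(abs(null$R_shuffle), 0.99, na.rm = TRUE))
})

test_that("z-scores and p-values follow their definitions", {
  # null values already non-negative: |R| leaves them unchanged
  Rs <- c(0.1, 0.2, 0.3, 0.2, 0.2)
  zp <- zscore_pvalue(0.2, Rs)
  expect_equal(zp$Z, 0)                       # raw at the null mean
  zp2 <- zscore_pvalue(mean(Rs) + stats::sd(Rs), Rs)
  expect_equal(zp2$Z, 1)
  # raw above every shuffle in the Monte Carlo branch: p = 1/(n+1)
  set.seed(32)
  skew <- abs(rcauchy(1000)) / 10             # decidedly non-normal null
  zp3 <- zscore_pvalue(max(skew) + 1, skew)
  expect_equal(zp3$p_method, "monte_carlo")
  expect_equal(zp3$p, 1 / 1001)
  expect_error(zscore_pvalue(0.5, c(0.1, 0.2)), "too small")
})

test_that("the three criteria combine as a conjunction", {
  sig <- classify_significance(R = 0.56, Z = 1.83, n_bins = 10,
                               avg_map_score = 0.4, n_support_bins = 40)
  expect_true(sig$significant)
  expect_equal(sig$direction, "forward")
  # criterion 1 fails
  c1 <- classify_significance(R = 0.49, Z = 3, n_bins = 10,
                              avg_map_score = 0.4, n_support_bins = 40)
  expect_false(c1$r_pass); expect_false(c1$significant)
  # 4-bin event fails regardless of R
  c2 <- classify_significance(R = 0.9, Z = 5, n_bins = 4,
                              avg_map_score = 0.4, n_support_bins = 40)
  expect_false(c2$length_pass); expect_false(c2$significant)
  # MAP score at chance fails
  c3 <- classify_significance(R = 0.9, Z = 5, n_bins = 10,
                              avg_map_score = 0.1, n_support_bins = 40)
  expect_false(c3$map_pass)
  # Monte Carlo branch gates on p < 0.05
  c4 <- classify_significance(R = 0.9, Z = NA, n_bins = 10,
                              avg_map_score = 0.4, n_support_bins = 40,
                              p = 0.01, p_method = "monte_carlo")
  expect_true(c4$z_pass)
  c5 <- classify_significance(R = -0.9, Z = 5, n_bins = 10,
                              avg_map_score = 0.4, n_support_bins = 40)
  expect_equal(c5$direction, "reverse")
})

test_that("the candidate detector finds an injected burst and applies the cell floor", {
  env <- test_env_1d()
  f <- make_ground_truth_fields(env, n_cells = 60, seed = 40)
  ev <- make_replay_event(f, line_path(env, 10), gain = 10, seed = 41)
  counts <- spike_matrix(cbind(matrix(rpois(60 * 250, 0.5 * 0.02), 60),
                               ev$event$counts,
                               matrix(rpois(60 * 250, 0.5 * 0.02), 60)),
                         0.02)
  events <- detect_candidate_events(ev$mua, counts)
  expect_equal(attr(events, "n_retained"), 1)
  got <- events[[1]]
  expect_lte(got$interval[1], ev$onset_bin + 2)
  expect_gte(got$interval[2], ev$onset_bin + 7)
  expect_gte(got$n_active, max(6, ceiling(0.10 * 60)))
  # an isolated burst activating only 3 of 60 cells: detected by the MUA
  # threshold but rejected by the 6-cell floor
  m3 <- matrix(0L, 60, 600)
  m3[1:3, 301:310] <- 5L
  sparse <- spike_matrix(m3, 0.02)
  ev2 <- detect_candidate_events(colSums(m3), sparse)
  expect_gte(attr(ev2, "n_detected"), 1)
  expect_equal(length(ev2), 0)
  # flat trace: warning, no events
  expect_warning(none <- detect_candidate_events(rep(5, 1000)), "flat")
  expect_equal(length(none), 0)
})

test_that("population comparison produces the summary-table schema", {
  env <- test_env_1d()
  f <- test_fields_1d()
  decoder <- replay_decoder_rf(true_field_map(f))
  strong <- lapply(1:4, function(i)
    assess_replay(make_replay_event(f, line_path(env, 10), gain = 5,
                                    seed = i)$event,
                  decoder, n_shuffle = 100, seed = 100 + i))
  set.seed(50)
  weak <- lapply(1:4, function(i) {
    noise <- spike_matrix(matrix(rpois(40 * 10, 0.3), 40, 10), 0.02)
    assess_replay(noise, decoder, n_shuffle = 100, seed = 200 + i)
  })
  cmp <- compare_epoch_populations(strong, weak, labels = c("post", "pre"))
  expect_setequal(names(cmp$table),
                  c("n_total", "n_active10", "n_r", "n_z", "n_sig",
                    "median_absR", "median_Z"))
  expect_equal(cmp$table$n_total, c(4L, 4L))
  expect_gte(cmp$table["post", "n_sig"], cmp$table["pre", "n_sig"])
  expect_true(all(unlist(cmp$tests) >= 0 & unlist(cmp$tests) <= 1, na.rm = TRUE))
})
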