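#' Poisson population log-likelihood over a decoding support
#'
#' For one temporal bin: `l(S) = sum_c [ y_c log(lambda_c(S) delta)
#' - lambda_c(S) delta - log(y_c!) ]`. Rates are floored at `rate_floor`
#' (default 0.01 Hz) before taking logs, so finite-sample empty field bins
#' never produce `-Inf`.
#'
#' @param y Spike counts, one per cell (vector) or cells x time-bins matrix.
#' @param lambda Rate matrix, cells x support bins, Hz (`NA` columns are the
#'   caller's responsibility to exclude).
#' @param delta Bin width, s.
#' @param rate_floor Minimum rate substituted before the log, Hz.
#' @return Log-likelihood: a vector over support bins (vector `y`) or a
#'   time-bins x support matrix (matrix `y`).
#' @export
poisson_loglik <- function(y, lambda, delta, rate_floor = 0.01) {
  vec <- is.null(dim(y))
  y <- if (vec) matrix(y, ncol = 1) else y
  if (any(y < 0)) stop("negative spike counts", call. = FALSE)
  lam <- pmax(lambda, rate_floor) * delta
  ll <- crossprod(y, log(lam))                       # T x S: sum_c y log(lam)
  ll <- sweep(ll, 2, colSums(lam), "-")
  ll <- ll - colSums(lgamma(y + 1))   # per-time-bin constant
  if (vec) ll[1, ] else ll
}

#' Bayesian position decoding from population spike counts
#'
#' Computes the posterior over the visited spatial bins for every temporal
#' bin under the Poisson likelihood. With a uniform temporal prior each bin
#' is decoded independently (row-normalised likelihood); with a Markov prior
#' the forward filter `p(S_t | y_{1:t})` is run with the supplied transition
#' matrix. All computation is in the log domain with per-row max
#' subtraction.
#'
#' @param sm A [spike_matrix()].
#' @param field A [estimate_place_fields()] map.
#' @param prior `"uniform"` or `"markov"`.
#' @param P Transition matrix over the support (required for `"markov"`),
#'   rows summing to 1, dimension = number of visited bins.
#' @param cells Optional indices (into the field's cell list) restricting
#'   the likelihood to a subset of cells; defaults to the epoch's
#'   `"active_cells"` attribute if present, else all cells.
#' @return A `posterior_matrix`: time bins x support numeric matrix, rows
#'   summing to 1, with attributes `support` (positions of the support bins,
#'   cm), `support_index` (spatial-bin indices), and `env`.
#' @export
decode_posterior <- function(sm, field, prior = c("uniform", "markov"),
                             P = NULL, cells = NULL) {
  prior <- match.arg(prior)
  stopifnot(inherits(sm, "spike_matrix"), inherits(field, "place_field_map"))
  row_map <- if (n_cells(sm) == nrow(field$lambda)) seq_len(n_cells(sm))
             else match(sm$cell_ids, field$cell_ids)
  if (anyNA(row_map))
    stop("spike matrix contains cells absent from the field map", call. = FALSE)
  cells <- if (!is.null(cells)) cells
           else if (!is.null(attr(sm, "active_cells")) &&
                    n_cells(sm) == nrow(field$lambda)) attr(sm, "active_cells")
           else seq_len(n_cells(sm))
  sup <- which(field$mask)
  lam <- field$lambda[row_map[cells], sup, drop = FALSE]
  ll <- poisson_loglik(sm$counts[cells, , drop = FALSE], lam, sm$delta)
  post <- if (prior == "uniform") {
    softmax_rows(ll)
  } else {
    if (is.null(P) || nrow(P) != length(sup))
      stop("`markov` prior needs a transition matrix over the support",
           call. = FALSE)
    forward_filter(ll, P)
  }
  structure(post,
            support = field$bins$centers[sup, , drop = FALSE],
            support_index = sup, env = field$env,
            class = c("posterior_matrix", "matrix"))
}

# Row-wise softmax in the log domain; an all--Inf row falls back to uniform
# with a warning.
softmax_rows <- function(ll) {
  mx <- apply(ll, 1, max)
  bad <- !is.finite(mx)
  if (any(bad)) {
    warning("bin(s) with degenerate likelihood; posterior set to uniform",
            call. = FALSE)
    ll[bad, ] <- 0; mx[bad] <- 0
  }
  w <- exp(ll - mx)
  w / rowSums(w)
}

# Forward filtering p(S_t | y_{1:t}) with a Markov temporal prior; uniform
# initial distribution.
forward_filter <- function(ll, P) {
  T <- nrow(ll); S <- ncol(ll)
  post <- matrix(0, T, S)
  pred <- rep(1 / S, S)
  for (t in seq_len(T)) {
    l <- ll[t, ]
    l <- l - max(l)
    a <- pred * exp(l)
    post[t, ] <- a / sum(a)
    pred <- as.numeric(post[t, ] %*% P)
  }
  post
}

#' Maximum a posteriori path and score from a posterior matrix
#'
#' @param post A `posterior_matrix`.
#' @return List with `map_index` (support index per bin, ties broken to the
#'   lowest index), `map_pos` (decoded positions, cm), `map_prob` (posterior
#'   mass at the MAP per bin) and `avg_map_score` (its mean).
#' @export
map_path <- function(post) {
  idx <- apply(post, 1, which.max)         # which.max: first (lowest) on ties
  sup <- attr(post, "support")
  list(map_index = idx,
       map_pos = sup[idx, , drop = FALSE],
       map_prob = post[cbind(seq_len(nrow(post)), idx)],
       avg_map_score = mean(post[cbind(seq_len(nrow(post)), idx)]))
}

#' Median decoding error against the true trajectory
#'
#' Distance per temporal bin between the MAP position and the animal's true
#' position (Euclidean in 2-D, linear or wrap-around on tracks), summarised
#' by the median.
#'
#' @param post A `posterior_matrix` (from [decode_posterior()]).
#' @param pos True per-bin positions: a data frame with `x` (, `y`), one row
#'   per time bin.
#' @return Median error in cm; the per-bin errors are attached as attribute
#'   `"errors"`.
#' @export
median_decoding_error <- function(post, pos) {
  if (nrow(post) == 0L) stop("empty posterior", call. = FALSE)
  if (nrow(pos) != nrow(post))
    stop("`pos` must have one row per decoded bin", call. = FALSE)
  env <- attr(post, "env")
  mp <- map_path(post)
  err <- position_distance(mp$map_pos, pos_matrix(pos), env)
  structure(stats::median(err), errors = err)
}

#' Decode an epoch set with the receptive-field decoder
#'
#' Decodes every epoch independently (each with its own active-cell subset,
#' if recorded) and scores the MAP positions against the true positions
#' carried by the epochs' bin-to-position metadata.
#'
#' @param epochs An `epoch_set` (or [spike_matrix()]).
#' @param field A [estimate_place_fields()] map.
#' @param prior,P Passed to [decode_posterior()].
#' @return List with `median_error` (cm, over all bins of all epochs),
#'   `errors` (per-bin), `avg_map_score`, and `posteriors` (list).
#' @export
decode_epochs_rf <- function(epochs, field, prior = "uniform", P = NULL) {
  epochs <- as_epoch_set(epochs)
  errs <- list(); scores <- numeric(0); posts <- list()
  for (k in seq_along(epochs$epochs)) {
    ep <- epochs$epochs[[k]]
    bp <- attr(ep, "bin_pos")
    if (is.null(bp)) stop("epochs carry no per-bin positions", call. = FALSE)
    post <- decode_posterior(ep, field, prior = prior, P = P)
    posts[[k]] <- post
    errs[[k]] <- attr(median_decoding_error(post, bp), "errors")
    scores[k] <- map_path(post)$avg_map_score
  }
  all_err <- unlist(errs)
  list(median_error = stats::median(all_err), errors = all_err,
       avg_map_score = mean(scores), posteriors = posts)
}
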