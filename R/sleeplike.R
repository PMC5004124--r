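#' Convert selected cells into non-place cells
#'
#' Redistributes each selected cell's spikes over time bins so the cell's
#' firing is no longer spatially modulated while its total spike count (and
#' hence average rate) is preserved exactly. Spikes are reassigned by a
#' multinomial draw across bins; with the default uniform per-bin weights
#' the spikes land evenly in time, i.e. across space in proportion to the
#' animal's occupancy, which flattens the tuning curve in the
#' large-sample limit.
#'
#' @param sm A [spike_matrix()].
#' @param cell_ids Indices of cells to transform (empty vector = no-op).
#' @param weights Optional per-bin occupancy weights (recycled/normalised);
#'   default uniform.
#' @param seed RNG seed.
#' @return A [spike_matrix()] with the selected rows redistributed.
#' @export
make_nonplace_cells <- function(sm, cell_ids, weights = NULL, seed = NULL) {
  stopifnot(inherits(sm, "spike_matrix"))
  if (length(cell_ids) == 0L) return(sm)
  if (any(cell_ids < 1L | cell_ids > n_cells(sm)))
    stop("invalid `cell_ids`", call. = FALSE)
  T <- n_bins(sm)
  if (is.null(weights)) weights <- rep(1, T)
  if (length(weights) != T || any(weights < 0) || sum(weights) <= 0)
    stop("`weights` must be non-negative with one entry per bin", call. = FALSE)
  p <- weights / sum(weights)
  with_seed(seed, {
    counts <- sm$counts
    for (c in cell_ids) {
      tot <- sum(counts[c, ])
      counts[c, ] <- if (tot > 0) stats::rmultinom(1, tot, p)[, 1] else 0L
    }
    out <- spike_matrix(counts, sm$delta, sm$t0, sm$cell_ids)
    attr(out, "bin_pos") <- attr(sm, "bin_pos")
    out
  })
}

#' Remove immobile periods with a speed filter
#'
#' Drops temporal bins whose mean running speed falls below `threshold`
#' (default 15 cm/s), concatenating the surviving bins in their original
#' order. The retained per-bin positions and the original bin indices are
#' kept as attributes so decoded positions can still be scored against the
#' true trajectory.
#'
#' @param sm A [spike_matrix()].
#' @param traj The aligned [trajectory()] (must cover the matrix time span).
#' @param threshold Speed threshold, cm/s.
#' @return A filtered [spike_matrix()] with attributes `"bin_pos"` (per-bin
#'   positions of the retained bins) and `"kept_bins"` (their original
#'   indices).
#' @export
apply_speed_filter <- function(sm, traj, threshold = 15) {
  stopifnot(inherits(sm, "spike_matrix"))
  pos <- bin_trajectory(traj, sm)
  if (anyNA(pos$speed))
    stop("trajectory does not cover the spike matrix time span", call. = FALSE)
  keep <- which(pos$speed >= threshold)
  if (length(keep) == 0L)
    stop("no data above speed threshold", call. = FALSE)
  out <- spike_matrix(sm$counts[, keep, drop = FALSE], sm$delta, sm$t0,
                      sm$cell_ids)
  bp <- pos[keep, , drop = FALSE]
  attr(bp, "env") <- attr(pos, "env")
  attr(out, "bin_pos") <- bp
  attr(out, "kept_bins") <- keep
  out
}

#' Split a spike matrix into sleep-like epochs
#'
#' Evenly splits the matrix into contiguous blocks of `T0` bins (a trailing
#' partial block is dropped), independently time-reverses each block with
#' probability `reverse_prob`, and optionally permutes the epoch order. This
#' emulates the short, temporally fragmented, possibly time-reversed
#' structure of sleep epochs while preserving within-epoch sequences.
#'
#' @param sm A [spike_matrix()].
#' @param T0 Bins per epoch, `1 <= T0 <= T`.
#' @param reverse_prob Per-epoch reversal probability.
#' @param shuffle_order Permute epoch order after splitting?
#' @param seed RNG seed.
#'
#' @return An object of class `epoch_set`: list with `epochs` (list of
#'   [spike_matrix()]), and `meta`, a data frame with per-epoch `start_bin`,
#'   `end_bin` (in the source matrix) and `reversed`. Each epoch carries a
#'   `"bin_index"` attribute: the source bin index of each of its bins, in
#'   epoch temporal order (so truth lookup survives reversal and
#'   reordering), and inherits any `"bin_pos"` rows from the source.
#' @export
split_into_epochs <- function(sm, T0, reverse_prob = 0.5, shuffle_order = TRUE,
                              seed = NULL) {
  stopifnot(inherits(sm, "spike_matrix"))
  T <- n_bins(sm)
  if (T0 < 1 || T0 > T) stop("`T0` must be in [1, T]", call. = FALSE)
  T0 <- as.integer(T0)
  n_ep <- T %/% T0
  bp <- attr(sm, "bin_pos")
  with_seed(seed, {
    rev_flags <- stats::runif(n_ep) < reverse_prob
    order_idx <- if (shuffle_order) sample.int(n_ep) else seq_len(n_ep)
    epochs <- vector("list", n_ep)
    meta <- data.frame(start_bin = integer(n_ep), end_bin = integer(n_ep),
                       reversed = logical(n_ep))
    for (k in seq_len(n_ep)) {
      src <- order_idx[k]
      idx <- ((src - 1L) * T0 + 1L):(src * T0)
      if (rev_flags[src]) idx <- rev(idx)
      ep <- spike_matrix(sm$counts[, idx, drop = FALSE], sm$delta,
                         sm$t0, sm$cell_ids)
      attr(ep, "bin_index") <- idx
      if (!is.null(bp)) {
        bpe <- bp[idx, , drop = FALSE]
        attr(bpe, "env") <- attr(bp, "env")
        attr(ep, "bin_pos") <- bpe
      }
      epochs[[k]] <- ep
      meta$start_bin[k] <- min(idx); meta$end_bin[k] <- max(idx)
      meta$reversed[k] <- rev_flags[src]
    }
    structure(list(epochs = epochs, meta = meta, T0 = T0,
                   cell_ids = sm$cell_ids, delta = sm$delta),
              class = "epoch_set")
  })
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d bins, %d cells, delta = %g s\n",
              length(x$epochs), x$T0, length(x$cell_ids), x$delta))
  invisible(x)
}

as_epoch_set <- function(x) {
  if (inherits(x, "epoch_set")) return(x)
  stopifnot(inherits(x, "spike_matrix"))
  ep <- x
  if (is.null(attr(ep, "bin_index")))
    attr(ep, "bin_index") <- seq_len(n_bins(x))
  structure(list(epochs = list(ep),
                 meta = data.frame(start_bin = 1L, end_bin = n_bins(x),
                                   reversed = FALSE),
                 T0 = n_bins(x), cell_ids = x$cell_ids, delta = x$delta),
            class = "epoch_set")
}

#' Restrict epochs to a random subset of active cells
#'
#' Emulates the partial cell participation of sleep epochs. The active set
#' has `max(round(rho * C), min_cells)` cells (round-half-up, floored at
#' `min_cells`). With `per_epoch = FALSE` one subset is drawn and applied to
#' all epochs; with `per_epoch = TRUE` an independent subset is drawn for
#' each epoch. In `"zero"` mode non-selected cells' rows are zeroed and the
#' active ids recorded per epoch (decoders then restrict the likelihood to
#' the active cells); in `"drop"` mode (fixed subsets only) the rows are
#' removed.
#'
#' @param epochs An `epoch_set` (or a [spike_matrix()], wrapped as one).
#' @param rho Fraction of cells active, `0 < rho <= 1`.
#' @param per_epoch Draw an independent subset per epoch?
#' @param min_cells Minimum active-set size.
#' @param mode `"zero"` or `"drop"`.
#' @param seed RNG seed.
#' @return An `epoch_set`; `meta` gains a list-column `active_cells`.
#' @export
subsample_cells <- function(epochs, rho, per_epoch = FALSE, min_cells = 10,
                            mode = c("zero", "drop"), seed = NULL) {
  mode <- match.arg(mode)
  epochs <- as_epoch_set(epochs)
  if (rho <= 0 || rho > 1) stop("`rho` must be in (0, 1]", call. = FALSE)
  C <- length(epochs$cell_ids)
  if (C < min_cells)
    stop(sprintf("population has %d cells; fewer than min_cells = %d", C,
                 min_cells), call. = FALSE)
  n_active <- min(C, max(floor(rho * C + 0.5), min_cells))
  if (per_epoch && mode == "drop")
    stop("`drop` mode requires a fixed subset (per_epoch = FALSE)", call. = FALSE)
  with_seed(seed, {
    n_ep <- length(epochs$epochs)
    draws <- if (per_epoch) replicate(n_ep, sort(sample.int(C, n_active)),
                                      simplify = FALSE)
             else rep(list(sort(sample.int(C, n_active))), n_ep)
    out <- epochs
    for (k in seq_len(n_ep)) {
      act <- draws[[k]]
      ep <- out$epochs[[k]]
      if (mode == "drop") {
        sub <- spike_matrix(ep$counts[act, , drop = FALSE], ep$delta, ep$t0,
                            ep$cell_ids[act])
      } else {
        m <- ep$counts
        m[setdiff(seq_len(C), act), ] <- 0L
        sub <- spike_matrix(m, ep$delta, ep$t0, ep$cell_ids)
      }
      attr(sub, "bin_index") <- attr(ep, "bin_index")
      attr(sub, "bin_pos") <- attr(ep, "bin_pos")
      attr(sub, "active_cells") <- act
      out$epochs[[k]] <- sub
    }
    out$meta$active_cells <- I(draws)
    if (mode == "drop") out$cell_ids <- epochs$cell_ids[draws[[1]]]
    out
  })
}

#' Thin spikes to at most one per bin
#'
#' Emulates sparse sleep-timescale firing. `"clip"` mode maps any count of
#' one or more to 1. `"subsample"` mode first retains each spike independently with
#' probability `p`, then clips, which lowers the overall rate as well as
#' sparsifying.
#'
#' @param sm A [spike_matrix()].
#' @param mode `"clip"` (default) or `"subsample"`.
#' @param p Per-spike retention probability for `"subsample"`.
#' @param seed RNG seed (used by `"subsample"` only).
#' @return A [spike_matrix()] with entries in \{0, 1\}.
#' @export
thin_spikes <- function(sm, mode = c("clip", "subsample"), p = 0.5,
                        seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(sm, "spike_matrix"))
  counts <- sm$counts
  if (mode == "subsample") {
    counts <- with_seed(seed, {
      matrix(stats::rbinom(length(counts), counts, p), nrow(counts))
    })
  }
  counts <- pmin(counts, 1L)
  out <- spike_matrix(counts, sm$delta, sm$t0, sm$cell_ids)
  attr(out, "bin_pos") <- attr(sm, "bin_pos")
  attr(out, "bin_index") <- attr(sm, "bin_index")
  attr(out, "active_cells") <- attr(sm, "active_cells")
  out
}

#' Zero out randomly chosen time bins
#'
#' Removes the spikes of all cells in `n_bins` randomly selected temporal
#' bins (the bins themselves remain, empty), sparsifying the event and
#' destroying part of its temporal structure.
#'
#' @param sm A [spike_matrix()].
#' @param n_bins Number of bins to empty, `0 <= n_bins <= T`.
#' @param seed RNG seed.
#' @return A [spike_matrix()] of unchanged dimensions.
#' @export
remove_time_bins <- function(sm, n_bins, seed = NULL) {
  stopifnot(inherits(sm, "spike_matrix"))
  T <- ncol(sm$counts)
  if (n_bins < 0 || n_bins > T)
    stop("`n_bins` must be in [0, T]", call. = FALSE)
  if (n_bins == 0) return(sm)
  with_seed(seed, {
    kill <- sample.int(T, n_bins)
    counts <- sm$counts
    counts[, kill] <- 0L
    out <- spike_matrix(counts, sm$delta, sm$t0, sm$cell_ids)
    attr(out, "bin_pos") <- attr(sm, "bin_pos")
    attr(out, "bin_index") <- attr(sm, "bin_index")
    attr(out, "removed_bins") <- sort(kill)
    out
  })
}
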