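# Spatial discretisation of an environment: bin counts and centres.
spatial_bins <- function(env) {
  if (env$is2d) {
    nx <- max(1L, ceiling(env$extent[1] / env$spatial_bin_cm))
    ny <- max(1L, ceiling(env$extent[2] / env$spatial_bin_cm))
    cx <- (seq_len(nx) - 0.5) * env$extent[1] / nx
    cy <- (seq_len(ny) - 0.5) * env$extent[2] / ny
    centers <- cbind(rep(cx, times = ny), rep(cy, each = nx))
    list(n = nx * ny, nx = nx, ny = ny, centers = centers)
  } else {
    nb <- max(1L, ceiling(env$extent / env$spatial_bin_cm))
    centers <- cbind((seq_len(nb) - 0.5) * env$extent / nb)
    list(n = nb, nx = nb, ny = 1L, centers = centers)
  }
}

# Map positions (rows of a matrix) to spatial bin index (column-major grid).
position_to_bin <- function(pos, env, bins = spatial_bins(env)) {
  pos <- as.matrix(pos)
  clampi <- function(i, n) pmin(pmax(i, 1L), n)
  if (env$is2d) {
    ix <- clampi(floor(pos[, 1] / env$extent[1] * bins$nx) + 1L, bins$nx)
    iy <- clampi(floor(pos[, 2] / env$extent[2] * bins$ny) + 1L, bins$ny)
    (iy - 1L) * bins$nx + ix
  } else {
    clampi(floor(pos[, 1] / env$extent * bins$n) + 1L, bins$n)
  }
}

# Mass-preserving Gaussian smoothing operator over the visited spatial bins.
# Kernel SD = 0.5 bins, truncated at 5 taps (1-D) / 3x3 (2-D). Returns a
# B_vis x B_vis matrix W with unit column sums: each visited source bin
# spreads its mass over visited, in-range targets (renormalised at edges and
# along the mask boundary), so sum(W %*% v) == sum(v) exactly.
smoothing_operator <- function(visited, bins, is2d) {
  half <- if (is2d) 1L else 2L
  k1 <- stats::dnorm(0:half, sd = 0.5)   # indexed by |offset| below
  vis_idx <- which(visited)
  ix <- ((vis_idx - 1L) %% bins$nx) + 1L
  iy <- ((vis_idx - 1L) %/% bins$nx) + 1L
  dx <- outer(ix, ix, "-")
  W <- matrix(0, length(vis_idx), length(vis_idx))
  ok <- abs(dx) <= half
  W[ok] <- k1[abs(dx[ok]) + 1L]
  if (is2d) {
    dy <- outer(iy, iy, "-")
    W2 <- matrix(0, length(vis_idx), length(vis_idx))
    ok2 <- abs(dy) <= half
    W2[ok2] <- k1[abs(dy[ok2]) + 1L]
    W <- W * W2
  }
  sweep(W, 2, colSums(W), "/")
}

#' Estimate occupancy-normalised place fields
#'
#' The classical supervised encoder: per spatial bin, rate = (spikes emitted
#' there) / (time spent there), followed by Gaussian smoothing with a small
#' discrete kernel (5 taps in 1-D, 3x3 in 2-D; SD = 0.5 spatial bins).
#' Smoothing is applied to the spike-count map and to the occupancy-time map
#' and the ratio taken, so each cell's total spike mass
#' `sum_S lambda_c(S) * time(S)` is conserved. Bins never visited are masked
#' (`NA`), not zeroed, and are excluded from the decoding support.
#'
#' @param sm A [spike_matrix()], normally speed-filtered; per-bin positions
#'   are taken from its `"bin_pos"` attribute unless `pos` is given.
#' @param pos Optional per-bin positions (data frame as returned by
#'   [bin_trajectory()], one row per time bin of `sm`).
#' @param env A [spatial_env()].
#' @param smooth Apply the Gaussian smoothing?
#'
#' @return An object of class `place_field_map`: `lambda` (cells x spatial
#'   bins, Hz, `NA` at unvisited bins), `occupancy` (probability per visited
#'   bin, sums to 1), `occupancy_time` (s), `mask` (visited flag per bin),
#'   `bins` (geometry with bin centres), `env`, `cell_ids`.
#' @export
estimate_place_fields <- function(sm, pos = NULL, env, smooth = TRUE) {
  stopifnot(inherits(sm, "spike_matrix"))
  if (is.null(pos)) pos <- attr(sm, "bin_pos")
  if (is.null(pos)) stop("per-bin positions required (`pos` or attr 'bin_pos')",
                         call. = FALSE)
  if (nrow(pos) != n_bins(sm))
    stop("`pos` must have one row per time bin", call. = FALSE)
  bins <- spatial_bins(env)
  sb <- position_to_bin(pos_matrix(pos), env, bins)
  time_map <- numeric(bins$n)
  tm <- rowsum(rep(sm$delta, length(sb)), sb)
  time_map[as.integer(rownames(tm))] <- tm
  spike_map <- matrix(0, n_cells(sm), bins$n)
  spk <- rowsum(t(sm$counts) + 0, sb)        # bins-present x cells
  spike_map[, as.integer(rownames(spk))] <- t(spk)
  visited <- time_map > 0
  if (!any(visited)) stop("zero total occupancy", call. = FALSE)
  tvis <- time_map[visited]
  svis <- spike_map[, visited, drop = FALSE]
  if (smooth) {
    W <- smoothing_operator(visited, bins, env$is2d)
    tvis <- as.numeric(W %*% tvis)
    svis <- svis %*% t(W)
  }
  lambda <- matrix(NA_real_, n_cells(sm), bins$n)
  lambda[, visited] <- sweep(svis, 2, tvis, "/")
  occ_t <- rep(NA_real_, bins$n); occ_t[visited] <- tvis
  occ <- occ_t / sum(tvis)
  structure(list(lambda = lambda, occupancy = occ, occupancy_time = occ_t,
                 mask = visited, bins = bins, env = env,
                 cell_ids = sm$cell_ids,
                 smoothing = if (smooth) "gaussian sd 0.5 bins" else "none"),
            class = "place_field_map")
}

#' @export
print.place_field_map <- function(x, ...) {
  cat(sprintf("<place_field_map> %d cells, %d/%d spatial bins visited (%s)\n",
              nrow(x$lambda), sum(x$mask), x$bins$n, x$smoothing))
  invisible(x)
}

#' Spatial information rate of place cells
#'
#' The Skaggs-style information carried by a cell's firing about position:
#' `I_c = sum_S p(S) lambda_c(S) log2(lambda_c(S) / lbar_c)` bits/s, with
#' `lbar_c = sum_S p(S) lambda_c(S)` the occupancy-weighted mean rate, and
#' the normalised rate `I_c / lbar_c` in bits/spike. The sum runs over
#' visited bins; `0 * log 0` is taken as 0. A silent cell (`lbar_c = 0`)
#' gets `I_c = 0` with a warning.
#'
#' @param field A [estimate_place_fields()] map.
#' @param cells Cell indices (default all).
#' @return Data frame with columns `cell`, `mean_rate_hz`, `bits_per_sec`,
#'   `bits_per_spike`.
#' @export
spatial_information_rate <- function(field, cells = NULL) {
  stopifnot(inherits(field, "place_field_map"))
  if (is.null(cells)) cells <- seq_len(nrow(field$lambda))
  p <- field$occupancy[field$mask]
  out <- data.frame(cell = cells, mean_rate_hz = NA_real_,
                    bits_per_sec = NA_real_, bits_per_spike = NA_real_)
  for (i in seq_along(cells)) {
    lam <- field$lambda[cells[i], field$mask]
    lbar <- sum(p * lam)
    if (lbar <= 0) {
      warning(sprintf("cell %d fired no spikes; information rate set to 0",
                      cells[i]), call. = FALSE)
      out$mean_rate_hz[i] <- 0
      out$bits_per_sec[i] <- 0
      out$bits_per_spike[i] <- 0
      next
    }
    term <- ifelse(lam > 0, p * lam * log2(lam / lbar), 0)
    I <- sum(term)
    out$mean_rate_hz[i] <- lbar
    out$bits_per_sec[i] <- I
    out$bits_per_spike[i] <- I / lbar
  }
  out
}

#' Median split of cells by normalised spatial information
#'
#' Splits the population into information-rich and information-poor halves
#' by their bits/spike. Ties are broken by cell index (deterministic); for
#' odd populations the extra cell goes to the low group.
#'
#' @param field A [estimate_place_fields()] map.
#' @return List with integer vectors `high_ids` and `low_ids`.
#' @export
partition_by_information <- function(field) {
  info <- spatial_information_rate(field)
  C <- nrow(info)
  if (C < 2L) stop("need at least 2 cells to partition", call. = FALSE)
  ord <- order(info$bits_per_spike, info$cell)   # ascending; index breaks ties
  n_high <- C %/% 2L
  list(high_ids = sort(info$cell[ord][(C - n_high + 1L):C]),
       low_ids = sort(info$cell[ord][seq_len(C - n_high)]))
}
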