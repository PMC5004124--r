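#' Spatial environment descriptor
#'
#' Describes the arena the (real or simulated) animal moves in: a linear
#' track, a circular track, or a rectangular open field, together with the
#' spatial bin size used for discretising position.
#'
#' @param kind One of `"linear_track"`, `"circular_track"`, `"open_field"`.
#' @param extent Extent in cm. A single length for tracks (for a circular
#'   track this is the circumference, i.e. positions live on `[0, extent)`
#'   with wrap-around), or a length-2 vector `c(width, height)` for an open
#'   field.
#' @param spatial_bin_cm Spatial bin size in cm (side length of the square
#'   bins for an open field). Defaults: 10 cm for tracks, 15 cm for an open
#'   field.
#'
#' @return An object of class `spatial_env`.
#' @export
spatial_env <- function(kind = c("linear_track", "circular_track", "open_field"),
                        extent,
                        spatial_bin_cm = NULL) {
  kind <- match.arg(kind)
  extent <- as.numeric(extent)
  if (any(!is.finite(extent)) || any(extent <= 0))
    stop("`extent` must be positive and finite", call. = FALSE)
  is2d <- kind == "open_field"
  if (is2d && length(extent) == 1L) extent <- c(extent, extent)
  if (!is2d && length(extent) != 1L)
    stop("track environments take a single extent (length in cm)", call. = FALSE)
  if (is.null(spatial_bin_cm)) spatial_bin_cm <- if (is2d) 15 else 10
  if (spatial_bin_cm <= 0 || spatial_bin_cm > min(extent))
    stop("`spatial_bin_cm` must be positive and no larger than the extent",
         call. = FALSE)
  structure(list(kind = kind, extent = extent, spatial_bin_cm = spatial_bin_cm,
                 is2d = is2d),
            class = "spatial_env")
}

#' @export
print.spatial_env <- function(x, ...) {
  cat(sprintf("<spatial_env> %s, extent %s cm, bin %g cm\n", x$kind,
              paste(x$extent, collapse = " x "), x$spatial_bin_cm))
  invisible(x)
}

#' Binned spike-count matrix
#'
#' Container for population spike counts: a cells x time-bins matrix of
#' non-negative integers, with bin width `delta` (s) and the start time of
#' bin 1. Bins are half-open `[t0 + (k-1) delta, t0 + k delta)`.
#'
#' @param counts Integer matrix, cells in rows, time bins in columns.
#' @param delta Temporal bin width in seconds.
#' @param t0 Start time (s) of the first bin.
#' @param cell_ids Optional cell identifiers (default `1:C`).
#'
#' @return An object of class `spike_matrix`.
#' @export
spike_matrix <- function(counts, delta, t0 = 0, cell_ids = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("spike counts must be non-negative integers", call. = FALSE)
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0)
    stop("`delta` must be a single positive number (seconds)", call. = FALSE)
  storage.mode(counts) <- "integer"
  if (is.null(cell_ids)) cell_ids <- seq_len(nrow(counts))
  if (length(cell_ids) != nrow(counts))
    stop("`cell_ids` must have one entry per row", call. = FALSE)
  structure(list(counts = counts, delta = delta, t0 = t0,
                 cell_ids = cell_ids),
            class = "spike_matrix")
}

#' @export
print.spike_matrix <- function(x, ...) {
  cat(sprintf("<spike_matrix> %d cells x %d bins, delta = %g s, %d spikes\n",
              nrow(x$counts), ncol(x$counts), x$delta, sum(x$counts)))
  invisible(x)
}

#' @export
dim.spike_matrix <- function(x) dim(x$counts)

n_bins <- function(sm) ncol(sm$counts)
n_cells <- function(sm) nrow(sm$counts)

#' Validate and construct a trajectory
#'
#' A trajectory is a data frame with strictly increasing, uniformly sampled
#' times `t` (s), position columns `x` (and `y` for 2-D environments) in cm,
#' and a derived `speed` column (cm/s, central differences).
#'
#' @param t Sample times in seconds (strictly increasing, uniform step).
#' @param x,y Position coordinates in cm (`y = NULL` for 1-D environments).
#' @param env The [spatial_env()] the positions live in.
#'
#' @return A data frame of class `trajectory` with columns `t`, `x`
#'   (, `y`), `speed`, and the environment stored as an attribute.
#' @export
trajectory <- function(t, x, y = NULL, env) {
  if (length(t) < 2L) stop("trajectory needs at least two samples", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0)) stop("trajectory times must be strictly increasing", call. = FALSE)
  if (max(dt) - min(dt) > 1e-6 * mean(dt))
    stop("trajectory must be uniformly sampled", call. = FALSE)
  if (env$is2d) {
    if (is.null(y)) stop("2-D environment requires `y`", call. = FALSE)
    step <- sqrt(diff(x)^2 + diff(y)^2)
  } else {
    if (!is.null(y)) stop("1-D environment takes no `y`", call. = FALSE)
    step <- if (env$kind == "circular_track") {
      d <- abs(diff(x)); pmin(d, env$extent - d)
    } else abs(diff(x))
  }
  speed <- c(step[1], step) / c(dt[1], dt)
  out <- if (env$is2d) data.frame(t = t, x = x, y = y, speed = speed)
         else data.frame(t = t, x = x, speed = speed)
  lo <- if (env$is2d) c(0, 0) else 0
  hi <- if (env$is2d) env$extent else env$extent
  pos <- if (env$is2d) cbind(x, y) else cbind(x)
  if (any(pos < rep(lo, each = nrow(pos)) - 1e-9) ||
      any(pos > rep(hi, each = nrow(pos)) + 1e-9))
    stop("positions fall outside the environment extent", call. = FALSE)
  attr(out, "env") <- env
  class(out) <- c("trajectory", "data.frame")
  out
}

traj_env <- function(traj) attr(traj, "env")

#' Per-time-bin position and speed
#'
#' Averages trajectory position and speed within each half-open temporal bin
#' of a spike matrix. This is the bin-to-position map used by field
#' estimation, decoding-error evaluation, and the state-space map.
#'
#' @param traj A [trajectory()].
#' @param sm A [spike_matrix()] (supplies `delta`, `t0` and the bin count),
#'   or `NULL` to pass `delta`/`t0`/`n` explicitly.
#' @param delta,t0,n Bin width (s), start time (s) and number of bins, used
#'   when `sm` is `NULL`.
#'
#' @return Data frame with one row per bin: `bin`, `x` (, `y`), `speed`.
#'   Bins not covered by the trajectory get `NA`.
#' @export
bin_trajectory <- function(traj, sm = NULL, delta = NULL, t0 = NULL, n = NULL) {
  if (!is.null(sm)) { delta <- sm$delta; t0 <- sm$t0; n <- ncol(sm$counts) }
  idx <- floor((traj$t - t0) / delta) + 1L
  keep <- idx >= 1L & idx <= n
  idx <- idx[keep]
  agg <- function(v) {
    s <- rowsum(v[keep], idx, reorder = TRUE)
    cnt <- rowsum(rep(1, sum(keep)), idx, reorder = TRUE)
    out <- rep(NA_real_, n)
    out[as.integer(rownames(s))] <- s / cnt
    out
  }
  env <- traj_env(traj)
  res <- data.frame(bin = seq_len(n))
  if (!is.null(env) && env$kind == "circular_track") {
    # circular mean so bins straddling the 0/extent seam stay on the track
    th <- traj$x * 2 * pi / env$extent
    cs <- agg(cos(th)); sn <- agg(sin(th))
    ang <- atan2(sn, cs) %% (2 * pi)
    res$x <- ang * env$extent / (2 * pi)
  } else {
    res$x <- agg(traj$x)
  }
  if ("y" %in% names(traj)) res$y <- agg(traj$y)
  res$speed <- agg(traj$speed)
  attr(res, "env") <- env
  res
}

pos_matrix <- function(pos) {
  if ("y" %in% names(pos)) cbind(pos$x, pos$y) else cbind(pos$x)
}

#' Distance between positions in an environment
#'
#' Euclidean distance in 2-D, absolute difference on a linear track, and
#' wrap-around (shorter-arc) distance on a circular track.
#'
#' @param a,b Positions: vectors (1-D) or 2-column matrices (2-D), recycled
#'   row-wise.
#' @param env A [spatial_env()].
#' @return Numeric vector of distances in cm.
#' @export
position_distance <- function(a, b, env) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (env$is2d) {
    sqrt((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2)
  } else if (env$kind == "circular_track") {
    d <- abs(a[, 1] - b[, 1]) %% env$extent
    pmin(d, env$extent - d)
  } else {
    abs(a[, 1] - b[, 1])
  }
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards, so seeded operations are bit-reproducible and side-effect
# free. A NULL seed uses (and advances) the ambient RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L)
    stop("`seed` must be a single number or NULL", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
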