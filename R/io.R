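fmt_num <- function(x) formatC(x, digits = 15, format = "g")

#' Write / read a binned spike-count matrix
#'
#' Dense tab-separated matrix (rows = cells) plus a JSON sidecar
#' (`<path>.json`) holding `delta`, `t0` and `cell_ids`.
#'
#' @param sm A [spike_matrix()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_spike_matrix <- function(sm, path) {
  stopifnot(inherits(sm, "spike_matrix"))
  utils::write.table(sm$counts, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(delta = sm$delta, t0 = sm$t0,
                            cell_ids = sm$cell_ids),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spike_matrix
#' @export
read_spike_matrix <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop(sprintf("missing sidecar '%s'", sidecar), call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  counts <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(counts) <- NULL
  spike_matrix(counts, delta = meta$delta, t0 = meta$t0,
               cell_ids = meta$cell_ids)
}

#' Write / read a trajectory
#'
#' Tab-separated columns `time_s`, `x_cm` (, `y_cm`); speed is rederived on
#' read. Reading validates monotone uniform sampling (malformed rows raise
#' an error naming the first offending line).
#'
#' @param traj A [trajectory()].
#' @param path TSV path.
#' @param env Environment used to revalidate on read.
#' @return `path` / the [trajectory()].
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(time_s = fmt_num(traj$t), x_cm = fmt_num(traj$x))
  if ("y" %in% names(traj)) df$y_cm <- fmt_num(traj$y)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path, env) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  need <- c("time_s", "x_cm")
  if (!all(need %in% names(df)))
    stop("trajectory file must have columns time_s, x_cm[, y_cm]", call. = FALSE)
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad))
    stop(sprintf("non-monotone time at line %d", bad[1] + 2L), call. = FALSE)
  trajectory(df$time_s, df$x_cm, if ("y_cm" %in% names(df)) df$y_cm else NULL,
             env = env)
}

#' Read spike times and bin them into a spike matrix
#'
#' Input: tab-separated `cell_id`, `time_s`, one spike per row. Spikes are
#' counted into half-open bins of width `delta` starting at `t0`.
#'
#' @param path TSV path with columns `cell_id`, `time_s`.
#' @param delta Bin width, s.
#' @param t0 Start of the first bin (default: floor of the first spike).
#' @param t_end End of the last bin (default: past the last spike).
#' @param cell_ids Full population (defaults to the ids present; pass
#'   explicitly to keep silent cells).
#' @return A [spike_matrix()].
#' @export
read_spike_times <- function(path, delta, t0 = NULL, t_end = NULL,
                             cell_ids = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  if (!all(c("cell_id", "time_s") %in% names(df)))
    stop("spike file must have columns cell_id, time_s", call. = FALSE)
  if (is.null(cell_ids)) cell_ids <- sort(unique(df$cell_id))
  if (is.null(t0)) t0 <- floor(min(df$time_s))
  if (is.null(t_end)) t_end <- max(df$time_s) + delta
  n <- max(1L, floor((t_end - t0) / delta))
  bin <- floor((df$time_s - t0) / delta) + 1L
  ok <- bin >= 1L & bin <= n
  row <- match(df$cell_id, cell_ids)
  if (anyNA(row[ok])) stop("spike file contains unknown cell ids", call. = FALSE)
  counts <- matrix(0L, length(cell_ids), n)
  idx <- (bin[ok] - 1L) * length(cell_ids) + row[ok]
  tab <- tabulate(idx, nbins = length(cell_ids) * n)
  counts[] <- tab
  spike_matrix(counts, delta = delta, t0 = t0, cell_ids = cell_ids)
}

#' Write a replay-result table
#'
#' One row per event: interval, bins, active-cell fraction, weighted
#' correlation, Z, p, the criterion flags and the significance call.
#'
#' @param results List of [assess_replay()] results.
#' @param path TSV path.
#' @return The table, invisibly.
#' @export
write_replay_results <- function(results, path) {
  df <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(event = i, n_bins = r$n_bins,
               rho = r$rho %||% NA_real_,
               R = r$R, abs_R = r$abs_R, Z = r$Z, p = r$p,
               p_method = r$p_method, avg_map_score = r$avg_map_score,
               r_pass = r$flags$r_pass, length_pass = r$flags$length_pass,
               map_pass = r$flags$map_pass, z_pass = r$flags$z_pass,
               significant = r$significant, direction = r$direction)
  }))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Export a topology graph as an edge list
#'
#' Tab-separated `i`, `j`, `w_ij` (undirected, upper triangle, nonzero
#' strengths only), loadable by standard graph tools.
#'
#' @param topo A [topology_layout()] result.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_topology_edges <- function(topo, path) {
  el <- igraph::as_edgelist(topo$graph)
  df <- data.frame(i = as.integer(el[, 1]), j = as.integer(el[, 2]),
                   w = igraph::E(topo$graph)$weight)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
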