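#' Directed node strength
#'
#' In-strength sums a node's inbound weights, out-strength its outbound
#' weights, and total strength is their sum:
#' `S_in(i) = sum_j F_{j->i}`, `S_out(i) = sum_j F_{i->j}`,
#' `S(i) = S_in(i) + S_out(i)`.
#'
#' @param w Nonnegative weight matrix with `w[i, j] = F_{i->j}` and zero
#'   diagonal.
#' @return `data.frame` with columns `node`, `s_in`, `s_out`, `s_total`.
#' @export
node_strength <- function(w) {
  w <- check_weights(w)
  data.frame(node = seq_len(nrow(w)),
             s_in = colSums(w), s_out = rowSums(w),
             s_total = colSums(w) + rowSums(w))
}

check_weights <- function(w) {
  w <- as.matrix(w)
  stopifnot(nrow(w) == ncol(w))
  if (any(w < 0)) stop("edge weights must be nonnegative")
  diag(w) <- 0
  w
}

#' Weighted clustering coefficient
#'
#' `C_i = sum_{j,k} w_ij w_ik w_jk / sum_{j,k} w_ij w_ik` over ordered
#' pairs `j != k`, both different from `i`; 0 when the denominator
#' vanishes. The triple-product indexing is inherently undirected, so the
#' directed matrix is symmetrized as `(F_{i->j} + F_{j->i}) / 2` first;
#' substitute a directed variant upstream if needed.
#'
#' @param w Weight matrix as in [node_strength()].
#' @return Numeric vector of per-node clustering coefficients.
#' @export
clustering_w <- function(w) {
  w <- check_weights(w)
  ws <- (w + t(w)) / 2
  num <- diag(ws %*% ws %*% ws)
  den <- rowSums(ws)^2 - rowSums(ws^2)
  ifelse(den > 0, num / den, 0)
}

#' Shortest-path distance matrix under inverse-weight edge lengths
#'
#' Each directed edge gets length `1 / w` (absent edges are impassable);
#' `d_ij` is the minimal summed length over directed paths, so strong
#' connections are short. Unreachable pairs get `Inf`.
#'
#' @param w Weight matrix as in [node_strength()].
#' @return `N x N` distance matrix with zero diagonal.
#' @export
weight_to_distance <- function(w) {
  w <- check_weights(w)
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, 0)
  g <- igraph::graph_from_adjacency_matrix(len, mode = "directed",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, mode = "out", algorithm = "dijkstra")
  dimnames(d) <- NULL
  d
}

#' Global efficiency of a directed weighted network
#'
#' `E = (1 / (n (n - 1))) * sum_{i != j} 1 / d_ij`, the mean inverse
#' shortest-path distance with `1 / Inf = 0` for unreachable pairs, so
#' disconnected networks remain comparable.
#'
#' @param w Weight matrix as in [node_strength()].
#' @return Scalar efficiency, >= 0.
#' @export
global_efficiency <- function(w) {
  d <- weight_to_distance(w)
  n <- nrow(d)
  stopifnot(n >= 2)
  off <- d[row(d) != col(d)]
  mean(ifelse(is.finite(off), 1 / off, 0))
}

#' Characteristic path length
#'
#' Mean shortest-path distance over ordered node pairs. Unreachable pairs
#' are excluded from the average (the reachable-pair count replaces
#' `n (n - 1)`), and the result carries a `disconnected` attribute flag.
#' A graph with no reachable pair returns `NA` with the flag set.
#'
#' @param w Weight matrix as in [node_strength()].
#' @return Scalar path length with logical attribute `disconnected`.
#' @export
char_path_length <- function(w) {
  d <- weight_to_distance(w)
  n <- nrow(d)
  stopifnot(n >= 2)
  off <- d[row(d) != col(d)]
  reachable <- is.finite(off)
  L <- if (any(reachable)) mean(off[reachable]) else NA_real_
  structure(L, disconnected = !all(reachable))
}

#' Retain the strongest fraction of edges
#'
#' Keeps the `ceiling(fraction * m)` largest of the `m` nonzero
#' off-diagonal weights (all ties at the cutoff are retained) and zeroes
#' the rest; used for the top-5% edge rendering of connectivity plots.
#'
#' @param w Weight matrix as in [node_strength()].
#' @param fraction Fraction of nonzero edges to keep, in (0, 1].
#' @return Thresholded weight matrix.
#' @export
retain_top_fraction <- function(w, fraction = 0.05) {
  w <- check_weights(w)
  stopifnot(fraction > 0, fraction <= 1)
  vals <- w[row(w) != col(w) & w > 0]
  if (length(vals) == 0) return(w)
  k <- ceiling(fraction * length(vals))
  thr <- sort(vals, decreasing = TRUE)[k]
  w[w < thr] <- 0
  w
}

#' Mean node strength per intrinsic functional network
#'
#' @param strength Per-node values (e.g. `s_total` from
#'   [node_strength()]), ordered as the atlas rows.
#' @param atlas `data.frame` with columns `channel_name` and `network`.
#' @return Named numeric vector of unweighted means per network; networks
#'   with no member nodes are omitted with a warning.
#' @export
aggregate_by_network <- function(strength, atlas) {
  stopifnot(length(strength) == nrow(atlas))
  out <- c(tapply(strength, atlas$network, mean))
  present <- unique(atlas$network)
  empty <- setdiff(names(out), present)
  if (length(empty)) warning("networks without members omitted: ",
                             paste(empty, collapse = ", "))
  out[!is.na(out)]
}

#' All metrics for one directed connectivity matrix
#'
#' @param w Weight matrix with `w[i, j] = F_{i->j}`.
#' @param atlas Optional channel-to-network atlas (`channel_name`,
#'   `network`), one row per node.
#' @return List with `node` (per-node strengths + clustering, with
#'   network affiliation when an atlas is given), `network` (mean total
#'   strength per intrinsic network, if atlas given) and `graph`
#'   (`e_global`, `char_path`, `disconnected`).
#' @export
network_metrics <- function(w, atlas = NULL) {
  w <- check_weights(w)
  ns <- node_strength(w)
  ns$clustering <- clustering_w(w)
  L <- char_path_length(w)
  out <- list(node = ns,
              graph = data.frame(e_global = global_efficiency(w),
                                 char_path = as.numeric(L),
                                 disconnected = attr(L, "disconnected")))
  if (!is.null(atlas)) {
    stopifnot(nrow(atlas) == nrow(w))
    out$node$network <- atlas$network
    bynet <- aggregate_by_network(ns$s_total, atlas)
    out$network <- data.frame(network = names(bynet),
                              mean_strength = as.numeric(bynet))
  }
  out
}

#' Long-format metric table for every analysis cell
#'
#' Applies [network_metrics()] to each (subject, condition, window)
#' Granger-causality matrix and stacks the results into the long table
#' consumed by [group_statistics()]: one row per
#' (subject, band, condition, window, unit, unit id, metric).
#'
#' @param gc_result Output of [gc_cells()].
#' @param atlas Channel-to-network atlas, one row per channel.
#' @return `data.frame` with columns subject, group, band, condition,
#'   window, unit (`node`/`network`/`graph`), unit_id, network, metric,
#'   value.
#' @export
metrics_table <- function(gc_result, atlas) {
  band <- unique(gc_result$long$band)
  rows <- lapply(gc_result$cells, function(cell) {
    m <- network_metrics(cell$gc$weights, atlas)
    base <- data.frame(subject = cell$subject, group = cell$group,
                       band = band, condition = cell$condition,
                       window = cell$window, stringsAsFactors = FALSE)
    node_rows <- do.call(rbind, lapply(
      c("s_in", "s_out", "s_total", "clustering"),
      function(met) cbind(base, unit = "node",
                          unit_id = atlas$channel_name,
                          network = m$node$network,
                          metric = met, value = m$node[[met]])))
    net_rows <- cbind(base, unit = "network", unit_id = m$network$network,
                      network = m$network$network, metric = "mean_strength",
                      value = m$network$mean_strength)
    graph_rows <- cbind(base, unit = "graph", unit_id = "graph",
                        network = NA_character_,
                        metric = c("e_global", "char_path"),
                        value = c(m$graph$e_global, m$graph$char_path))
    rbind(node_rows, net_rows, graph_rows)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
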