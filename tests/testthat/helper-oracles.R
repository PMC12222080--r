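# Independent oracles used to cross-check the package implementation.
# These deliberately share no code with the package internals.

# naive pairwise Granger causality: explicit lag-matrix construction and
# lm() fits, residual-variance log ratio
naive_gc_pair <- function(x, y, p) {
  x <- x - mean(x); y <- y - mean(y)
  n <- length(x)
  lags <- function(v) sapply(1:p, function(l) v[(p + 1 - l):(n - l)])
  Lx <- lags(x); Ly <- lags(y)
  rss <- function(target, design) {
    sum(stats::resid(stats::lm(target ~ design + 0))^2)
  }
  tx <- x[(p + 1):n]; ty <- y[(p + 1):n]
  c(y_to_x = log(rss(tx, Lx) / rss(tx, cbind(Lx, Ly))),
    x_to_y = log(rss(ty, Ly) / rss(ty, cbind(Lx, Ly))))
}

# all-pairs shortest paths by Floyd-Warshall on an edge-length matrix
# (Inf = absent edge)
floyd_warshall <- function(len) {
  n <- nrow(len)
  d <- len
  diag(d) <- 0
  for (k in 1:n) {
    for (i in 1:n) {
      for (j in 1:n) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# brute-force weighted clustering by explicit triple enumeration on the
# symmetrized matrix
brute_clustering <- function(w) {
  ws <- (w + t(w)) / 2
  diag(ws) <- 0
  n <- nrow(ws)
  vapply(1:n, function(i) {
    num <- 0; den <- 0
    for (j in 1:n) {
      for (k in 1:n) {
        if (j != i && k != i && j != k) {
          num <- num + ws[i, j] * ws[i, k] * ws[j, k]
          den <- den + ws[i, j] * ws[i, k]
        }
      }
    }
    if (den > 0) num / den else 0
  }, numeric(1))
}

# brute-force efficiency / path length built on the Floyd-Warshall oracle
brute_graph_metrics <- function(w) {
  len <- ifelse(w > 0, 1 / w, Inf)
  diag(len) <- Inf
  d <- floyd_warshall(len)
  off <- d[row(d) != col(d)]
  list(e_global = mean(ifelse(is.finite(off), 1 / off, 0)),
       char_path = if (any(is.finite(off))) mean(off[is.finite(off)]) else NA_real_)
}

# random nonnegative digraph weight matrix with zero diagonal
rand_digraph <- function(n, density = 0.5) {
  w <- matrix(stats::runif(n * n), n, n) *
    (matrix(stats::runif(n * n), n, n) < density)
  diag(w) <- 0
  w
}

# a small stable two-channel VAR(3) ground-truth pair used in several tests
var3_pair_graph <- function() {
  ground_truth_graph(
    2,
    data.frame(source = c(1, 2), target = c(2, 1),
               magnitude = c(0.4, 0.3), lag = c(3, 2)),
    order = 3)
}

# simulate one series matrix (samples x channels) from a gt_graph
sim_graph <- function(graph, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- build_var_coefficients(graph)
  tvgc:::simulate_var(A, n, 1, graph$noise_scale)[[1]]
}
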