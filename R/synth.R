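#' Directed ground-truth coupling graph for a synthetic session
#'
#' Defines the generative vector-autoregressive (VAR) structure of a
#' simulated multichannel recording: a set of directed lagged couplings
#' between channels plus a per-channel self-regression term. The implied
#' VAR must be stable (companion spectral radius < 1) before it can be
#' simulated; see [build_var_coefficients()].
#'
#' @param n_channels Number of channels (nodes).
#' @param edges `data.frame` with columns `source`, `target` (1-based
#'   channel indices), `magnitude` (coupling coefficient) and `lag`
#'   (samples, >= 1). May have zero rows.
#' @param noise_scale Innovation standard deviation, scalar or one value
#'   per channel.
#' @param self_coef Lag-1 self-regression coefficient giving each channel
#'   persistent autocorrelation, scalar or per channel.
#' @param order Generative model order; defaults to the largest edge lag
#'   (minimum 1). All edge lags must be <= `order`.
#' @return An object of class `gt_graph`.
#' @export
ground_truth_graph <- function(n_channels, edges = NULL,
                               noise_scale = 1, self_coef = 0.5,
                               order = NULL) {
  stopifnot(n_channels >= 1)
  if (is.null(edges)) {
    edges <- data.frame(source = integer(), target = integer(),
                        magnitude = numeric(), lag = integer())
  }
  edges <- as.data.frame(edges)
  needed <- c("source", "target", "magnitude", "lag")
  if (!all(needed %in% names(edges))) {
    stop("edges must have columns source, target, magnitude, lag")
  }
  if (nrow(edges) > 0) {
    if (any(edges$source == edges$target)) stop("self-edges are not allowed")
    if (any(edges$lag < 1)) stop("all edge lags must be >= 1")
    if (any(edges$source < 1 | edges$source > n_channels |
            edges$target < 1 | edges$target > n_channels)) {
      stop("edge endpoints out of range")
    }
  }
  if (is.null(order)) order <- max(1L, if (nrow(edges)) max(edges$lag) else 1L)
  if (nrow(edges) > 0 && any(edges$lag > order)) {
    stop("edge lags exceed the generative order")
  }
  noise_scale <- rep_len(noise_scale, n_channels)
  self_coef <- rep_len(self_coef, n_channels)
  structure(
    list(n_channels = as.integer(n_channels), edges = edges,
         noise_scale = noise_scale, self_coef = self_coef,
         order = as.integer(order)),
    class = "gt_graph"
  )
}

#' @export
print.gt_graph <- function(x, ...) {
  cat(sprintf("<gt_graph> %d channels, %d directed edges, order %d\n",
              x$n_channels, nrow(x$edges), x$order))
  invisible(x)
}

#' Expand a coupling graph into VAR coefficient matrices
#'
#' Builds the lag-indexed coefficient tensor `A` with `A[l, i, j]` the
#' weight of channel `j` at lag `l` in the equation for channel `i`
#' (so edges are placed at `A[lag, target, source]`). The lag-1 diagonal
#' carries the per-channel self term. If the companion matrix of the
#' resulting VAR has spectral radius >= 1 the diagonal self terms are
#' progressively shrunk; if no diagonal rescaling stabilizes the system
#' (the off-diagonal couplings alone are explosive) the function fails,
#' naming the largest coupling magnitudes.
#'
#' @param graph A [ground_truth_graph()].
#' @param order Model order; must be >= the largest edge lag. Defaults to
#'   the graph's own order.
#' @return Numeric array of dimension `order x N x N` with attribute
#'   `spectral_radius`.
#' @export
build_var_coefficients <- function(graph, order = graph$order) {
  stopifnot(inherits(graph, "gt_graph"))
  n <- graph$n_channels
  if (nrow(graph$edges) > 0 && order < max(graph$edges$lag)) {
    stop("order is smaller than the largest edge lag")
  }
  A <- array(0, dim = c(order, n, n))
  A[1, , ] <- diag(graph$self_coef, n)
  for (r in seq_len(nrow(graph$edges))) {
    e <- graph$edges[r, ]
    A[e$lag, e$target, e$source] <- A[e$lag, e$target, e$source] + e$magnitude
  }
  rad <- companion_radius(A)
  if (rad >= 1) {
    # shrink only the lag-1 diagonal; couplings are the quantity under study
    for (f in seq(0.9, 0, by = -0.1)) {
      A[1, , ][diag(n) == 1] <- graph$self_coef * f
      rad <- companion_radius(A)
      if (rad < 1) break
    }
    if (rad >= 1) {
      worst <- graph$edges[order(-abs(graph$edges$magnitude)), ]
      worst <- utils::head(worst, 3)
      stop(sprintf(
        "graph cannot be stabilized by diagonal rescaling (radius %.3f); largest couplings: %s",
        rad,
        paste(sprintf("%d->%d (%.3g, lag %d)", worst$source, worst$target,
                      worst$magnitude, worst$lag), collapse = ", ")))
    }
  }
  attr(A, "spectral_radius") <- rad
  A
}

#' Spectral radius of the VAR companion matrix
#'
#' @param A Coefficient array `order x N x N`.
#' @return Largest eigenvalue modulus of the `(N*order)`-dimensional
#'   companion matrix.
#' @export
companion_radius <- function(A) {
  p <- dim(A)[1]; n <- dim(A)[2]
  comp <- matrix(0, n * p, n * p)
  for (l in seq_len(p)) comp[1:n, ((l - 1) * n + 1):(l * n)] <- A[l, , ]
  if (p > 1) comp[(n + 1):(n * p), 1:(n * (p - 1))] <- diag(n * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Default two-group coupling graphs
#'
#' Builds a matched pair of ground-truth graphs for the two driver groups.
#' The experienced-driver graph is a directed ring backbone (every channel
#' has at least one inbound and one outbound edge) plus random extra edges
#' at coupling `coupling`. The novice graph reuses the same edge set with
#' magnitudes scaled by `novice_factor` and adds `novice_factor` times as
#' many extra edges, realizing the denser/stronger connectivity of the
#' novice group. Edge lags are drawn uniformly from `1:order`.
#'
#' @param n_channels Channels per subject.
#' @param order Generative VAR order.
#' @param coupling Base coupling magnitude of the experienced group.
#' @param n_extra Number of random non-ring edges in the experienced graph.
#' @param novice_factor Multiplier (> 1) on both coupling magnitude and
#'   extra-edge count for the novice group.
#' @param noise_scale,self_coef Passed to [ground_truth_graph()].
#' @return Named list with elements `experienced` and `novice`.
#' @export
group_graphs <- function(n_channels = 16, order = 3, coupling = 0.4,
                         n_extra = n_channels, novice_factor = 1.5,
                         noise_scale = 1, self_coef = 0.5) {
  ring <- data.frame(source = seq_len(n_channels),
                     target = c(seq_len(n_channels)[-1], 1L))
  draw_extra <- function(k, forbid) {
    out <- data.frame(source = integer(), target = integer())
    seen <- paste(forbid$source, forbid$target)
    k <- min(k, n_channels * (n_channels - 1) - nrow(forbid))
    while (nrow(out) < k) {
      s <- sample.int(n_channels, 1); t <- sample.int(n_channels, 1)
      key <- paste(s, t)
      if (s != t && !(key %in% seen)) {
        out <- rbind(out, data.frame(source = s, target = t))
        seen <- c(seen, key)
      }
    }
    out
  }
  extra_exp <- draw_extra(n_extra, ring)
  base <- rbind(ring, extra_exp)
  base$lag <- sample.int(order, nrow(base), replace = TRUE)
  base$magnitude <- coupling
  extra_nov <- draw_extra(round(n_extra * (novice_factor - 1)), base)
  if (nrow(extra_nov)) {
    extra_nov$lag <- sample.int(order, nrow(extra_nov), replace = TRUE)
    extra_nov$magnitude <- coupling * novice_factor
  }
  nov <- base
  nov$magnitude <- nov$magnitude * novice_factor
  nov <- rbind(nov, extra_nov)
  mk <- function(e) ground_truth_graph(
    n_channels, e[c("source", "target", "magnitude", "lag")],
    noise_scale, self_coef, order)
  out <- list(experienced = mk(base), novice = mk(nov))
  # overlapping feedback cycles among random extra edges can make the
  # denser graph explosive; shrink both groups' couplings by a common
  # factor (group ratio preserved) until the companion radius clears 1
  # with margin
  for (i in 1:60) {
    radii <- vapply(out, graph_radius, numeric(1))
    if (max(radii) < 0.97) break
    base$magnitude <- base$magnitude * 0.92
    nov$magnitude <- nov$magnitude * 0.92
    out <- list(experienced = mk(base), novice = mk(nov))
  }
  if (max(vapply(out, graph_radius, numeric(1))) >= 1) {
    stop("could not build a stable group-graph pair")
  }
  out
}

# companion spectral radius of the raw (unstabilized) graph
graph_radius <- function(graph) {
  n <- graph$n_channels
  A <- array(0, dim = c(graph$order, n, n))
  A[1, , ] <- diag(graph$self_coef, n)
  for (r in seq_len(nrow(graph$edges))) {
    e <- graph$edges[r, ]
    A[e$lag, e$target, e$source] <- A[e$lag, e$target, e$source] + e$magnitude
  }
  companion_radius(A)
}

#' Session design for the synthetic generator
#'
#' Captures every knob of a simulated recording session: trial structure,
#' sampling, epoch geometry, the two groups' coupling graphs and the root
#' seed. With an identical design (same seed included) the generator is
#' bit-reproducible.
#'
#' @param n_trials Trials per subject (default 40).
#' @param collision_fraction Fraction of collision trials (default 0.5);
#'   the collision count is `round(n_trials * collision_fraction)`.
#' @param sample_rate Acquisition rate in Hz (default 1000).
#' @param epoch_window Epoch span in seconds relative to the event,
#'   default `c(-2, 1)`.
#' @param trial_duration Trial length in seconds; must give full epoch
#'   support around the trial midpoint event.
#' @param n_subjects_per_group Subjects per group.
#' @param groups Named list of `gt_graph` objects, one per group; defaults
#'   to [group_graphs()] for groups `experienced` and `novice`.
#' @param n_channels Channel count used when `groups` is built by default.
#' @param error_rate Probability that a trial response is incorrect.
#' @param seed Integer root seed for all session randomness.
#' @return An object of class `session_design`.
#' @export
session_design <- function(n_trials = 40, collision_fraction = 0.5,
                           sample_rate = 1000, epoch_window = c(-2, 1),
                           trial_duration = 4, n_subjects_per_group = 10,
                           groups = NULL, n_channels = 16,
                           error_rate = 0, seed = 1) {
  stopifnot(n_trials >= 1, collision_fraction >= 0, collision_fraction <= 1,
            sample_rate > 0, length(epoch_window) == 2,
            epoch_window[1] < epoch_window[2],
            error_rate >= 0, error_rate < 1)
  if (trial_duration / 2 < max(-epoch_window[1], epoch_window[2])) {
    stop("trial_duration too short for the requested epoch window")
  }
  if (is.null(groups)) {
    set.seed(as.integer(seed) %% 2147483647L)
    groups <- group_graphs(n_channels = n_channels)
  }
  stopifnot(length(groups) >= 1, !is.null(names(groups)),
            all(vapply(groups, inherits, logical(1), "gt_graph")))
  nch <- unique(vapply(groups, function(g) g$n_channels, integer(1)))
  if (length(nch) != 1) stop("all group graphs must share a channel count")
  structure(
    list(n_trials = as.integer(n_trials),
         collision_fraction = collision_fraction,
         sample_rate = sample_rate, epoch_window = epoch_window,
         trial_duration = trial_duration,
         n_subjects_per_group = as.integer(n_subjects_per_group),
         groups = groups, n_channels = nch,
         error_rate = error_rate, seed = as.integer(seed)),
    class = "session_design"
  )
}

#' Continuous multichannel recording container
#'
#' @param data Numeric matrix, samples x channels.
#' @param sample_rate Sampling rate in Hz.
#' @param channel_names Optional channel labels.
#' @return Object of class `eeg_continuous`.
#' @export
eeg_continuous <- function(data, sample_rate, channel_names = NULL) {
  data <- as.matrix(data)
  if (is.null(channel_names)) {
    channel_names <- sprintf("C%02d", seq_len(ncol(data)))
  }
  stopifnot(length(channel_names) == ncol(data))
  colnames(data) <- channel_names
  structure(list(data = data, sample_rate = sample_rate,
                 channel_names = channel_names),
            class = "eeg_continuous")
}

#' @export
print.eeg_continuous <- function(x, ...) {
  cat(sprintf("<eeg_continuous> %d samples x %d channels @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sample_rate,
              nrow(x$data) / x$sample_rate))
  invisible(x)
}

# Simulate a stable VAR for several independent series at once.
# coefs: p x N x N array; returns list of n x N matrices.
simulate_var <- function(coefs, n, n_series, noise_scale, burn_in = NULL) {
  p <- dim(coefs)[1]; nch <- dim(coefs)[2]
  if (is.null(burn_in)) burn_in <- 10L * p
  # stack lag state as (N*p) x M and the coefficients as N x (N*p)
  Amat <- matrix(0, nch, nch * p)
  for (l in seq_len(p)) Amat[, ((l - 1) * nch + 1):(l * nch)] <- coefs[l, , ]
  sd_mat <- matrix(noise_scale, nch, n_series)
  Z <- matrix(0, nch * p, n_series)
  out <- matrix(0, nch * n_series, n)
  for (t in seq_len(burn_in + n)) {
    Xt <- Amat %*% Z + sd_mat * matrix(stats::rnorm(nch * n_series), nch, n_series)
    if (p > 1) Z <- rbind(Xt, Z[seq_len(nch * (p - 1)), , drop = FALSE]) else Z <- Xt
    if (t > burn_in) out[, t - burn_in] <- as.vector(Xt)
  }
  lapply(seq_len(n_series), function(m) {
    t(out[((m - 1) * nch + 1):(m * nch), , drop = FALSE])
  })
}

#' Simulate a full synthetic multi-subject session
#'
#' Generates, for every subject of every group, a continuous stable-VAR
#' recording (burn-in of 10x the generative order is discarded), a trial
#' events table and a channel-to-intrinsic-network atlas. Trials occupy
#' consecutive blocks of `trial_duration` seconds; the event marker is the
#' sample nearest each trial's temporal midpoint. Conditions are assigned
#' by drawing exactly `round(n_trials * collision_fraction)` collision
#' trials per subject in a random order; correctness is Bernoulli with the
#' design's error rate, and reaction times for correct collision trials
#' are log-normal around 600 ms.
#'
#' Event samples in the events table are 0-based indices into the
#' continuous recording at the acquisition rate.
#'
#' @param design A [session_design()].
#' @return Object of class `synthetic_session`: list with `subjects`
#'   (each `id`, `group`, `data` as [eeg_continuous()]), `events`
#'   (`data.frame` with subject_id, group, trial, event_sample, condition,
#'   correct, rt_ms), `atlas`, `design`.
#' @export
simulate_session <- function(design) {
  stopifnot(inherits(design, "session_design"))
  set.seed(design$seed %% 2147483647L)
  rate <- design$sample_rate
  trial_len <- round(design$trial_duration * rate)
  n_total <- design$n_trials * trial_len
  n_coll <- round(design$n_trials * design$collision_fraction)

  subjects <- list()
  events <- list()
  sid <- 0L
  for (g in names(design$groups)) {
    graph <- design$groups[[g]]
    coefs <- build_var_coefficients(graph)
    series <- simulate_var(coefs, n_total, design$n_subjects_per_group,
                           graph$noise_scale)
    for (m in seq_len(design$n_subjects_per_group)) {
      sid <- sid + 1L
      subj_id <- sprintf("S%02d", sid)
      cond <- rep("non-collision", design$n_trials)
      cond[sample.int(design$n_trials, n_coll)] <- "collision"
      correct <- stats::rbinom(design$n_trials, 1, 1 - design$error_rate) == 1
      rt <- ifelse(cond == "collision" & correct,
                   round(stats::rlnorm(design$n_trials, log(600), 0.25)), NA)
      ev_sample <- (seq_len(design$n_trials) - 1L) * trial_len +
        as.integer(round(trial_len / 2))
      events[[subj_id]] <- data.frame(
        subject_id = subj_id, group = g, trial = seq_len(design$n_trials),
        event_sample = ev_sample, condition = cond, correct = correct,
        rt_ms = rt, stringsAsFactors = FALSE)
      subjects[[subj_id]] <- list(
        id = subj_id, group = g,
        data = eeg_continuous(series[[m]], rate))
    }
  }
  structure(
    list(subjects = subjects,
         events = do.call(rbind, c(events, make.row.names = FALSE)),
         atlas = default_atlas(design$n_channels),
         design = design),
    class = "synthetic_session"
  )
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf(
    "<synthetic_session> %d subjects (%s), %d channels, %d trials each @ %g Hz\n",
    length(x$subjects),
    paste(names(x$design$groups), collapse = "/"),
    x$design$n_channels, x$design$n_trials, x$design$sample_rate))
  invisible(x)
}

#' Default channel-to-intrinsic-network atlas
#'
#' Assigns channels to the seven canonical intrinsic functional networks
#' in contiguous, nearly equal blocks. Real analyses should supply their
#' own atlas mapping; this synthetic one guarantees every network is
#' populated whenever `n_channels >= 7`.
#'
#' @param n_channels Number of channels.
#' @param networks Network labels, in block order.
#' @return `data.frame` with columns `channel_name`, `network`.
#' @export
default_atlas <- function(n_channels,
                          networks = c("Visual", "DMN", "DAN", "VAN",
                                       "FCN", "Limbic", "Somatomotor")) {
  idx <- sort(rep_len(seq_along(networks), n_channels))
  data.frame(channel_name = sprintf("C%02d", seq_len(n_channels)),
             network = networks[idx], stringsAsFactors = FALSE)
}

#' Write / read a synthetic session to disk
#'
#' Events and atlas go to CSV (`events.csv`, `atlas.csv`); each subject's
#' continuous array goes to an RDS file under `signals/`, with a JSON
#' sidecar recording rate and channel names.
#'
#' @param session A `synthetic_session`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "synthetic_session"))
  dir.create(file.path(dir, "signals"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(session$events, file.path(dir, "events.csv"), row.names = FALSE)
  utils::write.csv(session$atlas, file.path(dir, "atlas.csv"), row.names = FALSE)
  meta <- list()
  for (s in session$subjects) {
    saveRDS(s$data$data, file.path(dir, "signals", paste0(s$id, ".rds")))
    meta[[s$id]] <- list(group = s$group, sample_rate = s$data$sample_rate,
                         channel_names = s$data$channel_names)
  }
  jsonlite::write_json(meta, file.path(dir, "signals", "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  events <- utils::read.csv(file.path(dir, "events.csv"), stringsAsFactors = FALSE)
  atlas <- utils::read.csv(file.path(dir, "atlas.csv"), stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "signals", "meta.json"),
                              simplifyVector = TRUE)
  subjects <- lapply(names(meta), function(id) {
    m <- meta[[id]]
    list(id = id, group = m$group,
         data = eeg_continuous(readRDS(file.path(dir, "signals", paste0(id, ".rds"))),
                               m$sample_rate, m$channel_names))
  })
  names(subjects) <- names(meta)
  structure(list(subjects = subjects, events = events, atlas = atlas,
                 design = NULL),
            class = "synthetic_session")
}
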