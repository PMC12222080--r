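#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end analysis in one
#' serializable object. The defaults reproduce the reference settings:
#' 500 Hz analysis rate, \[-2, +1\] s epochs, 1-s sliding windows at 50%
#' overlap, model order 12 (searchable over 1-15), top-5% edge retention
#' and FDR level 0.05. All randomness flows from the single root `seed`.
#'
#' @param n_channels,n_subjects_per_group,n_trials Session size.
#' @param bands Bands to analyze (default alpha and beta).
#' @param target_rate Analysis sampling rate in Hz.
#' @param epoch_window Epoch span in seconds around the event.
#' @param window_length,overlap Sliding-window geometry in seconds /
#'   fraction.
#' @param order Autoregressive model order used for Granger causality.
#' @param order_range Candidate orders for [select_order()] when
#'   `select_order = TRUE`.
#' @param select_order Run the AIC order search instead of using `order`
#'   directly (default FALSE).
#' @param z_threshold Artifact-screen threshold.
#' @param retain_fraction Edge fraction kept by [retain_top_fraction()]
#'   for exported edge lists.
#' @param alpha FDR level for the statistics stage.
#' @param error_rate Probability of an incorrect trial response in the
#'   generator.
#' @param seed Root seed.
#' @param groups Optional named list of [ground_truth_graph()]s.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_channels = 16, n_subjects_per_group = 10,
                            n_trials = 40, bands = c("alpha", "beta"),
                            target_rate = 500, epoch_window = c(-2, 1),
                            window_length = 1, overlap = 0.5,
                            order = 12, order_range = 1:15,
                            select_order = FALSE, z_threshold = 3,
                            retain_fraction = 0.05, alpha = 0.05,
                            error_rate = 0, seed = 1, groups = NULL) {
  cfg <- list(n_channels = n_channels,
              n_subjects_per_group = n_subjects_per_group,
              n_trials = n_trials, bands = bands,
              target_rate = target_rate, epoch_window = epoch_window,
              window_length = window_length, overlap = overlap,
              order = order, order_range = order_range,
              select_order = select_order, z_threshold = z_threshold,
              retain_fraction = retain_fraction, alpha = alpha,
              error_rate = error_rate, seed = as.integer(seed),
              groups = groups)
  structure(cfg, class = "pipeline_config")
}

config_fingerprint <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  ser <- config
  ser$groups <- lapply(ser$groups, function(g) g[c("n_channels", "edges",
                                                   "noise_scale", "self_coef",
                                                   "order")])
  jsonlite::write_json(ser, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Orchestrates synth -> preprocess -> gc -> metrics -> stats on a
#' seeded synthetic session. Each stage records a manifest entry (stage,
#' seed, config fingerprint, duration); a rerun with an identical config
#' reproduces identical results. When `out_dir` is given, the stage
#' outputs are written beside the effective config: `events.csv`,
#' `atlas.csv`, `gc_long.csv`, `metrics.csv`, `stats.csv`,
#' `edges_top/*.csv` and `config.json` / `manifest.csv`.
#'
#' @param config A [pipeline_config()].
#' @param stages Subset of stages to run, in pipeline order; later stages
#'   need the earlier ones' outputs in `state`.
#' @param out_dir Optional output directory.
#' @param state Partial pipeline state from a previous call, for resuming.
#' @return List (pipeline state): `session`, `epochs` (per band), `gc`
#'   (per band), `metrics`, `stats`, `manifest`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("synth", "preprocess", "gc",
                                    "metrics", "stats"),
                         out_dir = NULL, state = list()) {
  stopifnot(inherits(config, "pipeline_config"))
  known <- c("synth", "preprocess", "gc", "metrics", "stats")
  stages <- known[known %in% stages]
  fp <- config_fingerprint(config)
  manifest <- state$manifest
  note <- function(stage, secs) {
    rbind(manifest, data.frame(stage = stage, seed = config$seed,
                               config = fp, seconds = round(secs, 3)))
  }

  if ("synth" %in% stages) {
    t0 <- proc.time()[3]
    design <- session_design(
      n_trials = config$n_trials, sample_rate = 1000,
      epoch_window = config$epoch_window,
      n_subjects_per_group = config$n_subjects_per_group,
      n_channels = config$n_channels, groups = config$groups,
      error_rate = config$error_rate, seed = config$seed)
    state$session <- simulate_session(design)
    manifest <- note("synth", proc.time()[3] - t0)
  }
  if ("preprocess" %in% stages) {
    if (is.null(state$session)) stop("preprocess stage needs a session (run synth first)")
    t0 <- proc.time()[3]
    state$epochs <- lapply(stats::setNames(config$bands, config$bands),
                           function(b) {
      preprocess_session(state$session, band = b,
                         target_rate = config$target_rate,
                         t_ahead = -config$epoch_window[1],
                         t_after = config$epoch_window[2],
                         z_threshold = config$z_threshold)
    })
    manifest <- note("preprocess", proc.time()[3] - t0)
  }
  if ("gc" %in% stages) {
    if (is.null(state$epochs)) stop("gc stage needs epochs (run preprocess first)")
    t0 <- proc.time()[3]
    state$gc <- lapply(state$epochs, function(ep) {
      windows <- make_windows(config$target_rate, config$epoch_window,
                              config$window_length, config$overlap)
      p <- config$order
      if (isTRUE(config$select_order)) {
        set.seed((config$seed + 101L) %% 2147483647L)
        p <- select_order(ep, config$order_range, windows)$p0
      }
      gc_cells(ep, p = p, windows = windows)
    })
    manifest <- note("gc", proc.time()[3] - t0)
  }
  if ("metrics" %in% stages) {
    if (is.null(state$gc)) stop("metrics stage needs gc output (run gc first)")
    t0 <- proc.time()[3]
    atlas <- state$session$atlas
    state$metrics <- do.call(rbind, c(
      lapply(state$gc, metrics_table, atlas = atlas),
      make.row.names = FALSE))
    manifest <- note("metrics", proc.time()[3] - t0)
  }
  if ("stats" %in% stages) {
    if (is.null(state$metrics)) stop("stats stage needs a metric table (run metrics first)")
    t0 <- proc.time()[3]
    state$stats <- group_statistics(state$metrics, alpha = config$alpha,
                                    groups = names(state$session$design$groups))
    manifest <- note("stats", proc.time()[3] - t0)
  }

  state$manifest <- manifest
  state$config <- config
  if (!is.null(out_dir)) write_pipeline_outputs(state, out_dir)
  state
}

write_pipeline_outputs <- function(state, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- state$config
  ser <- unclass(cfg)
  ser$groups <- NULL
  jsonlite::write_json(ser, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(state$session)) {
    utils::write.csv(state$session$events, file.path(out_dir, "events.csv"),
                     row.names = FALSE)
    utils::write.csv(state$session$atlas, file.path(out_dir, "atlas.csv"),
                     row.names = FALSE)
  }
  if (!is.null(state$gc)) {
    long <- do.call(rbind, c(lapply(state$gc, function(g) g$long),
                             make.row.names = FALSE))
    utils::write.csv(long, file.path(out_dir, "gc_long.csv"), row.names = FALSE)
    edge_dir <- file.path(out_dir, "edges_top")
    dir.create(edge_dir, showWarnings = FALSE)
    for (band in names(state$gc)) {
      for (cell in state$gc[[band]]$cells) {
        w <- retain_top_fraction(cell$gc$weights, cfg$retain_fraction)
        idx <- which(w > 0, arr.ind = TRUE)
        utils::write.csv(
          data.frame(source = idx[, 1], target = idx[, 2], weight = w[idx]),
          file.path(edge_dir, sprintf("%s_%s_%s_%s.csv", band, cell$subject,
                                      cell$condition, cell$window)),
          row.names = FALSE)
      }
    }
  }
  if (!is.null(state$metrics)) {
    utils::write.csv(state$metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
  }
  if (!is.null(state$stats)) {
    utils::write.csv(state$stats$tests, file.path(out_dir, "stats.csv"),
                     row.names = FALSE)
    jsonlite::write_json(state$stats$families,
                         file.path(out_dir, "fdr_families.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(state$manifest)) {
    utils::write.csv(state$manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  invisible(out_dir)
}
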