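#' Sliding-window layout over an epoch
#'
#' Generates half-open sample intervals (0-based) tiling the epoch with
#' overlapping windows. With the defaults (epoch \[-2, +1\] s, 1-s windows,
#' 50% overlap) the five windows are \[-2,-1\], \[-1.5,-0.5\], \[-1,0\],
#' \[-0.5,0.5\] and \[0,1\] s, each `window_length * rate` samples long.
#'
#' @param rate Sampling rate in Hz.
#' @param epoch_span Epoch limits in seconds relative to the event.
#' @param window_length Window length in seconds (default 1).
#' @param overlap Fractional overlap between adjacent windows in `[0, 1)`
#'   (default 0.5); the step is `window_length * (1 - overlap)`.
#' @return `data.frame` with columns `window`, `t_start`, `t_end`,
#'   `start_sample`, `end_sample` (half-open, 0-based).
#' @export
make_windows <- function(rate, epoch_span = c(-2, 1), window_length = 1,
                         overlap = 0.5) {
  stopifnot(length(epoch_span) == 2, epoch_span[2] > epoch_span[1])
  span <- epoch_span[2] - epoch_span[1]
  if (window_length > span + 1e-9) stop("window length exceeds epoch length")
  step <- window_length * (1 - overlap)
  if (step <= 0) stop("window step is zero (overlap must be < 1)")
  starts <- seq(epoch_span[1], epoch_span[2] - window_length + 1e-9, by = step)
  starts <- starts[starts + window_length <= epoch_span[2] + 1e-9]
  n_win <- as.integer(round(window_length * rate))
  data.frame(
    window = seq_along(starts),
    t_start = starts,
    t_end = starts + window_length,
    start_sample = as.integer(round((starts - epoch_span[1]) * rate)),
    end_sample = as.integer(round((starts - epoch_span[1]) * rate)) + n_win)
}

#' Akaike information criterion from a residual sum of squares
#'
#' `AIC = n * ln(RSS / n) + 2k`, the form used throughout the model-order
#' search, where `n` is the effective observation count (window samples
#' minus the lag truncation) and `k` the number of estimated coefficients.
#'
#' @param n_obs Effective observations, > 0.
#' @param rss Residual sum of squares, > 0.
#' @param k Number of estimated parameters.
#' @return The AIC score.
#' @export
aic <- function(n_obs, rss, k) {
  stopifnot(n_obs > 0, k >= 0)
  if (any(rss <= 0)) stop("rss must be strictly positive (log divergence)")
  n_obs * log(rss / n_obs) + 2 * k
}

#' Least-squares autoregressive fit
#'
#' Fits `target_t = sum_l coef[pred, l] * pred_{t-l} + e_t` over lags
#' `1..p` of one or more predictor series by ordinary least squares with
#' no intercept (series are expected to be demeaned). Residuals are
#' orthogonal to the lagged design.
#'
#' @param target Numeric series to predict.
#' @param predictors A numeric series, a list of series, or a matrix with
#'   one series per column (typically including the target's own past).
#' @param p Model order (number of lags).
#' @return Object of class `ar_fit`: `order`, `coefficients` (matrix
#'   `p x n_predictors`), `rss`, `n_obs`, `residual_variance`
#'   (`rss / n_obs`), `residuals`.
#' @export
fit_ar <- function(target, predictors, p) {
  if (is.numeric(predictors) && is.null(dim(predictors))) {
    predictors <- matrix(predictors, ncol = 1)
  }
  if (is.list(predictors) && !is.data.frame(predictors)) {
    predictors <- do.call(cbind, predictors)
  }
  predictors <- as.matrix(predictors)
  n <- length(target)
  stopifnot(nrow(predictors) == n, p >= 1)
  if (n <= 2 * p + 2) stop("series too short for the requested order")
  if (!all(is.finite(target)) || !all(is.finite(predictors))) {
    stop("series contain non-finite values")
  }
  X <- lag_design(predictors, p)
  y <- target[(p + 1):n]
  fit <- stats::.lm.fit(X, y, tol = 1e-12)
  if (fit$rank < ncol(X)) {
    stop("rank-deficient lagged design (constant or linearly dependent series)")
  }
  beta <- numeric(ncol(X))
  beta[fit$pivot] <- fit$coefficients
  res <- fit$residuals
  rss <- sum(res^2)
  structure(
    list(order = p,
         coefficients = matrix(beta, nrow = p,
                               dimnames = list(paste0("lag", 1:p), NULL)),
         rss = rss, n_obs = length(y),
         residual_variance = rss / length(y),
         residuals = as.numeric(res)),
    class = "ar_fit")
}

# lagged design matrix: columns are (pred1 lag1..p, pred2 lag1..p, ...)
lag_design <- function(M, p) {
  n <- nrow(M)
  do.call(cbind, lapply(seq_len(ncol(M)), function(j) {
    vapply(1:p, function(l) M[(p + 1 - l):(n - l), j], numeric(n - p))
  }))
}

# Shared lagged design for all AR fits within one data window.
# X: samples x channels, already demeaned. Columns of the lag block are
# ordered lag-major: (lag1 ch1..chN, lag2 ch1..chN, ...).
window_stats <- function(X, p) {
  n <- nrow(X); nch <- ncol(X)
  if (n <= 2 * p + 2) stop("window too short for the requested order")
  E <- stats::embed(X, p + 1)
  list(Y = E[, 1:nch, drop = FALSE], L = E[, -(1:nch), drop = FALSE],
       yy = colSums(E[, 1:nch, drop = FALSE]^2),
       n_eff = n - p, nch = nch, p = p)
}

# residual sums of squares of the `targets` channels regressed on the
# lags of the `preds` channels, by Householder QR least squares.
# Narrow-band (filtered) signals give severely ill-conditioned lag
# designs, so the fit runs on the design itself (never on its Gram
# matrix) with a rank tolerance that only trips on true singularity.
ws_rss <- function(ws, targets, preds) {
  idx <- as.vector(outer(preds, ws$nch * (0:(ws$p - 1)), "+"))
  fit <- stats::.lm.fit(ws$L[, idx, drop = FALSE],
                        ws$Y[, targets, drop = FALSE], tol = 1e-12)
  if (fit$rank < length(idx)) {
    stop(sprintf("rank-deficient lagged design for channels {%s} predicting {%s}",
                 paste(preds, collapse = ","),
                 paste(targets, collapse = ",")))
  }
  colSums(as.matrix(fit$residuals)^2)
}

#' Pairwise Granger causality for two series
#'
#' For demeaned series `x` and `y`, fits univariate and bivariate AR
#' models of order `p` by OLS and returns the log-ratios of
#' prediction-error variances:
#' `F_{y->x} = ln(var(e_x | x past) / var(e_x | x,y past))` and the
#' symmetric counterpart. In-sample nesting of the OLS fits makes both
#' values nonnegative up to rounding. The symmetric interaction strength
#' `max(F_{y->x}, F_{x->y})` is attached as attribute `symmetric_max`.
#'
#' @param x,y Numeric series of equal length.
#' @param p Model order.
#' @return Named numeric vector `c(y_to_x, x_to_y)`.
#' @export
gc_pair <- function(x, y, p) {
  stopifnot(length(x) == length(y), p >= 1)
  if (length(x) <= 2 * p + 2) stop("series too short for order ", p)
  X <- cbind(x - mean(x), y - mean(y))
  ws <- window_stats(X, p)
  rss_ux <- ws_rss(ws, 1, 1)
  rss_uy <- ws_rss(ws, 2, 2)
  rss_biv <- ws_rss(ws, c(1, 2), c(1, 2))
  tol <- 1e-20 * max(ws$yy, 1)
  if (any(rss_biv <= tol)) {
    stop("degenerate pair: bivariate residual variance is numerically zero")
  }
  out <- c(y_to_x = log(rss_ux / rss_biv[1]), x_to_y = log(rss_uy / rss_biv[2]))
  attr(out, "symmetric_max") <- max(out)
  out
}

# GC matrix for a single trial window (samples x channels), demeaned here
gc_trial_matrix <- function(X, p) {
  nch <- ncol(X)
  X <- sweep(X, 2, colMeans(X))
  ws <- window_stats(X, p)
  rss_uni <- vapply(seq_len(nch), function(i) ws_rss(ws, i, i), numeric(1))
  W <- matrix(0, nch, nch)
  tol <- 1e-20 * max(ws$yy, 1)
  for (i in seq_len(nch - 1)) {
    for (j in (i + 1):nch) {
      rss_biv <- ws_rss(ws, c(i, j), c(i, j))
      if (any(rss_biv <= tol)) {
        stop(sprintf("degenerate channel pair (%d, %d): zero bivariate residual variance", i, j))
      }
      W[j, i] <- log(rss_uni[i] / rss_biv[1])  # F_{j -> i}
      W[i, j] <- log(rss_uni[j] / rss_biv[2])  # F_{i -> j}
    }
  }
  W
}

#' Granger-causality matrix over trials of one window
#'
#' Computes the full `N x N` directed matrix `F_{i->j}` (entry `[i, j]`)
#' for every trial of a windowed data block and averages across trials.
#' Each trial window is mean-subtracted per channel before fitting; the
#' diagonal is zero by convention.
#'
#' @param window Numeric array, trials x channels x samples (a single
#'   trial may be passed as a channels x samples matrix).
#' @param p Model order.
#' @return Object of class `gc_matrix`: list with `weights` (N x N,
#'   `[i, j] = F_{i->j}` averaged over trials), `symmetric_max`
#'   (`max(F_{i->j}, F_{j->i})`), `order`, `n_trials`.
#' @export
gc_matrix <- function(window, p) {
  if (length(dim(window)) == 2) {
    window <- array(window, dim = c(1, dim(window)))
  }
  stopifnot(length(dim(window)) == 3)
  nt <- dim(window)[1]; nch <- dim(window)[2]
  if (nch < 2) stop("Granger causality needs at least 2 channels")
  acc <- matrix(0, nch, nch)
  for (tr in seq_len(nt)) {
    acc <- acc + gc_trial_matrix(t(window[tr, , ]), p)
  }
  W <- acc / nt
  structure(list(weights = W, symmetric_max = pmax(W, t(W)),
                 order = p, n_trials = nt),
            class = "gc_matrix")
}

#' @export
print.gc_matrix <- function(x, ...) {
  cat(sprintf("<gc_matrix> %d nodes, order %d, averaged over %d trial(s); mean F = %.4g\n",
              nrow(x$weights), x$order, x$n_trials,
              mean(x$weights[row(x$weights) != col(x$weights)])))
  invisible(x)
}

#' AIC-guided autoregressive model-order selection
#'
#' Implements the lead-trial selection protocol: the first
#' `n_lead_trials` trials of the lead condition (plus an optional random
#' subsample of the remaining trials) are selected; for every candidate
#' order the bivariate AR model of each ordered channel pair is fitted in
#' every sliding window of every selected trial and scored with
#' [aic()] (`k = 2p`, `n` = window samples minus `p`); scores are averaged
#' across pairs, trials and windows; the order minimizing the averaged
#' trace wins, with ties broken toward the smaller order.
#'
#' @param epochs An [epoch_set()], or a plain trials x channels x samples
#'   array (then treated as a single full-length window).
#' @param p_range Candidate orders (default 1:15).
#' @param windows Window table from [make_windows()]; defaults to the
#'   standard five-window layout for an `epoch_set`, or one full window
#'   for a plain array.
#' @param n_lead_trials Lead trials to always include (default 5).
#' @param trial_subsample Fraction of the remaining trials to add at
#'   random (default 0.1; 0 disables).
#' @param lead_condition Condition whose first trials are the lead set
#'   (default `"collision"`; ignored when metadata has no condition).
#' @return List with `p0` (selected order) and `trace`
#'   (`data.frame(p, aic)`).
#' @export
select_order <- function(epochs, p_range = 1:15, windows = NULL,
                         n_lead_trials = 5, trial_subsample = 0.1,
                         lead_condition = "collision") {
  if (inherits(epochs, "epoch_set")) {
    arr <- epochs$data
    rate <- epochs$sample_rate
    len <- dim(arr)[3]
    if (is.null(windows)) {
      span <- c(-epochs$t_zero_index, len - epochs$t_zero_index) / rate
      windows <- make_windows(rate, span)
    }
    cond <- epochs$meta$condition
  } else {
    arr <- epochs
    stopifnot(length(dim(arr)) == 3)
    if (is.null(windows)) {
      windows <- data.frame(window = 1L, start_sample = 0L,
                            end_sample = dim(arr)[3])
    }
    cond <- NULL
  }
  p_range <- sort(unique(as.integer(p_range)))
  win_len <- min(windows$end_sample - windows$start_sample)
  if (max(p_range) * 2 + 2 >= win_len) {
    stop("order range exceeds the data support of the windows")
  }
  nt <- dim(arr)[1]
  lead <- if (!is.null(cond)) which(cond == lead_condition) else seq_len(nt)
  lead <- utils::head(lead, n_lead_trials)
  rest <- setdiff(seq_len(nt), lead)
  extra <- if (trial_subsample > 0 && length(rest) > 0) {
    sample(rest, max(0, round(length(rest) * trial_subsample)))
  } else integer(0)
  trials <- sort(c(lead, extra))
  if (length(trials) == 0) stop("empty trial selection for order search")
  nch <- dim(arr)[2]
  if (nch < 2) stop("order selection needs at least 2 channels")

  trace <- vapply(p_range, function(p) {
    total <- 0; count <- 0
    for (tr in trials) {
      for (w in seq_len(nrow(windows))) {
        sl <- (windows$start_sample[w] + 1):windows$end_sample[w]
        X <- t(arr[tr, , sl])
        X <- sweep(X, 2, colMeans(X))
        ws <- window_stats(X, p)
        for (i in seq_len(nch - 1)) {
          for (j in (i + 1):nch) {
            rss_biv <- ws_rss(ws, c(i, j), c(i, j))
            total <- total + aic(ws$n_eff, rss_biv[1], 2 * p) +
              aic(ws$n_eff, rss_biv[2], 2 * p)
            count <- count + 2
          }
        }
      }
    }
    total / count
  }, numeric(1))
  list(p0 = p_range[which.min(trace)],
       trace = data.frame(p = p_range, aic = trace))
}

#' Sliding-window Granger-causality matrices for every analysis cell
#'
#' Splits an epoch set into (subject, condition) cells, computes the
#' trial-averaged GC matrix in every sliding window of every cell, and
#' returns both the matrices and a long-format table of directed weights.
#'
#' @param epochs An [epoch_set()] whose metadata has `subject_id`,
#'   `group` and `condition` columns.
#' @param p Model order (default 12).
#' @param windows Window table from [make_windows()]; defaults to the
#'   standard layout derived from the epoch geometry.
#' @return List with `cells` (one element per subject/condition/window:
#'   `subject`, `group`, `condition`, `window`, `gc` a [gc_matrix()])
#'   and `long` (`data.frame`: subject, group, band, condition, window,
#'   source, target, F).
#' @export
gc_cells <- function(epochs, p = 12, windows = NULL) {
  stopifnot(inherits(epochs, "epoch_set"),
            all(c("subject_id", "condition") %in% names(epochs$meta)))
  rate <- epochs$sample_rate
  len <- dim(epochs$data)[3]
  if (is.null(windows)) {
    span <- c(-epochs$t_zero_index, len - epochs$t_zero_index) / rate
    windows <- make_windows(rate, span)
  }
  band <- if (is.null(epochs$band)) "broadband" else attr(epochs$band, "label")
  meta <- epochs$meta
  if (!"group" %in% names(meta)) meta$group <- "all"
  cells <- list()
  long <- list()
  for (sub in unique(meta$subject_id)) {
    for (cnd in unique(meta$condition[meta$subject_id == sub])) {
      sel <- which(meta$subject_id == sub & meta$condition == cnd)
      grp <- meta$group[sel[1]]
      for (w in seq_len(nrow(windows))) {
        sl <- (windows$start_sample[w] + 1):windows$end_sample[w]
        gm <- gc_matrix(epochs$data[sel, , sl, drop = FALSE], p)
        key <- sprintf("%s|%s|SW%d", sub, cnd, w)
        cells[[key]] <- list(subject = sub, group = grp, condition = cnd,
                             window = paste0("SW", w), gc = gm)
        nch <- nrow(gm$weights)
        idx <- which(row(gm$weights) != col(gm$weights), arr.ind = TRUE)
        long[[key]] <- data.frame(
          subject = sub, group = grp, band = band, condition = cnd,
          window = paste0("SW", w),
          source = idx[, 1], target = idx[, 2],
          F = gm$weights[idx], stringsAsFactors = FALSE)
      }
    }
  }
  list(cells = cells,
       long = do.call(rbind, c(long, make.row.names = FALSE)),
       windows = windows, order = p)
}
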