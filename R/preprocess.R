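#' Canonical EEG frequency-band passbands
#'
#' @param band Band label (`"alpha"`, `"beta"`, `"gamma"`) or a numeric
#'   passband `c(low, high)` in Hz, returned unchanged.
#' @return Numeric passband `c(low, high)` in Hz with a `label` attribute.
#' @export
band_limits <- function(band) {
  if (is.numeric(band)) {
    stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1])
    lab <- attr(band, "label")
    return(structure(as.numeric(band),
                     label = if (is.null(lab)) paste0(band[1], "-", band[2], "Hz") else lab))
  }
  bands <- list(alpha = c(8, 13), beta = c(13, 30), gamma = c(30, 45))
  if (!band %in% names(bands)) {
    stop("unknown band '", band, "'; use alpha/beta/gamma or c(low, high)")
  }
  structure(bands[[band]], label = band)
}

#' Resample a continuous recording
#'
#' Anti-aliased downsampling to `target_rate`. Integer decimation factors
#' use a zero-phase FIR decimator; other rational factors use polyphase
#' resampling. Upsampling is refused.
#'
#' @param continuous An [eeg_continuous()].
#' @param target_rate Target rate in Hz, <= the source rate.
#' @return An [eeg_continuous()] at `target_rate`.
#' @export
resample_signal <- function(continuous, target_rate) {
  stopifnot(inherits(continuous, "eeg_continuous"))
  src <- continuous$sample_rate
  if (target_rate > src) stop("upsampling is not supported (target > source rate)")
  if (target_rate == src) return(continuous)
  q <- src / target_rate
  if (abs(q - round(q)) < 1e-9) {
    q <- as.integer(round(q))
    out <- apply(continuous$data, 2, signal::decimate, q = q, ftype = "fir")
  } else {
    g <- rational_factors(target_rate, src)
    out <- apply(continuous$data, 2, signal::resample, p = g[1], q = g[2])
  }
  eeg_continuous(out, target_rate, continuous$channel_names)
}

# reduce target/source to a small integer ratio p/q
rational_factors <- function(target, src) {
  scale <- 1
  while (abs(target * scale - round(target * scale)) > 1e-9 ||
         abs(src * scale - round(src * scale)) > 1e-9) {
    scale <- scale * 10
    if (scale > 1e6) stop("cannot express rate ratio as a small rational")
  }
  p <- round(target * scale); q <- round(src * scale)
  g <- gcd_int(p, q)
  c(p / g, q / g)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Zero-phase bandpass filtering
#'
#' Applies a Butterworth bandpass forwards and backwards (`filtfilt`) so
#' that the output has no group delay: event alignment, on which the
#' sliding-window analysis depends, is preserved.
#'
#' @param continuous An [eeg_continuous()].
#' @param band Band label or numeric passband, see [band_limits()].
#' @param order Butterworth order per pass (default 4).
#' @return Filtered [eeg_continuous()]; the band is recorded in the
#'   `band` attribute.
#' @export
bandpass_filter <- function(continuous, band = "alpha", order = 4) {
  stopifnot(inherits(continuous, "eeg_continuous"))
  pb <- band_limits(band)
  nyq <- continuous$sample_rate / 2
  if (pb[1] <= 0 || pb[2] >= nyq) {
    stop(sprintf("passband [%g, %g] Hz outside (0, Nyquist = %g) Hz",
                 pb[1], pb[2], nyq))
  }
  bf <- signal::butter(order, pb / nyq, type = "pass")
  out <- apply(continuous$data, 2, function(ch) signal::filtfilt(bf, ch))
  res <- eeg_continuous(out, continuous$sample_rate, continuous$channel_names)
  attr(res, "band") <- pb
  res
}

#' Event-aligned epoch container
#'
#' @param data Numeric array, trials x channels x samples.
#' @param sample_rate Rate in Hz.
#' @param t_zero_index 0-based sample index of the event within each epoch.
#' @param meta Per-trial metadata `data.frame` (one row per trial).
#' @param band Passband from [band_limits()], or `NULL`.
#' @return Object of class `epoch_set`.
#' @export
epoch_set <- function(data, sample_rate, t_zero_index, meta, band = NULL) {
  stopifnot(length(dim(data)) == 3, nrow(meta) == dim(data)[1])
  structure(list(data = data, sample_rate = sample_rate,
                 t_zero_index = as.integer(t_zero_index),
                 meta = meta, band = band),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  lab <- if (is.null(x$band)) "broadband" else attr(x$band, "label")
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz [%s], t0 at index %d\n",
              d[1], d[2], d[3], x$sample_rate, lab, x$t_zero_index))
  invisible(x)
}

n_trials <- function(epochs) dim(epochs$data)[1]

#' Cut event-aligned epochs out of a continuous recording
#'
#' Each epoch spans the half-open sample interval
#' `[event - t_ahead * rate, event + t_after * rate)` (0-based), so every
#' epoch has exactly `(t_ahead + t_after) * rate` samples and the event
#' falls at index `t_ahead * rate`. Events whose epoch would run off either
#' end of the recording are dropped with a warning.
#'
#' @param continuous An [eeg_continuous()].
#' @param events Events `data.frame` with at least `event_sample` (0-based,
#'   at `event_rate`) plus any per-trial metadata to carry along.
#' @param t_ahead Seconds before the event (default 2).
#' @param t_after Seconds after the event (default 1).
#' @param event_rate Rate at which `event_sample` is expressed; defaults to
#'   the recording's rate. Event samples are rescaled when they differ
#'   (e.g. after downsampling).
#' @return An [epoch_set()].
#' @export
extract_epochs <- function(continuous, events, t_ahead = 2, t_after = 1,
                           event_rate = continuous$sample_rate) {
  stopifnot(inherits(continuous, "eeg_continuous"), nrow(events) > 0)
  rate <- continuous$sample_rate
  ev <- as.integer(round(events$event_sample * rate / event_rate))
  n_pre <- as.integer(round(t_ahead * rate))
  n_post <- as.integer(round(t_after * rate))
  len <- n_pre + n_post
  n_samp <- nrow(continuous$data)
  ok <- (ev - n_pre) >= 0 & (ev + n_post) <= n_samp
  if (!any(ok)) stop("no event has full epoch support within the recording")
  if (any(!ok)) {
    warning(sprintf("dropping %d event(s) without full epoch support (trials: %s)",
                    sum(!ok), paste(which(!ok), collapse = ", ")))
  }
  ev <- ev[ok]
  out <- array(0, dim = c(length(ev), ncol(continuous$data), len))
  for (i in seq_along(ev)) {
    out[i, , ] <- t(continuous$data[(ev[i] - n_pre + 1):(ev[i] + n_post), ])
  }
  epoch_set(out, rate, n_pre, events[ok, , drop = FALSE],
            band = attr(continuous, "band"))
}

#' Keep only correctly answered trials
#'
#' @param epochs An [epoch_set()] whose metadata has a logical `correct`
#'   column.
#' @return The epoch set restricted to correct trials.
#' @export
filter_correct_trials <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"), "correct" %in% names(epochs$meta))
  keep <- as.logical(epochs$meta$correct)
  if (!any(keep)) stop("no correct trials survive the correctness filter")
  subset_epochs(epochs, keep)
}

subset_epochs <- function(epochs, keep) {
  epoch_set(epochs$data[keep, , , drop = FALSE], epochs$sample_rate,
            epochs$t_zero_index, epochs$meta[keep, , drop = FALSE],
            epochs$band)
}

#' Statistical artifact screen over trials
#'
#' Computes three per-trial summary features -- mean channel variance,
#' mean channel kurtosis and the maximum absolute amplitude -- z-scores
#' each feature across trials, and rejects any trial whose |z| exceeds
#' the threshold on any feature. This is the trial-level analogue of
#' feature-z-score artifact screening with the conventional |z| > 3 cut.
#'
#' @param epochs An [epoch_set()] with at least 3 trials.
#' @param z_threshold Rejection threshold on |z| (default 3; `Inf`
#'   disables rejection).
#' @return List with `epochs` (trials retained) and `report`
#'   (`data.frame`: trial, the three z-scores, `rejected`, `features`
#'   naming the triggering feature(s)).
#' @export
artifact_screen <- function(epochs, z_threshold = 3) {
  stopifnot(inherits(epochs, "epoch_set"))
  nt <- n_trials(epochs)
  if (nt < 3) stop("artifact screening needs at least 3 trials")
  feats <- t(vapply(seq_len(nt), function(i) {
    x <- epochs$data[i, , , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    v <- apply(x, 1, stats::var)
    k <- apply(x, 1, kurtosis_pearson)
    c(variance = mean(v), kurtosis = mean(k), max_amp = max(abs(x)))
  }, numeric(3)))
  z <- scale(feats)
  z[is.nan(z)] <- 0  # zero-variance feature across trials
  bad <- abs(z) > z_threshold
  rejected <- rowSums(bad) > 0
  report <- data.frame(
    trial = seq_len(nt),
    z_variance = z[, 1], z_kurtosis = z[, 2], z_max_amp = z[, 3],
    rejected = rejected,
    features = vapply(seq_len(nt), function(i) {
      paste(colnames(feats)[bad[i, ]], collapse = ",")
    }, character(1)))
  list(epochs = subset_epochs(epochs, !rejected), report = report)
}

kurtosis_pearson <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 == 0) return(0)
  mean(x^4) / m2^2
}

#' Preprocess a synthetic session into a band-limited epoch set
#'
#' Runs the fixed pipeline resample -> bandpass -> epoch -> correctness
#' filter -> artifact screen for every subject and concatenates the
#' per-subject epochs into one [epoch_set()]. The artifact screen is
#' applied within subject (z-scores across that subject's trials).
#'
#' @param session A [simulate_session()] result (or equivalent structure).
#' @param band Band label or passband, see [band_limits()].
#' @param target_rate Analysis rate in Hz (default 500).
#' @param t_ahead,t_after Epoch span in seconds around the event.
#' @param correct_only Drop incorrect trials (default TRUE).
#' @param z_threshold Artifact screen threshold; `Inf` disables.
#' @param filter_order Butterworth order per pass.
#' @return An [epoch_set()] covering all subjects, with a
#'   `screen_reports` attribute (per-subject rejection reports).
#' @export
preprocess_session <- function(session, band = "beta", target_rate = 500,
                               t_ahead = 2, t_after = 1,
                               correct_only = TRUE, z_threshold = 3,
                               filter_order = 4) {
  stopifnot(inherits(session, "synthetic_session") || is.list(session))
  pieces <- list()
  reports <- list()
  for (s in session$subjects) {
    ev <- session$events[session$events$subject_id == s$id, , drop = FALSE]
    x <- resample_signal(s$data, target_rate)
    x <- bandpass_filter(x, band, order = filter_order)
    ep <- extract_epochs(x, ev, t_ahead, t_after,
                         event_rate = s$data$sample_rate)
    if (correct_only) ep <- filter_correct_trials(ep)
    if (is.finite(z_threshold)) {
      scr <- artifact_screen(ep, z_threshold)
      ep <- scr$epochs
      reports[[s$id]] <- scr$report
    }
    pieces[[s$id]] <- ep
  }
  len <- unique(vapply(pieces, function(e) dim(e$data)[3], integer(1)))
  nch <- unique(vapply(pieces, function(e) dim(e$data)[2], integer(1)))
  stopifnot(length(len) == 1, length(nch) == 1)
  total <- sum(vapply(pieces, n_trials, integer(1)))
  data <- array(0, dim = c(total, nch, len))
  meta <- list()
  at <- 0L
  for (id in names(pieces)) {
    e <- pieces[[id]]
    k <- n_trials(e)
    data[(at + 1):(at + k), , ] <- e$data
    meta[[id]] <- e$meta
    at <- at + k
  }
  out <- epoch_set(data, target_rate, pieces[[1]]$t_zero_index,
                   do.call(rbind, c(meta, make.row.names = FALSE)),
                   band = band_limits(band))
  attr(out, "screen_reports") <- reports
  out
}
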