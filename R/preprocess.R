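#' Construct a multi-lead ECG record
#'
#' @param signal numeric matrix, time samples in rows and leads in columns
#'   (a plain vector is taken as a single lead). Amplitudes in millivolts.
#' @param fs sampling frequency in Hz, positive.
#' @param labels character vector of diagnostic labels attached to the
#'   record (may be empty).
#' @param record_id identifier string.
#' @return an object of class `ecg_record`.
#' @export
ecg_record <- function(signal, fs, labels = character(), record_id = "rec") {
  if (is.vector(signal)) signal <- matrix(signal, ncol = 1)
  signal <- as.matrix(signal)
  if (!is.numeric(signal) || nrow(signal) == 0)
    stop("signal must be a non-empty numeric matrix (time x leads)")
  if (length(fs) != 1 || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  structure(list(signal = signal, fs = fs,
                 labels = as.character(labels),
                 record_id = record_id),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ECG record '%s': %d leads x %d samples @ %g Hz (%.1f s)\n",
              x$record_id, ncol(x$signal), nrow(x$signal), x$fs,
              nrow(x$signal) / x$fs))
  if (length(x$labels))
    cat("labels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Resample an ECG record to a target rate
#'
#' Per lead: when down-sampling, an anti-alias zero-phase Butterworth
#' low-pass (order 5, cutoff `0.45 * target_fs`) precedes cubic-spline
#' interpolation onto the target time grid; up-sampling interpolates
#' directly. Duration is preserved to within one sample
#' (`n_out = round(n * target_fs / fs)`), and a record already at the
#' target rate is returned unchanged.
#'
#' @param rec an [ecg_record()].
#' @param target_fs target sampling frequency in Hz (default 250).
#' @return the resampled [ecg_record()].
#' @export
resample_record <- function(rec, target_fs = 250) {
  stopifnot(inherits(rec, "ecg_record"))
  if (rec$fs == target_fs) return(rec)
  n <- nrow(rec$signal)
  n_out <- round(n * target_fs / rec$fs)
  if (n_out < 2) stop("record too short to resample")
  t_in <- (seq_len(n) - 1) / rec$fs
  t_out <- (seq_len(n_out) - 1) / target_fs
  filt <- NULL
  if (target_fs < rec$fs)
    filt <- signal::butter(5, 0.45 * target_fs / (rec$fs / 2), type = "low")
  out <- apply(rec$signal, 2, function(x) {
    if (!is.null(filt)) x <- signal::filtfilt(filt, x)
    stats::spline(t_in, x, xout = t_out, method = "natural")$y
  })
  rec$signal <- matrix(out, nrow = n_out)
  rec$fs <- target_fs
  rec
}

#' Remove baseline wander by moving-average subtraction
#'
#' The baseline of each lead is estimated with a centered moving average over
#' a one-second window (250 samples at the working rate of 250 Hz) with
#' reflection padding at the edges, and subtracted from the signal.
#'
#' @param rec an [ecg_record()] at 250 Hz.
#' @param window_seconds moving-average window length in seconds (default 1).
#' @return the de-trended [ecg_record()].
#' @export
remove_baseline <- function(rec, window_seconds = 1) {
  stopifnot(inherits(rec, "ecg_record"))
  n <- nrow(rec$signal)
  w <- round(window_seconds * rec$fs)
  if (w > n) {
    warning("record shorter than the baseline window; shrinking window to ",
            n, " samples")
    w <- n
  }
  rec$signal <- apply(rec$signal, 2, function(x) x - moving_average(x, w))
  rec$signal <- matrix(rec$signal, nrow = n)
  rec
}

# centered moving average with reflection padding; exact window length w
moving_average <- function(x, w) {
  n <- length(x)
  left <- (w - 1) %/% 2
  right <- w - 1 - left
  xp <- c(rev(x[seq_len(left) + 1]), x, rev(x[n - seq_len(right)]))
  cs <- cumsum(c(0, xp))
  (cs[(w + 1):(n + w)] - cs[1:n]) / w
}

#' Band-pass filter an ECG record (0.1-50 Hz)
#'
#' Suppresses residual baseline drift, power-line interference, muscle and
#' respiration noise. Implemented as a cascade of zero-phase Butterworth
#' filters: high-pass order 2 at `low` Hz and low-pass order 5 at `high` Hz
#' (both applied forward-backward, so the passband edge at 10 Hz keeps gain
#' within 5% and a 60 Hz tone is attenuated by more than 90%).
#'
#' @param rec an [ecg_record()].
#' @param low,high passband edges in Hz.
#' @return the filtered [ecg_record()].
#' @export
bandpass_record <- function(rec, low = 0.1, high = 50) {
  stopifnot(inherits(rec, "ecg_record"))
  nyq <- rec$fs / 2
  if (high >= nyq) stop("upper band edge must be below Nyquist")
  hp <- signal::butter(2, low / nyq, type = "high")
  lp <- signal::butter(5, high / nyq, type = "low")
  n <- nrow(rec$signal)
  rec$signal <- apply(rec$signal, 2, function(x)
    signal::filtfilt(lp, signal::filtfilt(hp, x)))
  rec$signal <- matrix(rec$signal, nrow = n)
  rec
}

#' Standardize each lead to zero mean and unit variance
#'
#' Normalization is per lead, using the population variance. A lead with
#' (numerically) zero variance is set to all zeros with a warning.
#'
#' @param rec an [ecg_record()].
#' @param eps variance guard below which a lead counts as constant.
#' @return the standardized [ecg_record()].
#' @export
standardize_record <- function(rec, eps = 1e-12) {
  stopifnot(inherits(rec, "ecg_record"))
  n <- nrow(rec$signal)
  rec$signal <- apply(rec$signal, 2, function(x) {
    mu <- mean(x)
    v <- mean((x - mu)^2)
    if (v < eps) {
      warning("constant lead standardized to zeros")
      rep(0, length(x))
    } else (x - mu) / sqrt(v)
  })
  rec$signal <- matrix(rec$signal, nrow = n)
  rec
}

#' Fix record length by end-truncation or zero-padding
#'
#' Longer records keep their first `target_seconds * fs` samples; shorter
#' records are padded with zeros at the end.
#'
#' @param rec an [ecg_record()].
#' @param target_seconds target duration (default 20 s, i.e. 5000 samples at
#'   250 Hz).
#' @return the length-fixed [ecg_record()].
#' @export
fix_length <- function(rec, target_seconds = 20) {
  stopifnot(inherits(rec, "ecg_record"))
  n_target <- round(target_seconds * rec$fs)
  n <- nrow(rec$signal)
  if (n >= n_target) {
    rec$signal <- rec$signal[seq_len(n_target), , drop = FALSE]
  } else {
    pad <- matrix(0, n_target - n, ncol(rec$signal))
    rec$signal <- rbind(rec$signal, pad)
  }
  rec
}

#' Full ECG pre-processing chain
#'
#' Resample to 250 Hz, remove baseline wander, band-pass 0.1-50 Hz,
#' standardize per lead, and fix the length to 20 s — in that order
#' (standardization precedes padding so that padded zeros do not distort the
#' lead statistics). Output is always `5000 x l` at 250 Hz.
#'
#' @param rec an [ecg_record()] at any sampling rate/length.
#' @param target_fs target rate (default 250 Hz).
#' @param target_seconds target duration (default 20 s).
#' @return the pre-processed [ecg_record()].
#' @export
preprocess_ecg <- function(rec, target_fs = 250, target_seconds = 20) {
  rec <- resample_record(rec, target_fs)
  rec <- remove_baseline(rec)
  rec <- bandpass_record(rec)
  rec <- standardize_record(rec)
  fix_length(rec, target_seconds)
}
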