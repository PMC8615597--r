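#' Generate an imbalanced multi-label annotation matrix
#'
#' Each category is a Bernoulli draw at its target prevalence, optionally
#' tilted by pairwise co-occurrence odds multipliers: when sampling category
#' `j`, the odds are multiplied by `co_occurrence[k, j]` for every earlier
#' category `k` already positive in the sample. With the identity multiplier
#' the columns are independent and the empirical prevalence is binomial
#' around the target. Prevalences spanning `1/(1+IR)` for `IR` from 1 to
#' 1000 emulate the extreme imbalance of realistic ECG corpora; choosing
#' prevalences that sum to about 2 reproduces the typical label cardinality.
#'
#' @param n_samples number of recordings.
#' @param prevalence length-`m` vector of target prevalences in `(0, 1]`.
#' @param labels category identifiers (default ECG-style names).
#' @param co_occurrence optional `m x m` matrix of odds multipliers (upper
#'   triangle used; 1 = independent). Must be positive and finite.
#' @param seed integer seed.
#' @return binary `n_samples x m` matrix with `labels` as column names.
#' @export
gen_label_matrix <- function(n_samples, prevalence,
                             labels = default_labels(length(prevalence)),
                             co_occurrence = NULL, seed = 1L) {
  m <- length(prevalence)
  if (any(prevalence <= 0 | prevalence > 1))
    stop("prevalences must lie in (0, 1]")
  if (!is.null(co_occurrence)) {
    co_occurrence <- as.matrix(co_occurrence)
    if (any(!is.finite(co_occurrence)) || any(co_occurrence <= 0))
      stop("co-occurrence odds multipliers must be positive and finite")
    if (!all(dim(co_occurrence) == m))
      stop("co_occurrence must be m x m")
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old))
  set.seed(seed)
  y <- matrix(0L, n_samples, m, dimnames = list(NULL, labels))
  base_odds <- prevalence / (1 - pmin(prevalence, 1 - 1e-12))
  if (is.null(co_occurrence)) {
    for (j in seq_len(m))
      y[, j] <- stats::rbinom(n_samples, 1L, prevalence[j])
  } else {
    for (j in seq_len(m)) {
      odds <- rep(base_odds[j], n_samples)
      for (k in seq_len(j - 1L)) {
        mult <- co_occurrence[k, j]
        if (mult != 1) odds <- odds * ifelse(y[, k] == 1L, mult, 1)
      }
      p <- odds / (1 + odds)
      p[prevalence[j] == 1] <- 1
      y[, j] <- stats::rbinom(n_samples, 1L, p)
    }
  }
  y
}

#' Generate calibrated classifier scores for a label matrix
#'
#' Models the output of a probabilistic classifier whose scores are true
#' posterior probabilities. For a category with prevalence `pi`, a latent
#' posterior is drawn per recording from `Beta(pi / sharpness,
#' (1 - pi) / sharpness)` — mean `pi`, so the marginal prevalence is
#' preserved — and emitted as the score.
#'
#' * `mode = "resample"`: the cell's label is redrawn as `Bernoulli(p)`,
#'   making the scores exactly calibrated by construction
#'   (`P(label = 1 | score = p) = p`). The returned labels replace the input
#'   ones and must be used in their place.
#' * `mode = "fixed-label"`: the input labels are kept and scores are drawn
#'   from the matching conditionals `Beta(a + y, b + 1 - y)` — approximately
#'   calibrated when the input labels follow their nominal prevalence.
#'
#' `sharpness` controls informativeness: as it grows the Beta mass moves to
#' \{0, 1\} (a near-perfect classifier); as it shrinks, scores concentrate at
#' the prevalence (an uninformative one). The default 1 emulates a
#' moderately informative classifier.
#'
#' @param y binary `N x m` label matrix (defines prevalences; in
#'   `"resample"` mode its cells are redrawn).
#' @param sharpness positive scalar (default 1).
#' @param mode `"resample"` (exact calibration) or `"fixed-label"`.
#' @param seed integer seed.
#' @param prevalence optional prevalences overriding the empirical column
#'   means of `y` (useful when a column has no positives).
#' @return list with `scores` (`N x m` matrix in `[0, 1]`) and `labels`
#'   (binary matrix: redrawn in `"resample"` mode, the input otherwise).
#' @export
gen_calibrated_scores <- function(y, sharpness = 1,
                                  mode = c("resample", "fixed-label"),
                                  seed = 1L, prevalence = NULL) {
  mode <- match.arg(mode)
  if (sharpness <= 0) stop("sharpness must be positive")
  y <- check_label_matrix(y)
  n <- nrow(y); m <- ncol(y)
  if (is.null(prevalence)) prevalence <- colMeans(y)
  prevalence <- pmin(pmax(prevalence, 1e-6), 1 - 1e-6)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old))
  set.seed(seed)
  scores <- matrix(0, n, m, dimnames = dimnames(y))
  labels <- y
  for (j in seq_len(m)) {
    a <- prevalence[j] / sharpness
    b <- (1 - prevalence[j]) / sharpness
    if (mode == "resample") {
      p <- stats::rbeta(n, a, b)
      labels[, j] <- stats::rbinom(n, 1L, p)
    } else {
      p <- stats::rbeta(n, a + y[, j], b + 1 - y[, j])
    }
    scores[, j] <- p
  }
  list(scores = scores, labels = labels)
}

#' Generate a parametric multi-lead ECG-like waveform
#'
#' Builds a signal as a train of Gaussian-wavelet heartbeats (P wave, QRS
#' complex with narrow positive and negative lobes, T wave) placed on an
#' RR-interval process, with additive broadband noise and sinusoidal
#' baseline drift. The active labels deterministically modulate the
#' generator:
#'
#' * `NSR` — about 75 bpm, small RR variability;
#' * `STach` — fast rhythm, about 120 bpm;
#' * `SB` — slow rhythm, about 45 bpm;
#' * `AF` — irregular RR intervals (high variability) and absent P waves;
#' * `PVC` — about 20% of beats replaced by wide-complex ectopic beats
#'   (broad, large QRS, no P wave).
#'
#' Rhythm labels combine by applying the fastest/slowest rate modifier last
#' in the order above; morphology labels act per beat. The second lead is an
#' amplitude-rescaled variant of the first with partially inverted T waves,
#' enough to exercise multi-lead code paths.
#'
#' @param labels character subset of `c("NSR", "STach", "SB", "AF", "PVC")`.
#' @param duration_s record duration in seconds (default 20).
#' @param fs sampling frequency in Hz (default 250).
#' @param n_leads number of leads (default 2).
#' @param noise_sd standard deviation of additive Gaussian noise (mV).
#' @param drift_amp amplitude of a 0.25 Hz baseline drift (mV).
#' @param seed integer seed.
#' @param record_id identifier for the returned record.
#' @return an [ecg_record()] carrying `labels`.
#' @export
gen_ecg <- function(labels = "NSR", duration_s = 20, fs = 250, n_leads = 2,
                    noise_sd = 0.02, drift_amp = 0.1, seed = 1L,
                    record_id = "synth") {
  supported <- c("NSR", "STach", "SB", "AF", "PVC")
  labels <- as.character(labels)
  bad <- setdiff(labels, supported)
  if (length(bad))
    stop("unsupported label(s): ", paste(bad, collapse = ", "),
         " (supported: ", paste(supported, collapse = ", "), ")")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old))
  set.seed(seed)

  rate_bpm <- 75; rr_cv <- 0.03; p_amp <- 0.15; pvc_frac <- 0
  if ("STach" %in% labels) rate_bpm <- 120
  if ("SB" %in% labels) rate_bpm <- 45
  if ("AF" %in% labels) { rr_cv <- 0.2; p_amp <- 0 }
  if ("PVC" %in% labels) pvc_frac <- 0.2

  rr_mean <- 60 / rate_bpm
  n_beats <- ceiling(duration_s / rr_mean) + 3
  rr <- stats::rnorm(n_beats, rr_mean, rr_cv * rr_mean)
  rr <- pmax(rr, 0.25)
  beat_t <- cumsum(rr)
  beat_t <- beat_t[beat_t < duration_s + rr_mean]
  is_pvc <- stats::runif(length(beat_t)) < pvc_frac

  n <- round(duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  gauss <- function(center, width, amp) amp * exp(-((tt - center)^2) / (2 * width^2))
  x <- numeric(n)
  for (b in seq_along(beat_t)) {
    tc <- beat_t[b]
    if (is_pvc[b]) {
      # wide-complex ectopic: broad tall R, deep wide S, discordant T, no P
      x <- x + gauss(tc, 0.04, 1.6) + gauss(tc + 0.09, 0.05, -0.7) +
        gauss(tc + 0.35, 0.09, -0.4)
    } else {
      x <- x + gauss(tc - 0.17, 0.025, p_amp) +      # P
        gauss(tc - 0.025, 0.012, -0.15) +            # Q
        gauss(tc, 0.012, 1.2) +                      # R
        gauss(tc + 0.03, 0.014, -0.25) +             # S
        gauss(tc + 0.3, 0.07, 0.35)                  # T
    }
  }
  sig <- matrix(0, n, n_leads)
  lead_gain <- c(1, 0.7, rep(0.5, max(0, n_leads - 2)))[seq_len(n_leads)]
  for (l in seq_len(n_leads)) {
    xl <- x * lead_gain[l]
    if (l == 2) xl <- xl - 2 * lead_gain[l] * gauss_train_t(tt, beat_t[!is_pvc], 0.3, 0.07, 0.35)
    drift <- drift_amp * sin(2 * pi * 0.25 * tt + stats::runif(1, 0, 2 * pi))
    sig[, l] <- xl + drift + stats::rnorm(n, 0, noise_sd)
  }
  ecg_record(sig, fs = fs, labels = labels, record_id = record_id)
}

# sum of Gaussian bumps at offsets from beat times (helper for lead shaping)
gauss_train_t <- function(tt, centers, offset, width, amp) {
  out <- numeric(length(tt))
  for (tc in centers)
    out <- out + amp * exp(-((tt - tc - offset)^2) / (2 * width^2))
  out
}
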