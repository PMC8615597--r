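#' Apply per-category thresholds to a score matrix
#'
#' A category enters a recording's predicted label set when its score is
#' strictly larger than the category threshold. The comparison is strict, so
#' a score exactly equal to the threshold is negative — the boundary case
#' matters for saturated scores (e.g. score 0.5 against threshold 0.5).
#'
#' @param scores `N x m` numeric matrix of classifier scores in `[0, 1]`.
#' @param thresholds length-`m` numeric vector; when named and the score
#'   matrix has column names, names must match in order.
#' @return binary prediction matrix of the same shape and dimnames.
#' @export
apply_thresholds <- function(scores, thresholds) {
  scores <- check_score_matrix(scores)
  if (length(thresholds) != ncol(scores))
    stop("got ", length(thresholds), " thresholds for ", ncol(scores),
         " score columns")
  if (!is.null(names(thresholds)) && !is.null(colnames(scores)) &&
      !identical(names(thresholds), colnames(scores)))
    stop("threshold names are not aligned with score columns")
  yhat <- (scores > rep(thresholds, each = nrow(scores))) * 1
  dimnames(yhat) <- dimnames(scores)
  yhat
}

#' Rank-based thresholding (Rcut)
#'
#' Assigns to every recording exactly the `t_count` highest-scoring
#' categories; `t_count` is conventionally the label cardinality of the
#' training set (about 2 for multi-label ECG corpora). Ties are broken by
#' ascending category index for reproducibility.
#'
#' @param scores `N x m` score matrix.
#' @param t_count number of labels to assign per recording, `1 <= t <= m`.
#' @return binary prediction matrix with exactly `t_count` ones per row.
#' @export
rcut <- function(scores, t_count) {
  scores <- check_score_matrix(scores)
  m <- ncol(scores)
  if (length(t_count) != 1 || t_count < 1 || t_count > m)
    stop("t_count must be a single integer in [1, ", m, "]")
  yhat <- matrix(0, nrow(scores), m, dimnames = dimnames(scores))
  for (i in seq_len(nrow(scores))) {
    # order(-x) is stable: ties resolve to the lower category index
    top <- order(-scores[i, ])[seq_len(t_count)]
    yhat[i, top] <- 1
  }
  yhat
}

#' Proportion-based thresholding (Pcut)
#'
#' For every category `j`, the `k_j = round(prevalence_j * N)` top-scoring
#' recordings are predicted positive, where the prevalence is taken from the
#' training set. Rounding is R's banker's rounding (round half to even);
#' score ties resolve to the lower recording index.
#'
#' @param scores `N x m` score matrix.
#' @param train_prevalence length-`m` vector of training-set label
#'   proportions in `[0, 1]`.
#' @return binary prediction matrix with exactly `k_j` ones in column `j`.
#' @export
pcut <- function(scores, train_prevalence) {
  scores <- check_score_matrix(scores)
  m <- ncol(scores)
  if (length(train_prevalence) != m)
    stop("need one prevalence per category")
  if (any(train_prevalence < 0 | train_prevalence > 1))
    stop("prevalences must lie in [0, 1]")
  n <- nrow(scores)
  yhat <- matrix(0, n, m, dimnames = dimnames(scores))
  k <- round(train_prevalence * n)
  for (j in seq_len(m)) {
    if (k[j] > 0) {
      top <- order(-scores[, j])[seq_len(min(k[j], n))]
      yhat[top, j] <- 1
    }
  }
  yhat
}

#' Fixed thresholding
#'
#' Applies one constant threshold (conventionally 0.5; 0.2 is a common tuned
#' alternative for imbalanced ECG corpora) to all categories. Equivalent to
#' [apply_thresholds()] with a constant vector.
#'
#' @param scores `N x m` score matrix.
#' @param value scalar threshold in `[0, 1]`.
#' @return binary prediction matrix.
#' @export
fixed_threshold <- function(scores, value = 0.5) {
  if (length(value) != 1 || value < 0 || value > 1)
    stop("value must be a single number in [0, 1]")
  scores <- check_score_matrix(scores)
  apply_thresholds(scores, rep(value, ncol(scores)))
}

check_score_matrix <- function(scores) {
  scores <- as.matrix(scores)
  if (!is.numeric(scores)) stop("scores must be numeric")
  if (any(!is.finite(scores)) || any(scores < 0 | scores > 1))
    stop("scores must lie in [0, 1]")
  scores
}
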