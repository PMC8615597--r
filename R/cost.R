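#' Per-category false-positive costs from a cost matrix and training labels
#'
#' Converts the pairwise misclassification cost matrix `C'` into one
#' representative false-positive cost per category, averaged over the label
#' distribution of a training set (the false-negative cost is fixed at 1 by
#' convention). The steps are:
#'
#' 1. `L[i] = max(sum(Y[i, ]), 1)` — label count of sample `i` (label-free
#'    samples divide by 1 and contribute zero cost rows);
#' 2. `Yn[i, ] = Y[i, ] / L[i]` — row-normalized labels;
#' 3. `SC' = Yn %*% C'` — expected cost of predicting each category on each
#'    sample, given its annotated labels;
#' 4. `SC'' = SC' * (1 - Y)` — correct predictions cost nothing;
#' 5. `c'[j] = sum(SC''[, j]) / sum(1 - Y[, j])` — mean over the negative
#'    samples of category `j`.
#'
#' The matrix product in step 3 is accumulated column-by-column in label
#' order, so results are bitwise-reproducible and independent of the BLAS.
#'
#' @param cost numeric `m x m` cost matrix (see [benefit_to_cost()]).
#' @param y binary `N x m` label matrix; column names, when present, must
#'   match the cost matrix labels in order.
#' @return list with `fp_costs_raw` (named length-`m` vector `c'`) and
#'   `trace`, a list of the intermediates `per_sample_label_count`,
#'   `normalized_labels`, `per_sample_costs` (`SC'`) and `masked_costs`
#'   (`SC''`).
#' @examples
#' cp <- matrix(c(0, .5, .5, 0), 2, 2)
#' y <- rbind(c(1, 0), c(0, 1))
#' compute_false_positive_costs(cp, y)$fp_costs_raw
#' @export
compute_false_positive_costs <- function(cost, y) {
  cost <- as.matrix(cost)
  y <- check_label_matrix(y, ncol(cost), colnames(cost))
  n <- nrow(y); m <- ncol(y)
  L <- pmax(rowSums(y), 1)
  yn <- y / L
  # fixed-order accumulation over the true-label index: bitwise equal to an
  # elementwise loop regardless of BLAS kernel
  scp <- matrix(0, n, m, dimnames = dimnames(y))
  for (k in seq_len(m))
    scp <- scp + outer(yn[, k], cost[k, ])
  scpp <- scp * (1 - y)
  n_neg <- colSums(1 - y)
  cp <- numeric(m)
  for (j in seq_len(m)) {
    if (n_neg[j] == 0) {
      warning("category '", colnames(y)[j], "' has no negative samples; ",
              "its false-positive cost is set to 0 (it can never be a ",
              "false positive in this set)")
      cp[j] <- 0
    } else {
      cp[j] <- sum(scpp[, j]) / n_neg[j]
    }
  }
  names(cp) <- colnames(y)
  list(fp_costs_raw = cp,
       trace = list(per_sample_label_count = L,
                    normalized_labels = yn,
                    per_sample_costs = scp,
                    masked_costs = scpp))
}

#' Per-category imbalance ratios
#'
#' `IR[j]` is the ratio of negative to positive samples for category `j` in
#' the training set. With Laplace smoothing (the default) both counts are
#' incremented by one, so categories without positive samples keep a finite
#' ratio; in strict mode a zero-positive category is an error.
#'
#' @param y binary `N x m` label matrix.
#' @param smoothing logical; add-one smoothing of both counts.
#' @return named length-`m` numeric vector of imbalance ratios.
#' @export
imbalance_ratios <- function(y, smoothing = TRUE) {
  y <- check_label_matrix(y)
  pos <- colSums(y)
  neg <- nrow(y) - pos
  if (smoothing) {
    ir <- (neg + 1) / (pos + 1)
  } else {
    if (any(pos == 0))
      stop("category '", colnames(y)[which(pos == 0)[1]],
           "' has no positive samples; enable smoothing or drop it")
    ir <- neg / pos
  }
  names(ir) <- colnames(y)
  ir
}

#' Blend predefined false-positive costs with imbalance ratios
#'
#' The final false-positive cost of category `i` mixes the benefit-matrix
#' derived cost `c'_i` with the inverse imbalance ratio through a modulating
#' factor `alpha` in `[0, 1]`. Under the default `"cost"` convention
#'
#'   `c_i = c'_i^alpha * IR_i^(alpha - 1)`,
#'
#' so `alpha = 1` returns the predefined costs exactly and `alpha = 0`
#' returns `1 / IR_i` exactly: the rarer a category, the cheaper a false
#' positive, hence the lower its threshold. `convention = "mirror"` swaps the
#' roles (`alpha <-> 1 - alpha`) to reproduce the opposite reading of the
#' endpoints found in parts of the literature.
#'
#' `0^0` is taken as 1 (R's convention), so a zero predefined cost at the
#' pure-imbalance endpoint still yields `1 / IR`.
#'
#' @param fp_costs_raw non-negative numeric vector `c'`.
#' @param ir positive numeric vector of imbalance ratios, same length.
#' @param alpha modulating factor in `[0, 1]`.
#' @param convention `"cost"` (default; `alpha = 1` keeps `c'`) or
#'   `"mirror"` (`alpha = 0` keeps `c'`).
#' @return numeric vector of blended costs `c`.
#' @export
blend_costs <- function(fp_costs_raw, ir, alpha = 0.3,
                        convention = c("cost", "mirror")) {
  convention <- match.arg(convention)
  if (length(alpha) != 1 || !is.finite(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must be a single value in [0, 1]")
  if (length(fp_costs_raw) != length(ir))
    stop("fp_costs_raw and ir must have the same length")
  if (any(fp_costs_raw < 0)) stop("fp costs must be non-negative")
  if (any(ir <= 0)) stop("imbalance ratios must be positive")
  a <- if (convention == "cost") alpha else 1 - alpha
  fp_costs_raw^a * ir^(a - 1)
}

#' Cost-sensitive decision thresholds
#'
#' For a binary detector with true-positive and true-negative cost 0,
#' false-negative cost 1 and false-positive cost `c`, the expected-cost
#' minimizing threshold on a calibrated posterior score is
#' `t = c / (1 + c)`, in `[0, 1)` and increasing in `c`.
#'
#' @param fp_costs_blended non-negative numeric vector of costs `c`.
#' @return numeric vector of thresholds, same names as the input.
#' @export
compute_thresholds <- function(fp_costs_blended) {
  if (any(!is.finite(fp_costs_blended)) || any(fp_costs_blended < 0))
    stop("blended costs must be finite and non-negative")
  fp_costs_blended / (1 + fp_costs_blended)
}

# Validate a binary label matrix; optionally enforce width/label order.
check_label_matrix <- function(y, m = NULL, labels = NULL) {
  y <- as.matrix(y)
  if (!is.numeric(y)) stop("label matrix must be numeric 0/1")
  if (any(y != 0 & y != 1)) stop("label matrix entries must be exactly 0 or 1")
  if (!is.null(m) && ncol(y) != m)
    stop("label matrix has ", ncol(y), " columns, expected ", m)
  if (!is.null(labels) && !is.null(colnames(y)) &&
      !identical(colnames(y), as.character(labels)))
    stop("label matrix columns are not aligned with the cost/benefit labels")
  if (is.null(colnames(y)) && !is.null(labels)) colnames(y) <- labels
  y
}
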