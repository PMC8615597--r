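#' Union-normalized weighted multi-class confusion matrix
#'
#' Generalizes the multi-class confusion matrix to multi-label predictions.
#' For a recording with annotated label set `L` and predicted set `P`, every
#' pair `(i in P, j in L)` receives weight `1 / |L U P|` (and `1` when both
#' sets are empty, a documented convention), so each recording contributes
#' total mass proportional to its share of correct and incorrect
#' assignments. Entry `A[i, j]` accumulates the weight of recordings of true
#' category `j` classified as category `i`.
#'
#' @param y binary `N x m` annotation matrix.
#' @param yhat binary `N x m` prediction matrix, same shape/labels.
#' @return `m x m` numeric matrix `A` (rows = predicted, cols = annotated).
#' @export
build_weighted_confusion <- function(y, yhat) {
  y <- check_label_matrix(y)
  yhat <- check_label_matrix(yhat, ncol(y), colnames(y))
  if (nrow(yhat) != nrow(y)) stop("y and yhat must have the same rows")
  nu <- rowSums((y + yhat) > 0)
  nu[nu == 0] <- 1
  a <- t(yhat / nu) %*% y
  dimnames(a) <- list(colnames(y), colnames(y))
  a
}

#' Normalized cost-weighted accuracy (CWAcc)
#'
#' The raw score is the benefit-weighted mass of the union-normalized
#' confusion matrix, `sum(A * B)`. It is normalized against two anchors
#' computed on the same recording set: the perfect classifier
#' (predictions identical to annotations) maps to 1 and the trivial
#' classifier that always outputs only the normal-rhythm class maps to 0:
#'
#'   `CWAcc = (s - s_normal) / (s_true - s_normal)`.
#'
#' Scores below 0 are possible (worse than always predicting normal).
#'
#' @param y binary annotation matrix.
#' @param yhat binary prediction matrix.
#' @param benefit a [benefit_matrix()] covering the label set; its
#'   `normal_label` attribute designates the normal class.
#' @param normal_label override for the normal class identifier.
#' @return scalar normalized score (1 = perfect, 0 = always-normal).
#' @export
cwacc <- function(y, yhat, benefit, normal_label = NULL) {
  benefit <- as_benefit_matrix(benefit)
  labels <- colnames(benefit)
  if (is.null(normal_label)) normal_label <- attr(benefit, "normal_label")
  if (!normal_label %in% labels) stop("normal label not in benefit matrix")
  y <- check_label_matrix(y, length(labels), labels)
  yhat <- check_label_matrix(yhat, length(labels), labels)
  b <- unclass(benefit)
  raw <- function(pred) sum(build_weighted_confusion(y, pred) * b)
  s <- raw(yhat)
  s_true <- raw(y)
  normal_only <- matrix(0, nrow(y), length(labels),
                        dimnames = dimnames(y))
  normal_only[, match(normal_label, labels)] <- 1
  s_normal <- raw(normal_only)
  if (s_true == s_normal) {
    warning("degenerate dataset: perfect and always-normal scores coincide; ",
            "returning 0")
    return(0)
  }
  (s - s_normal) / (s_true - s_normal)
}

#' Exact-match accuracy
#'
#' Fraction of recordings whose predicted label set equals the annotated set
#' exactly (every category agrees).
#'
#' @param y binary annotation matrix.
#' @param yhat binary prediction matrix of the same shape.
#' @return scalar in `[0, 1]`.
#' @export
exact_match_accuracy <- function(y, yhat) {
  y <- check_label_matrix(y)
  yhat <- check_label_matrix(yhat, ncol(y), colnames(y))
  if (nrow(yhat) != nrow(y)) stop("y and yhat must have the same rows")
  mean(rowSums(y != yhat) == 0)
}

#' Micro-averaged sensitivity and specificity
#'
#' True/false positive/negative counts are summed over all categories
#' (micro-aggregation); `Se = TP / (TP + FN)` and `Sp = TN / (TN + FP)`.
#' A zero denominator yields 0 with a warning.
#'
#' @param y binary annotation matrix.
#' @param yhat binary prediction matrix of the same shape.
#' @return named list with `se`, `sp`, `tp`, `fp`, `tn`, `fn`.
#' @export
micro_se_sp <- function(y, yhat) {
  y <- check_label_matrix(y)
  yhat <- check_label_matrix(yhat, ncol(y), colnames(y))
  if (nrow(yhat) != nrow(y)) stop("y and yhat must have the same rows")
  tp <- sum(y == 1 & yhat == 1)
  fp <- sum(y == 0 & yhat == 1)
  tn <- sum(y == 0 & yhat == 0)
  fn <- sum(y == 1 & yhat == 0)
  se <- if (tp + fn == 0) {
    warning("no positive annotations; sensitivity set to 0"); 0
  } else tp / (tp + fn)
  sp <- if (tn + fp == 0) {
    warning("no negative annotations; specificity set to 0"); 0
  } else tn / (tn + fp)
  list(se = se, sp = sp, tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Full metric report for a prediction matrix
#'
#' Bundles [cwacc()], [exact_match_accuracy()] and [micro_se_sp()] into one
#' record — the per-method row of a thresholding comparison table.
#'
#' @inheritParams cwacc
#' @return a one-row `data.frame` with columns `cwacc`, `accuracy`, `se`,
#'   `sp`, `tp`, `fp`, `tn`, `fn`.
#' @export
metric_report <- function(y, yhat, benefit, normal_label = NULL) {
  ss <- micro_se_sp(y, yhat)
  data.frame(cwacc = cwacc(y, yhat, benefit, normal_label),
             accuracy = exact_match_accuracy(y, yhat),
             se = ss$se, sp = ss$sp,
             tp = ss$tp, fp = ss$fp, tn = ss$tn, fn = ss$fn)
}
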