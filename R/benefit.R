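#' Construct a benefit matrix
#'
#' A benefit matrix `B` encodes, for an ordered set of diagnostic categories,
#' the expert-judged benefit `B[i, j]` of predicting category `i` for a
#' recording whose true category is `j`. Entries lie in `[0, 1]`, the diagonal
#' is exactly 1 (a correct prediction earns full benefit), and a high
#' off-diagonal value marks a pair of diagnoses with similar outcomes or
#' treatments. One category is designated as the normal rhythm class; it
#' anchors the normalization of [cwacc()].
#'
#' @param entries square numeric matrix of benefits in `[0, 1]` with unit
#'   diagonal. Dimnames, when present, must agree with `labels`.
#' @param labels character vector of category identifiers, one per row/column.
#'   Defaults to the column names of `entries`.
#' @param normal_label identifier of the normal-rhythm category. Defaults to
#'   `"NSR"` when that label is present, otherwise the first label.
#' @return an object of class `benefit_matrix`: the numeric matrix with
#'   `labels` as dimnames and a `normal_label` attribute.
#' @examples
#' b <- benefit_matrix(diag(3), labels = c("NSR", "AF", "PVC"))
#' attr(b, "normal_label")
#' @seealso [benefit_to_cost()], [gen_benefit_matrix()], [read_benefit_csv()]
#' @export
benefit_matrix <- function(entries, labels = colnames(entries),
                           normal_label = NULL) {
  entries <- as.matrix(entries)
  if (nrow(entries) != ncol(entries))
    stop("benefit matrix must be square, got ", nrow(entries), "x", ncol(entries))
  m <- ncol(entries)
  if (is.null(labels))
    labels <- paste0("C", seq_len(m))
  labels <- as.character(labels)
  if (length(labels) != m) stop("need exactly ", m, " labels")
  if (anyDuplicated(labels)) stop("category labels must be unique")
  bad <- which(entries < 0 | entries > 1 | !is.finite(entries), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("benefit entry out of [0,1] at (%s, %s): %g",
                 labels[bad[1, 1]], labels[bad[1, 2]],
                 entries[bad[1, 1], bad[1, 2]]))
  if (any(diag(entries) != 1))
    stop("benefit matrix diagonal must equal 1 exactly")
  if (is.null(normal_label))
    normal_label <- if ("NSR" %in% labels) "NSR" else labels[1]
  if (!normal_label %in% labels)
    stop("normal_label '", normal_label, "' is not among the category labels")
  dimnames(entries) <- list(labels, labels)
  structure(entries, normal_label = normal_label,
            class = c("benefit_matrix", "matrix", "array"))
}

#' Derive a misclassification cost matrix from a benefit matrix
#'
#' Costs are the complement of benefits: `C'[i, j] = 1 - B[i, j]`, the cost of
#' classifying a recording of true category `j` as category `i`. The diagonal
#' is exactly 0.
#'
#' @param benefit a [benefit_matrix()].
#' @return numeric `m x m` cost matrix with the same dimnames.
#' @export
benefit_to_cost <- function(benefit) {
  benefit <- as_benefit_matrix(benefit)
  cost <- 1 - unclass(benefit)
  attr(cost, "normal_label") <- NULL
  class(cost) <- c("matrix", "array")
  cost
}

as_benefit_matrix <- function(x) {
  if (inherits(x, "benefit_matrix")) return(x)
  benefit_matrix(x)
}

#' Generate a clustered synthetic benefit matrix
#'
#' Emulates the structure of an expert benefit matrix: categories fall into
#' clusters of clinically similar diagnoses; pairs within a cluster share a
#' high benefit, pairs across clusters a low one, and the diagonal is 1.
#' Cluster membership is a seeded random assignment (each cluster is
#' guaranteed at least one member when `m >= n_clusters`).
#'
#' @param m number of categories.
#' @param n_clusters number of similarity clusters.
#' @param within off-diagonal benefit for same-cluster pairs.
#' @param between benefit for cross-cluster pairs; `0 <= between < within < 1`.
#' @param labels optional category identifiers; default is ECG-style names for
#'   `m <= 12`, generic `LBL01, ...` beyond.
#' @param seed integer seed for the cluster assignment.
#' @return a [benefit_matrix()] with a `clusters` attribute.
#' @export
gen_benefit_matrix <- function(m, n_clusters = 3, within = 0.5, between = 0.1,
                               labels = NULL, seed = 1L) {
  if (!(between >= 0 && between < within && within < 1))
    stop("need 0 <= between < within < 1")
  if (is.null(labels)) labels <- default_labels(m)
  cl <- local({
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_seed(old))
    set.seed(seed)
    base <- rep_len(seq_len(n_clusters), m)
    sample(base, m, replace = FALSE)
  })
  same <- outer(cl, cl, "==")
  entries <- ifelse(same, within, between)
  diag(entries) <- 1
  out <- benefit_matrix(entries, labels = labels)
  attr(out, "clusters") <- cl
  out
}

#' Perturb a benefit matrix (simulated cost-definition change)
#'
#' Randomly selects a fraction of the categories and rescales every benefit
#' entry in their rows and columns by `factor`, clipping to `[0, 1]`; the
#' diagonal is left untouched. `factor = 1.5` simulates the "benefits
#' increased by 50%" scenario, `factor = 0.7` the "decreased to 70%" one.
#'
#' @param b a [benefit_matrix()].
#' @param fraction fraction of categories to select (default 0.5).
#' @param factor multiplicative change applied to the selected rows/columns.
#' @param seed integer seed driving the category selection.
#' @return a perturbed [benefit_matrix()] with a `selected` attribute naming
#'   the rescaled categories.
#' @export
perturb_benefit <- function(b, fraction = 0.5, factor = 1.5, seed = 1L) {
  b <- as_benefit_matrix(b)
  if (factor <= 0) stop("factor must be positive")
  labels <- colnames(b)
  m <- length(labels)
  k <- max(1L, round(fraction * m))
  sel <- local({
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_seed(old))
    set.seed(seed)
    sort(sample.int(m, k))
  })
  entries <- unclass(b)
  touched <- matrix(FALSE, m, m)
  touched[sel, ] <- TRUE
  touched[, sel] <- TRUE
  d <- diag(entries)
  entries[touched] <- pmin(1, pmax(0, entries[touched] * factor))
  diag(entries) <- d
  out <- benefit_matrix(entries, labels = labels,
                        normal_label = attr(b, "normal_label"))
  attr(out, "selected") <- labels[sel]
  out
}

default_labels <- function(m) {
  pool <- c("NSR", "AF", "AFL", "STach", "SB", "RBBB", "LBBB", "PAC", "PVC",
            "TAb", "TInv", "IAVB")
  if (m <= length(pool)) pool[seq_len(m)]
  else c(pool, sprintf("LBL%02d", seq_len(m - length(pool))))
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
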