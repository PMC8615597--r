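#' Seeded k-fold split
#'
#' Indices are shuffled once and split into `k` validation folds whose sizes
#' differ by at most one; the folds partition the index set exactly.
#'
#' @param n number of samples (or a label matrix whose rows are counted).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return list of `k` lists with integer vectors `train` and `val`.
#' @export
kfold_split <- function(n, k = 5, seed = 1L) {
  if (is.matrix(n)) n <- nrow(n)
  if (k < 2) stop("k must be at least 2")
  if (n < k) stop("need at least k samples")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old))
  set.seed(seed)
  idx <- sample.int(n)
  fold_id <- rep_len(seq_len(k), n)
  lapply(seq_len(k), function(f) {
    val <- sort(idx[fold_id == f])
    list(train = setdiff(seq_len(n), val), val = val)
  })
}

#' Sweep the modulating factor and score each setting
#'
#' For every `alpha` on the grid, CICST thresholds are fitted on the
#' training labels, applied to the validation scores, and scored with the
#' normalized cost-weighted accuracy. On imbalanced data with a calibrated
#' but imperfect classifier the resulting curve typically rises from the
#' pure-imbalance endpoint, peaks at an interior `alpha`, and falls towards
#' the pure-predefined-cost endpoint.
#'
#' @param scores_val validation score matrix.
#' @param y_train training label matrix (threshold fitting).
#' @param y_val validation label matrix (scoring).
#' @param benefit a [benefit_matrix()].
#' @param alpha_grid numeric vector of `alpha` values in `[0, 1]`.
#' @param convention passed to [cicst()].
#' @return `data.frame` with columns `alpha` and `cwacc`.
#' @export
alpha_sweep <- function(scores_val, y_train, y_val, benefit,
                        alpha_grid = seq(0, 1, by = 0.1),
                        convention = "cost") {
  rows <- lapply(alpha_grid, function(a) {
    fit <- cicst(benefit, y_train, alpha = a, convention = convention)
    yhat <- predict(fit, scores_val)
    data.frame(alpha = a, cwacc = cwacc(y_val, yhat, benefit))
  })
  do.call(rbind, rows)
}

#' Compare thresholding strategies on one validation split
#'
#' Produces one [metric_report()] row per method. `cicst` fits thresholds on
#' the training labels; `rcut` uses the (rounded) training label
#' cardinality unless `t_count` is given; `pcut` uses training prevalences;
#' `fixed` is evaluated once per entry of `fixed_values`.
#'
#' @param scores_val validation score matrix.
#' @param y_train,y_val training and validation label matrices.
#' @param benefit a [benefit_matrix()].
#' @param methods subset of `c("cicst", "rcut", "pcut", "fixed")`.
#' @param alpha CICST modulating factor.
#' @param t_count Rcut label count; default `max(1, round(mean labels per
#'   training sample))`.
#' @param fixed_values fixed thresholds to evaluate (default 0.5 and 0.2).
#' @return `data.frame` of metric rows, one per method, with a `method`
#'   column such as `"fixed(0.5)"`.
#' @export
compare_thresholding <- function(scores_val, y_train, y_val, benefit,
                                 methods = c("cicst", "rcut", "pcut", "fixed"),
                                 alpha = 0.3, t_count = NULL,
                                 fixed_values = c(0.5, 0.2)) {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  if ("cicst" %in% methods) {
    fit <- cicst(benefit, y_train, alpha = alpha)
    rows$cicst <- cbind(method = "cicst",
                        metric_report(y_val, predict(fit, scores_val), benefit))
  }
  if ("rcut" %in% methods) {
    if (is.null(t_count)) t_count <- max(1, round(mean(rowSums(y_train))))
    rows$rcut <- cbind(method = sprintf("rcut(%d)", t_count),
                       metric_report(y_val, rcut(scores_val, t_count), benefit))
  }
  if ("pcut" %in% methods) {
    rows$pcut <- cbind(method = "pcut",
                       metric_report(y_val, pcut(scores_val, colMeans(y_train)),
                                     benefit))
  }
  if ("fixed" %in% methods) {
    for (v in fixed_values) {
      rows[[sprintf("fixed%g", v)]] <-
        cbind(method = sprintf("fixed(%g)", v),
              metric_report(y_val, fixed_threshold(scores_val, v), benefit))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Threshold adaptation under simulated cost-definition changes
#'
#' Repeatedly perturbs the benefit matrix ([perturb_benefit()]) and scores a
#' fixed set of validation predictions twice under the *perturbed* benefits:
#' once with the stale thresholds fitted to the original benefit matrix, and
#' once with thresholds updated to the perturbed one. Because thresholds are
#' post-processing, updating costs nothing but recomputing `t = c/(1+c)`;
#' the updated scores should dominate the stale ones.
#'
#' @param scores_val validation score matrix.
#' @param y_train,y_val training and validation label matrices.
#' @param benefit the original [benefit_matrix()].
#' @param n_perturbations number of simulated cost changes (default 100).
#' @param fraction,factor passed to [perturb_benefit()].
#' @param alpha CICST modulating factor.
#' @param seed base seed; perturbation `i` uses `seed + i`.
#' @return list with `table` (`data.frame`: perturbation id,
#'   `score_stale`, `score_updated`) and `fraction_improved`, the share of
#'   pairs with `score_updated >= score_stale`.
#' @export
cost_change_adaptation <- function(scores_val, y_train, y_val, benefit,
                                   n_perturbations = 100, fraction = 0.5,
                                   factor = 1.5, alpha = 0.3, seed = 1L) {
  benefit <- as_benefit_matrix(benefit)
  fit0 <- cicst(benefit, y_train, alpha = alpha)
  yhat_stale <- predict(fit0, scores_val)
  rows <- vector("list", n_perturbations)
  for (i in seq_len(n_perturbations)) {
    bp <- perturb_benefit(benefit, fraction = fraction, factor = factor,
                          seed = seed + i)
    fit_new <- update(fit0, benefit = bp)
    yhat_new <- predict(fit_new, scores_val)
    rows[[i]] <- data.frame(perturbation = i,
                            score_stale = cwacc(y_val, yhat_stale, bp),
                            score_updated = cwacc(y_val, yhat_new, bp))
  }
  tab <- do.call(rbind, rows)
  list(table = tab,
       fraction_improved = mean(tab$score_updated >= tab$score_stale))
}

#' One seeded synthetic benchmark scenario
#'
#' Bundles the generators into the study conditions used throughout the
#' package's experiments: `m` categories with imbalance ratios log-spaced
#' over `ir_range`, a clustered benefit matrix, a calibrated (resample-mode)
#' score matrix, and a train/validation split. The defaults emulate an
#' imbalanced multi-label ECG corpus at desk scale with a moderately
#' informative classifier.
#'
#' @param n_train,n_val sample sizes.
#' @param m number of categories.
#' @param ir_range range of imbalance ratios, log-spaced over categories
#'   (default 3 to 300; the normal class keeps the lowest ratio).
#' @param sharpness score informativeness, see [gen_calibrated_scores()].
#' @param n_clusters,within,between benefit-matrix structure, see
#'   [gen_benefit_matrix()].
#' @param seed integer seed.
#' @return list with `benefit`, `y_train`, `y_val`, `scores_train`,
#'   `scores_val`, `prevalence`.
#' @export
synthetic_scenario <- function(n_train = 16000, n_val = 4000, m = 10,
                               ir_range = c(3, 300), sharpness = 1,
                               n_clusters = 3, within = 0.5, between = 0.1,
                               seed = 1L) {
  ir <- exp(seq(log(ir_range[1]), log(ir_range[2]), length.out = m))
  prevalence <- 1 / (1 + ir)
  benefit <- gen_benefit_matrix(m, n_clusters = n_clusters, within = within,
                                between = between, seed = seed)
  n <- n_train + n_val
  y0 <- gen_label_matrix(n, prevalence, labels = colnames(benefit),
                         seed = seed + 1L)
  cs <- gen_calibrated_scores(y0, sharpness = sharpness, mode = "resample",
                              seed = seed + 2L, prevalence = prevalence)
  tr <- seq_len(n_train)
  list(benefit = benefit,
       y_train = cs$labels[tr, , drop = FALSE],
       y_val = cs$labels[-tr, , drop = FALSE],
       scores_train = cs$scores[tr, , drop = FALSE],
       scores_val = cs$scores[-tr, , drop = FALSE],
       prevalence = prevalence)
}
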