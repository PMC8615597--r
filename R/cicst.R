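#' Fit CICST decision thresholds
#'
#' Category imbalance and cost-sensitive thresholding (CICST) computes one
#' decision threshold per diagnostic category for a binary-relevance
#' multi-label classifier. The fit composes five steps:
#' cost matrix `C' = 1 - B` from the expert benefit matrix, representative
#' false-positive costs `c'` averaged over the training label distribution
#' ([compute_false_positive_costs()]), imbalance ratios `IR`
#' ([imbalance_ratios()]), blended costs `c = c'^alpha * IR^(alpha - 1)`
#' ([blend_costs()]), and thresholds `t = c / (1 + c)`
#' ([compute_thresholds()]).
#'
#' Because thresholds depend on the benefit matrix only through fast
#' post-processing, a fitted object can be re-thresholded for a new cost
#' definition with [update()] — no classifier retraining.
#'
#' @param benefit a [benefit_matrix()] (or plain matrix coercible to one).
#' @param y binary `N x m` training label matrix, columns in benefit order.
#' @param alpha modulating factor in `[0, 1]` balancing predefined costs
#'   (`alpha = 1`) against imbalance-derived costs (`alpha = 0`);
#'   default 0.3.
#' @param convention exponent convention passed to [blend_costs()].
#' @param smoothing Laplace-smooth the imbalance ratios (default `TRUE`).
#' @return an object of class `"cicst"`: a list with `labels`,
#'   `normal_label`, `alpha`, `convention`, `cost_matrix`, `fp_costs_raw`,
#'   `imbalance_ratios`, `fp_costs_blended`, `thresholds`, `trace`
#'   (Algorithm intermediates), `prevalence`, and the training label matrix
#'   `y` (kept so that [update()] can re-derive `c'` under a new benefit
#'   matrix).
#' @examples
#' b <- gen_benefit_matrix(5, seed = 1)
#' y <- gen_label_matrix(200, prevalence = c(.5, .2, .1, .05, .3), seed = 2)
#' fit <- cicst(b, y, alpha = 0.3)
#' coef(fit)                      # per-category thresholds
#' s <- gen_calibrated_scores(y, seed = 3)
#' yhat <- predict(fit, s$scores)
#' @seealso [apply_thresholds()], [cwacc()], [rcut()], [pcut()]
#' @export
cicst <- function(benefit, y, alpha = 0.3, convention = c("cost", "mirror"),
                  smoothing = TRUE) {
  convention <- match.arg(convention)
  benefit <- as_benefit_matrix(benefit)
  labels <- colnames(benefit)
  y <- check_label_matrix(y, length(labels), labels)
  cost <- benefit_to_cost(benefit)
  fp <- compute_false_positive_costs(cost, y)
  ir <- imbalance_ratios(y, smoothing = smoothing)
  c_blend <- blend_costs(fp$fp_costs_raw, ir, alpha, convention)
  thr <- compute_thresholds(c_blend)
  structure(list(labels = labels,
                 normal_label = attr(benefit, "normal_label"),
                 alpha = alpha,
                 convention = convention,
                 smoothing = smoothing,
                 benefit = benefit,
                 cost_matrix = cost,
                 fp_costs_raw = fp$fp_costs_raw,
                 imbalance_ratios = ir,
                 fp_costs_blended = c_blend,
                 thresholds = thr,
                 trace = fp$trace,
                 prevalence = colMeans(y),
                 y = y),
            class = "cicst")
}

#' @export
print.cicst <- function(x, ...) {
  cat("CICST thresholds (", length(x$labels), " categories, alpha = ",
      format(x$alpha), ", convention = ", x$convention, ")\n", sep = "")
  df <- data.frame(fp_cost = x$fp_costs_raw, IR = x$imbalance_ratios,
                   blended = x$fp_costs_blended, threshold = x$thresholds,
                   row.names = x$labels)
  print(round(df, 4), ...)
  invisible(x)
}

#' @export
summary.cicst <- function(object, ...) {
  out <- list(m = length(object$labels),
              n = nrow(object$y),
              alpha = object$alpha,
              convention = object$convention,
              normal_label = object$normal_label,
              threshold_range = range(object$thresholds),
              ir_range = range(object$imbalance_ratios),
              table = data.frame(label = object$labels,
                                 prevalence = unname(object$prevalence),
                                 fp_cost = unname(object$fp_costs_raw),
                                 IR = unname(object$imbalance_ratios),
                                 blended = unname(object$fp_costs_blended),
                                 threshold = unname(object$thresholds)))
  class(out) <- "summary.cicst"
  out
}

#' @export
print.summary.cicst <- function(x, ...) {
  cat("CICST fit: m =", x$m, "categories, N =", x$n, "training recordings\n")
  cat("alpha =", format(x$alpha), "(", x$convention, "convention ), normal class:",
      x$normal_label, "\n")
  cat(sprintf("thresholds in [%.4f, %.4f], imbalance ratios in [%.1f, %.1f]\n",
              x$threshold_range[1], x$threshold_range[2],
              x$ir_range[1], x$ir_range[2]))
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Extract CICST thresholds
#'
#' @param object a fitted [cicst()] object.
#' @param ... unused.
#' @return named numeric vector of per-category thresholds.
#' @export
coef.cicst <- function(object, ...) object$thresholds

#' Threshold a score matrix with a fitted CICST object
#'
#' @param object a fitted [cicst()] object.
#' @param scores `N x m` matrix of classifier scores in `[0, 1]`, columns
#'   aligned with the fitted label order.
#' @param ... unused.
#' @return binary prediction matrix (`score > threshold`, strict).
#' @export
predict.cicst <- function(object, scores, ...) {
  apply_thresholds(scores, object$thresholds)
}

#' Re-threshold a CICST fit under a new cost definition
#'
#' Recomputes `c'`, the blended costs and the thresholds from a new benefit
#' matrix, reusing the stored training label matrix (so `IR` is unchanged).
#' This is the "adapt without retraining" property of threshold-based
#' cost-sensitivity.
#'
#' @param object a fitted [cicst()] object.
#' @param benefit the new [benefit_matrix()].
#' @param alpha optionally a new modulating factor; defaults to the fitted one.
#' @param ... unused.
#' @return a new `"cicst"` object.
#' @export
update.cicst <- function(object, benefit, alpha = object$alpha, ...) {
  cicst(benefit, object$y, alpha = alpha, convention = object$convention,
        smoothing = object$smoothing)
}

#' Plot CICST thresholds against imbalance ratios
#'
#' @param x a fitted [cicst()] object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cicst <- function(x, ...) {
  graphics::plot(x$imbalance_ratios, x$thresholds, log = "x",
                 xlab = "imbalance ratio (negatives / positives)",
                 ylab = "decision threshold",
                 main = sprintf("CICST thresholds (alpha = %s)",
                                format(x$alpha)), ...)
  graphics::text(x$imbalance_ratios, x$thresholds, x$labels,
                 pos = 3, cex = 0.7)
  invisible(x)
}

#' Serialize a CICST fit to JSON
#'
#' Writes labels, `alpha`, `c'`, `IR`, blended `c` and thresholds `t` as a
#' JSON object (the cost-profile interchange format).
#'
#' @param object a fitted [cicst()] object.
#' @param path file to write; when `NULL` the JSON string is returned.
#' @return invisibly, the JSON string.
#' @export
write_cost_profile <- function(object, path = NULL) {
  stopifnot(inherits(object, "cicst"))
  payload <- list(labels = object$labels,
                  normal_label = object$normal_label,
                  alpha = object$alpha,
                  convention = object$convention,
                  fp_costs_raw = unname(object$fp_costs_raw),
                  imbalance_ratios = unname(object$imbalance_ratios),
                  fp_costs_blended = unname(object$fp_costs_blended),
                  thresholds = unname(object$thresholds))
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) writeLines(json, path)
  invisible(json)
}

#' Read a serialized cost profile
#'
#' @param path JSON file written by [write_cost_profile()].
#' @return a named list with the profile fields (vectors named by label).
#' @export
read_cost_profile <- function(path) {
  p <- jsonlite::fromJSON(path)
  for (f in c("fp_costs_raw", "imbalance_ratios", "fp_costs_blended",
              "thresholds"))
    names(p[[f]]) <- p$labels
  p
}
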