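test_that("benefit-to-cost conversion is the complement and validates input", {
  b <- benefit_matrix(diag(3), labels = c("A", "B", "C"))
  cp <- benefit_to_cost(b)
  expect_equal(unname(diag(cp)), rep(0, 3))
  expect_equal(unname(cp[1, 2]), 1)

  e <- diag(3); e[1, 2] <- 0.5
  cp2 <- benefit_to_cost(benefit_matrix(e, labels = c("A", "B", "C")))
  expect_equal(unname(cp2[1, 2]), 0.5)

  all_ones <- matrix(1, 3, 3)
  expect_true(all(benefit_to_cost(benefit_matrix(all_ones)) == 0))

  e_bad <- diag(3); e_bad[2, 1] <- 1.4
  expect_error(benefit_matrix(e_bad, labels = c("A", "B", "C")), "out of \\[0,1\\]")
  e_diag <- diag(3) * 0.9
  expect_error(benefit_matrix(e_diag), "diagonal")
})

test_that("false-positive cost derivation matches the hand-worked example", {
  cp <- matrix(c(0, .5, .5, 0), 2, 2)
  y <- rbind(c(1, 0), c(0, 1))
  res <- compute_false_positive_costs(cp, y)
  expect_equal(unname(res$fp_costs_raw), c(0.5, 0.5))
  # trace invariants
  expect_equal(rowSums(res$trace$normalized_labels), c(1, 1))
  expect_true(all(res$trace$masked_costs[y == 1] == 0))
})

test_that("zero cost matrices propagate to zero fp costs", {
  y <- rand_label_matrix(20, 4)
  res <- compute_false_positive_costs(matrix(0, 4, 4), y)
  expect_true(all(res$fp_costs_raw == 0))
})

test_that("vectorized fp-cost derivation equals the triple-loop oracle exactly", {
  set.seed(11)
  for (r in 1:40) {
    n <- sample(2:50, 1); m <- sample(2:10, 1)
    cp <- matrix(runif(m * m), m, m); diag(cp) <- 0
    y <- rand_label_matrix(n, m)
    got <- compute_false_positive_costs(cp, y)$fp_costs_raw
    expect_identical(unname(got), fp_costs_loop_oracle(cp, y))
  }
})

test_that("label-free samples contribute zero cost rows", {
  cp <- matrix(runif(9), 3, 3); diag(cp) <- 0
  y <- rbind(c(0, 0, 0), c(1, 0, 0))
  res <- compute_false_positive_costs(cp, y)
  expect_equal(unname(res$trace$per_sample_label_count), c(1, 1))
  expect_true(all(res$trace$per_sample_costs[1, ] == 0))
})

test_that("a category with no negative samples gets cost 0 with a warning", {
  cp <- matrix(0.5, 2, 2); diag(cp) <- 0
  y <- cbind(A = c(1, 1), B = c(0, 1))
  expect_warning(res <- compute_false_positive_costs(cp, y), "no negative")
  expect_equal(unname(res$fp_costs_raw[1]), 0)
})

test_that("fp costs are linear in the cost matrix", {
  set.seed(5)
  cp <- matrix(runif(25), 5, 5); diag(cp) <- 0
  y <- rand_label_matrix(30, 5)
  c1 <- compute_false_positive_costs(cp, y)$fp_costs_raw
  c3 <- compute_false_positive_costs(3 * cp, y)$fp_costs_raw
  expect_equal(c3, 3 * c1)
})

test_that("imbalance ratios follow the counts, with Laplace smoothing", {
  y <- cbind(a = c(rep(0, 9), 1), b = c(rep(1, 5), rep(0, 5)))
  expect_equal(unname(imbalance_ratios(y, smoothing = FALSE)), c(9, 1))
  y0 <- cbind(a = rep(0, 10))
  expect_equal(unname(imbalance_ratios(y0, smoothing = TRUE)), 11)
  expect_error(imbalance_ratios(y0, smoothing = FALSE), "no positive")
})

test_that("cost blending hits both endpoints exactly in both conventions", {
  cp <- c(0.2, 0.7, 0); ir <- c(9, 3, 50)
  # default convention: alpha = 1 -> predefined costs, alpha = 0 -> 1/IR
  expect_identical(blend_costs(cp, ir, alpha = 1), cp)
  expect_identical(blend_costs(cp, ir, alpha = 0), 1 / ir)
  # mirrored reading swaps the endpoints
  expect_identical(blend_costs(cp, ir, alpha = 0, convention = "mirror"), cp)
  expect_identical(blend_costs(cp, ir, alpha = 1, convention = "mirror"), 1 / ir)
  # interior value: direct evaluation of c'^a * IR^(a-1)
  expect_equal(blend_costs(0.5, 9, alpha = 0.5), sqrt(0.5 / 9),
               tolerance = 1e-12)
  expect_error(blend_costs(c(.1, .2), c(1, 2), alpha = 1.2), "alpha")
})

test_that("thresholds are c/(1+c), in [0,1), monotone", {
  expect_equal(compute_thresholds(1), 0.5)
  expect_equal(compute_thresholds(0), 0)
  expect_equal(compute_thresholds(sqrt(0.5 / 9)),
               sqrt(0.5 / 9) / (1 + sqrt(0.5 / 9)))
  cs <- sort(runif(20, 0, 10))
  ts <- compute_thresholds(cs)
  expect_true(all(ts >= 0 & ts < 1))
  expect_true(all(diff(ts) >= 0))
  expect_error(compute_thresholds(-0.1), "non-negative")
})

test_that("the cicst fit equals the step-by-step composition", {
  set.seed(21)
  b <- tiny_benefit(5)
  y <- rand_label_matrix(80, 5)
  colnames(y) <- colnames(b)
  fit <- cicst(b, y, alpha = 0.4)
  cp <- benefit_to_cost(b)
  raw <- compute_false_positive_costs(cp, y)$fp_costs_raw
  ir <- imbalance_ratios(y)
  cb <- blend_costs(raw, ir, 0.4)
  expect_identical(fit$fp_costs_raw, raw)
  expect_identical(fit$imbalance_ratios, ir)
  expect_identical(fit$fp_costs_blended, cb)
  expect_identical(fit$thresholds, compute_thresholds(cb))
})

test_that("all-ones benefit yields zero thresholds via the fit", {
  y <- rand_label_matrix(40, 3)
  b <- benefit_matrix(matrix(1, 3, 3), labels = colnames(y))
  fit <- cicst(b, y, alpha = 1)
  expect_true(all(fit$thresholds == 0))
})

test_that("thresholds are equivariant under joint label permutation", {
  set.seed(31)
  b <- tiny_benefit(6)
  y <- rand_label_matrix(60, 6)
  colnames(y) <- colnames(b)
  fit <- cicst(b, y, alpha = 0.3)
  perm <- sample(6)
  bp <- benefit_matrix(unclass(b)[perm, perm],
                       labels = colnames(b)[perm],
                       normal_label = attr(b, "normal_label"))
  fitp <- cicst(bp, y[, perm], alpha = 0.3)
  expect_equal(fitp$thresholds, fit$thresholds[perm])
})

test_that("cicst methods expose the fit: coef, predict, update, summary", {
  set.seed(41)
  b <- tiny_benefit(4)
  y <- rand_label_matrix(50, 4)
  colnames(y) <- colnames(b)
  fit <- cicst(b, y)
  expect_identical(coef(fit), fit$thresholds)
  s <- matrix(runif(20), 5, 4, dimnames = list(NULL, colnames(b)))
  expect_identical(predict(fit, s), apply_thresholds(s, fit$thresholds))
  b2 <- perturb_benefit(b, factor = 1.3, seed = 2)
  fit2 <- update(fit, benefit = b2)
  expect_identical(fit2$imbalance_ratios, fit$imbalance_ratios)
  expect_false(identical(fit2$thresholds, fit$thresholds))
  expect_output(print(summary(fit)), "CICST fit")
})

test_that("cost profiles roundtrip through JSON", {
  b <- tiny_benefit(3)
  y <- rand_label_matrix(30, 3)
  colnames(y) <- colnames(b)
  fit <- cicst(b, y)
  path <- withr::local_tempfile(fileext = ".json")
  write_cost_profile(fit, path)
  p <- read_cost_profile(path)
  expect_equal(p$thresholds, fit$thresholds)
  expect_equal(p$alpha, fit$alpha)
  expect_identical(p$labels, fit$labels)
})
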