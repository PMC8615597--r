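test_that("label generation hits target prevalences within binomial error", {
  y <- gen_label_matrix(10000, prevalence = c(0.5, 0.05, 0.005), seed = 3)
  p_hat <- colMeans(y)
  se <- sqrt(c(0.5, 0.05, 0.005) * c(0.5, 0.95, 0.995) / 10000)
  expect_true(all(abs(p_hat - c(0.5, 0.05, 0.005)) < 3 * se))
})

test_that("degenerate and seeded label generation behave as documented", {
  expect_true(all(gen_label_matrix(50, prevalence = c(1, 1), seed = 1) == 1))
  a <- gen_label_matrix(100, prevalence = c(0.3, 0.1), seed = 9)
  b <- gen_label_matrix(100, prevalence = c(0.3, 0.1), seed = 9)
  expect_identical(a, b)
  expect_error(gen_label_matrix(10, prevalence = c(0.5, 0)), "\\(0, 1\\]")
})

test_that("co-occurrence multipliers tilt pair frequencies upward", {
  co <- matrix(1, 2, 2); co[1, 2] <- 20
  y <- gen_label_matrix(20000, prevalence = c(0.3, 0.1),
                        co_occurrence = co, seed = 5)
  p_given_1 <- mean(y[y[, 1] == 1, 2])
  p_given_0 <- mean(y[y[, 1] == 0, 2])
  expect_gt(p_given_1, p_given_0 * 2)
})

test_that("resample-mode scores are calibrated within binomial error", {
  y0 <- gen_label_matrix(50000, prevalence = c(0.5, 0.1), seed = 6)
  cs <- gen_calibrated_scores(y0, sharpness = 1, mode = "resample", seed = 7)
  for (j in 1:2) {
    bins <- cut(cs$scores[, j], breaks = seq(0, 1, 0.1), include.lowest = TRUE)
    for (b in levels(bins)) {
      idx <- bins == b
      if (sum(idx) < 200) next
      p_obs <- mean(cs$labels[idx, j])
      p_exp <- mean(cs$scores[idx, j])
      se <- sqrt(p_exp * (1 - p_exp) / sum(idx))
      expect_lt(abs(p_obs - p_exp), 4 * se + 1e-3)
    }
  }
})

test_that("sharpness controls score separation and seeds reproduce", {
  y0 <- gen_label_matrix(5000, prevalence = c(0.3), seed = 8)
  hard <- gen_calibrated_scores(y0, sharpness = 1000, seed = 9)
  expect_gt(mean(hard$scores < 0.01 | hard$scores > 0.99), 0.95)
  a <- gen_calibrated_scores(y0, sharpness = 2, seed = 10)
  b <- gen_calibrated_scores(y0, sharpness = 2, seed = 10)
  expect_identical(a, b)
})

test_that("fixed-label mode keeps the input labels and separates classes", {
  y0 <- gen_label_matrix(2000, prevalence = c(0.2), seed = 11)
  cs <- gen_calibrated_scores(y0, sharpness = 1, mode = "fixed-label",
                              seed = 12)
  expect_identical(cs$labels, y0)
  expect_gt(mean(cs$scores[y0 == 1]), mean(cs$scores[y0 == 0]))
})

test_that("generated benefit matrices satisfy their invariants", {
  for (m in c(3, 12, 30)) {
    b <- gen_benefit_matrix(m, n_clusters = min(4, m), within = 0.6,
                            between = 0.15, seed = m)
    expect_true(all(diag(b) == 1))
    expect_true(all(b >= 0 & b <= 1))
    expect_equal(unclass(b), t(unclass(b)), ignore_attr = TRUE)
    off <- unclass(b)[upper.tri(b)]
    expect_true(all(off %in% c(0.6, 0.15)))
  }
  b1 <- gen_benefit_matrix(6, n_clusters = 1, within = 0.4, between = 0.1)
  expect_true(all(unclass(b1)[upper.tri(b1)] == 0.4))
  bm <- gen_benefit_matrix(5, n_clusters = 5, within = 0.4, between = 0.1)
  expect_true(all(unclass(bm)[upper.tri(bm)] == 0.1))
})

test_that("benefit perturbation: identity at factor 1, diagonal fixed, clipped", {
  b <- gen_benefit_matrix(8, seed = 2)
  expect_equal(unclass(perturb_benefit(b, factor = 1, seed = 3)),
               unclass(b), ignore_attr = TRUE)
  up <- perturb_benefit(b, fraction = 0.5, factor = 1.5, seed = 3)
  expect_true(all(diag(up) == 1))
  expect_true(all(up >= 0 & up <= 1))
  expect_equal(length(attr(up, "selected")), 4)
  sel <- attr(up, "selected")
  unsel <- setdiff(colnames(b), sel)
  expect_equal(unclass(up)[unsel, unsel], unclass(b)[unsel, unsel])
  down <- perturb_benefit(b, fraction = 0.5, factor = 0.7, seed = 3)
  expect_true(all(unclass(down) <= unclass(b) + 1e-12))
  # seeded selection is reproducible
  expect_identical(attr(perturb_benefit(b, seed = 3), "selected"), sel)
})

test_that("ecg generation responds to rhythm labels and seeds", {
  fast <- gen_ecg("STach", duration_s = 20, seed = 1)
  slow <- gen_ecg("SB", duration_s = 20, seed = 1)
  # beat rate via autocorrelation-free peak counting on lead 1
  count_beats <- function(rec) {
    x <- rec$signal[, 1]
    th <- max(x) * 0.5
    sum(diff(x > th) == 1)
  }
  expect_gt(count_beats(fast) * 3, 100)   # mean rate above 100 bpm
  expect_lt(count_beats(slow) * 3, 60)    # clearly bradycardic
  expect_identical(gen_ecg("AF", seed = 5)$signal,
                   gen_ecg("AF", seed = 5)$signal)
  expect_error(gen_ecg("XXX"), "unsupported")
})

test_that("a clean normal waveform is periodic at the programmed rate", {
  rec <- gen_ecg("NSR", duration_s = 20, noise_sd = 0, drift_amp = 0,
                 seed = 13)
  x <- rec$signal[, 1]
  th <- max(x) * 0.6
  peaks <- which(diff(x > th) == 1)
  rr <- diff(peaks) / 250
  expect_lt(abs(mean(rr) - 60 / 75), 0.06)
  expect_lt(sd(rr) / mean(rr), 0.1)
})

test_that("AF waveforms are irregular and P-wave free relative to NSR", {
  nsr <- gen_ecg("NSR", duration_s = 20, noise_sd = 0, drift_amp = 0, seed = 14)
  af <- gen_ecg("AF", duration_s = 20, noise_sd = 0, drift_amp = 0, seed = 14)
  rr_cv <- function(rec) {
    x <- rec$signal[, 1]
    peaks <- which(diff(x > max(x) * 0.6) == 1)
    rr <- diff(peaks) / 250
    sd(rr) / mean(rr)
  }
  expect_gt(rr_cv(af), rr_cv(nsr) * 2)
})

test_that("synthetic_scenario assembles consistent aligned pieces", {
  sc <- synthetic_scenario(n_train = 600, n_val = 200, m = 6, seed = 3)
  expect_equal(dim(sc$y_train), c(600, 6))
  expect_equal(dim(sc$scores_val), c(200, 6))
  expect_identical(colnames(sc$y_train), colnames(sc$benefit))
  expect_true(all(sc$scores_train >= 0 & sc$scores_train <= 1))
})
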