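# Independent brute-force oracles used to cross-check the vectorized
# implementations. These deliberately use explicit elementwise loops.

# Algorithm-style false-positive costs: elementwise triple loop, accumulating
# the matrix product over the true-label index in fixed order 1..m (the same
# mathematically-defined order the package uses, so equality is exact).
fp_costs_loop_oracle <- function(cost, y) {
  n <- nrow(y); m <- ncol(y)
  yn <- matrix(0, n, m)
  for (i in seq_len(n)) {
    L <- max(sum(y[i, ]), 1)
    for (j in seq_len(m)) yn[i, j] <- y[i, j] / L
  }
  scp <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- 0
    for (k in seq_len(m)) s <- s + yn[i, k] * cost[k, j]
    scp[i, j] <- s
  }
  scpp <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m))
    scpp[i, j] <- scp[i, j] * (1 - y[i, j])
  cp <- numeric(m)
  for (j in seq_len(m)) {
    neg <- sum(1 - y[, j])
    cp[j] <- if (neg == 0) 0 else sum(scpp[, j]) / neg
  }
  cp
}

# elementwise thresholding oracle (strict >)
threshold_loop_oracle <- function(scores, thresholds) {
  out <- matrix(0, nrow(scores), ncol(scores))
  for (i in seq_len(nrow(scores))) for (j in seq_len(ncol(scores)))
    out[i, j] <- as.numeric(scores[i, j] > thresholds[j])
  dimnames(out) <- dimnames(scores)
  out
}

# stable sort-then-take oracle for rcut
rcut_loop_oracle <- function(scores, t_count) {
  out <- matrix(0, nrow(scores), ncol(scores))
  for (i in seq_len(nrow(scores))) {
    s <- scores[i, ]
    picked <- integer(0)
    for (r in seq_len(t_count)) {
      cand <- setdiff(seq_along(s), picked)
      best <- cand[which.max(s[cand])]   # which.max ties -> lowest index
      picked <- c(picked, best)
    }
    out[i, picked] <- 1
  }
  dimnames(out) <- dimnames(scores)
  out
}

# per-recording weighted confusion oracle (explicit pair enumeration)
confusion_loop_oracle <- function(y, yhat) {
  m <- ncol(y)
  a <- matrix(0, m, m, dimnames = list(colnames(y), colnames(y)))
  for (r in seq_len(nrow(y))) {
    L <- which(y[r, ] == 1)
    P <- which(yhat[r, ] == 1)
    nu <- length(union(L, P))
    if (nu == 0) nu <- 1
    for (i in P) for (j in L) a[i, j] <- a[i, j] + 1 / nu
  }
  a
}

# small random binary label matrix guaranteeing no degenerate all-one column
rand_label_matrix <- function(n, m, p = 0.3) {
  y <- matrix(rbinom(n * m, 1, p), n, m,
              dimnames = list(NULL, paste0("C", seq_len(m))))
  full <- colSums(y) == n
  if (any(full)) y[1, full] <- 0
  y
}

tiny_benefit <- function(m = 4, seed = 42) {
  gen_benefit_matrix(m, n_clusters = 2, within = 0.6, between = 0.2,
                     seed = seed)
}
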