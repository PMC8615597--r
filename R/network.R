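# 1D residual network with class-wise attention, in base R matrix algebra.
# Activations are rank-3 arrays [batch, time, channels]; convolutions are
# im2col + BLAS matrix products; gradients are derived by hand so that
# training is a pure function of (data, config$seed).

## ---- low-level layers -------------------------------------------------

conv1d_forward <- function(x, W, bias) {
  d <- dim(x); b <- d[1]; tt <- d[2]; cin <- d[3]
  k <- nrow(W) %/% cin
  left <- (k - 1L) %/% 2L
  if (k == 1L) {
    xm <- x; dim(xm) <- c(b * tt, cin)
    out <- xm %*% W
  } else {
    xp <- array(0, c(b, tt + k - 1L, cin))
    xp[, left + seq_len(tt), ] <- x
    cols <- array(0, c(b, tt, k * cin))
    for (j in seq_len(k))
      cols[, , ((j - 1L) * cin + 1L):(j * cin)] <-
        xp[, j:(j + tt - 1L), , drop = FALSE]
    dim(cols) <- c(b * tt, k * cin)
    out <- cols %*% W
  }
  out <- out + matrix(bias, b * tt, ncol(W), byrow = TRUE)
  dim(out) <- c(b, tt, ncol(W))
  out
}

conv1d_backward <- function(dout, x, W) {
  d <- dim(x); b <- d[1]; tt <- d[2]; cin <- d[3]
  cout <- ncol(W); k <- nrow(W) %/% cin
  left <- (k - 1L) %/% 2L
  dom <- dout; dim(dom) <- c(b * tt, cout)
  db <- colSums(dom)
  if (k == 1L) {
    xm <- x; dim(xm) <- c(b * tt, cin)
    dW <- crossprod(xm, dom)
    dx <- dom %*% t(W)
    dim(dx) <- c(b, tt, cin)
    return(list(dx = dx, dW = dW, db = db))
  }
  xp <- array(0, c(b, tt + k - 1L, cin))
  xp[, left + seq_len(tt), ] <- x
  cols <- array(0, c(b, tt, k * cin))
  for (j in seq_len(k))
    cols[, , ((j - 1L) * cin + 1L):(j * cin)] <-
      xp[, j:(j + tt - 1L), , drop = FALSE]
  dim(cols) <- c(b * tt, k * cin)
  dW <- crossprod(cols, dom)
  dcols <- dom %*% t(W)
  dim(dcols) <- c(b, tt, k * cin)
  dxp <- array(0, c(b, tt + k - 1L, cin))
  for (j in seq_len(k))
    dxp[, j:(j + tt - 1L), ] <- dxp[, j:(j + tt - 1L), , drop = FALSE] +
      dcols[, , ((j - 1L) * cin + 1L):(j * cin), drop = FALSE]
  dx <- dxp[, left + seq_len(tt), , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

bn_forward <- function(x, gamma, beta, rm, rv, training, momentum = 0.9,
                       eps = 1e-5) {
  d <- dim(x); M <- d[1] * d[2]; cc <- d[3]
  xm <- x; dim(xm) <- c(M, cc)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm * xm) - mu * mu
    rm <- momentum * rm + (1 - momentum) * mu
    rv <- momentum * rv + (1 - momentum) * v
  } else {
    mu <- rm; v <- rv
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (xm - matrix(mu, M, cc, byrow = TRUE)) *
    matrix(invstd, M, cc, byrow = TRUE)
  out <- xhat * matrix(gamma, M, cc, byrow = TRUE) +
    matrix(beta, M, cc, byrow = TRUE)
  dim(out) <- d
  list(out = out, xhat = xhat, invstd = invstd, rm = rm, rv = rv, dims = d)
}

bn_backward <- function(dout, cache, gamma) {
  d <- cache$dims; M <- d[1] * d[2]; cc <- d[3]
  dy <- dout; dim(dy) <- c(M, cc)
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * matrix(gamma, M, cc, byrow = TRUE)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dx <- (matrix(cache$invstd, M, cc, byrow = TRUE) / M) *
    (M * dxhat - matrix(s1, M, cc, byrow = TRUE) -
       xhat * matrix(s2, M, cc, byrow = TRUE))
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

pool_forward <- function(x) {
  d <- dim(x); t2 <- d[2] %/% 2L
  i1 <- seq.int(1L, 2L * t2, 2L)
  a1 <- x[, i1, , drop = FALSE]
  a2 <- x[, i1 + 1L, , drop = FALSE]
  mask <- a1 >= a2
  out <- pmax(a1, a2)
  list(out = out, mask = mask, t_in = d[2])
}

pool_backward <- function(dout, cache) {
  d <- dim(dout)
  dx <- array(0, c(d[1], cache$t_in, d[3]))
  i1 <- seq.int(1L, 2L * d[2], 2L)
  dx[, i1, ] <- dout * cache$mask
  dx[, i1 + 1L, ] <- dout * (1 - cache$mask)
  dx
}

## ---- class-wise attention ---------------------------------------------

#' Class-wise attention pooling
#'
#' Pools a time-resolved feature map into one feature vector per category.
#' The query matrix `q` (one row per category, one-hot in the reference
#' model) selects a relevance channel from the key tensor; the relevance
#' series is softmax-normalized over time into attention weights, and each
#' category's feature vector is the weight-averaged value tensor:
#' `FV[b, i, ] = sum_t w[b, t, i] * v[b, t, ]`. Weights are non-negative and
#' sum to 1 over time, so every feature vector is a convex combination of
#' time slices.
#'
#' @param k_logits key tensor, array `[batch, time, m]` (one channel per
#'   category).
#' @param v value tensor, array `[batch, time, f]` (the feature map).
#' @param q `m x m` query matrix; default identity (one-hot queries).
#' @return list with `fv` (`[batch, m, f]` feature vectors) and `weights`
#'   (`[batch, time, m]` attention weights).
#' @export
class_wise_attention <- function(k_logits, v, q = NULL) {
  dk <- dim(k_logits); dv <- dim(v)
  if (length(dk) != 3 || length(dv) != 3) stop("k and v must be rank-3 arrays")
  m <- dk[3]
  if (m == 0) stop("category count must be positive")
  if (dk[1] != dv[1] || dk[2] != dv[2]) stop("k and v batch/time dims differ")
  if (!is.null(q)) {
    if (!all(dim(q) == c(m, m))) stop("q must be m x m")
    km <- k_logits; dim(km) <- c(dk[1] * dk[2], m)
    km <- km %*% t(q)
    dim(km) <- dk
    k_logits <- km
  }
  w <- attention_softmax(k_logits)
  fv <- array(0, c(dk[1], m, dv[3]))
  for (i in seq_len(m)) {
    wi <- as.vector(w[, , i])          # length b*t, recycles over channels
    prod <- v * wi
    fv[, i, ] <- colSums(aperm(prod, c(2, 1, 3)))
  }
  list(fv = fv, weights = w)
}

# softmax over the time dimension of [b, t, m]
attention_softmax <- function(s) {
  d <- dim(s)
  w <- s
  for (i in seq_len(d[3])) {
    si <- s[, , i, drop = FALSE]
    dim(si) <- d[1:2]
    si <- exp(si - apply(si, 1, max))
    w[, , i] <- si / rowSums(si)
  }
  w
}

## ---- model configuration and initialization ---------------------------

#' Configuration for the ECG classification network
#'
#' Desk-scale defaults for the 1D full-pre-activation residual network with
#' class-wise attention. Each residual block halves the time dimension by
#' max-pooling (width/stride 2). Training uses unweighted binary
#' cross-entropy, Adam (`beta1 = 0.9`, `beta2 = 0.999`), an initial learning
#' rate of 0.001 and per-epoch exponential decay with factor 0.9.
#'
#' @param n_categories number of output categories `m`.
#' @param n_leads input lead count.
#' @param n_blocks residual block count (default 6).
#' @param filters channels per block; a length-2 vector is expanded to the
#'   first/second half of the blocks (default `c(32, 64)`).
#' @param kernel_size convolution width (default 15).
#' @param learning_rate,adam_beta1,adam_beta2,lr_decay optimizer settings.
#' @param batch_size,epochs training loop settings.
#' @param seed RNG seed governing initialization and batch shuffling.
#' @return a list of class `ecg_net_config`.
#' @export
ecg_net_config <- function(n_categories, n_leads = 2, n_blocks = 6,
                           filters = c(32, 64), kernel_size = 15,
                           learning_rate = 0.001, adam_beta1 = 0.9,
                           adam_beta2 = 0.999, lr_decay = 0.9,
                           batch_size = 32, epochs = 20, seed = 1L) {
  if (n_categories < 1 || n_blocks < 1) stop("counts must be positive")
  if (length(filters) == 2 && n_blocks > 2) {
    filters <- c(rep(filters[1], ceiling(n_blocks / 2)),
                 rep(filters[2], floor(n_blocks / 2)))
  } else {
    filters <- rep_len(filters, n_blocks)
  }
  stopifnot(learning_rate > 0, lr_decay > 0, lr_decay <= 1,
            adam_beta1 > 0, adam_beta1 < 1, adam_beta2 > 0, adam_beta2 < 1)
  structure(list(n_categories = n_categories, n_leads = n_leads,
                 n_blocks = n_blocks, filters = filters,
                 kernel_size = kernel_size, learning_rate = learning_rate,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 lr_decay = lr_decay, batch_size = batch_size,
                 epochs = epochs, seed = as.integer(seed)),
            class = "ecg_net_config")
}

he_init <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out)
}

init_ecg_net <- function(config) {
  set.seed(config$seed)
  k <- config$kernel_size
  f <- config$filters
  m <- config$n_categories
  params <- list()
  state <- list()
  params$stem.W <- he_init(k * config$n_leads, f[1])
  params$stem.b <- numeric(f[1])
  cin <- f[1]
  for (i in seq_len(config$n_blocks)) {
    cout <- f[i]
    pre <- sprintf("blk%d.", i)
    params[[paste0(pre, "g1")]] <- rep(1, cin)
    params[[paste0(pre, "be1")]] <- numeric(cin)
    params[[paste0(pre, "W1")]] <- he_init(k * cin, cout)
    params[[paste0(pre, "b1")]] <- numeric(cout)
    params[[paste0(pre, "g2")]] <- rep(1, cout)
    params[[paste0(pre, "be2")]] <- numeric(cout)
    params[[paste0(pre, "W2")]] <- he_init(k * cout, cout)
    params[[paste0(pre, "b2")]] <- numeric(cout)
    if (cin != cout)
      params[[paste0(pre, "Wp")]] <- he_init(cin, cout)
    state[[paste0(pre, "rm1")]] <- numeric(cin)
    state[[paste0(pre, "rv1")]] <- rep(1, cin)
    state[[paste0(pre, "rm2")]] <- numeric(cout)
    state[[paste0(pre, "rv2")]] <- rep(1, cout)
    cin <- cout
  }
  params$cwa.Wk <- he_init(cin, m)
  params$cwa.bk <- numeric(m)
  params$head.W <- matrix(stats::rnorm(cin * m, 0, sqrt(1 / cin)), cin, m)
  params$head.b <- numeric(m)
  structure(list(params = params, state = state, config = config,
                 history = data.frame()),
            class = "ecg_net")
}

## ---- forward / backward -----------------------------------------------

net_forward <- function(net, x, training = FALSE) {
  p <- net$params; st <- net$state; cfg <- net$config
  cache <- list(x = x)
  a <- conv1d_forward(x, p$stem.W, p$stem.b)
  cache$stem_out <- a
  for (i in seq_len(cfg$n_blocks)) {
    pre <- sprintf("blk%d.", i)
    cb <- list(x_in = a)
    bn1 <- bn_forward(a, p[[paste0(pre, "g1")]], p[[paste0(pre, "be1")]],
                      st[[paste0(pre, "rm1")]], st[[paste0(pre, "rv1")]],
                      training)
    if (training) {
      st[[paste0(pre, "rm1")]] <- bn1$rm
      st[[paste0(pre, "rv1")]] <- bn1$rv
    }
    r1 <- pmax(bn1$out, 0)
    c1 <- conv1d_forward(r1, p[[paste0(pre, "W1")]], p[[paste0(pre, "b1")]])
    bn2 <- bn_forward(c1, p[[paste0(pre, "g2")]], p[[paste0(pre, "be2")]],
                      st[[paste0(pre, "rm2")]], st[[paste0(pre, "rv2")]],
                      training)
    if (training) {
      st[[paste0(pre, "rm2")]] <- bn2$rm
      st[[paste0(pre, "rv2")]] <- bn2$rv
    }
    r2 <- pmax(bn2$out, 0)
    c2 <- conv1d_forward(r2, p[[paste0(pre, "W2")]], p[[paste0(pre, "b2")]])
    if (!is.null(p[[paste0(pre, "Wp")]])) {
      short <- conv1d_forward(a, p[[paste0(pre, "Wp")]],
                              numeric(ncol(p[[paste0(pre, "Wp")]])))
    } else short <- a
    s <- short + c2
    pl <- pool_forward(s)
    cb$bn1 <- bn1; cb$r1 <- r1; cb$bn2 <- bn2; cb$r2 <- r2
    cb$pool <- pl
    cache[[paste0("blk", i)]] <- cb
    a <- pl$out
  }
  cache$v <- a
  k_logits <- conv1d_forward(a, p$cwa.Wk, p$cwa.bk)
  att <- class_wise_attention(k_logits, a)
  cache$att <- att
  fv <- att$fv                       # [b, m, f]
  b <- dim(fv)[1]; m <- cfg$n_categories; f <- dim(fv)[3]
  z <- matrix(0, b, m)
  for (i in seq_len(m))
    z[, i] <- fv[, i, , drop = FALSE][, 1, ] %*% p$head.W[, i] + p$head.b[i]
  prob <- 1 / (1 + exp(-z))
  list(prob = prob, z = z, cache = cache, state = st,
       attention = att$weights)
}

net_backward <- function(net, fw, y) {
  p <- net$params; cfg <- net$config
  cache <- fw$cache
  b <- nrow(fw$prob); m <- ncol(fw$prob)
  grads <- list()
  dz <- (fw$prob - y) / (b * m)
  v <- cache$v
  fv <- cache$att$fv; w <- cache$att$weights
  f <- dim(v)[3]; tt <- dim(v)[2]
  grads$head.W <- matrix(0, f, m)
  grads$head.b <- colSums(dz)
  dv <- array(0, dim(v))
  dS <- array(0, c(b, tt, m))
  for (i in seq_len(m)) {
    fvi <- fv[, i, , drop = FALSE]; dim(fvi) <- c(b, f)
    grads$head.W[, i] <- colSums(fvi * dz[, i])
    dfv_i <- outer(dz[, i], p$head.W[, i])          # [b, f]
    wi <- w[, , i, drop = FALSE]; dim(wi) <- c(b, tt)
    # dV accumulation and attention-score gradient
    dw_i <- matrix(0, b, tt)
    for (ff in seq_len(f)) {
      dv[, , ff] <- dv[, , ff] + wi * dfv_i[, ff]
      dw_i <- dw_i + v[, , ff] * dfv_i[, ff]
    }
    dS[, , i] <- wi * (dw_i - rowSums(wi * dw_i))
  }
  ck <- conv1d_backward(dS, v, p$cwa.Wk)
  grads$cwa.Wk <- ck$dW; grads$cwa.bk <- ck$db
  dv <- dv + ck$dx
  da <- dv
  for (i in rev(seq_len(cfg$n_blocks))) {
    pre <- sprintf("blk%d.", i)
    cb <- cache[[paste0("blk", i)]]
    ds <- pool_backward(da, cb$pool)
    # conv2 branch
    g2 <- conv1d_backward(ds, cb$r2, p[[paste0(pre, "W2")]])
    grads[[paste0(pre, "W2")]] <- g2$dW
    grads[[paste0(pre, "b2")]] <- g2$db
    dr2 <- g2$dx * (cb$r2 > 0)
    g_bn2 <- bn_backward(dr2, cb$bn2, p[[paste0(pre, "g2")]])
    grads[[paste0(pre, "g2")]] <- g_bn2$dgamma
    grads[[paste0(pre, "be2")]] <- g_bn2$dbeta
    g1 <- conv1d_backward(g_bn2$dx, cb$r1, p[[paste0(pre, "W1")]])
    grads[[paste0(pre, "W1")]] <- g1$dW
    grads[[paste0(pre, "b1")]] <- g1$db
    dr1 <- g1$dx * (cb$r1 > 0)
    g_bn1 <- bn_backward(dr1, cb$bn1, p[[paste0(pre, "g1")]])
    grads[[paste0(pre, "g1")]] <- g_bn1$dgamma
    grads[[paste0(pre, "be1")]] <- g_bn1$dbeta
    da_main <- g_bn1$dx
    # shortcut branch
    if (!is.null(p[[paste0(pre, "Wp")]])) {
      gp <- conv1d_backward(ds, cb$x_in, p[[paste0(pre, "Wp")]])
      grads[[paste0(pre, "Wp")]] <- gp$dW
      da <- da_main + gp$dx
    } else {
      da <- da_main + ds
    }
  }
  gs <- conv1d_backward(da, cache$x, p$stem.W)
  grads$stem.W <- gs$dW
  grads$stem.b <- gs$db
  grads
}

bce_loss <- function(prob, y, eps = 1e-7) {
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

## ---- training ----------------------------------------------------------

#' Train the residual network with class-wise attention
#'
#' Mini-batch training with unweighted binary cross-entropy, Adam and
#' per-epoch exponential learning-rate decay
#' (`lr_epoch = learning_rate * lr_decay^epoch`). Given the same data and
#' config (including `seed`), training is deterministic.
#'
#' @param x input array `[n, time, leads]` of pre-processed signals (see
#'   [preprocess_ecg()]) or a list of [ecg_record()]s of equal length.
#' @param y binary `n x m` label matrix.
#' @param config an [ecg_net_config()].
#' @param verbose print per-epoch loss.
#' @return a fitted object of class `ecg_net` with elements `params`,
#'   `state` (batch-norm running moments), `config` and `history`
#'   (per-epoch mean training loss and learning rate).
#' @export
train_ecg_net <- function(x, y, config, verbose = FALSE) {
  x <- as_signal_array(x)
  y <- check_label_matrix(y, config$n_categories)
  n <- dim(x)[1]
  if (n == 0 || nrow(y) != n) stop("need a nonempty aligned dataset")
  net <- init_ecg_net(config)
  adam_m <- lapply(net$params, function(p) p * 0)
  adam_v <- adam_m
  step <- 0
  history <- data.frame(epoch = integer(), loss = numeric(), lr = numeric())
  for (epoch in seq_len(config$epochs)) {
    lr <- config$learning_rate * config$lr_decay^(epoch - 1)
    idx <- sample.int(n)                    # seeded: init_ecg_net set the RNG
    losses <- c()
    for (start in seq(1, n, by = config$batch_size)) {
      bi <- idx[start:min(start + config$batch_size - 1, n)]
      if (length(bi) < 2) next              # batch norm needs > 1 sample
      xb <- x[bi, , , drop = FALSE]
      yb <- y[bi, , drop = FALSE]
      fw <- net_forward(net, xb, training = TRUE)
      net$state <- fw$state
      loss <- bce_loss(fw$prob, yb)
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", epoch,
             "; last finite losses: ",
             paste(round(utils::tail(losses, 3), 4), collapse = ", "))
      losses <- c(losses, loss)
      grads <- net_backward(net, fw, yb)
      step <- step + 1
      for (nm in names(grads)) {
        g <- grads[[nm]]
        adam_m[[nm]] <- config$adam_beta1 * adam_m[[nm]] +
          (1 - config$adam_beta1) * g
        adam_v[[nm]] <- config$adam_beta2 * adam_v[[nm]] +
          (1 - config$adam_beta2) * g * g
        mhat <- adam_m[[nm]] / (1 - config$adam_beta1^step)
        vhat <- adam_v[[nm]] / (1 - config$adam_beta2^step)
        net$params[[nm]] <- net$params[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
      }
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, loss = mean(losses), lr = lr))
    if (verbose)
      message(sprintf("epoch %d: loss %.4f (lr %.5f)", epoch,
                      mean(losses), lr))
  }
  net$history <- history
  net
}

#' Predict category scores with a trained network
#'
#' @param object a trained `ecg_net` (see [train_ecg_net()]).
#' @param x input array `[n, time, leads]` or list of [ecg_record()]s.
#' @param attention also return the attention weight tensor.
#' @param batch_size evaluation batch size.
#' @param ... unused.
#' @return an `n x m` score matrix in `(0, 1)`; with `attention = TRUE`, a
#'   list with `scores` and `attention` (`[n, t', m]`, softmax over time).
#' @export
predict.ecg_net <- function(object, x, attention = FALSE, batch_size = 64,
                            ...) {
  x <- as_signal_array(x)
  n <- dim(x)[1]
  scores <- NULL; att <- NULL
  for (start in seq(1, n, by = batch_size)) {
    bi <- start:min(start + batch_size - 1, n)
    fw <- net_forward(object, x[bi, , , drop = FALSE], training = FALSE)
    scores <- rbind(scores, fw$prob)
    if (attention) {
      att <- if (is.null(att)) fw$attention else {
        ab <- array(0, dim(fw$attention) + c(dim(att)[1], 0, 0))
        ab[seq_len(dim(att)[1]), , ] <- att
        ab[dim(att)[1] + seq_len(dim(fw$attention)[1]), , ] <- fw$attention
        ab
      }
    }
  }
  if (attention) list(scores = scores, attention = att) else scores
}

#' @export
print.ecg_net <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$params, length, 1L))
  cat(sprintf(
    "ECG ResNet+CWA: %d blocks, filters %s, kernel %d, %d categories (%d parameters)\n",
    cfg$n_blocks, paste(unique(cfg$filters), collapse = "->"),
    cfg$kernel_size, cfg$n_categories, n_par))
  if (nrow(x$history))
    cat(sprintf("trained %d epochs, final loss %.4f\n",
                max(x$history$epoch), utils::tail(x$history$loss, 1)))
  invisible(x)
}

# Accept a [n, t, l] array or a list of equally-shaped ecg_records.
as_signal_array <- function(x) {
  if (is.array(x) && length(dim(x)) == 3) return(x)
  if (is.list(x) && all(vapply(x, inherits, TRUE, "ecg_record"))) {
    dims <- vapply(x, function(r) dim(r$signal), integer(2))
    if (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1)
      stop("records must share signal shape; run preprocess_ecg() first")
    out <- array(0, c(length(x), dims[1, 1], dims[2, 1]))
    for (i in seq_along(x)) out[i, , ] <- x[[i]]$signal
    return(out)
  }
  stop("x must be an [n, time, leads] array or a list of ecg_record objects")
}
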