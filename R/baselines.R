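#' Fixed linear readout control
#'
#' The simplest unmodulated control, `y = W x`. For every pair of contexts a
#' weight matrix is fitted by ordinary least squares on 1024 consecutive
#' samples of the training context and tested on held-out 1024 samples of the
#' test context, giving the full cross-context generalisation matrix of R^2
#' values. A fixed `W` can invert one mixture but not two different ones, so
#' the off-diagonal entries fall below the diagonal.
#'
#' @param n_ctx number of random contexts (default 20, giving a 20 x 20
#'   matrix).
#' @param n_train,n_test consecutive training and test samples per context.
#' @param sigma_n stimulus noise.
#' @param det_threshold determinant threshold for the sampled contexts.
#' @return list with `r2` (`n_ctx` x `n_ctx`; rows = training context,
#'   columns = test context) and the sampled `contexts`.
#' @export
baseline_linear <- function(n_ctx = 20, n_train = 1024, n_test = 1024,
                            sigma_n = 0, det_threshold = 0.2) {
  bank <- generate_sources("chord", T_samples = n_train + n_test)
  s_tr <- bank$samples[seq_len(n_train), , drop = FALSE]
  s_te <- bank$samples[(n_train + 1):(n_train + n_test), , drop = FALSE]
  contexts <- replicate(n_ctx, sample_mixing_matrix(2, det_threshold),
                        simplify = FALSE)
  noisy <- function(s, A) {
    x <- s %*% t(A)
    if (sigma_n > 0) x <- x + sigma_n * matrix(rnorm(length(x)), nrow(x))
    x
  }
  x_tr <- lapply(contexts, noisy, s = s_tr)
  x_te <- lapply(contexts, noisy, s = s_te)
  r2 <- matrix(NA_real_, n_ctx, n_ctx)
  for (i in seq_len(n_ctx)) {
    X <- cbind(1, x_tr[[i]])
    W <- qr.solve(X, s_tr)
    for (j in seq_len(n_ctx)) {
      pred <- cbind(1, x_te[[j]]) %*% W
      r2[i, j] <- r_squared(s_te, pred)
    }
  }
  list(r2 = r2, contexts = contexts)
}

# Coefficient of determination, averaged over target channels.
r_squared <- function(target, pred) {
  target <- as.matrix(target); pred <- as.matrix(pred)
  mean(vapply(seq_len(ncol(target)), function(j) {
    ss_res <- sum((target[, j] - pred[, j])^2)
    ss_tot <- sum((target[, j] - mean(target[, j]))^2)
    1 - ss_res / ss_tot
  }, numeric(1)))
}

#' Multilayer feedforward control
#'
#' An unmodulated nonlinear control: a fully connected network with rectified
#' linear hidden layers of 32, 16 and 8 units, trained with Adam (learning
#' rate 1e-3) on the mean squared error over batches of fresh contexts. With
#' `seq_len = 1` the network maps single time points; with `seq_len > 1` the
#' input and output are flattened windows of `seq_len` consecutive samples,
#' giving the network access to enough history to infer the context in
#' principle.
#'
#' @param seq_len input/output window length (>= 1).
#' @param hidden hidden layer sizes.
#' @param n_batches training batches (default 5000).
#' @param contexts_per_batch fresh contexts per batch (default 32); each
#'   contributes one window.
#' @param n_t trial length the windows are drawn from.
#' @param learning_rate Adam step size.
#' @param sigma_n stimulus noise.
#' @return list with `predict(x)` (matrix in, matrix out of flattened
#'   windows), the weight list `params`, and the per-batch `loss` curve.
#' @export
baseline_mlp <- function(seq_len = 1, hidden = c(32, 16, 8), n_batches = 5000,
                         contexts_per_batch = 32, n_t = 1000,
                         learning_rate = 1e-3, sigma_n = 0.001) {
  stopifnot(seq_len >= 1)
  n_s <- 2
  d_in <- d_out <- seq_len * n_s
  sizes <- c(d_in, hidden, d_out)
  L <- length(sizes) - 1
  W <- lapply(seq_len(L), function(l)
    matrix(rnorm(sizes[l] * sizes[l + 1], 0, sqrt(2 / sizes[l])),
           sizes[l], sizes[l + 1]))
  bvec <- lapply(seq_len(L), function(l) rep(0, sizes[l + 1]))
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(bvec, function(b) b * 0); vb <- mb
  bank <- generate_sources("chord", T_samples = n_t)

  fwd <- function(X) {
    acts <- list(X)
    for (l in seq_len(L)) {
      Z <- acts[[l]] %*% W[[l]] + matrix(bvec[[l]], nrow(X), sizes[l + 1], byrow = TRUE)
      acts[[l + 1]] <- if (l < L) pmax(Z, 0) else Z
    }
    acts
  }

  loss_hist <- numeric(n_batches)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  for (it in seq_len(n_batches)) {
    X <- matrix(0, contexts_per_batch, d_in)
    Y <- matrix(0, contexts_per_batch, d_out)
    for (bb in seq_len(contexts_per_batch)) {
      A <- sample_mixing_matrix(2)
      off <- sample.int(n_t - seq_len + 1, 1)
      s <- bank$samples[off:(off + seq_len - 1), , drop = FALSE]
      x <- s %*% t(A)
      if (sigma_n > 0) x <- x + sigma_n * matrix(rnorm(length(x)), nrow(x))
      X[bb, ] <- as.vector(x)
      Y[bb, ] <- as.vector(s)
    }
    acts <- fwd(X)
    err <- acts[[L + 1]] - Y
    loss_hist[it] <- mean(err^2)
    delta <- 2 * err / length(err)
    lr_t <- learning_rate * sqrt(1 - beta2^it) / (1 - beta1^it)
    for (l in L:1) {
      gW <- t(acts[[l]]) %*% delta
      gb <- colSums(delta)
      if (l > 1) delta <- (delta %*% t(W[[l]])) * (acts[[l]] > 0)
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
      W[[l]] <- W[[l]] - lr_t * mW[[l]] / (sqrt(vW[[l]]) + eps)
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
      bvec[[l]] <- bvec[[l]] - lr_t * mb[[l]] / (sqrt(vb[[l]]) + eps)
    }
  }
  list(predict = function(X) fwd(as.matrix(X))[[L + 1]],
       params = list(W = W, b = bvec),
       loss = loss_hist, seq_len = seq_len, hidden = hidden)
}
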