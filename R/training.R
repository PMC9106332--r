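#' Smooth L1 reconstruction loss
#'
#' Per-element Huber-style distance with unit transition,
#' `h(d) = d^2/2` for `|d| < 1` and `|d| - 1/2` otherwise, reduced by the mean
#' over all elements (time, channels and, for batched input, trials). Less
#' sensitive to outliers than the squared error.
#' @param pred,target numeric arrays of equal shape.
#' @param reduce `"mean"` (default) or `"sum"`.
#' @export
smooth_l1 <- function(pred, target, reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  if (!identical(dim(pred) %||% length(pred), dim(target) %||% length(target)))
    stop("pred and target must have the same shape", call. = FALSE)
  d <- abs(pred - target)
  h <- ifelse(d < 1, 0.5 * d^2, d - 0.5)
  if (reduce == "mean") mean(h) else sum(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Feedback-magnitude regulariser
#'
#' `lambda_out * sum(|l_j(t)|)` over time and feedback signals; keeps the
#' modulator readout small and (in the Dalean model) the gains away from
#' saturation.
#' @param feedback_trace matrix of feedback signals (time x signals, or any
#'   numeric array).
#' @param lambda_out penalty weight (default 1e-5).
#' @export
output_regulariser <- function(feedback_trace, lambda_out = 1e-5) {
  if (lambda_out < 0) stop("lambda_out must be >= 0", call. = FALSE)
  lambda_out * sum(abs(feedback_trace))
}

#' Training configuration
#'
#' Defaults follow the study conditions: batches of 32 trials of `n_t = 1000`
#' samples, Adam with learning rate 1e-3, feedback penalty `lambda_out = 1e-5`,
#' per-element gradient clipping to \[-1, 1\], 10,000 batches, and a
#' 16,000-sample source bank from which each trial draws independent random
#' chunks per source (phase randomisation).
#'
#' @param batch_size trials per batch.
#' @param n_batches parameter updates.
#' @param learning_rate Adam step size.
#' @param lambda_out feedback-magnitude penalty.
#' @param clip per-element gradient bound.
#' @param n_t trial length in samples.
#' @param bank_length source-bank samples used for phase randomisation.
#' @param sigma_n additive stimulus noise during training.
#' @param det_threshold mixing-matrix determinant threshold.
#' @param beta1,beta2,eps Adam moment parameters.
#' @export
training_config <- function(batch_size = 32, n_batches = 10000,
                            learning_rate = 1e-3, lambda_out = 1e-5,
                            clip = 1, n_t = 1000, bank_length = 16000,
                            sigma_n = 0.001, det_threshold = 0.2,
                            beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  stopifnot(batch_size >= 1, n_batches >= 0, n_t >= 1, bank_length >= n_t,
            lambda_out >= 0, clip > 0)
  structure(list(batch_size = batch_size, n_batches = n_batches,
                 learning_rate = learning_rate, lambda_out = lambda_out,
                 clip = clip, n_t = n_t, bank_length = bank_length,
                 sigma_n = sigma_n, det_threshold = det_threshold,
                 beta1 = beta1, beta2 = beta2, eps = eps),
            class = "training_config")
}

#' Assemble one training batch
#'
#' Each trial gets a freshly sampled mixing matrix and, independently for each
#' source, a random chunk of `n_t` consecutive samples from the bank, so the
#' source phases vary across trials and the modulator cannot memorise the
#' exact sequence.
#'
#' @param bank a [source_bank][generate_sources()] of at least `n_t` samples.
#' @param batch_size number of trials.
#' @param n_t samples per trial.
#' @param sigma_n additive stimulus noise.
#' @param det_threshold determinant threshold for the mixing matrices.
#' @return list with arrays `x`, `s` of dimension `(n_s, batch, n_t)` and the
#'   per-trial mixing matrices `A`.
#' @export
make_training_batch <- function(bank, batch_size = 32, n_t = 1000,
                                sigma_n = 0.001, det_threshold = 0.2) {
  n_s <- ncol(bank$samples)
  if (bank$T < n_t) stop("source bank shorter than n_t", call. = FALSE)
  x <- array(0, c(n_s, batch_size, n_t))
  s <- array(0, c(n_s, batch_size, n_t))
  A_list <- vector("list", batch_size)
  for (bb in seq_len(batch_size)) {
    A <- sample_mixing_matrix(n_s, det_threshold)
    A_list[[bb]] <- A
    off <- sample.int(bank$T - n_t + 1, n_s, replace = TRUE)
    sb <- vapply(seq_len(n_s), function(i)
      bank$samples[off[i]:(off[i] + n_t - 1), i], numeric(n_t))
    xb <- sb %*% t(A)
    if (sigma_n > 0) xb <- xb + sigma_n * matrix(rnorm(length(xb)), n_t, n_s)
    s[, bb, ] <- t(sb)
    x[, bb, ] <- t(xb)
  }
  list(x = x, s = s, A = A_list)
}

batch_gradients <- function(net, batch, lambda_out) {
  msk <- input_masks(net)
  opt <- list(tau = net$tau, dt = 1, lambda_out = lambda_out,
              mask_x = msk$mask_x, mask_y = msk$mask_y)
  fn <- switch(net$architecture,
               simple = cpp_grad_simple,
               population = cpp_grad_population,
               dalean = cpp_grad_dalean)
  fn(net$params, batch$x, batch$s, opt)
}

#' Train the modulator by backpropagation through time
#'
#' Simulates the closed loop (feedforward network plus LSTM modulator) over
#' batches of independent trials, accumulates the smooth-L1 reconstruction
#' loss plus the feedback-magnitude penalty, backpropagates through all `n_t`
#' steps of every trial, clips each gradient element to `[-clip, clip]` and
#' applies an Adam update. The modulator parameters are always trained; for
#' the Dalean model the feedforward weights (`WLx`, `WIL`, `WHL`, `WHI`,
#' `Wro`) are trained as well, with sign-constrained weights entering the
#' forward pass as absolute values. Modulator and modulation states are reset
#' to zero at every trial start.
#'
#' All randomness (context sampling, chunk offsets, noise) is drawn from R's
#' RNG, so a `set.seed()` call before training makes the run reproducible.
#'
#' @param net a [modulated_network()].
#' @param config a [training_config()].
#' @param bank optional [source_bank][generate_sources()]; defaults to fresh
#'   chord sources of `config$bank_length` samples.
#' @param verbose print a log line every 100 batches.
#' @return list with the trained `net` and `history`, a data.frame with one
#'   row per batch (`batch`, `loss`, `reg`).
#' @export
train_modulator <- function(net, config = training_config(), bank = NULL,
                            verbose = FALSE) {
  stopifnot(inherits(net, "modulated_network"))
  if (config$n_batches == 0)
    return(list(net = net, history = data.frame(batch = integer(),
                                                loss = numeric(),
                                                reg = numeric())))
  if (is.null(bank))
    bank <- generate_sources("chord", T_samples = config$bank_length)
  tr <- trainable_names(net)
  zero_like <- function(p) if (is.matrix(p)) p * 0 else numeric(length(p))
  mstate <- lapply(net$params[tr], zero_like)
  vstate <- mstate
  loss_hist <- reg_hist <- numeric(config$n_batches)
  for (it in seq_len(config$n_batches)) {
    batch <- make_training_batch(bank, config$batch_size, config$n_t,
                                 config$sigma_n, config$det_threshold)
    res <- batch_gradients(net, batch, config$lambda_out)
    if (!is.finite(res$loss)) {
      hist <- data.frame(batch = seq_len(it - 1),
                         loss = loss_hist[seq_len(it - 1)],
                         reg = reg_hist[seq_len(it - 1)])
      cond <- structure(class = c("training_failure", "error", "condition"),
                        list(message = sprintf("non-finite loss at batch %d", it),
                             call = sys.call(), history = hist))
      stop(cond)
    }
    loss_hist[it] <- res$loss_rec
    reg_hist[it] <- res$reg
    lr_t <- config$learning_rate *
      sqrt(1 - config$beta2^it) / (1 - config$beta1^it)
    for (nm in tr) {
      g <- res$grads[[nm]]
      if (!is.matrix(net$params[[nm]])) g <- as.numeric(g)
      g <- pmin(pmax(g, -config$clip), config$clip)
      mstate[[nm]] <- config$beta1 * mstate[[nm]] + (1 - config$beta1) * g
      vstate[[nm]] <- config$beta2 * vstate[[nm]] + (1 - config$beta2) * g^2
      net$params[[nm]] <- net$params[[nm]] -
        lr_t * mstate[[nm]] / (sqrt(vstate[[nm]]) + config$eps)
    }
    if (verbose && it %% 100 == 0)
      message(sprintf("batch %5d  loss %.5f  reg %.2e", it,
                      mean(loss_hist[max(1, it - 99):it]), reg_hist[it]))
  }
  list(net = net,
       history = data.frame(batch = seq_len(config$n_batches),
                            loss = loss_hist, reg = reg_hist))
}
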