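#' Simulate a network on a stimulus stream
#'
#' Runs the closed loop (feedforward network + modulator) over a single
#' continuous stimulus stream with forward Euler at one sample per step.
#' Modulator and modulation states start at zero and are carried across
#' context switches within the stream. Manipulation hooks: `freeze_window`
#' clamps the modulation variable (`M`, `m`) at its pre-window value while the
#' modulator's hidden dynamics continue unseen; `delta` adds a constant drive
#' to the modulation-unit dynamics inside `delta_window` (population/Dalean
#' models).
#'
#' @param net a [modulated_network()].
#' @param x stimulus matrix (`T` x `n_s`).
#' @param freeze_window integer vector `c(from, to)` of 1-based sample indices
#'   (inclusive) during which the modulation is clamped, or `NULL`.
#' @param delta additive drive to the modulation units (e.g. +3 / -3).
#' @param delta_window sample window for `delta` (default: whole stream).
#' @param state optional initial state (list `h`, `c`, `mod`) to continue a
#'   previous simulation.
#' @return list of traces, all with time along rows: `y`, `feedback`, `mod`
#'   (modulation matrix entries or `m`), plus `z` (population) or
#'   `zL`/`zI`/`zH`/`p` (dalean), and the final `state`.
#' @export
simulate_network <- function(net, x, freeze_window = NULL, delta = 0,
                             delta_window = NULL, state = NULL) {
  stopifnot(inherits(net, "modulated_network"))
  if (ncol(x) != net$dims$n_s) stop("x must have n_s columns", call. = FALSE)
  msk <- input_masks(net)
  opt <- list(tau = net$tau, dt = 1, mask_x = msk$mask_x, mask_y = msk$mask_y)
  if (!is.null(freeze_window)) {
    opt$freeze_from <- as.integer(freeze_window[1] - 1)
    opt$freeze_to <- as.integer(freeze_window[2])
  }
  if (delta != 0) {
    if (net$architecture == "simple")
      stop("modulation-unit manipulation needs a population or dalean model",
           call. = FALSE)
    opt$delta <- delta
    if (is.null(delta_window)) delta_window <- c(1, nrow(x))
    opt$delta_from <- as.integer(delta_window[1] - 1)
    opt$delta_to <- as.integer(delta_window[2])
  }
  if (!is.null(state)) {
    opt$h0 <- state$h; opt$c0 <- state$c; opt$mod0 <- state$mod
  }
  res <- cpp_simulate(net$architecture, net$params, t(x), opt)
  out <- list(y = t(res$y), feedback = t(res$feedback), mod = t(res$mod),
              state = res$state)
  for (nm in c("z", "zL", "zI", "zH", "p"))
    if (!is.null(res[[nm]])) out[[nm]] <- t(res[[nm]])
  out
}

# Activity of the modulated population stage (z or zH), used by the
# population-level analyses.
population_activity <- function(sim, net) {
  switch(net$architecture,
         population = sim$z,
         dalean = sim$zH,
         stop("no modulated population in the simple model", call. = FALSE))
}

#' Evaluate a model on fresh random contexts
#'
#' Draws an independent random set of contexts (as during training), mixes the
#' same source signals through them, simulates the network over the continuous
#' stream (modulator state carried across context switches) and reports
#' per-context signal clarity of output and stimuli plus the deviation
#' `|y - s|`.
#'
#' @param net a (typically trained) [modulated_network()].
#' @param n_contexts test contexts (default 20).
#' @param n_t samples per context.
#' @param sigma_n stimulus noise amplitude.
#' @param bank optional source bank (defaults to fresh chords long enough for
#'   the stream).
#' @param det_threshold determinant threshold for test contexts.
#' @return class `protocol_result`: list with the `stream`, simulation
#'   `traces`, and `metrics` (one row per context: clarity of y and x,
#'   mean deviation, deviation in first/last decile of the context).
#' @export
evaluate_model <- function(net, n_contexts = 20, n_t = 1000, sigma_n = 0.001,
                           bank = NULL, det_threshold = 0.2) {
  if (is.null(bank))
    bank <- generate_sources("chord", T_samples = n_contexts * n_t)
  schedule <- build_schedule(n_contexts, n_t, net$dims$n_s, det_threshold)
  stream <- mix_stream(bank, schedule, sigma_n)
  sim <- simulate_network(net, stream$x)
  dev <- rowMeans(abs(sim$y - stream$s))
  dec <- max(1L, floor(n_t / 10))
  metrics <- do.call(rbind, lapply(seq_len(n_contexts), function(k) {
    idx <- which(stream$context_index == k)
    data.frame(
      context = k,
      clarity_y = mean(signal_clarity(sim$y[idx, , drop = FALSE],
                                      stream$s[idx, , drop = FALSE])),
      clarity_x = mean(signal_clarity(stream$x[idx, , drop = FALSE],
                                      stream$s[idx, , drop = FALSE])),
      deviation = mean(dev[idx]),
      dev_first_decile = mean(dev[idx[seq_len(dec)]]),
      dev_last_decile = mean(dev[idx[(length(idx) - dec + 1):length(idx)]])
    )
  }))
  structure(list(stream = stream, traces = sim, metrics = metrics,
                 n_contexts = n_contexts, n_t = n_t, sigma_n = sigma_n),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("<protocol_result> %d contexts x %d samples; mean clarity y = %.3f, x = %.3f\n",
              x$n_contexts, x$n_t, mean(x$metrics$clarity_y),
              mean(x$metrics$clarity_x)))
  invisible(x)
}

#' Signal clarity as a function of stimulus noise
#'
#' Repeats [evaluate_model()] at each noise amplitude and reports the clarity
#' distribution over contexts per level, together with the measured
#' signal-to-noise ratio in dB.
#' @param net a trained [modulated_network()].
#' @param sigma_n_levels noise amplitudes to test.
#' @param n_contexts,n_t evaluation stream shape.
#' @return data.frame with one row per (level, context).
#' @export
sweep_noise <- function(net, sigma_n_levels, n_contexts = 20, n_t = 1000) {
  do.call(rbind, lapply(sigma_n_levels, function(sn) {
    ev <- evaluate_model(net, n_contexts, n_t, sigma_n = sn)
    sigma_s <- sd(ev$stream$s %*% t(ev$stream$schedule$contexts[[1]]))
    data.frame(sigma_n = sn,
               snr_db = if (sn > 0) snr_db(sigma_s, sn) else Inf,
               context = ev$metrics$context,
               clarity_y = ev$metrics$clarity_y,
               clarity_x = ev$metrics$clarity_x)
  }))
}

#' Train and evaluate across modulation timescales
#'
#' Trains one simple filtered-modulation model per relative timescale
#' `tau / n_t` and evaluates its signal clarity; the reference fast and slow
#' relative timescales are 0.001 and 1.
#' @param taus_relative timescales relative to the context duration `n_t`.
#' @param config a [training_config()] shared by all runs.
#' @param n_hidden LSTM size for the swept models.
#' @param n_contexts evaluation contexts per model.
#' @return data.frame with one row per (tau, context); `tau_abs` is the
#'   absolute time constant in samples.
#' @export
sweep_timescale <- function(taus_relative, config = training_config(),
                            n_hidden = 100, n_contexts = 20) {
  do.call(rbind, lapply(taus_relative, function(rt) {
    tau_abs <- max(rt * config$n_t, 1e-9)
    net <- modulated_network("simple", n_hidden = n_hidden, tau = tau_abs)
    fit <- train_modulator(net, config)
    ev <- evaluate_model(fit$net, n_contexts, config$n_t, config$sigma_n)
    data.frame(tau_relative = rt, tau_abs = tau_abs,
               context = ev$metrics$context,
               clarity_y = ev$metrics$clarity_y)
  }))
}

#' Train a model with ablated modulator inputs
#'
#' Trains and evaluates a model whose modulator observes only the sensory
#' stimuli (`x_only`), only the network output (`y_only`), or both
#' (`x_and_y`, the default model). The omitted input is zero-masked, so
#' parameter counts are identical across variants.
#' @param variant input mode.
#' @param architecture model variant to train.
#' @param config a [training_config()].
#' @param n_hidden LSTM size.
#' @param n_contexts evaluation contexts.
#' @param ... passed to [modulated_network()].
#' @return list with the trained `net`, training `history` and the
#'   `evaluation` [protocol_result][evaluate_model()].
#' @export
ablate_modulator_inputs <- function(variant = c("x_and_y", "x_only", "y_only"),
                                    architecture = "simple",
                                    config = training_config(),
                                    n_hidden = 100, n_contexts = 20, ...) {
  variant <- match.arg(variant)
  net <- modulated_network(architecture, n_hidden = n_hidden,
                           input_mode = variant, ...)
  fit <- train_modulator(net, config)
  ev <- evaluate_model(fit$net, n_contexts, config$n_t, config$sigma_n)
  list(net = fit$net, history = fit$history, evaluation = ev)
}

#' Freeze-feedback protocol
#'
#' Three-stage protocol that dissociates the effects of context and feedback:
#' stage 1 runs context 1 with intact feedback; at the context switch the
#' modulation (`M` or `m`, hence the gains `p`) is clamped at its pre-switch
#' value for `freeze_duration` samples while the modulator's hidden dynamics
#' continue unseen (stage 2); feedback is then re-enabled for the rest of
#' context 2 (stage 3). Pure sine sources are used by default.
#'
#' @param net a trained [modulated_network()].
#' @param context_pair list of two mixing matrices; sampled fresh if `NULL`.
#' @param n_t samples per context.
#' @param freeze_duration frozen samples after the switch (default `n_t / 2`;
#'   must not exceed `n_t`).
#' @param freqs sine frequencies for the visualisation sources.
#' @param sigma_n stimulus noise.
#' @return list with `traces` (full 2`n_t` simulation), the `stream`,
#'   `stages` (data.frame: stage, start, end, mean deviation) and the
#'   `freeze_window`.
#' @export
freeze_feedback <- function(net, context_pair = NULL, n_t = 1000,
                            freeze_duration = n_t / 2, freqs = c(100, 150),
                            sigma_n = 0.001) {
  if (freeze_duration > n_t)
    stop("freeze_duration must not exceed n_t", call. = FALSE)
  if (is.null(context_pair))
    context_pair <- list(sample_mixing_matrix(net$dims$n_s),
                         sample_mixing_matrix(net$dims$n_s))
  bank <- generate_sources("sine", freqs = freqs, T_samples = 2 * n_t)
  schedule <- structure(list(contexts = context_pair, n_t = n_t,
                             n_contexts = 2L, n_s = net$dims$n_s),
                        class = "context_schedule")
  stream <- mix_stream(bank, schedule, sigma_n)
  fw <- c(n_t + 1, n_t + freeze_duration)
  sim <- simulate_network(net, stream$x, freeze_window = fw)
  dev <- rowMeans(abs(sim$y - stream$s))
  bounds <- rbind(c(1, n_t), c(n_t + 1, n_t + freeze_duration),
                  c(n_t + freeze_duration + 1, 2 * n_t))
  stages <- data.frame(
    stage = c("intact_ctx1", "frozen_ctx2", "intact_ctx2"),
    start = bounds[, 1], end = bounds[, 2],
    mean_deviation = apply(bounds, 1, function(b) mean(dev[b[1]:b[2]]))
  )
  list(traces = sim, stream = stream, stages = stages, freeze_window = fw,
       contexts = context_pair)
}

#' Perturb the modulation units
#'
#' Adds a constant input (`+3` activates, `-3` inactivates by default) to the
#' modulation-unit dynamics of a Dalean model; through the inhibitory sigmoid,
#' positive input lowers the gains. The perturbation enters only the
#' m-dynamics, never the feedforward weights.
#' @param net a dalean [modulated_network()].
#' @param delta additive drive, typically `+3` or `-3`.
#' @param n_contexts,n_t stimulus stream shape.
#' @param sigma_n stimulus noise.
#' @return list with perturbed and unperturbed traces and the stream.
#' @export
manipulate_modulation_units <- function(net, delta = 3, n_contexts = 2,
                                        n_t = 1000, sigma_n = 0.001) {
  if (net$architecture != "dalean")
    stop("modulation-unit manipulation requires a dalean model", call. = FALSE)
  bank <- generate_sources("chord", T_samples = n_contexts * n_t)
  schedule <- build_schedule(n_contexts, n_t, net$dims$n_s)
  stream <- mix_stream(bank, schedule, sigma_n)
  baseline <- simulate_network(net, stream$x)
  perturbed <- simulate_network(net, stream$x, delta = delta)
  list(baseline = baseline, perturbed = perturbed, stream = stream,
       delta = delta)
}
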