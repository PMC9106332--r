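#' Generate clean source signals
#'
#' Builds the multichannel source signals of the dynamic blind source
#' separation task. The default is two "chords", each the sum of two unit
#' sines, sampled at 8 kHz:
#' \deqn{s_1(t) = \sin(2\pi f_{11} t/f_s) + \sin(2\pi f_{12} t/f_s)}
#' with frequencies (100, 125) Hz and (150, 210) Hz. Pure sines, sawtooth and
#' square waves are available as alternative source families.
#'
#' @param waveform one of `"chord"`, `"sine"`, `"sawtooth"`, `"square"`.
#' @param freqs frequencies in Hz. For chords, a list with one numeric vector
#'   of two frequencies per source; for the other waveforms a numeric vector
#'   with one frequency per source.
#' @param T_samples number of samples to generate.
#' @param fs sampling frequency in Hz.
#' @param phases initial phases in radians, matching the structure of `freqs`
#'   (a list for chords, a vector otherwise). Defaults to zero. Exposed so that
#'   training can randomise phases across trials.
#' @return an object of class `source_bank`: a list with `samples`
#'   (`T_samples` x `n_s` matrix), `fs`, `waveform`, `freqs`, `T`.
#' @examples
#' bank <- generate_sources(T_samples = 2000)
#' dim(bank$samples)
#' @export
generate_sources <- function(waveform = c("chord", "sine", "sawtooth", "square"),
                             freqs = NULL, T_samples = 8000, fs = 8000,
                             phases = NULL) {
  waveform <- match.arg(waveform)
  if (T_samples < 1) stop("T_samples must be >= 1", call. = FALSE)
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  if (is.null(freqs)) {
    freqs <- if (waveform == "chord") list(c(100, 125), c(150, 210)) else c(100, 150)
  }
  if (waveform == "chord") {
    if (!is.list(freqs) || !all(vapply(freqs, length, 1L) == 2L))
      stop("chord sources need a list of two frequencies per source", call. = FALSE)
    if (any(unlist(freqs) <= 0)) stop("frequencies must be positive", call. = FALSE)
    n_s <- length(freqs)
    if (is.null(phases)) phases <- rep(list(c(0, 0)), n_s)
    t <- seq_len(T_samples) - 1
    samples <- vapply(seq_len(n_s), function(i) {
      f <- freqs[[i]]; ph <- phases[[i]]
      sin(2 * pi * f[1] * t / fs + ph[1]) + sin(2 * pi * f[2] * t / fs + ph[2])
    }, numeric(T_samples))
  } else {
    freqs <- unlist(freqs)
    if (any(freqs <= 0)) stop("frequencies must be positive", call. = FALSE)
    n_s <- length(freqs)
    if (is.null(phases)) phases <- rep(0, n_s)
    t <- seq_len(T_samples) - 1
    samples <- vapply(seq_len(n_s), function(i) {
      cyc <- freqs[i] * t / fs + phases[i] / (2 * pi)
      switch(waveform,
        sine = sin(2 * pi * cyc),
        # rises linearly from -1 to 1 once per period; sampled at midpoints so
        # the discrete mean over whole periods is exactly zero
        sawtooth = {
          mid <- cyc + 0.5 * freqs[i] / fs
          2 * (mid - floor(mid)) - 1
        },
        square = ifelse(cyc - floor(cyc) < 0.5, 1, -1)
      )
    }, numeric(T_samples))
  }
  structure(list(samples = samples, fs = fs, waveform = waveform,
                 freqs = freqs, T = T_samples),
            class = "source_bank")
}

#' @export
print.source_bank <- function(x, ...) {
  cat(sprintf("<source_bank> %d samples, %d sources, %s waveform, fs = %g Hz\n",
              x$T, ncol(x$samples), x$waveform, x$fs))
  invisible(x)
}

#' Sample a random row-normalised mixing matrix
#'
#' Draws matrix entries uniformly from \[0, 1\], renormalises every row to sum
#' to one (keeping overall stimulus amplitudes comparable across contexts) and
#' rejection-samples until the absolute determinant reaches `det_threshold`,
#' so the mixture is comfortably invertible. For `n_s = 2` the accepted
#' matrices live on a two-dimensional manifold parameterised by
#' `(a, b) = (A[1,1], A[2,1])` with rows `(a, 1-a)` and `(b, 1-b)`, and
#' `det(A) = a - b`.
#'
#' @param n_s number of sources (matrix dimension).
#' @param det_threshold minimum `|det(A)|`; default 0.2.
#' @param max_tries rejection-sampling cap; exceeding it signals an
#'   infeasible threshold.
#' @return an `n_s` x `n_s` matrix of class `mixing_matrix`.
#' @export
sample_mixing_matrix <- function(n_s = 2, det_threshold = 0.2, max_tries = 1e4) {
  if (n_s < 2) stop("n_s must be >= 2", call. = FALSE)
  if (det_threshold < 0 || det_threshold >= 1)
    stop("det_threshold must be in [0, 1)", call. = FALSE)
  for (i in seq_len(max_tries)) {
    A <- matrix(runif(n_s * n_s), n_s, n_s)
    A <- A / rowSums(A)
    if (abs(det(A)) >= det_threshold) {
      class(A) <- c("mixing_matrix", class(A))
      return(A)
    }
  }
  stop("rejection sampling failed after ", max_tries,
       " tries; det_threshold likely infeasible", call. = FALSE)
}

#' Context variables of a 2x2 row-normalised mixing matrix
#'
#' The free parameters after row normalisation: `a = A[1,1]`, `b = A[2,1]`.
#' The map `(a, b) -> A` is bijective on the accepted region, so this inverts
#' [sample_mixing_matrix()] exactly.
#' @param A a 2x2 row-normalised mixing matrix.
#' @return named numeric vector `c(a =, b =)`.
#' @export
context_vars <- function(A) {
  stopifnot(nrow(A) == 2, ncol(A) == 2)
  c(a = A[1, 1], b = A[2, 1])
}

#' Build a schedule of mixing contexts
#'
#' An ordered list of independently sampled mixing matrices, each held constant
#' for `n_t` samples.
#'
#' @param n_contexts number of contexts.
#' @param n_t samples per context (default 1000).
#' @inheritParams sample_mixing_matrix
#' @return class `context_schedule`: list with `contexts`, `n_t`,
#'   `n_contexts`, `n_s`.
#' @export
build_schedule <- function(n_contexts, n_t = 1000, n_s = 2, det_threshold = 0.2) {
  if (n_contexts < 1 || n_t < 1) stop("n_contexts and n_t must be >= 1", call. = FALSE)
  contexts <- replicate(n_contexts,
                        sample_mixing_matrix(n_s, det_threshold),
                        simplify = FALSE)
  structure(list(contexts = contexts, n_t = n_t, n_contexts = n_contexts,
                 n_s = n_s),
            class = "context_schedule")
}

#' @export
print.context_schedule <- function(x, ...) {
  cat(sprintf("<context_schedule> %d contexts x %d samples (n_s = %d)\n",
              x$n_contexts, x$n_t, x$n_s))
  invisible(x)
}

#' Mix sources through a context schedule
#'
#' Produces the noisy sensory stimuli
#' \deqn{x(t) = A(t) s(t) + \sigma_n \xi(t)}
#' where `A(t)` steps through the schedule every `n_t` samples and `xi` is
#' i.i.d. standard Gaussian white noise per sample and channel.
#'
#' @param bank a [source_bank][generate_sources()] covering the schedule.
#' @param schedule a [context_schedule][build_schedule()].
#' @param sigma_n additive noise amplitude (default 0.001).
#' @return class `stimulus_stream`: list with `x`, `s` (both `T` x `n_s`),
#'   `context_index` (per-sample context id), `sigma_n`, `schedule`.
#' @export
mix_stream <- function(bank, schedule, sigma_n = 0.001) {
  T_need <- schedule$n_contexts * schedule$n_t
  if (bank$T < T_need)
    stop("source bank too short for schedule (need ", T_need, " samples)",
         call. = FALSE)
  s <- bank$samples[seq_len(T_need), , drop = FALSE]
  ctx <- rep(seq_len(schedule$n_contexts), each = schedule$n_t)
  x <- matrix(0, T_need, schedule$n_s)
  for (k in seq_len(schedule$n_contexts)) {
    idx <- which(ctx == k)
    x[idx, ] <- s[idx, , drop = FALSE] %*% t(schedule$contexts[[k]])
  }
  if (sigma_n > 0)
    x <- x + sigma_n * matrix(rnorm(length(x)), nrow(x), ncol(x))
  structure(list(x = x, s = s, context_index = ctx, sigma_n = sigma_n,
                 schedule = schedule),
            class = "stimulus_stream")
}

#' @export
print.stimulus_stream <- function(x, ...) {
  cat(sprintf("<stimulus_stream> %d samples, %d channels, %d contexts, sigma_n = %g\n",
              nrow(x$x), ncol(x$x), x$schedule$n_contexts, x$sigma_n))
  invisible(x)
}

#' Signal-to-noise ratio in decibels
#'
#' `10 * log10(sigma_s^2 / sigma_n^2)`, with `sigma_s` the measured standard
#' deviation of the noise-free stimuli and `sigma_n` the noise amplitude.
#' @param sigma_s signal standard deviation (> 0).
#' @param sigma_n noise standard deviation (> 0).
#' @export
snr_db <- function(sigma_s, sigma_n) {
  if (any(sigma_s <= 0) || any(sigma_n <= 0))
    stop("sigma_s and sigma_n must be positive", call. = FALSE)
  10 * log10(sigma_s^2 / sigma_n^2)
}

#' Regular grid of mixing contexts
#'
#' Evenly spaced grid over the context variables `(a, b)` on \[0, 1\]^2
#' (endpoints included), keeping only points with `|det(A)| = |a - b|` at or
#' above the threshold. With 20 points per dimension and threshold 0.2 this
#' leaves exactly 272 contexts.
#'
#' @param n_per_dim grid points per dimension (>= 2).
#' @param det_threshold determinant threshold.
#' @return list with `contexts` (list of 2x2 matrices) and `vars`
#'   (data.frame with columns `a`, `b`).
#' @export
context_grid <- function(n_per_dim = 20, det_threshold = 0.2) {
  if (n_per_dim < 2) stop("n_per_dim must be >= 2", call. = FALSE)
  g <- expand.grid(a = seq(0, 1, length.out = n_per_dim),
                   b = seq(0, 1, length.out = n_per_dim))
  keep <- abs(g$a - g$b) >= det_threshold
  g <- g[keep, , drop = FALSE]
  rownames(g) <- NULL
  contexts <- lapply(seq_len(nrow(g)), function(i)
    matrix(c(g$a[i], g$b[i], 1 - g$a[i], 1 - g$b[i]), 2, 2))
  list(contexts = contexts, vars = g)
}
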