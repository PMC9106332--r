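#' Initialise network and modulator parameters
#'
#' Random initial parameters for a modulated network. Gaussian entries follow
#' the model's initialisation table: `W0 ~ N(1, 0.001)`, `Wx`, `WLx`,
#' `Wro ~ N(0, 0.5)`, `WHL ~ N(1, 0.5) * 20/N_H`, `WIL ~ N(1, 0.5) / N_I`,
#' `WHI ~ N(1, 1) * 20/N_H`; all LSTM weights and biases follow the PyTorch
#' LSTM default, uniform on `(-1/sqrt(N_h), 1/sqrt(N_h))`, and the modulator
#' readout is uniform on
#' `(-1/n_out, 1/n_out)`. The second Gaussian argument is read as a variance
#' by default; set `gaussian_arg = "sd"` for the standard-deviation reading.
#'
#' @param architecture `"simple"`, `"population"` or `"dalean"`.
#' @param dims named list of sizes as produced by [modulated_network()]
#'   (`n_s`, `n_hidden`, `n_out`, and for the larger models `N_z` or
#'   `N_L`/`N_H`/`N_I`).
#' @param gaussian_arg how to read the second argument of the Gaussian
#'   initialisers, `"variance"` (default) or `"sd"`.
#' @return named list of parameter matrices/vectors.
#' @export
init_parameters <- function(architecture, dims, gaussian_arg = c("variance", "sd")) {
  gaussian_arg <- match.arg(gaussian_arg)
  if (!architecture %in% c("simple", "population", "dalean"))
    stop("unknown architecture '", architecture, "'", call. = FALSE)
  dev <- function(v) if (gaussian_arg == "variance") sqrt(v) else v
  gauss <- function(nr, nc, mean, v) matrix(rnorm(nr * nc, mean, dev(v)), nr, nc)
  n_s <- dims$n_s; H <- dims$n_hidden; n_out <- dims$n_out
  n_in <- 2 * n_s
  k <- 1 / sqrt(H)
  par <- list(
    Wi = matrix(runif(4 * H * n_in, -k, k), 4 * H, n_in),
    Wh = matrix(runif(4 * H * H, -k, k), 4 * H, H),
    b  = runif(4 * H, -k, k),
    Wl = matrix(runif(n_out * H, -1 / n_out, 1 / n_out), n_out, H),
    bl = runif(n_out, -1 / n_out, 1 / n_out)
  )
  if (architecture == "simple") {
    par$W0 <- gauss(n_s, n_s, 1, 0.001)
  } else if (architecture == "population") {
    par$Wx <- gauss(dims$N_z, n_s, 0, 0.5)
    par$Wro <- gauss(n_s, dims$N_z, 0, 0.5)
  } else if (architecture == "dalean") {
    par$WLx <- gauss(dims$N_L, n_s, 0, 0.5)
    par$WIL <- gauss(dims$N_I, dims$N_L, 1, 0.5) / dims$N_I
    par$WHL <- gauss(dims$N_H, dims$N_L, 1, 0.5) * 20 / dims$N_H
    par$WHI <- gauss(dims$N_H, dims$N_I, 1, 1) * 20 / dims$N_H
    par$Wro <- gauss(n_s, dims$N_H, 0, 0.5)
  } else {
    stop("unknown architecture '", architecture, "'", call. = FALSE)
  }
  par
}

#' Construct a feedback-modulated feedforward network
#'
#' Builds one of the three model variants together with its LSTM modulator:
#' \describe{
#'   \item{simple}{`y = (M .* W0) x`; the modulator readout (of size `n_s^2`)
#'     is the modulation matrix `M`, optionally low-pass filtered with time
#'     constant `tau`.}
#'   \item{population}{`z = m .* (Wx x)`, `y = Wro z`; `N_FB` feedback signals
#'     are spread over the `N_z` units (arranged on a ring) by a von Mises
#'     kernel, and `m` follows `tau dm/dt = -m + K l`.}
#'   \item{dalean}{a hierarchy `zL -> (zI, zH) -> y` with positive rates,
#'     Dalean inter-population weights (used via absolute values) and an
#'     inhibitory sigmoidal gain `p = 1/(1 + exp(m))` on the higher-level
#'     population.}
#' }
#'
#' @param architecture `"simple"`, `"population"` or `"dalean"`.
#' @param n_s number of sources/stimulus channels.
#' @param n_hidden LSTM hidden units (default 100).
#' @param input_mode which signals the modulator observes: `"x_and_y"`
#'   (default), `"x_only"`, `"y_only"`. Ablated inputs are zero-masked so the
#'   parameter count is unchanged.
#' @param tau modulation time constant in samples. `NULL` (simple model
#'   default) applies the modulator readout instantaneously; the population
#'   and Dalean models require a finite `tau` (default 100).
#' @param N_z,N_FB,sigma_m_sq population-model sizes: units in the modulated
#'   population, number of distinct feedback signals, spatial spread of the
#'   modulation kernel (defaults 100, 4, 0.2).
#' @param N_L,N_H,N_I Dalean population sizes (defaults 40, 100, 20).
#' @param normalize_kernel rescale each kernel row to sum 1 so the modulation
#'   magnitude is independent of `N_FB` and `sigma_m_sq` (default TRUE).
#' @param gaussian_arg passed to [init_parameters()].
#' @return object of class `modulated_network`.
#' @examples
#' set.seed(1)
#' net <- modulated_network("simple", n_hidden = 16)
#' @export
modulated_network <- function(architecture = c("simple", "population", "dalean"),
                              n_s = 2, n_hidden = 100,
                              input_mode = c("x_and_y", "x_only", "y_only"),
                              tau = NULL, N_z = 100, N_FB = 4, sigma_m_sq = 0.2,
                              N_L = 40, N_H = 100, N_I = 20,
                              normalize_kernel = TRUE,
                              gaussian_arg = "variance") {
  architecture <- match.arg(architecture)
  input_mode <- match.arg(input_mode)
  dims <- list(n_s = n_s, n_hidden = n_hidden)
  if (architecture == "simple") {
    dims$n_out <- n_s^2
  } else {
    dims$n_out <- N_FB
    if (is.null(tau)) tau <- 100
    if (architecture == "population") dims$N_z <- N_z
    else { dims$N_L <- N_L; dims$N_H <- N_H; dims$N_I <- N_I }
  }
  if (!is.null(tau) && tau <= 0) stop("tau must be positive", call. = FALSE)
  par <- init_parameters(architecture, dims, gaussian_arg)
  if (architecture == "population")
    par$K <- von_mises_kernel(N_z, N_FB, sigma_m_sq, normalize = normalize_kernel)
  if (architecture == "dalean")
    par$K <- von_mises_kernel(N_H, N_FB, sigma_m_sq, normalize = normalize_kernel)
  structure(list(architecture = architecture, dims = dims, params = par,
                 tau = tau, input_mode = input_mode,
                 N_FB = if (architecture == "simple") n_s^2 else N_FB,
                 sigma_m_sq = sigma_m_sq),
            class = "modulated_network")
}

#' @export
print.modulated_network <- function(x, ...) {
  cat(sprintf("<modulated_network> %s model, n_s = %d, N_h = %d, input = %s, tau = %s\n",
              x$architecture, x$dims$n_s, x$dims$n_hidden, x$input_mode,
              if (is.null(x$tau)) "none" else format(x$tau)))
  invisible(x)
}

# Parameter groups updated by the optimiser: the modulator always; the
# feedforward weights additionally for the Dalean model.
trainable_names <- function(net) {
  base <- c("Wi", "Wh", "b", "Wl", "bl")
  if (net$architecture == "dalean")
    base <- c(base, "WLx", "WIL", "WHL", "WHI", "Wro")
  base
}

input_masks <- function(net) {
  n_s <- net$dims$n_s
  switch(net$input_mode,
    x_and_y = list(mask_x = rep(1, n_s), mask_y = rep(1, n_s)),
    x_only  = list(mask_x = rep(1, n_s), mask_y = rep(0, n_s)),
    y_only  = list(mask_x = rep(0, n_s), mask_y = rep(1, n_s))
  )
}

#' One step of the LSTM modulator
#'
#' Advances the recurrent modulator by one sample: a standard LSTM cell with
#' input, forget and output gates (no peephole connections) followed by a
#' linear readout of the hidden state. This is the reference R implementation
#' of the step that the compiled simulation loop uses internally; stepping
#' from the same state and input is deterministic.
#'
#' @param net a [modulated_network()].
#' @param x_t stimulus vector at the current sample (length `n_s`).
#' @param y_prev network output at the previous sample (length `n_s`);
#'   the closed loop uses the one-step-delayed output.
#' @param state list with hidden and cell state `h`, `c` (zeros if `NULL`).
#' @return list with `feedback` (the readout, length `n_out`) and the new
#'   `state`.
#' @export
modulator_step <- function(net, x_t, y_prev = NULL, state = NULL) {
  p <- net$params
  n_s <- net$dims$n_s
  H <- net$dims$n_hidden
  if (length(x_t) != n_s) stop("x_t must have n_s entries", call. = FALSE)
  if (is.null(y_prev)) y_prev <- rep(0, n_s)
  if (length(y_prev) != n_s) stop("y_prev must have n_s entries", call. = FALSE)
  if (is.null(state)) state <- list(h = rep(0, H), c = rep(0, H))
  msk <- input_masks(net)
  u <- c(msk$mask_x * x_t, msk$mask_y * y_prev)
  a <- drop(p$Wi %*% u + p$Wh %*% state$h) + p$b
  sig <- function(z) 1 / (1 + exp(-z))
  gi <- sig(a[1:H]); gf <- sig(a[(H + 1):(2 * H)])
  gg <- tanh(a[(2 * H + 1):(3 * H)]); go <- sig(a[(3 * H + 1):(4 * H)])
  cn <- gf * state$c + gi * gg
  hn <- go * tanh(cn)
  list(feedback = drop(p$Wl %*% hn) + p$bl, state = list(h = hn, c = cn))
}

#' Forward pass of the simple modulated network
#'
#' `y = (M .* W0) x`: element-wise multiplicative modulation of the baseline
#' weights. With `M` all ones the network is the fixed linear map `W0`.
#' @param net a simple [modulated_network()].
#' @param x_t stimulus vector.
#' @param M current modulation matrix (`n_s` x `n_s`).
#' @export
forward_simple <- function(net, x_t, M) {
  drop((M * net$params$W0) %*% x_t)
}

#' Low-pass filter step for the modulation
#'
#' Forward-Euler step of `tau dM/dt = -M + drive`:
#' `M + (dt/tau) (drive - M)`. With `tau = dt` the filter is transparent.
#' @param M current modulation (any numeric shape).
#' @param drive instantaneous drive (same shape).
#' @param tau time constant in samples (> 0).
#' @param dt Euler step (default 1 sample).
#' @export
step_filtered_modulation <- function(M, drive, tau, dt = 1) {
  if (tau <= 0 || dt <= 0) stop("tau and dt must be positive", call. = FALSE)
  M + (dt / tau) * (drive - M)
}

#' Von Mises modulation kernel on a ring
#'
#' `K[i, j] = exp(cos(z_i - l_j) / sigma_m_sq)` with unit locations
#' `z_i = 2 pi i / N_units` and preferred feedback locations `l_j` evenly
#' spaced on the ring. `sigma_m_sq = Inf` gives a uniform kernel (every unit
#' receives the same modulation). With `normalize = TRUE` each row is rescaled
#' to sum to one so the total drive per unit is independent of the number of
#' feedback signals and of the spread.
#'
#' @param N_units modulated units on the ring.
#' @param N_FB number of feedback signals (columns).
#' @param sigma_m_sq spatial spread (variance) of the modulation; may be `Inf`.
#' @param normalize rescale rows to sum 1 (default TRUE).
#' @export
von_mises_kernel <- function(N_units, N_FB, sigma_m_sq = 0.2, normalize = TRUE) {
  if (N_FB < 1) stop("N_FB must be >= 1", call. = FALSE)
  if (sigma_m_sq <= 0) stop("sigma_m_sq must be positive (or Inf)", call. = FALSE)
  zi <- 2 * pi * seq_len(N_units) / N_units
  lj <- 2 * pi * seq_len(N_FB) / N_FB
  K <- exp(outer(zi, lj, function(z, l) cos(z - l)) / sigma_m_sq)
  if (normalize) K <- K / rowSums(K)
  K
}

#' Euler step of the population modulation dynamics
#'
#' `m + (dt/tau) (K l - m)`: the feedback signals `l` are spread over the
#' population by the kernel `K` and low-pass filtered.
#' @param m current per-unit modulation vector.
#' @param feedback feedback signal vector (length `N_FB`).
#' @param K modulation kernel (`N_units` x `N_FB`).
#' @param tau time constant (> 0).
#' @param dt Euler step.
#' @export
step_population_modulation <- function(m, feedback, K, tau, dt = 1) {
  if (tau <= 0 || dt <= 0) stop("tau and dt must be positive", call. = FALSE)
  m + (dt / tau) * (drop(K %*% feedback) - m)
}

#' Forward pass of the population model
#'
#' `z = m .* (Wx x)`, `y = Wro z`. Unit activities are not constrained to be
#' positive in this variant.
#' @param net a population [modulated_network()].
#' @param x_t stimulus vector.
#' @param m per-unit modulation vector.
#' @return list with `z` and `y`.
#' @export
forward_population <- function(net, x_t, m) {
  z <- m * drop(net$params$Wx %*% x_t)
  list(z = z, y = drop(net$params$Wro %*% z))
}

#' Gain from modulation-unit activity
#'
#' `p = 1 / (1 + exp(m))`: an inhibitory sigmoidal gain, strictly decreasing
#' in the modulation-unit activity and bounded in (0, 1); stronger feedback
#' decreases the gain.
#' @param m modulation-unit activities.
#' @export
gain_from_modulation <- function(m) 1 / (1 + exp(m))

#' Forward pass of the hierarchical Dalean model
#'
#' `zL = [WLx x]+`, `zI = [|WIL| zL]+`,
#' `zH = [p .* (|WHL| zL - |WHI| zI)]+`, `y = Wro zH`. The inter-population
#' weights obey Dale's principle by entering as absolute values; the
#' rectifications keep all rates non-negative.
#' @param net a dalean [modulated_network()].
#' @param x_t stimulus vector.
#' @param p per-neuron gains in (0, 1).
#' @return list with `zL`, `zI`, `zH`, `y`.
#' @export
forward_dalean <- function(net, x_t, p) {
  pr <- net$params
  zL <- pmax(drop(pr$WLx %*% x_t), 0)
  zI <- pmax(drop(abs(pr$WIL) %*% zL), 0)
  zH <- pmax(p * drop(abs(pr$WHL) %*% zL - abs(pr$WHI) %*% zI), 0)
  list(zL = zL, zI = zI, zH = zH, y = drop(pr$Wro %*% zH))
}

#' Effective stimulus-to-output weights at the current operating point
#'
#' The end-to-end linear map implied by the current modulation: `M .* W0` for
#' the simple model, `Wro diag(m) Wx` for the population model, and for the
#' Dalean model the composition of the stage maps linearised through the
#' rectifications active at the supplied operating point `x_t`.
#'
#' @param net a [modulated_network()].
#' @param state list with the current modulation: `M` (simple), `m`
#'   (population) or `p` (dalean), plus `x_t` for the Dalean linearisation.
#' @return `n_s` x `n_s` matrix.
#' @export
effective_weights <- function(net, state) {
  pr <- net$params
  switch(net$architecture,
    simple = state$M * pr$W0,
    population = pr$Wro %*% (state$m * pr$Wx),
    dalean = {
      fw <- forward_dalean(net, state$x_t, state$p)
      DL <- as.numeric(fw$zL > 0)
      DI <- as.numeric(fw$zI > 0)
      DH <- as.numeric(fw$zH > 0)
      JL <- DL * pr$WLx                      # d zL / d x
      JI <- DI * (abs(pr$WIL) %*% JL)        # d zI / d x
      JH <- DH * (state$p * (abs(pr$WHL) %*% JL - abs(pr$WHI) %*% JI))
      pr$Wro %*% JH
    }
  )
}
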