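# Small deterministic model builders shared across test files.

tiny_net <- function(arch = "simple", seed = 11, ...) {
  set.seed(seed)
  defaults <- list(n_hidden = 8, N_z = 10, N_FB = 3, N_L = 6, N_H = 10, N_I = 4)
  args <- utils::modifyList(defaults, list(...))
  do.call(modulated_network, c(list(architecture = arch), args))
}

# A modulator that emits a constant feedback vector regardless of input:
# all LSTM readout weights zero, readout bias = `value`.
constant_modulator <- function(net, value) {
  net$params$Wl[] <- 0
  net$params$bl[] <- value
  net
}

random_stream <- function(n_contexts = 2, n_t = 200, seed = 3, sigma_n = 0.001,
                          waveform = "chord", freqs = NULL) {
  set.seed(seed)
  bank <- generate_sources(waveform, freqs = freqs,
                           T_samples = n_contexts * n_t)
  mix_stream(bank, build_schedule(n_contexts, n_t), sigma_n = sigma_n)
}
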