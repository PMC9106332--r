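# modinvar

Feedback-modulated feedforward networks for dynamic blind source separation.

## The problem

A sensory system often has to produce the *same* output while its input
statistics change — voices at a cocktail party keep their identity while the
speakers move. `modinvar` implements a computational testbed for this kind of
context-invariant processing: two source signals $\vec s(t)$ are observed
only through a time-varying linear mixture

$$\vec x(t) = A(t)\,\vec s(t) + \sigma_n \vec\xi(t),$$

where the mixing matrix $A(t)$ (the *context*) is a random row-normalised
matrix with $|\det A| \ge 0.2$, redrawn every $n_t = 1000$ samples. A
feedforward network with **fixed** weights cannot solve this task across
contexts. The package builds networks whose weights or per-neuron gains are
multiplied by a feedback signal from a recurrent modulator — an LSTM that
observes the stimuli and the network's own (one-step-delayed) output and
must infer the current context online:

$$\vec y(t) = (M(t) \odot W_0)\,\vec x(t), \qquad
  M(t) = \mathrm{LSTM}\big(\vec x(t), \vec y(t-1)\big),$$

plus two biologically richer variants: a population of 100 units on a ring
receiving spatially diffuse gain modulation through a von Mises kernel
($\tau \dot{\vec m} = -\vec m + K\,\vec l$), and a hierarchical Dalean rate
network in which feedback drives inhibitory modulation units and scales
gains $p_i = 1/(1+e^{m_i}) \in (0,1)$. The modulator is trained end-to-end
by backpropagation through time (smooth-L1 loss, Adam at $10^{-3}$, gradient
clipping at 1, feedback-magnitude penalty $10^{-5}$); the BPTT engine is
hand-written RcppArmadillo validated against finite differences.

Analyses included: **signal clarity**
$c_j = \lvert\,|r_{1j}| - |r_{2j}|\,\rvert / (|r_{1j}| + |r_{2j}|)$ per
output channel (≈ 1 for a clean separation, ≈ 0.45–0.5 for the raw mixed
stimuli), cross-context linear decoding of sources and context variables
(R², 272-context grid, quadratic and inverse-matrix decoders), and
invariant-subspace geometry (total-least-squares plane fits in the
readout ⊕ PC1 space, folded angles in [0°, 90°]). Manipulation protocols:
feedback freezing at context switches, ±3 drive to the modulation units,
modulator input ablations, plus unmodulated linear and multilayer controls.

For whom: computational neuroscientists studying gain modulation,
feedback and population codes, and anyone needing a clean, tested
implementation of a dynamic blind-source-separation benchmark with a
trainable closed-loop controller.

## Worked example

Train a scaled-down simple model (LSTM with 64 hidden units, 300-sample
contexts, 1500 batches — a couple of minutes on one CPU) and evaluate it on
20 fresh contexts:

```r
library(modinvar)
set.seed(101)
net <- modulated_network("simple", n_hidden = 64)
fit <- train_modulator(net, training_config(n_batches = 1500, n_t = 300))
ev  <- evaluate_model(fit$net, n_contexts = 20, n_t = 300)
round(c(clarity_y = mean(ev$metrics$clarity_y),
        clarity_x = mean(ev$metrics$clarity_x),
        dev_first = mean(ev$metrics$dev_first_decile),
        dev_last  = mean(ev$metrics$dev_last_decile)), 3)
#> clarity_y clarity_x dev_first  dev_last
#>     0.568     0.377     0.483     0.241
```

The output channels correlate far more cleanly with single sources than the
raw stimuli do (`clarity_y` ≫ `clarity_x`), and the deviation $|y - s|$
spikes right after each context switch (`dev_first`, the first decile of
each context) before the modulator re-infers the mixture and the error
decays (`dev_last`): transient-then-recover, the signature of online
context inference. The same workflow applies to
`modulated_network("population")` and `modulated_network("dalean")`;
`freeze_feedback()`, `manipulate_modulation_units()`, `decode_sources()`,
`decode_context()` and `angle_vs_context_distance()` implement the
population-level analyses. A thin CLI over the same functions is in
`inst/cli/modinvar.R`.

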