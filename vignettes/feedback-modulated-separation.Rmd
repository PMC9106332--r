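---
title: "Feedback-modulated networks for dynamic blind source separation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feedback-modulated networks for dynamic blind source separation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task

`modinvar` studies how a *fixed* feedforward network can perform a
context-dependent computation when a recurrent modulatory system adjusts its
weights or gains from the outside. The testbed is a dynamic variant of blind
source separation: two source signals $\vec s(t)$ are observed only through a
linear mixture

$$\vec x(t) = A(t)\,\vec s(t) + \sigma_n \vec\xi(t),$$

where the mixing matrix $A(t)$ — the *context*, analogous to the positions of
speakers at a cocktail party — is redrawn every $n_t$ samples, and $\vec\xi$
is i.i.d. Gaussian white noise. The network must output $\vec y(t) \approx
\vec s(t)$ across contexts, which requires inverting a mixture it is never
told; a fixed linear readout provably cannot do it for two different
contexts (see `baseline_linear()`).

Default sources are two "chords", each the sum of two unit sines
((100, 125) Hz and (150, 210) Hz at $f_s = 8$ kHz). Contexts are sampled by
drawing matrix entries uniformly from $[0,1]$, renormalising rows to sum to
one, and rejecting draws with $|\det A| < 0.2$ so the mixture stays
comfortably invertible. For $n_s = 2$ a row-normalised matrix is fully
described by the pair $(a, b) = (A_{11}, A_{21})$ and $\det A = a - b$, so the
accepted contexts form a two-dimensional manifold minus a band around the
diagonal. Defaults throughout: $n_t = 1000$ samples per context,
$\sigma_n = 10^{-3}$.

Two distributional details are worth knowing. First, because
$a = u_1/(u_1+u_2)$ for uniform $u_i$, the context variables concentrate near
$0.5$ rather than being uniform; the mean normalised *signal clarity* of the
raw stimuli (the chance reference, see below) therefore comes out slightly
below $0.5$ — around $0.45$ — rather than at the $0.52$ one would get for
uniform $(a,b)$. Second, with unit-amplitude chords and row-normalised
mixtures the noise-free stimulus standard deviation is measured by the code
itself (roughly $0.7$–$1$ per channel, context-dependent); `snr_db()` converts
any measured pair $(\sigma_s, \sigma_n)$ to decibels.

## The three model variants

All variants share the same closed loop: a long short-term memory (LSTM)
modulator with $N_h$ hidden units (forget gates, no peepholes) observes the
stimulus $\vec x(t)$ and the one-step-delayed network output
$\vec y(t{-}1)$, and a linear readout of its hidden state provides the
feedback signals $\vec l(t)$. The one-step delay is our resolution of the
instantaneous (and algebraically circular) textbook definition; it is the
standard closed-loop convention and makes the simulation explicit. The
modulator's hidden and cell states start at zero at every trial or stream
start.

* **Simple model** — `modulated_network("simple")`:
  $\vec y = (M \odot W_0)\,\vec x$ with baseline weights
  $W_0 \sim \mathcal N(1, 0.001)$ and $M$ the $n_s^2$ modulator readouts,
  optionally low-pass filtered, $\tau \dot M = -M + \mathrm{LSTM}(\cdot)$.
  With `tau = NULL` (the default here) the readout *is* the modulation.
* **Population model** — `modulated_network("population")`: the stimuli drive
  $N_z = 100$ units arranged on a ring, $\vec z = \vec m \odot (W_x \vec x)$,
  read out by a fixed $W_{ro}$. A small number $N_{FB} = 4$ of feedback
  signals is spread over the ring by a von Mises kernel
  $K_{ij} = \exp(\cos(z_i^{loc} - l_j^{loc})/\sigma_m^2)$ with spread
  $\sigma_m^2 = 0.2$, and $\tau \dot{\vec m} = -\vec m + K \vec l$ with
  $\tau = 100$ samples. Unit activities may be negative. $\sigma_m^2 = \infty$
  yields spatially uniform modulation.
* **Dalean model** — `modulated_network("dalean")`: a hierarchy with positive
  rates. $\vec z_L = [W_{Lx}\vec x]_+$ ($N_L = 40$),
  feedforward inhibition $\vec z_I = [|W_{IL}|\vec z_L]_+$ ($N_I = 20$), and
  $\vec z_H = [\vec p \odot (|W_{HL}|\vec z_L - |W_{HI}|\vec z_I)]_+$
  ($N_H = 100$). Inter-population weights obey Dale's principle by entering
  as absolute values; $W_{Lx}$ and $W_{ro}$ are unconstrained. Feedback is
  inhibitory gain control: modulation units $\vec m$ follow the same kernel
  dynamics and set gains $p_i = 1/(1+e^{m_i}) \in (0,1)$, so stronger
  feedback *lowers* the gain.

**Kernel normalisation.** The raw von Mises kernel reaches $e^{1/\sigma_m^2}$
(about $e^5$ at the default spread), which couples the modulation magnitude
to $N_{FB}$ and $\sigma_m^2$. By default each row of $K$ is rescaled to sum
to one; the modulator's readout scale can absorb either convention, and the
raw kernel is available via `normalize = FALSE`.

**Filter initialisation.** Filtered modulation states start at
$M(0) = 0$ and $\vec m(0) = 0$ (giving Dalean gains of $0.5$), an unbiased
neutral start that the trial-based training also uses.

## Training

`train_modulator()` unrolls the closed loop over trials of $n_t$ samples
(forward Euler, $\Delta t = 1$ sample) and minimises the smooth-L1
reconstruction loss plus a feedback-magnitude penalty
$\lambda_{out} \sum_{t,j} |l_j(t)|$ with $\lambda_{out} = 10^{-5}$, by full
backpropagation through time (no truncation). Gradients are clipped
elementwise to $[-1, 1]$ and applied with Adam at $\eta = 10^{-3}$
(conventional $\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$).
Batches hold 32 trials, each with a freshly sampled context, and each trial
draws an independent random chunk per source from a 16,000-sample bank, so
source phases vary across trials and the modulator cannot memorise the
sequence. The modulator parameters are always trained; for the Dalean model
the feedforward weights ($W_{Lx}, W_{IL}, W_{HL}, W_{HI}, W_{ro}$) are
trained too. The loss is reduced by the *mean* over time, channels and
trials (a pure rescaling of the learning rate relative to a summed loss,
kept so that $\eta$ is comparable across trial lengths and batch sizes).

Initialisation: Gaussian entries per the table in `init_parameters()` (the
second argument of $\mathcal N(\mu, v)$ is read as a **variance**; a `"sd"`
reading is available via `gaussian_arg`). LSTM weights and biases use the
PyTorch LSTM default $U(-1/\sqrt{N_h}, 1/\sqrt{N_h})$ — we follow the
"framework defaults" description rather than the $1/N_h$ variant, as the
former is what those defaults actually are — and the modulator readout uses
$U(-1/N_{FB}, 1/N_{FB})$.

The gradient engine is hand-written C++ (RcppArmadillo): one fused
forward/backward pass per batch through the LSTM, the modulation dynamics
and the architecture-specific feedforward stages. It is validated in the
test-suite against central finite differences for every architecture.
All randomness (contexts, chunk offsets, noise, initialisation) is drawn
from R's RNG, so a single `set.seed()` makes training bit-reproducible on a
platform.

## Protocols and analyses

* `evaluate_model()` draws fresh contexts, simulates the continuous stream
  (modulator state carried across switches — online inference is the point),
  and reports per-context signal clarity and deviation $|y - s|$.
* **Signal clarity** (`signal_clarity()`): for output $j$ and sources 1, 2,
  $c_j = ||r_{1j}| - |r_{2j}||$, by default normalised by
  $|r_{1j}| + |r_{2j}|$. The normalised variant is the package default; the
  raw variant is exposed via `normalized = FALSE` and both are easy to
  compute. Clarity is measured over whole contexts (onset transients
  included) — only the context decoder excludes transients, using the second
  half of each context, because that is where a stationary average is wanted.
* **Decoding** (`decode_sources()`, `decode_context()`): ordinary least
  squares with intercept, no regularisation; rank-deficient designs fall
  back to the least-norm solution. Source decoding trains one decoder on 10
  contexts × 1000 samples = 10,000 samples and tests on 10 novel contexts.
  Context decoding regresses $(a, b)$ (or the four entries of $A^{-1}$)
  on per-context mean activity over a 20×20 grid of contexts with
  $|a - b| \ge 0.2$ — 272 grid points, endpoints included — with fivefold
  cross-validation; a quadratic feature expansion probes nonlinear context
  codes.
* **Subspace geometry** (`subspace_coordinates()`, `fit_plane()`,
  `plane_angle()`): population activity is projected onto the two
  orthonormalised readout axes plus the first principal component of a
  reference condition *after* removing its readout components (so the three
  display axes are non-redundant; the reference is the first intact-feedback
  stage of the protocol at hand). Planes are total-least-squares fits;
  angles are folded, $\arccos|\cos\theta| \in [0^\circ, 90^\circ]$, since a
  plane's normal has no sign.
* `freeze_feedback()` clamps the modulation variable at its pre-switch value
  for the first half of the new context (default; configurable) while the
  modulator's hidden dynamics continue unseen, then releases it. Pure sine
  sources (100 and 150 Hz, taken from the chord set) are the default for
  this protocol. `manipulate_modulation_units()` injects $\pm 3$ into the
  Dalean m-dynamics only — never the weights.

## What the generator emulates, and what it does not

The synthetic task reproduces the stated study conditions exactly: waveform
families, the context distribution and its determinant filter, context
switching every $n_t$ samples, and Gaussian white stimulus noise. It does
*not* emulate natural signal statistics (speech), convolutive or nonlinear
mixing, observation nonstationarity beyond the context switches, or sensor
dynamics. Passing tests therefore show that the mechanism works under the
idealised mixing model, not that it transfers to natural audio; the trained
modulator is also idiosyncratic to the source family it saw during training
(we deliberately do not test generalisation to qualitatively new sources).

## Problem sizes used by the tests

Full-scale training (10,000–12,000 batches of 32 × 1000-step trials, five
initialisations) is an hours-scale computation. The package's own acceptance
tests instead train scaled-down models chosen once: the simple model with
$N_h = 64$, $n_t = 300$, 1500 batches, and a population model with the same
budget and $\tau = 30$, which preserves the default relative timescale
$\tau / n_t = 0.1$. The behavioural signatures asserted at that scale are
qualitative (loss improvement, output clearer than input by a margin,
transient-then-recover deviations, decoding contrast, freeze-release
phenomenology), not the clarity ceilings a full-scale run reaches. The stimulus-clarity
chance reference is estimated over several hundred random contexts, where
its standard error is a few thousandths.

## Known limitations

* The modulator's internal dynamics are treated as a black box; we analyse
  its effect on the feedforward pathway only.
* Clarity for $n_s > 2$ uses a best-versus-second-best generalisation that
  is a package choice, not an established definition.
* Training at the full published scale is supported but slow on one CPU;
  the examples and tests use the scaled-down configurations above.
* Serialisation uses JSON/CSV text formats; traces of long runs are large
  and better regenerated from the (seeded) configuration than stored.
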