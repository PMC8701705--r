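---
title: "Condensing small clinical networks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condensing small clinical networks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nncondense` implements three ways of shrinking small neural networks for
in-hospital mortality prediction from ICU time series — a hidden-kernel LSTM
cell, quantile-based channel pruning, and post-training 8-bit quantization —
together with everything needed to exercise them end to end: a synthetic
cohort generator, the standard clinical time-series preprocessing pipeline,
the baseline architectures, and training/evaluation harnesses. This vignette
explains the models, the parameters that matter, and the design decisions
taken where more than one reasonable choice existed.

## The prediction task and its preprocessing

The input is an irregular event stream per ICU stay: tuples of
(time in hours, variable, value) over the first 48 hours, plus a binary
in-hospital-mortality label. The pipeline converts each stay into a
model-ready tensor in four steps:

1. **Resampling.** Time is cut into regular bins (default width 1 hour, so
   48 steps). Within a bin, the chronologically last measurement of a
   variable wins. The bin width is a free parameter; 1 hour over the 48-hour
   window is the conventional grid for this task and keeps sequences short.
2. **Imputation.** Empty bins take the most recent observed value of the same
   variable (forward fill) or, before the first observation, a prespecified
   per-variable "normal" value.
3. **Masks and one-hot coding.** Each raw variable gets a binary observation
   mask channel (1 where the bin holds a true measurement, 0 where the value
   is imputed); categorical variables are one-hot encoded per time step. One
   mask bit per *raw* variable is kept even after one-hot expansion, since
   all categories of one variable are observed or imputed together.
4. **Normalization.** Value columns are z-scored with means and SDs computed
   on the *training* split after imputation. A constant column would have
   SD 0; its SD is replaced by 1 so the column normalizes to exact zeros
   rather than dividing by zero. Mask channels are never normalized.

The default roster has 36 raw variables — 34 continuous (twelve named
physiology channels and 22 generic laboratory channels) and 2 categorical
(capillary refill with 2 levels, a banded coma score with 4) — giving
40 value columns + 36 mask channels = **76 model inputs**. The parameter
counts of all bundled architectures are stated at this width. The split
between value and mask channels is configurable through the feature roster;
only the total of 76 is load-bearing for the published counts.

The feedforward model uses the same 76 dimensions collapsed over time:
per value column the mean over truly observed bins (never-observed variables
fall back to their constant imputed, normalized value), and per mask channel
the observed fraction.

**Masking semantics.** The recurrent models start with a masking layer that
skips a time step — carrying hidden and cell state through unchanged — only
when the step's entire input row is zero. Because imputation plus mask
channels make genuinely all-zero rows rare, imputed steps remain visible to
the model; the masking layer matters for padded or deliberately blanked
steps, and the contract (appending all-zero steps never changes the output)
is tested explicitly.

## The three architectures

**Baseline RNN.** masking → LSTM(76→16) → LSTM(16→16) → dropout 0.3 →
dense(16→1, sigmoid). The LSTM cell is the standard one; per gate
$g \in \{f, i, o, c\}$, with $\sigma$ the logistic function and $\odot$ the
elementwise product:

$$
\begin{aligned}
f_t &= \sigma(W_{x,f} x_t + W_{h,f} h_{t-1} + b_f), \quad
i_t, o_t \text{ analogously}, \\
\tilde c_t &= \tanh(W_{x,c} x_t + W_{h,c} h_{t-1} + b_c), \\
c_t &= f_t \odot c_{t-1} + i_t \odot \tilde c_t, \qquad
h_t = o_t \odot \tanh(c_t).
\end{aligned}
$$

An LSTM layer with input width $D$ and $U$ units has $4(D + U + 1)U$
parameters; the baseline model totals $4 \cdot 93 \cdot 16 + 4 \cdot 33
\cdot 16 + 17 = 8081$.

**Hidden-kernel LSTM (hLSTM).** One recurrent layer replaces the two: a
bias-free $U \times U$ "hidden kernel" $H_g$ is inserted between the input
kernel and the recurrent kernel of each gate, with a ReLU between the two
input transformations:

$$
z_g = W_{h,g}\, h_{t-1} + H_g\, \mathrm{ReLU}(W_{x,g}\, x_t) + b_g,
$$

and the rest of the cell is unchanged. The layer costs
$4\big((D + U + 1)U + U^2\big)$ parameters; the full model
$4(93 \cdot 16 + 256) + 17 = 6993$. This wiring is the unique natural
reading of "inserted between the input kernel and the recurrent kernel"
whose count matches the published 6993: giving the hidden kernels biases
would add $4U = 64$ parameters (7057), and placing the ReLU elsewhere
changes nothing countable but breaks the reduction property below. Under
identity hidden kernels and non-negative input-kernel products the hLSTM
pre-activation equals the standard LSTM's exactly, which is tested to
1e-12.

**Feedforward DNN.** dense(76→256, ReLU) → dense(256→128, ReLU) →
dense(128→64, ReLU) → dropout 0.5 → dense(64→1, sigmoid), on the
time-collapsed inputs; $(D+1)U$ parameters per layer, 60,929 in total.

**Initialization.** Glorot-uniform kernels, per-gate orthogonal recurrent
kernels, zero biases with a forget-gate offset of 1 — the ecosystem defaults
for these cells. The forget-gate offset keeps early cell-state gradients
alive; it does not change any parameter count.

**Training.** Adam (learning rate 0.001, $\beta_1 = 0.9$,
$\beta_2 = 0.999$, $\epsilon = 10^{-7}$), binary cross-entropy, batch size 8,
seeded shuffling and inverted dropout, 20 epochs by default, last-epoch test
AUROC reported and a per-epoch history kept for learning curves. The
recurrent forward/backward passes (backpropagation through time, including
the masking skip path) are compiled code; all gradients are verified against
central finite differences in the test suite. Single-threaded seeded runs
reproduce bitwise.

## Channel pruning

Pruning is channel-level: a pruned neuron disappears together with every
connection touching it. The criterion scores neuron $j$ by the **mean
absolute weight over its incoming connections** — for an LSTM unit, the
$j$-th columns of all four gate blocks in both the input and recurrent
kernels (plus the hidden kernels for hLSTM). The signed mean is available
behind a flag (`use_abs = FALSE`) but concentrates near zero and is not the
default.

Per prunable layer, exactly $\lfloor q \cdot \text{width} \rfloor$
lowest-scoring neurons are removed (a strict per-layer quantile, not a
global threshold), with ties broken toward the lowest index for determinism.
At $q = 0.5$ the baseline RNN shrinks from widths (16, 16) to (8, 8):
$4 \cdot 85 \cdot 8 + 4 \cdot 17 \cdot 8 + 9 = 3273$ parameters. The output
head is never prunable.

Surgery removes, per pruned unit: its incoming kernel columns (all four
gates), its bias entries, its recurrent row and column, and its outgoing
row in the next weight-bearing layer. Surviving weights are carried over
bit-identically, and the pruned forward pass is tested against an
independent "zero-out" oracle (the original model with the pruned units'
outgoing connections zeroed).

The schedule is train 1 epoch → prune → train 19 more epochs; both phase
lengths are arguments. The optimizer state restarts after surgery (moment
estimates for removed coordinates are meaningless), and the second phase
advances the seed by one so its shuffles are not a replay of the first
epoch's.

Uniform 50% channel pruning of the (256, 128, 64) feedforward model yields
20,225 parameters by the same closed form; no published figure is asserted
for the pruned DNN.

## Post-training quantization

Weights are quantized per tensor to 8-bit codes: with
$(F_{\min}, F_{\max})$ the tensor's float range and
$\text{scale} = (F_{\max} - F_{\min})/255$,

$$
x_q = \mathrm{round}\!\left(\frac{x - F_{\min}}{\text{scale}}\right)
\in \{0, \dots, 255\}, \qquad
\hat x = F_{\min} + \text{scale} \cdot x_q .
$$

Rounding is half-away-from-zero (stated so the worked examples are exactly
reproducible; e.g. codes of $(0, 1, 2)$ are $(0, 128, 255)$). A constant
tensor degenerates to scale 0 and all-zero codes, which reconstruct the
constant exactly. The round-trip error is at most scale/2 elementwise, and
codes are monotone in the inputs and invariant under positive affine maps of
the whole tensor — all tested properties.

Granularity is per tensor (one range pair per weight matrix or bias vector);
inference is *simulated* quantization — dequantize, then a real-arithmetic
forward pass — because accuracy and storage, not integer throughput, are
what is evaluated. Stored payload is 1 byte per parameter plus 8 bytes of
range metadata per tensor, against 4 bytes per parameter for the float
model: about 25% for any of the bundled models. Weights-only quantization is
the default and what the accuracy comparisons use; a dynamic
activation-quantization mode exists behind a flag for the feedforward model.

## The synthetic cohort generator

Real critical-care data with these characteristics is access-restricted, so
the package ships a generator whose *structure* matches the task: per stay,
one latent severity level per raw variable (standard normal, optionally
correlated through a shared factor, independent by default); observation
times from a per-variable homogeneous Poisson process over the 48-hour
horizon (vitals about hourly, laboratories several times per stay);
continuous observations equal to the latent level plus measurement noise at
0.3 population SDs; categorical observations by thresholding the noisy
latent at equal population quantiles. Labels are Bernoulli with a logistic
probability linear in the latent levels plus Gaussian noise (SD 0.5); the
intercept is solved by bisection so the expected prevalence over the
realized cohort equals the configured 10.9%. The default signal weights put
weight 0.8 on twelve physiology channels and 0.6 on both categorical scores
— a strong, learnable signal chosen so that models of this size plausibly
reach the high-0.8 AUROC range seen on real cohorts of this kind.

Because the label model is linear in the latents, the Bayes-optimal linear
score is known (the generator attaches the latent matrix as an attribute),
which gives the tests a ground truth: calibration of the realized
prevalence, monotonicity of the Bayes AUROC in the signal strength, and so
on.

What the generator does **not** emulate: physiological dynamics within a
stay (latent levels are constant over the 48 hours), inter-variable
correlation structure beyond one optional shared factor, informative
missingness (observation times are independent of severity), unit
conversions, outliers, or ICU transfers. Passing tests therefore demonstrate
that the condensation machinery preserves discrimination on structurally
realistic inputs — not that any model reproduces real-data AUROC values.

## Evaluation scale and numerical choices

The accuracy-preservation checks train every variant on cohorts of 4000
stays (15% held out), for 8 epochs per model (the pruned run as 1 + 7), and
compare medians over three seeds: pruned RNN and hLSTM within 0.03 AUROC of
the baseline RNN, quantized DNN within 0.01 of the float DNN. These sizes
are the package's chosen test scale — large enough that AUROC differences of
a few hundredths are meaningful, small enough to run routinely on one CPU;
the published 20-epoch schedule remains the API default.

Other numerical details, collected in one place:

* AUROC is the Mann-Whitney rank statistic with midranks, so ties get half
  credit; it errors on single-class label vectors and is checked against an
  exhaustive pairwise count.
* Binary cross-entropy clips probabilities to $[10^{-12}, 1 - 10^{-12}]$;
  a non-finite training loss aborts with diagnostics rather than continuing.
* Events exactly at the horizon boundary fall into the last bin; events
  outside $[0, \text{horizon}]$ are rejected.
* Weight containers are JSON with base64-encoded little-endian doubles
  (gate blocks in fixed f, i, o, c order), so reloads are bit-exact; the
  binary payload used for size accounting stores 32-bit floats, or bytes
  plus range metadata for quantized tensors.

## Limitations

The generator's independence and stationarity assumptions make the task
easier than real clinical prediction; absolute AUROC values on synthetic
cohorts say nothing about real-data performance and are only used
relatively, model against model, under identical training. Training is
single-threaded CPU code tuned for clarity and exact reproducibility, not
throughput. Only the three published architectures and the two published
condensation families are implemented; iterative pruning, quantization-aware
training, and integer inference kernels are out of scope.
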