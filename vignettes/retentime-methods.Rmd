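---
title: "Methods: retentive decoder pre-training for healthcare time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retentive decoder pre-training for healthcare time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(retentime)
```

## The model and its assumptions

`retentime` implements a decoder-only generative model for two regimes of
clinical time series: continuously monitored multivariate biosignals and
irregularly-sampled sequences of discrete codes. The token mixer is
multi-head *Retention*: per head,

$$\mathrm{Ret}(X) = (Q K^\top \odot D)\,V, \qquad
  D_{nm} = \begin{cases}\gamma^{\,t_n - t_m} & n \ge m\\ 0 & n < m\end{cases}$$

with rotary phases $e^{i\theta t}$ applied to $Q$ and $K$ (values are not
rotated). The decay mask is causal by construction, so the model is
autoregressive at every layer. The central modelling assumptions are:

* *relevance decays exponentially with elapsed time* — each head has a fixed,
  untrained rate $\gamma_h = 1 - 2^{-5-h}$ (head index $h$ from 0), giving a
  bank of effective memories from ~30 steps up to thousands;
* *periodic structure is a relative-phase phenomenon* — the rotary angles
  $\theta_i = \mathrm{base}^{-2i/d_{head}}$ encode it through
  $\theta (t_n - t_m)$, which is defined for any gap, seen or unseen. This,
  plus the decay, is what lets the decoder forecast beyond the lengths it
  was trained on;
* *irregular sampling is a change of clock, not of mechanism* — replacing
  $n - m$ by $t_n - t_m$ in the mask (and in the recurrent update
  $S_n = \gamma^{\Delta t} S_{n-1} + K_n^\top V_n$) is the entire
  continuous-time extension. On unit gaps it reproduces the integer-grid
  model exactly, which the tests assert to machine precision.

The same layer is evaluated in three forms — parallel, recurrent and
chunk-wise — that are algebraically identical. Training always
differentiates the parallel form; inference may use any. The equivalence
suite holds them to ~1e-15 relative, far inside the 1e-5 contract.

One wrinkle in the recurrence deserves a note: taking the published
base case "$S_1 = 0$" literally would zero the first token's output and
contradict the parallel form at $n = 1$. We initialize $S_0 = 0$, so
$S_1 = K_1^\top V_1$, which keeps all three forms consistent; this is a
deliberate reading, documented rather than silently chosen.

For time-specific queries at a future time $t'$ the state is decayed across
the full gap from the second-to-last event while the last event's
$K_N^\top V_N$ joins undecayed:
$S' = \gamma^{t' - t_{N-1}} S_{N-1} + K_N^\top V_N$. Two consequences are
asserted by tests: a query at the immediate next grid point is *identical*
to trajectory-rollout step 1 (one code path), and as $t' \to \infty$ the
state converges to $K_N^\top V_N$ exactly (the decay underflows to true
zero). After the normalization layers this contraction is no longer
strictly monotone per step in the output probabilities, so the monotonicity
property is asserted at the retention-output level and only overall
convergence at the model level.

## Architecture around the mixer

Continuous input passes through a convolution-subsampling tokenizer: two
causal 1-D convolutions (kernel 3, stride 2, swish between), widths
$V \to d/2 \to d$, then a linear projection. Each layer halves the length
via $T \mapsto \lfloor (T-1)/2 \rfloor + 1$, so 4000 raw timesteps become
exactly 1000 tokens. Padding is left-only everywhere: symmetric padding
would leak future samples into a next-token objective, so causal padding is
the default and the tested configuration. Discrete codes use a learnable
codebook instead; a learned `[SOS]` vector is prepended in both modes, with
a token time preceding the first observation.

Each decoder layer applies, with pre-norm residuals: multi-head retention →
temporal convolution block (layer norm, causal depth-wise convolution,
batch norm, swish, point-wise projection, residual) → position-wise
feed-forward. The feed-forward sublayer is included by default (the
standard decoder block) and can be disabled (`use_ffn = FALSE`) since the
source architecture diagram is ambiguous about it. The forecast head emits
a 4-timestep × V patch per token, matching the 4× subsampling, so raw-
resolution forecasts come out one token step at a time; a transposed-
convolution upsampler was the alternative and the patch head was chosen for
being exactly invertible in the loss (each raw step is predicted once).

Because the decoders are small enough to train on a laptop CPU, the entire
network — forward and backward — is written in base R matrix algebra with
hand-derived gradients, checked against central finite differences to
~1e-7 relative in the test suite. Adam with linear warmup and cosine decay,
global-norm gradient clipping at 1.0, teacher forcing for the next-token
objective. The optimizer and its defaults (peak rate 3e-3, batch 4 by
gradient accumulation) are this package's choices; the source work does not
report its optimizer settings, and no claim of matching them is made.

### Normalization (a genuinely open design point)

The literal retention sum grows with the row mass of $D$, which is
numerically hostile for long sequences and $\gamma \to 1$. We adopt the
retentive-network stabilization: each mask row is divided by its running
decay mass (recurrently, $r_n = \gamma^{\Delta t} r_{n-1} + 1$), and head
outputs are group-normalized per position, identically in all three forms
so the equivalence contract survives. `normalize = FALSE` gives the literal
form, used by the brute-force oracle tests. A swish output gate is
available but off by default, as the source describes none.

### Ablation toggles

`use_subsampling`, `use_temporal_conv`, `use_decay` (γ fixed to 1, causal
mask kept), and `use_rope`. Turning rotation off replaces retention with
causal softmax attention plus *learned* absolute position embeddings — the
GPT-2-style decoder. The position table is finite (`max_positions`, default
1024); rows beyond the training length simply remain at their random
initialization, which is precisely the failure mode that motivates
extrapolatable embeddings. Decay without rotation is rejected at
configuration time (the decay is a component of the rotary-decay scheme).

## Positions for irregular data

Decay always uses real time gaps. For the rotary phase on irregular
sequences, both real timestamps (default, consistent with the decay
semantics) and ordinal indices (`rotate_by_time = FALSE`) are implemented;
in the package's own recall study the choice made no measurable difference,
so the default follows the decay semantics.

## What the synthetic generators emulate — and what they do not

`generate_biosignal()` produces per channel
$\text{slope}\cdot t + \sum_j a_j \sin(2\pi t / p_j + \phi) + \varepsilon$:
trend plus periodicity plus Gaussian noise, the two structures the position
embedding is designed to encode. `generate_event_sequences()` draws, per
patient, homogeneous Poisson arrival times (rate in events per abstract
"day") and codes from a softmax over per-code log-weights in which
designated *trend codes* gain logit linearly over the expected observation
span (age-related susceptibility) and *periodic codes* oscillate with a
relapse period (exacerbation/recovery cycles). Softmax normalization was
chosen over literally-linear weights so the categorical is always valid;
the testable consequence (trend codes concentrate in the last quartile of
each record) holds either way.

Neither generator attempts physiological morphology (ECG waveforms),
code ontologies, state-dependent visit rates, or measurement artifacts.
Passing tests on these data therefore demonstrate that the *mechanisms*
work — causality, continuous-time consistency, extrapolation of planted
trend/periodic structure, recall of a planted relapse cycle above chance —
not that the model reaches any particular accuracy on real recordings.

## Numerical choices

* Decay is computed in log space; exponents below −60 underflow to exact 0,
  so "infinite" gaps forget history exactly rather than approximately.
* Rotary angle base 10000 (the standard schedule); the head width must be
  even for the 2-D rotation pairs.
* Layer/batch norm epsilons 1e-5; group norm 1e-6. Batch norm uses batch
  statistics during training and running statistics elsewhere; a norm-free
  block (`tc_norm = "none"`) exists for strict determinism checks.
* Initialization: scaled Gaussians with output projections shrunk by
  $1/\sqrt{2L}$; uniform codebook; every draw flows from `config$seed`.
* Ranking ties break by code index; AUPRC uses the step-wise threshold
  integral (so constant scores give exactly the prevalence).
* Degenerate inputs fail loudly with classed errors: non-monotone
  timestamps (`ordering_error`), odd head widths and toggle conflicts
  (`config_error`), too-short tokenizer input (`input_error`), malformed
  files with line numbers (`parse_error`).
* Checkpoints are a single RDS archive of config + parameter tensors +
  batch-norm buffers: one file, bit-exact round trip.

## Study designs and problem sizes

The package ships its experiments as functions so results are recomputable
from a seed (`scripts/acceptance.R` drives them):

* **Extrapolation + ablation** (`run_ablation_study()`): per seed, 8
  noiseless trend+seasonal series of length 512 (period 64, slope 0.002,
  random phase), a 2-layer d=32 model per variant, 60 epochs; evaluation
  rolls out from a 256-step prompt on 3 held-out series. Horizon 256 probes
  forecasting up to the training length; horizon 768 keeps the source
  geometry (prompt:horizon 1:3, total span 2× the pre-training length) for
  the length-extrapolation stress. These sizes were chosen to keep a full
  5-seed, 3-variant study inside a few CPU-minutes while leaving the
  qualitative contrasts visible.
* **Irregular recall** (`run_irregular_recall_study()`): 800 training + 50
  held-out patients, vocabulary 50, ~40 events/patient, planted periodic
  codes (relapse 90 days) and trend codes; 8 epochs. The first design used
  60 patients and memorized them — held-out recall *fell* with more
  training; the cohort was scaled until the model had to generalize. Recall
  is scored per patient over the second half of each record, each event
  queried time-specifically at its true timestamp, against the analytic
  chance level $K/\text{vocab}$.
* **Transfer study** (`run_pretrain_transfer_study()`): identical fine-
  tuning budgets from pre-trained versus random trunks; the regime where
  pre-training pays off is scarce labels on a period-defined class — the
  feature a next-token model must internalize anyway.

## Known limitations

* Desk scale. With 2 layers, d = 32 and a handful of sequences, the decay
  ablation reproduces its expected direction (removing decay worsens median
  long-horizon MAE), but the no-rotation (GPT-2-style) variant remains
  competitive — the large separations reported for that ablation arise at
  millions of parameters and orders of magnitude more data than these
  studies use. The ablation harness reports the medians either way.
* The recurrent/chunk-wise forms are forward-only; training always uses the
  parallel form (their equivalence makes this a pure implementation
  convenience).
* Trajectory rollout for the no-rotation ablation has no recurrent form and
  re-encodes the sequence each step (quadratic), which is the honest cost
  of that baseline.
* Continuous prompts whose length is not a multiple of 4 misalign the final
  partial patch with the token grid; studies use multiples of 4.
* The event generator's Poisson clock is memoryless; real visit processes
  are bursty and state-dependent, so recall numbers here bound nothing
  about real EHR data.
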