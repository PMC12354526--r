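---
title: "EEG-based OSA risk screening: model, pipeline, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG-based OSA risk screening: model, pipeline, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegrisk)
```

## The screening problem

Obstructive sleep apnea leaves measurable traces in waking EEG: cognitive
fatigue and working-memory strain appear as suppressed alpha-band (8–12 Hz)
power and elevated theta-band (4–7 Hz) power, and the ~400 ms negative
event-related deflection tied to semantic processing is attenuated.
`eegrisk` treats screening as binary classification of 60-second EEG
windows — high risk vs. low risk — with window labels inherited from the
recording and a secondary subject-level majority vote.

Clinical recordings with trustworthy risk labels are hard to obtain, and
surrogate labels (questionnaire thresholds, behavioral annotation) are not
reproducible from public data. The package therefore ships a synthetic
cohort generator as a first-class, tested component: it realizes exactly
the qualitative class contrast above, so every downstream stage can be
exercised and validated end to end.

## Signal model of the synthetic cohort

Each recording is a channels × samples matrix

$$x_c(t) = \varepsilon_c(t) + a\,g^{\alpha}_c \sin(2\pi f_\alpha t + \phi_c)
          + b\,g^{\theta}_c \sin(2\pi f_\theta t + \psi_c) + \mathrm{erp}(t),$$

with Gaussian broadband noise $\varepsilon_c$ (sd `noise_sd`, default 1),
one narrowband oscillation per band (frequency drawn uniformly inside the
band per recording, phase per channel), fixed opposing spatial gain ramps
$g^{\alpha}, g^{\theta}$ across the montage (so the class contrast is
spatial as well as spectral, giving CSP something to find), and an optional
negative Gaussian-windowed pulse (sd 50 ms) centered 400 ms after each
stimulus onset. For high-risk recordings the alpha amplitude is multiplied
by `risk_alpha_factor` (default 0.5), the theta amplitude by
`risk_theta_factor` (default 1.8), and the pulse by `erp_attenuation`
(default 0.4).

The default cohort — 24 subjects, 8 channels, 128 Hz, 300 s, balanced
classes — is the package's reference study condition; it yields 216
windows of 390 spectrogram features, a size at which the full pipeline
(simulation, preprocessing, three replicate training runs) completes in a
few minutes on one CPU. The effect sizes are free parameters, not
clinically estimated quantities: no published mapping from questionnaire
surrogate labels to EEG structure exists, so they were chosen once so that
the contrast is unambiguous to a spectral oracle yet still requires the
model to learn a multivariate decision rule. Context vectors carry
label-independent nuisance draws plus a noise-profile scalar; they are
deliberately uninformative about the class so that the context pathway is
exercised without leaking labels.

What the generator does **not** emulate: sleep-stage architecture, apnea
event waveforms, ocular/muscular artifacts, 1/f background structure,
inter-channel correlation beyond the gain ramps, and AHI severity grades.
Passing tests therefore demonstrate correctness of the machinery and
learnability of a planted spectral contrast — not clinical performance.

Surrogate labels: `stop_bang_label()` returns high-risk when strictly more
than `threshold` of the 8 STOP-BANG indicators are positive. The default
`threshold = 5` follows the strict "exceeding 5 of 8" reading; common
screening practice uses ≥ 5, available as `threshold = 4`. The rule is
monotone by construction.

## Preprocessing pipeline

The stage order is fixed: band-pass filter → artifact hook → per-channel
standardization → windowing → CSP → STFT → feature standardization, and is
recorded in the run manifest so tests can audit the sequencing.

* **Band-pass 0.5–45 Hz** — 4th-order Butterworth applied
  forward-backward (`signal::filtfilt`), i.e. zero-phase; only the band is
  prescribed, the realization is a package choice. Edge transients of the
  zero-phase filter decay within ~2 s; tests measure interior samples.
* **Artifact hook** — identity. The synthetic data contain no ocular or
  muscular artifacts, so no decomposition is fitted; the hook keeps an
  explicit slot in the stage sequence where a real deployment would clean
  artifacts.
* **Standardization** — each channel to mean 0, population variance 1.
  Constant channels are an error, named in the message.
* **Windows** — 60 s, 50 % overlap, starts at $k\cdot 30$ s; the trailing
  incomplete window is dropped rather than padded (padding would distort
  spectrogram statistics). Windows inherit the recording label.
* **CSP** — class covariances are trace-normalized per window, averaged,
  and ridged by $10^{-6}\,\mathrm{tr}/d$ for numerical stability. The
  filters are generalized eigenvectors of $(\Sigma_1, \Sigma_1+\Sigma_2)$
  computed by whitening + symmetric eigendecomposition, normalized so
  $w^\top(\Sigma_1+\Sigma_2)w = 1$; the bank keeps `m = 3` filters from
  each spectral end. CSP is supervised, so it is fit on training-subject
  windows only.
* **STFT** — Hann window, 1 s frames, 50 % hop, one-sided magnitudes
  scaled by $1/\sqrt{n}$, floored at $10^{-10}$ before the log. Frames are
  stacked time-major with $d = \text{channels} \times (\!n/2+1)$ columns.
* **Feature standardization** — column means/sds computed on the training
  split and frozen for validation/test, preventing leakage.
* **Augmentation** — time/frequency span masking (spans filled with the
  per-column mean, which keeps batch statistics stable; the fill value is a
  package choice) and mixup (convex combination of features and one-hot
  labels, $\lambda \sim \mathrm{Beta}(0.2, 0.2)$). Both are applied by the
  trainer to training batches only; the evaluation path never augments, and
  manifests record the flags.

## Model

For a window $X \in \mathbb{R}^{T\times d}$ with context vector $C$:

1. **Projection + positional encoding.** $F_0 = XW + b$, plus sinusoidal
   codes $P[t, 2k] = \sin(t/10000^{2k/d})$ with the cosine counterpart on
   odd dimensions. The sinusoidal definition only fixes the sine half; the
   default interleaves cosines (the standard construction) and a literal
   sine-only mode is available (`positional_mode = "sine_only"`).
2. **Encoder stack.** Post-norm transformer blocks: multi-head
   self-attention and position-wise feedforward, residual + layer norm +
   dropout after each sub-layer.
3. **Noise suppression.** A learnable odd-width (default 3) 1-D
   convolution along time, shared across features, initialized to the
   identity kernel.
4. **Frame weighting.** $W_t = \mathrm{softmax}(QK^\top/\sqrt{d_k})$,
   $F_w = W_t V$ with learned projections of the cleaned frames. This is
   the stage removed by the acoustic-encoding ablation.
5. **Hierarchical fusion.** Learned query tokens attend over $F_w$
   (temporal focus); the result is enriched with learnable global and
   speaker embeddings, $C_{agg} = \mathrm{LN}(C_{focus} + \alpha S + \beta
   E)$, then $C_{final} = \mathrm{FFN}(C_{agg}) + C_{agg}$.
6. **Acoustic self-attention.** Literal projection-free form
   $A = \mathrm{softmax}(F_w F_w^\top / \sqrt{d})$, $H_{ASA} =
   \mathrm{LN}(A F_w + F_w)$. A flag enables learned projections for
   ablation comparisons, but the default follows the stated form exactly.
7. **Context gate.** $C_{dyn} = \sigma(W_c C + b_c) \odot C$. The gate is
   a contraction ($|C_{dyn}| \le |C|$ elementwise) and monotone in $b_c$.
   The context is a per-recording vector; its shape is otherwise
   unspecified, so the gated vector is linearly projected to model space
   and broadcast across the $T$ frames. Gate dropout applies to the
   sigmoid activations, not to $C$.
8. **Context-aware cross-attention.** $Q$ from the fused states (the
   "linguistic states" role is played by the current fused query states),
   $K$ a projection of $V = H_{ASA} + C_{dyn}$, output
   $\mathrm{LN}(AV + \text{residual})$. When the query count differs from
   $T$, the residual uses the row-mean of $H_{ASA}$ — the same pooling
   rule as the losses.
9. **Head.** Mean-pool → linear → softmax over {low, high}. The published
   task is binary but the decoding head is transcription-shaped; the
   classifier head is the package's explicit resolution, with the
   token-sequence decoder retained (`head_mode = "token_sequence"`) so the
   autoregressive pathway — teacher-forced distributions, cross-entropy,
   beam search — stays fully exercised.

**Losses.** $L = \lambda_1 L_{CE} + \lambda_2 (L_{cons} + L_{CA})$ with
defaults $\lambda_1 = 1$, $\lambda_2 = 0.1$ (no published values; 0.1
keeps the quadratic terms from dominating early training). $L_{cons}$ and
$L_{CA}$ are squared distances between *time-mean-pooled* representations:
the written forms subtract arrays of different shapes ($T\times d$ vs
$N\times d$), and pooling is the minimal consistent resolution. The L1
sparsity penalty on attention weights is implemented literally, but the L1
norm of a row-stochastic matrix is identically $T$ — a constant that
cannot regularize — so its default weight is 0 and an entropy-mode
alternative (0 at one-hot rows, $\log T$ at uniform) is provided for users
who want attention actually sharpened. Both are documented; the intent of
the literal form is not guessed.

**Beam search** keeps `width` hypotheses for a fixed horizon and breaks
log-probability ties toward the lexicographically smaller token sequence,
making decoding fully deterministic; EOS is a vocabulary symbol read at
output rather than an early-termination trigger, which keeps width-1
decoding exactly greedy and an exhaustive beam exactly the brute-force
argmax.

## Training protocol

AdamW (learning rate 3e-4, weight decay 1e-4, $\beta = (0.9, 0.999)$),
cosine annealing $\eta(e) = \frac{\eta_0}{2}(1 + \cos(\pi e / 100))$ with
$\eta_{\min} = 0$ and no warm restarts, batch size 64 (128 supported),
dropout 0.2 after each sub-layer, early stopping on validation loss with
patience 10 and `min_delta` 1e-4 (the mechanism is prescribed, the
constants are package choices), and three replicate runs with seeds
`base_seed + 0, 1, 2` aggregated as mean ± sample sd (ddof = 1; a single
run reports sd 0 with a flag). Everything — initialization, shuffling,
dropout, augmentation — derives from the run seed, and reruns are
bit-identical.

Splits are subject-level and stratified by class; windows from one subject
never straddle splits (asserted). Evaluation uses a single held-out subject
split per run rather than cross-validation: the reference protocol
mentions averaging over test folds without specifying fold count or
stratification, and at 24 synthetic subjects a fixed stratified split is
the more transparent choice. Mixed-precision training is ignored — the
artifact targets CPUs and is numerically irrelevant at this scale. A
`load_checkpoint()` + `train_once()` path allows load-then-finetune, but
the package trains from scratch and makes no transfer-learning fidelity
claims (the reference pre-training corpora are out of scope).

**Ablations** map component names to concrete removals: acoustic-encoding
→ bypass the frame-weighting attention; linguistic-decoding → set
$\lambda_2 = 0$ (drop both quadratic alignment objectives);
contextual-adaptation → bypass the gate and use the raw context. The
harness trains the full model plus the three removals and emits a four-row
table. With the gate bypassed the forward pass is provably independent of
$W_c, b_c$ (verified by parameter perturbation), and with $C \equiv 0$ the
context path is severed entirely.

**Gradients** come from a reverse-mode autodiff tape written in the
package (R has no installed automatic-differentiation framework): ~20
matrix operations with hand-derived vector-Jacobian products, validated
per-op and end-to-end against central finite differences at 1e-4 relative
tolerance. The tape also exposes the attention maps for inspection.

## Numerical choices

Layer-norm stabilizer $10^{-6}$ (population variance); spectrogram floor
$10^{-10}$ pre-log; probability clamp $10^{-12}$ in cross-entropy (with a
warning when hit); CSP shrinkage $10^{-6}\,\mathrm{tr}/d$; fan-in-scaled
uniform initialization for projections, ones/zeros for norm affines,
identity kernel for the convolution, 0.1 for the fusion scalars; EDF
export quantizes to 16 bits against an outward-rounded physical range so
round-trip error stays within half a least-significant bit; per-subject
sub-seeds are derived as `(20011*seed + 7919*i) mod 2147483629` so they
stay in 32-bit range and subjects are reproducible independently of roster
order.

## Known limitations

* Synthetic-only validation: the planted contrast is far cleaner than
  clinical EEG; reported metrics characterize the machinery, not clinical
  accuracy.
* Single held-out split per run, not cross-validation.
* The context vector is label-independent by construction, so the context
  pathway's *benefit* is not demonstrated on the default cohort — only its
  correctness and its ablation behavior.
* The token-sequence decoder is exercised (forward, losses, beam search)
  but not trained by the classifier-mode harness.
* EDF export is limited to integer sampling rates and whole-second
  records; the RDS container is the lossless path.
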