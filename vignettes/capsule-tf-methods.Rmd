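---
title: "Methods: capsule-network classification of transcription factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: capsule-network classification of transcription factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Transcription factors (TFs) are sequence-specific DNA-binding proteins that
switch target genes on or off. `capstf` classifies a protein as TF or non-TF
from its amino-acid sequence alone, with no hand-designed features. The model
is a five-stage stack:

1. **Embedding.** Each residue token $x_i$ is mapped to a dense vector
   $\hat{x}_i = W_e x_i$ through a learned lookup table
   $W_e \in \mathbb{R}^{|V| \times k}$. The padding row of $W_e$ is frozen at
   zero.
2. **Bidirectional LSTM.** A standard gated recurrence, run in both
   directions. At step $t$, with input $x_t$ and previous hidden state
   $h_{t-1}$:
   $f_t = \sigma(W_f [h_{t-1}, x_t] + b_f)$,
   $i_t = \sigma(W_i [h_{t-1}, x_t] + b_i)$,
   $\tilde{C}_t = \tanh(W_c [h_{t-1}, x_t] + b_c)$,
   $C_t = f_t \odot C_{t-1} + i_t \odot \tilde{C}_t$,
   $o_t = \sigma(W_o [h_{t-1}, x_t] + b_o)$,
   $h_t = o_t \odot \tanh(C_t)$.
   The per-position output is the concatenation of the forward and backward
   hidden states (width $2h$).
3. **Capsule layer with dynamic routing.** The $L \times 2h$ encoder output is
   cut into $N_{in}$ input capsules $v_i$ of width $d_{in}$ (by default
   $d_{in} = 2h$: one capsule per sequence position). Prediction vectors are
   $\hat{u}_{j|i} = W_{ij} v_i$. Routing iterates, $r$ times: couplings
   $c_{ij}$ from a softmax over routing logits $b_{ij}$ (initialized at zero);
   $s_j = \sum_i c_{ij} \hat{u}_{j|i}$; the squashing nonlinearity
   $a_j = \frac{\lVert s_j \rVert^2}{1 + \lVert s_j \rVert^2}
   \frac{s_j}{\lVert s_j \rVert}$; and, except after the final iteration, the
   agreement update $b_{ij} \leftarrow b_{ij} + a_j \cdot \hat{u}_{j|i}$.
4. **Dense head.** The flattened output capsules pass through three fully
   connected layers (ReLU between, sigmoid output) to a probability
   $p_{TF} \in (0,1)$; class TF iff $p_{TF} \ge 0.5$.
5. **Ablation variant.** With `model$use_capsule = FALSE` the capsule stage is
   replaced by mask-aware mean pooling of the encoder outputs over the real
   (non-padded) positions — the minimal-surgery bypass, leaving the dense head
   unchanged.

Training minimizes binary cross-entropy with Adam; forward and backward
passes (including backpropagation through the unrolled routing loop) are
implemented from scratch in compiled code and verified against central finite
differences in the test suite.

## Design choices in detail

Several aspects of this architecture family are conventionally
under-specified; the package fixes each one explicitly and exposes it in
`capstf_config()`:

* **Squashing form.** The standard
  $\lVert s\rVert^2/(1+\lVert s\rVert^2)$ length factor is the default: it is
  the form consistent with "long vectors shrink to a length slightly below 1"
  (the norm approaches 1 as $\lVert s\rVert \to \infty$). The alternative
  $\lVert s\rVert/(1+\lVert s\rVert^2)$ reading, whose norm peaks at 0.5, is
  available as `model$squash_variant = "norm1"`.
* **Coupling softmax axis.** The capsule-network convention normalizes
  couplings over *output* capsules for each input ($\sum_j c_{ij} = 1$); that
  is the default. The literal per-output normalization over inputs
  ($\sum_i c_{ij} = 1$) is available as `model$softmax_axis = "input"`. Both
  satisfy the coupling-sum invariant on their own axis at every iteration.
* **Routing iterations.** $r = 3$, the usual choice for dynamic routing;
  configurable, $r \ge 1$.
* **Capsule geometry.** One input capsule per sequence position
  ($d_{in} = 2h = 128$, $N_{in} = L = 500$), $N_{out} = 8$ output capsules of
  width $d_{out} = 16$, flattened to a 128-wide feature vector. With these
  defaults the capsule feature width equals the pooled-encoder width, so the
  ablation differs from the full model by exactly the capsule transform
  tensor ($N_{in} N_{out} d_{in} d_{out}$ = 8,192,000 parameters).
* **Dense head.** $128 \to 64 \to 16 \to 1$.
* **Token unit.** Single residues by default (a closed 22-token vocabulary:
  20 amino acids + padding + unknown), which keeps the model trainable on
  small corpora; overlapping 3-mers are available (`token$unit = "kmer3"`)
  for experiments with a compositional unit.
* **Windowing.** Inputs are fixed at $L = 500$ residues: the first $L$
  (upstream, default), centred $L$ (start offset $\lfloor (n-L)/2 \rfloor$),
  or last $L$ (downstream). Shorter sequences are right-padded; padded
  positions carry the zero embedding through the recurrence and are excluded
  from the ablation's pooling mask.
* **Classification threshold** 0.5, inclusive.

### Numerical and optimization choices

* Glorot-uniform initialization; forget-gate biases start at $+1$ (a standard
  recurrent-network stabilizer); the padding embedding row is zero and
  receives no gradient.
* Adam (`learning_rate = 3e-4`, $\beta_1 = 0.9$, $\beta_2 = 0.999$) with
  global gradient-norm clipping at 5. The default rate was chosen for
  stability of the large capsule transform: at `1e-3` the 8.2M-parameter
  default model is prone to long chance-level plateaus and collapses out of
  early progress, while `3e-4` descends steadily.
* Early stopping on a stratified 10% validation slice with patience 15;
  the best-validation parameters are restored. `epochs = 40` by default.
* The squashing function and its derivative are guarded at the origin
  (zero maps to zero; the standard variant's Jacobian vanishes there).
* BCE probabilities are clamped at $10^{-12}$ from the boundaries; a
  non-finite loss aborts training with a diagnostic rather than continuing.
* Ties in the AUC are handled by the Mann–Whitney convention (1/2 credit);
  a degenerate MCC denominator reports 0 with a warning flag.

## The synthetic benchmark

Real TF/non-TF collections are external downloads, so the package ships a
generator (`synth_config()`, `generate_dataset()`) that emulates the
*structure* of the classification problem:

* **Lengths** follow a log-normal law (meanlog $\log 536 - 0.32$, sdlog 0.8)
  truncated by resampling to $[51, 4834]$ — matching the minimum, mean
  (≈ 536) and maximum of curated TF sequence lengths, with the right skew
  typical of protein lengths. Truncation mass is below 1%, so the mean is
  essentially unshifted.
* **Negatives** are i.i.d. draws from a residue background (uniform by
  default; a composition-biased "swissprot" preset is included).
* **Positives** additionally carry each configured motif exactly once,
  planted by *replacement* (length law stays exact), with each motif residue
  independently resampled from the background with probability `noise_rate`.
* **Motif placement** defaults to `first_k` with $k = 500$: the class signal
  is confined to the region covered by the default upstream-500 window, so
  the default benchmark is well-posed for the default model. With
  `"anywhere"` and the long-tailed length law, a fraction of positives would
  carry their motif outside *every* 500-residue window and the Bayes error
  would be bounded away from zero — that regime remains available for
  windowing experiments.

The default "easy" regime (one intact 9-mer, `noise_rate = 0`) is linearly
separable in motif presence; a 3-mer at `noise_rate = 0.5` is a near-chance
"hard" regime. What passing tests on this generator do **not** show: real TF
sequences have homology structure, domain grammar and composition biases that
i.i.d. background + one planted motif does not emulate, so synthetic accuracy
says nothing quantitative about accuracy on curated TF data.

## Problem sizes used by the checks

The test suite validates the numerics (routing, LSTM, squashing, gradients)
on small random instances against explicit-loop oracles, and exercises
training contracts on a scaled-down model (window 120, hidden size 8, 4×8
capsules) where a run takes seconds. The end-to-end study — the package's own
choice of study size — trains the *default* model on 200+200 synthetic
sequences with a 9-mer motif and evaluates on 100+100 held-out sequences,
expecting ≥ 0.95 held-out accuracy for the capsule model; the same run drives
the capsule-ablation comparison. `scripts/acceptance.R` repeats that study
from scratch at the same sizes and also reconstructs the published benchmark
row's accuracy and MCC from its printed sensitivity/specificity at 106+106
test sequences (TP = 97, FN = 9, TN = 90, FP = 16), which pins down the
standard MCC denominator.

## Known limitations

* Dynamic routing is quadratic in capsule counts and dominates inference
  cost; the implementation is single-threaded apart from BLAS.
* Training-time behaviour on very long proteins is governed entirely by the
  window; residues outside the chosen 500-residue window are invisible to the
  model.
* The optimizer landscape of the large capsule transform is rough at this
  training-set scale: different seeds can converge at different speeds, which
  is why the default budget is 40 epochs with patience 15 rather than a
  minimal schedule.
* `kmer3` mode builds its vocabulary from the training corpus only; unseen
  3-mers at test time map to the unknown token.
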