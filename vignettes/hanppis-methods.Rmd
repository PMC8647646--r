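---
title: "Hierarchical attention networks for interaction-site prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical attention networks for interaction-site prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hanppis)
```

## The problem

A protein–protein interaction (PPI) site is a residue whose solvent
accessibility changes when the protein binds a partner. Identifying these
residues experimentally is slow; sequence-based predictors instead score
each residue of a protein from features computable (or precomputable) from
sequence alone. The task is a residue-level binary classification with a
heavy class imbalance — roughly 5.5 non-site residues per site residue in
the benchmark collections this model family is trained on.

`hanppis` implements a two-level hierarchical attention network for this
task: the residue is the "word", a short K-mer of the surrounding window is
the "sentence", and the whole sliding window is the "document". Both levels
use a bidirectional GRU encoder followed by attention pooling, and the
attention weights double as interpretability scores.

## Input features

Each residue is encoded as six blocks, fused into a single vector:

| block | width | content |
|---|---|---|
| `one_hot` | 20 | residue identity over `ACDEFGHIKLMNPQRSTVWY`; nonstandard residues (X, B, Z, U, O) are all-zero |
| `pssm` | 20 | PSI-BLAST log-odds, squashed by the logistic `1/(1+e^{-x})` into (0,1) |
| `ss9` | 9 | secondary structure: one-hot over G, H, I, B, E, T, S and an "other" bucket, plus a ninth presence flag |
| `hydropathy` | 1 | Kyte–Doolittle free-energy-of-transfer scale; unknowns map to 0 |
| `rel_pos` | 1 | 1-based position divided by protein length, in (0, 1] |
| `embedding` | 50 | a 1024-dimensional pre-trained per-residue embedding, projected to 50 by a trained affine + rectifier layer |

The fused width is therefore 20+20+9+1+1+50 = 101 under defaults. Design
choices worth stating:

* **Hydropathy scale.** The Kyte–Doolittle table is the field's default
  free-energy-of-transfer scale; any named numeric vector can be
  substituted via the `scale` argument of `hydropathy()`.
* **PSSM squashing.** Raw PSI-BLAST log-odds are unbounded integers; the
  logistic map bounds them in (0,1) and is monotone, so ordering
  information is preserved. `parse_pssm(..., scale = FALSE)` exposes the
  raw values.
* **Secondary-structure absence.** DSSP omits residues it cannot assign;
  those get the all-zero 9-vector (flag 0). DSSP's blank (coil) code is an
  *assigned* state and lands in the "other" bucket with flag 1.
* **Embedding provider.** Running a protein language model is outside this
  package's scope, so embeddings come from a pluggable provider: either
  precomputed per-protein tables (`file_embedding_provider()`) or a
  deterministic hash expansion of the residue character
  (`hash_embedding_provider()`). The hash provider is a pure function of
  (residue, seed), which makes every pipeline stage reproducible without
  stored model weights; it carries residue identity but, unlike a real
  language model, no context information.

## Fragments and K-mers

For each residue we extract an odd-length window (default `w = 7`) centred
on it. Windows overhanging the sequence ends are padded with zero-feature
rows and an explicit mask; masked positions are forced to exactly zero
attention (their scores are set to negative infinity before the softmax),
and the recurrent encoders copy the hidden state across them. The window
is segmented into consecutive non-overlapping K-mers (default `k = 3`, so
a 7-window gives chunks of 3+3+1). A K-mer consisting entirely of padding
is skipped at the residue level and masked at the K-mer level. Proteins
longer than `max_len = 500` are truncated; the truncated length is also the
denominator of the position feature.

The train/test split is performed at the protein level (default 80/20,
seeded), never at the fragment level, so no protein contributes fragments
to both partitions.

## The network

Per fragment, with fused inputs $x_1,\dots,x_w$:

1. **Residue level.** Each K-mer's rows are encoded by a bidirectional GRU
   (update gate $z$, reset gate $r$, candidate $\tanh$; hidden size
   $u = 86$ per direction), giving $h_t \in \mathbb{R}^{2u}$. Attention
   pooling computes $s_t = u_1^\top \tanh(W_1 h_t + b_1)$,
   $\alpha = \mathrm{softmax}(s)$, and the K-mer vector
   $v = \sum_t \alpha_t h_t$.
2. **K-mer level.** The K-mer vectors are encoded by a second Bi-GRU of
   the same hidden size and pooled by a second attention head into a
   fragment vector.
3. **Output.** An affine layer and a two-way softmax yield
   $p(\text{site})$.

The loss is the mean cross-entropy with the positive class weighted by 7
(the published "about 1:7" sample weighting against the ~1:5.5 imbalance);
probabilities are clipped at $10^{-7}$ so the loss stays finite.
Optimization is Adam
($\theta \leftarrow \theta - \alpha\,\hat m/(\sqrt{\hat v}+\varepsilon)$)
with $\alpha = 10^{-3}$, $\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\varepsilon = 10^{-8}$, batch size 3.

Choices made where the design was genuinely open:

* **Recurrent cell.** The architecture description and figure specify a
  Bi-GRU while the training-settings prose mentions LSTM units; the
  architecture section governs, and only the GRU cell is implemented (the
  `cell` configuration field exists and validates this).
* **Output head.** A 2-unit softmax rather than a single sigmoid, matching
  the "softmax for classification" description; the two are equivalent in
  expressive power.
* **Projection nonlinearity.** The embedding projection is a single
  feed-forward layer; a rectifier is used and the layer is trained jointly
  with the rest of the network.
* **Initialization.** Seeded Glorot-style uniform draws
  ($\pm\sqrt{6/(\text{fan}_{in}+\text{fan}_{out})}$) for weights, zeros
  for biases.
* **Epochs and early stopping.** Defaults are 10 epochs with patience 3 on
  validation F1, measured on a protein-level 10% carve-out of the training
  partition. On window-local tasks the model converges within a handful of
  epochs, so a larger epoch budget buys nothing at these problem sizes;
  both knobs are configurable.
* **Decision threshold.** 0.5 by default, configurable; it affects every
  confusion-matrix metric.
* **K-mer scheme.** Non-overlapping chunks of `k = 3`. The window's center
  residue falls in the middle K-mer for `w = 7`, matching the published
  center-heavy K-mer attention pattern; `k` is configurable.

## Implementation and numerics

The forward and backward passes are implemented twice: a pure-R reference
(`bigru_encode()`, `attention_pool()`, and an internal full forward) and a
compiled RcppArmadillo backend used for training and batch prediction. The
test suite asserts the two paths agree to 1e-12 and that the analytic
gradient of the full forward + weighted loss matches central finite
differences to a relative error below 1e-4 on a small network — the
standard correctness oracle for hand-derived backpropagation. Softmaxes
subtract the row maximum before exponentiation; attention logits of masked
positions are $-\infty$, giving exactly zero weight rather than a small
one. Training, batching, initialization and the protein split all draw
from seeded generators, so a (data, configuration, seed) triple reproduces
results bit-for-bit.

## The synthetic-data generator

The generator emulates the *structure* the model assumes, not real
biology. Sequences are drawn from a background composition (uniform by
default); a short motif (default `KDY`) is planted at seeded
non-overlapping positions at a rate chosen so the realized non-site:site
ratio matches the 5.5:1 target; accidental motif occurrences arising in
the background are mutated away. A residue is labeled 1 exactly when it
sits at the configured `site_index` of a planted occurrence — by default
the motif's central residue. Features come from
`synth_feature_source()`: the PSSM is the logistic of a scaled one-hot
pattern plus Gaussian noise, secondary structure is a seeded categorical
with occasional absences, and embeddings come from the hash provider.

Because the label is an exact function of the local window, the task is
learnable by construction with a 7-residue window — this is what makes the
end-to-end training checks meaningful. What passing those checks does
*not* show: performance on real PSSM/DSSP/language-model features, where
the signal is distributed, noisy and only partially local. A `motif =
NULL` mode draws labels independently of sequence as a negative control
(nothing should be learnable there beyond the base rate).

The default acceptance-scale conditions are 200 proteins of length 50
with noise-free features — about 10,000 residue fragments, a size at which
full training runs in a few minutes on one CPU; the generator defaults
otherwise emulate the benchmark corpus structure (lengths 50–500,
imbalance 5.5:1).

## Attention-based interpretability

`explain_attention()` reruns a forward pass for a chosen residue and
reports both attention levels; `mean_attention()` averages them over a
dataset partition. One subtlety is worth understanding before reading
attention weights as importance: because the K-mer level uses a
*bidirectional* encoder, every encoded K-mer state contains information
from the whole fragment, so the attention head can in principle place its
mass on any K-mer and still classify perfectly. Empirically, when the
label-determining motif lies entirely inside the central K-mer
(`site_index = 1` with the default geometry puts the planted motif at
window positions 4–6, exactly the middle K-mer), trained models
concentrate K-mer-level attention on that K-mer in the large majority of
runs, reproducing the published center-heavy pattern — but not in every
run: occasionally the attention head drifts toward a flanking K-mer in
the first epoch and is reinforced there, since the classification loss
cannot distinguish the two placements. Placement is decided early and
stays fixed through further training. When the motif straddles a K-mer
boundary, the preferred K-mer varies with the seed far more often. The
package therefore asserts only ordering properties (central exceeds
flanks under the within-central-K-mer design), not specific weight
magnitudes, which are a property of one trained parameter set rather
than of the method — and even the ordering should be read as a
strong-majority behaviour over training runs, not a certainty.

## Known limitations

* Real-data performance is not evaluated here: the benchmark corpora,
  PSI-BLAST profiles against NR and language-model embeddings are external
  inputs. The package parses their formats and the pipeline runs end to
  end on synthetic stand-ins.
* Single-threaded, one-fragment-at-a-time recurrence; adequate for desk
  scale (minutes for 10⁴ fragments), not for corpus-scale sweeps.
* The GRU is the only recurrent cell implemented.
* Homology-aware splitting is out of scope; the protein-level split
  assumes the input collection is already redundancy-reduced.
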