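---
title: "Methods: attentive multimodal graph convolution for bipartite link prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attentive multimodal graph convolution for bipartite link prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `ammgc`, the choices made
where the design was genuinely open, the synthetic data generator used to
test it, and the method's observed behavior at small sample sizes.

## Model

### Graph and features

Known miRNA–drug resistance associations form a binary matrix `B` (drugs in
rows). The model operates on the bipartite graph with adjacency
`A = [[0, B], [Bᵀ, 0]]`, symmetric-normalized with self-loops:
`Â = D̃^(-1/2)(A + I)D̃^(-1/2)`. Self-loops are added to *all* nodes,
including isolated ones, which therefore keep an identity-like row and pass
their own features through unchanged; every degree is at least 1, so the
normalization is always defined. The spectrum of `Â` lies in `[-1, 1]`,
which keeps repeated propagation non-expansive.

Two drug feature blocks (binary substructure fingerprints; integer
label-encoded SMILES) and two miRNA feature blocks (expression profiles;
GO-derived similarity scores) are combined pairwise into four *modal*
inputs `X^1 = [X_d1; X_m1]`, `X^2 = [X_d1; X_m2]`, `X^3 = [X_d2; X_m1]`,
`X^4 = [X_d2; X_m2]`. Within a modal the two blocks rarely share a width,
so the narrower block is padded with zero columns *prepended in front*
(e.g. 748 leading zeros bring a 172-wide expression block up to the
920-wide fingerprint block). A consequence worth knowing: the trailing
columns of the wider block share first-layer weights with the narrower
block's columns. Padding is a fixed convention, not a learned alignment.

### Encoder and scores

Each modal has an independent two-layer graph convolutional encoder

```
E^u = ReLU( Â · ReLU( Â X^u W₀ ) · W₁ )
```

with hidden width `h1` and embedding width `d`. The per-modal association
score is `sigmoid(E^u_i · E^u_{p+j})`. Because both layers end in ReLU, all
embeddings are non-negative and all first-stage logits are `≥ 0`: modal
scores live in `[0.5, 1)` and ranking, not calibrated classification, is
the meaningful output of this stage.

The attention stage learns one vector per modal, `g^u = W_u E^u + b_u`,
with `W_u` deliberately reduced to a `1 × (p+q)` row and `b_u` to `1 × d`,
and fuses the modals by dimension-wise rescaling and concatenation,
`Z = ‖_u E^u diag(g^u)`; the final score is `sigmoid(Z_i · Z_{p+j})`. The
attention vectors are used raw — no softmax or other normalization — so
they can be negative, which is the only mechanism by which fused logits can
drop below zero. `export_attention_coefficients()` tabulates `|g^u|` per
modal and dimension for heatmap-style inspection of modal contributions.

### Two-step training

1. **Modal stage.** Each sub-network minimizes binary cross-entropy over
   the training positives plus `neg_ratio` times as many negatives drawn
   uniformly without replacement from the zero pairs, *resampled every
   epoch* with fixed size. Full-batch Adam, learning rate 0.01.
2. **Attention stage.** The four embedding matrices are frozen (no
   gradient reaches the GCN weights) and only `(W_u, b_u)` are trained,
   under class-weighted cross-entropy over *all* `p·q` pairs except
   held-out test pairs, the positive term multiplied by
   `pos_weight = (p·q − N)/N` where `N` is the number of *training-fold*
   positives. Using the training-fold count (rather than the full-dataset
   count) keeps the weight leakage-free; with ~4% fill the two differ by
   under 1%. Joint fine-tuning through both stages is not offered — the
   frozen-embedding contract is what makes the attention coefficients
   interpretable as weights over fixed representations.

Sub-sets of modals (`modals =`) and unit attention (`use_attention =
FALSE`, equivalent to fusing with all `g^u = 1`, i.e. plain concatenation)
reproduce the standard ablations; the unit-weight path is exactly the
unweighted concatenation model, an identity the test suite asserts.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `learning_rate` | 0.01 | Adam step size, both stages |
| `epochs` | 200 | full-batch epochs per stage |
| `neg_ratio` | 1 | negatives per positive in the modal stage |
| `h1` | 128 | first GCN layer width |
| `d` | 64 | per-modal embedding width (fused width `4d = 256`) |
| `layers` | 2 | GCN depth (1–6 supported for sweeps) |

The `h1 = 128`, `d = 64` defaults target full-scale data (hundreds of
nodes); the fused width is then 256. The two-layer depth is the shipped
default because one layer under-propagates and deeper stacks over-smooth.
For the packaged 70-node synthetic studies every example in this package
uses `h1 = 32`, `d = 16` — widths scaled to the graph — which is also what
the test suite and the acceptance script use. Epoch counts are a genuinely
open choice (no convergence criterion is built in); 200 is enough for the
loss to plateau at either scale, and the small-sample section below
explains why *more* is not better here.

## Numerical choices

- Losses are computed in logit form with a stable softplus
  (`log1p(exp(-|z|)) + max(z, 0)`), mathematically identical to the
  sigmoid/log composition but immune to overflow; divergence (non-finite
  loss) raises an error rather than propagating NaNs.
- Both loss sums are divided by the sample count. Adam's per-coordinate
  normalization makes this equivalent to the plain sum up to its bias
  correction; the mean keeps loss values comparable across sample sizes.
- Weights are Glorot-uniform, biases zero, drawn from a seeded RNG. Stage
  seeds derive from the master seed by fixed offsets (modal `u`:
  `seed + u`; attention: `seed + 11`; in cross-validation, repeat `r`
  folds use `seed + 1000r` and the fold-`f` model `seed + 1000r + 20f`),
  so any stage can be reproduced in isolation and identical seeds give
  bit-identical results end to end.
- AUC uses mean ranks (ties count one half), identical to the brute-force
  pairwise count; AUPR is step-wise average precision with no linear
  interpolation. F1/ACC/REC binarize at 0.5 by default — the natural
  decision boundary of a sigmoid — but see the limitation below.
- Candidate ranking breaks score ties lexicographically by
  `(drug_id, mirna_id)` so output tables are deterministic.
- SMILES are tokenized per character (so `Cl` is two tokens), codes
  assigned in first-appearance order starting at 1, 0 reserved for
  padding; characters outside the vocabulary map to one shared fallback
  code (`max + 1`) with a warning; strings longer than the encoding width
  keep their prefix. The integer codes are fed to the GCN as raw real
  values — no one-hot expansion — so code magnitude acts as an arbitrary
  scale the first layer must absorb.

## The synthetic generator

`generate_synthetic()` plants a recoverable low-rank structure: latent
factors `U` (p × r), `V` (q × r) are standard normal, pair logits are
`signal_scale · U Vᵀ / √r` plus an offset solved by bisection so the
expected density matches the target (default 4%, the sparsity regime of
real resistance data), and `B` is sampled Bernoulli. Features derive from
the same factors:

- fingerprints: median-binarized random projection of `U`;
- SMILES: toy-grammar strings over `{C,O,N,=,(,),1,2,c,n}` with lengths
  tracking `U`'s first factor (their label encoding is the feature);
- expression: non-negative-clipped affine image of `V` plus Gaussian noise
  (sd `feature_noise`, default 0.1);
- GO-style similarity: cosine similarity of `V` rows mapped to `[0, 1]`.

A `mask_fraction` (default 0.15) of miRNA rows per block is withheld as
unknown to exercise the imputation path. Setting a modal non-informative
replaces the latent input of its feature blocks with fresh noise. Because
the four modals share the four blocks pairwise, per-modal informativeness
is only approximately realizable: a block is generated informative when
*any* modal that uses it is informative, so "only modal 1 informative"
means blocks `d1`/`m1` carry signal and modals 2–3 are half-informative.
Full-scale block widths (920/85/172/2587) are available via
`profile = "full"`; the default `"small"` profile (64/16/32/128) keeps the
padding semantics while running fast.

What the generator deliberately does *not* emulate: real miRNA expression
distributions, chemically valid SMILES, fingerprint bit correlations, or
the size of the published dataset (754 × 106). Passing tests on this
generator demonstrate that the pipeline's machinery is correct and that it
can exploit planted feature signal — not that it attains any particular
performance on real resistance data.

## Small-sample behavior and known limitations

The packaged studies run at 30 drugs × 40 miRNAs with ~48 positives, and
at that scale the method's behavior differs qualitatively from the
full-scale regime it was designed for. Three findings, each reproducible
from the test suite and `scripts/acceptance.R`:

- **Memorization dominates.** With ~38 training positives, no
  regularization (the method specifies none) and full-batch Adam, the
  sub-networks drive training loss down by giving each node a nearly
  unique embedding; held-out ranking quality peaks within the first few
  dozen epochs and then decays toward chance as embeddings orthogonalize.
  Feature-informative data outperform matched non-informative (null) data
  by only a modest AUC margin at any epoch budget we probed, far short of
  the recovery one would expect at hundreds of nodes. The acceptance
  script reports both numbers (`planted_signal_auc`, `null_auc`) so the
  margin is visible rather than hidden.
- **Attention tracks usefulness, not provenance.** When handed embeddings
  that genuinely differ in predictive value, the attention stage reliably
  upweights the predictive modal (a property the test suite asserts). But
  when all four sub-networks have memorized the same training positives —
  the small-sample regime — their embeddings are equally "useful" to the
  attention objective and the learned magnitudes no longer single out the
  informative modal.
- **Thresholded metrics are degenerate at 0.5.** Non-negative embeddings
  put all first-stage scores at or above 0.5, and at small scale the
  attention stage rarely learns vectors signed so that many fused scores
  cross below it; recall then saturates at 1 and accuracy collapses to the
  positive prevalence. AUPR and AUC are the metrics to read. At full
  scale, with far more negatives shaping the weighted loss, the fused
  scores spread to both sides of 0.5 and the thresholded metrics become
  meaningful.

These are properties of the method at desk scale, not implementation
defects: the forward/backward passes are verified against naive
message-passing oracles and finite differences, and every training path is
bit-reproducible under its seed.
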