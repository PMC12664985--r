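---
title: "Methods: tag-token classification and model interrogation in proteotag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tag-token classification and model interrogation in proteotag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

proteotag screens translated ORFeomes for contamination by asking a small
causal language model to *finish the sentence*: the model reads an
amino-acid sequence character by character and the probability it assigns to
class-tag tokens at the next position is the classification. This vignette
explains the model, the data construction, the evaluation, the
interpretability suite, and the design decisions behind each — including
the places where the design was genuinely open and the package had to pick
a convention.

## The classification model

The model is a standard decoder-only transformer over a character
vocabulary: the 20 canonical amino acids, the ambiguity code `X`, one
single-character tag token per class, the `<` delimiter, and a reserved pad
token. Non-canonical residue codes (B, Z, J, U, O, `?`) map to `X`; the pad
token is masked out of the loss and never emitted at prediction time.

Given a token sequence $x = (x_1, \dots, x_T)$, the model computes hidden
states $h_t$ and next-token probabilities
$p(x_t \mid x_{<t}; \theta) = \mathrm{softmax}(W h_t + b)_{x_t}$, and
training minimizes the average next-token negative log-likelihood (reported
in nats per unmasked token). Each training item carries its label *inside
the string*: in TI-free mode the item is a fixed-length fragment with the
tag appended; in TI-inclusive mode it is the full sequence, `<`, then the
tag. Classification needs no extra head: prompt with the sequence, read the
softmax mass on the tag tokens at the first generated position, and take
the argmax (ties break to the first configured class and are flagged; a
`scan_k` option instead generates up to k tokens greedily and accepts the
first tag encountered, yielding `"unknown"` when none appears).

The default architecture is deliberately desk-scale: 2 blocks, $d=64$, 4
heads, context 128, learned positional embeddings, pre-norm blocks with
ReLU MLPs (about 115k parameters). This trains in a few minutes on one CPU
core while preserving the multi-layer, multi-head structure the
interpretability tools need; every size is configurable upward. A 0-block
variant without the final normalization is exposed because its tag logit is
exactly linear in the input embeddings, which gives the attribution tests
closed-form oracles. Optimization is AdamW (weight decay 0.01 on weight
matrices) under a cosine schedule with linear warmup. The default peak
learning rate is 1e-3: rates around 1e-4, appropriate when fine-tuning
models four orders of magnitude larger, converge too slowly for a ~100k
parameter model trained from scratch. Checkpoint selection keeps the
weights with the best evaluation macro F1, ties resolved toward the earlier
step because over-trained checkpoints degrade.

The forward and backward passes are written in R matrix code with one
RcppArmadillo kernel for the per-sequence, per-head causal attention loop
(the only place where interpreter overhead dominated); gradients were
verified against central finite differences at every parameter group, and
causality is asserted by exhaustive suffix perturbation.

## Terminal-information-free training data

Full-length sequences carry terminal signals — start/stop context, length,
gene boundaries — that a classifier can exploit without learning anything
about internal composition. The TI-free construction destroys them: all
sequences of a class are concatenated in file order into one "unisequence"
(headers and newlines removed), cut into fragments of exactly $l = 100$
residues ($f_j$ covers positions $(j-1)l+1, \dots, jl$; the trailing
remainder is discarded, never padded, so length is uninformative), and the
fragments — chimeric on purpose, since they may straddle gene boundaries —
are pooled. Larger class pools are downsampled (seeded, without
replacement) to the smallest so classes stay exactly 1:1, the combined pool
is shuffled, and then split train/eval/test. The split fractions default to
0.8/0.1/0.1, a convention this package fixes since only the existence of
splits is standard. Shuffling happens before the split boundary is drawn —
the same choice implied by "shuffle, then split" pipelines.

The holdout screen `dedup_screen()` removes any held-out item whose bare
text exactly equals a training item (fixed-string, whole-line matching) and
reports the overlap; it is idempotent.

At inference, whole proteins are covered: `classify_fasta()` cuts each
sequence into non-overlapping 100-mers plus a final shorter remainder
prompt, classifies every fragment, and takes the majority vote (ties give
`"unknown"`). Including the remainder at inference deviates from the
training-side discard rule deliberately — screening must assign something
to proteins shorter than the window.

## Evaluation

Per-class one-vs-rest confusion counts give precision $TP/(TP+FP)$, recall
$TP/(TP+FN)$ and F1 (harmonic mean); macro F1 is the unweighted mean of
per-class F1, weighted F1 the support-weighted mean. An `"unknown"`
prediction is a missed detection: it enters its true class's recall
denominator and is never a false positive for any class. Unknowns are
tallied in a separate column so the per-class totals
$TP+FP+FN+TN+\mathrm{unknown}$ still sum to the number evaluated.

## The synthetic benchmark

Because no external corpus is downloaded, a generator produces the study
conditions. A `class_profile` fixes a class's residue sampling
distribution, sequence-length range, and optional planted motifs (inserted
with a given per-sequence probability at a uniform position, *overwriting*
residues so the length distribution is untouched). The default benchmark
enriches Q/A/R in the "algal" class and G/S/L in the "bacterial" class at
0.12 probability each — a strong compositional contrast of the kind that
separates algal from bacterial proteomes, where glutamine/glycine usage
dominates the signal — with 0.1% `X` to exercise ambiguity handling, and
lengths uniform on 150–450 residues. `tifree_benchmark()` runs the full
construction to 2,500 fragments per class, i.e. ~2,000 training and ~500
held-out fragments per class under the default splits.

What the generator does *not* emulate: phylogenetic correlation between
sequences, positional composition gradients, domain architecture, codon- or
DNA-level signals, and realistic motif grammars. Residues are i.i.d. given
the class. Passing the recovery test therefore shows the pipeline can learn
and evaluate a compositional contrast end to end — it does not certify
performance on real proteomes, where signals are weaker and correlated. The
chance-level control (two profiles with identical frequencies and different
labels) bounds the other side: held-out accuracy stays at 0.5 when there is
nothing to learn.

## Attribution methods

All attribution targets default to the pre-softmax logit $F$ of the chosen
tag token at the last prompt position (the negative log-likelihood variant
is an option). Attribution is taken with respect to the token embeddings.

**Gradient x embedding** (`shap_like()`): $\phi_i = \sum_j (\nabla_{e_i}
F)_j \, e_{ij}$ — the fast SHAP-flavoured saliency. On an additive linear
surrogate it reproduces exact Shapley values, which the package can verify
directly: `exhaustive_shapley()` enumerates all $2^n$ coalitions (refused
above $n = 12$; it is a test oracle, not a production path).

**Integrated gradients** (`integrated_gradients()`):
$\mathrm{IG}_i = (x_i - x_{0,i}) \cdot \int_0^1 \partial F / \partial x_i
\,d\alpha$ along the straight path from a reference embedding. The default
reference is the pad token's embedding at every position (the all-padding
baseline); a zero-vector baseline is the alternative. The integral uses the
midpoint rule with 50 steps by default: completeness
($\sum_i \mathrm{IG}_i = F(x) - F(x_0)$) then holds to well under 1% on the
trained desk-scale model, exactly for linear targets, and the quadrature
error shrinks monotonically with the step count.

**Windowed reference-based attribution** (`deeplift_windowed()`): sequences
are processed in sliding windows (32 residues, stride 16, so adjacent
windows share 16 positions: window 1 covers 0–31, window 2 covers 16–47; a
final truncated window is appended whenever trailing residues would
otherwise be uncovered). Each window is encoded as its own prompt and
attributed against the reference independently; the per-position profile
averages the attributions of all covering windows (sum is an option). The
per-window attribution is computed as the path integral of gradients from
the reference — the multi-point form of the rescale rule — because that is
the only form that actually satisfies the per-window decomposition
$\sum_i A_i = y(x) - y(x_0)$ the method promises; a single-point
gradient-times-difference does not, for a nonlinear network.

**Attribution clustering** (`cluster_attributions()`): rows are z-scored
per position, k-means runs for $k = 1..\min(10, n)$ with 10 seeded
restarts, and the selected $k$ is the first whose percentage inertia
decrease versus $k-1$ falls below 20%. Degenerate inputs (one row,
identical rows) resolve to $k = 1$; when $k$ reaches the number of distinct
rows the zero-inertia partition is assigned directly, since the k-means
implementation refuses center counts at the row count.

## Motif mining

`influence_profile()` scores position $i$ of each layer by
$\lVert h_i - \mu \rVert_2$, the deviation of its hidden state from the
layer mean, min-max normalizes per layer, then averages layers and
normalizes again (a constant profile maps to zeros, a guarded case). The
normalization order — per layer, then average — follows the vectorized
definition of the profile; the alternative (normalize once after averaging)
changes little but is not what the formula says.

The **flexible finder** thresholds the averaged profile at its 95th
percentile, finds peaks (local maxima at or above the threshold, separated
by at least `window_size` positions — the minimum peak distance defaults to
the window size), extracts a `window_size` window centred on each peak,
masks below-threshold positions to `X`, keeps windows with at least two
above-threshold residues, and merges overlapping or adjacent windows
(combined mean influence is the length-weighted mean of the parts — a
convention; no combiner is canonical). Because the threshold is a
percentile, the output is invariant to monotone rescaling of the profile.

The **strict finder** combines three min-max-normalized channels into
$0.4 \cdot \mathrm{divergence} + 0.3 \cdot \mathrm{attention} + 0.3 \cdot
\mathrm{IG}$, where divergence is the hidden-state influence profile,
attention is the self-attention diagonal (how much each position attends to
itself, averaged over layers and heads), and IG is integrated gradients (50
steps, reused from the flexible pipeline's convention). Windows of 3–9
residues are accepted when the window mean exceeds the 95th percentile of
the composite *and* at least 75% of the window's residues individually
exceed it; accepted windows are fully specified (no `X`) and ranked by mean
composite.

`class_separation()` provides the corpus-level seed set: $I(a, i) =
\lVert \mu_{a,i} - \mu_{\neg a, i} \rVert_2$ measures how far residue $a$'s
mean embedding at aligned position $i$ sits from the mean of all other
residues there; $\theta$ is the 95th percentile of all defined $I$ values
and the seed set collects every (sequence, position) exceeding it.
Positions where the complement is empty are excluded and counted.
Percentiles throughout the package use linear interpolation between closest
ranks (R type 7), fixed once for reproducibility.

## Layer-wise projections

`layer_projection()` decomposes a layer's hidden-state matrix $H \in
\mathbb{R}^{n \times d}$ by *uncentered* SVD, $H = U \Sigma V^\top$, and
projects onto the first two right singular vectors, $Z = H V_{:,1:2}$ — no
mean subtraction, following the decomposition as written; `center = TRUE`
gives conventional PCA. Sign indeterminacy is fixed by scaling each singular
vector so its largest-magnitude entry is positive; singular-value ties are
taken in decomposition order and flagged. `project_all_layers()` projects
every depth including layer 0 (the input embedding after positional mixing
— chosen over the raw embedding table as the more informative convention)
and reports a per-layer separation statistic: mean pairwise distance
between residue-identity centroids over mean within-identity spread.

One empirical caution, measured on the desk-scale models this package
trains: that statistic *decreases* with depth. Layer 0 is residue embedding
plus positional offset, so points cluster almost perfectly by identity
before any mixing; attention then contextualizes and blurs identity
clusters. Expectations of increasing separation formed on much deeper,
wider models do not transfer to this regime, so the package reports the
per-layer statistic without asserting a direction.

## Motif-to-domain mapping

`scan_motifs()` counts occurrences of each motif in every sequence of a
domain-database FASTA — overlapping matches included (lookahead scanning),
`X` matching any single residue — and aggregates counts per (motif,
accession), parsing accessions as the first `PF\d{5}` token with version
suffix stripped, falling back to the first header token. Overlap counting
is the maximal-information choice where no overlap rule is canonical, and
the tests pin it. `score_and_rank()` appends the weighted score
$\mathrm{count} \times \mathrm{mean\ score}$ — high when a motif is both
salient to the model and recurrent in a domain — and sorts descending,
ties broken by count then motif so the ranking is stable.
`top_k_unique_domains()` measures how far the top pairs collapse onto few
domains. Occurrences are counted per match, not per sequence.

## Problem sizes and numerical choices

The package's own validation uses: the default benchmark (2,500 fragments
per class, 100-residue fragments, 300 training steps at batch 64) for the
recovery and chance-level checks; a 160-fragment disjoint-alphabet corpus
with a 2-layer $d=32$ model for the interpretability oracles; and
constructed fixtures for everything exact. Finite-difference gradient
checks, the causality assertion, percentile conventions, tie-breaks
(prediction ties to the first configured class; ranking ties by count then
lexicographic motif; singular-vector signs by largest entry), degenerate
inputs (constant profiles, empty pools, single rows), and the pad-masking
of the loss are all pinned by tests. Training determinism holds for a fixed
seed on a fixed BLAS; eval batches are chunked so memory stays modest.

## Known limitations

The synthetic generator's i.i.d. residues make the benchmark easier than
real contamination screening; F1 values here do not transfer to real
proteomes. The remainder-fragment prompt at inference sees positions it
rarely saw during TI-free training, so very short sequences classify less
reliably. The attention kernel stores full attention cubes, which is
comfortable at context 128 but quadratic beyond. TI-inclusive mode pads to
the longest training string, so one very long sequence inflates the batch
cost. Four-way (multi-class) screening works through the same operations,
but the default profiles and benchmark exercise the binary case.
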