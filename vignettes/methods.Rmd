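---
title: "Multi-task self-supervised pretraining of a molecular graph encoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task self-supervised pretraining of a molecular graph encoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Experimental property labels for molecules are scarce; unlabeled SMILES
corpora are enormous. `molssl` pretrains a graph neural network encoder on
unlabeled molecules so that the learned representation transfers to
downstream property-prediction tasks with few labels. Two self-supervised
objectives are trained jointly:

1. **Pseudo-label classification.** Every molecule is fingerprinted with
   166-bit MACCS structural keys, and k-means is run on the fingerprints at
   several granularities $K$ (the reference configuration is
   $K \in \{100, 1000, 10000\}$). The cluster index of a molecule at each
   granularity becomes a *pseudo-label* $y^K_n$, and a classifier with one
   fully connected head per granularity (widths $K_1, K_2, K_3$) predicts
   them from the encoder's latent vector $f_\theta(x_n)$:
   $$\mathcal{L}_{MLCT} = \frac{1}{N}\sum_n \sum_i
     \ell_i\!\left(W_{K_i} f_\theta(x_n),\; y^{K_i}_n\right),$$
   with $\ell_i$ the cross-entropy. Coarse clusters encode broad chemotype
   membership, fine clusters encode close analogy, so the arity of the label
   tuple carries multi-scale structural information.
2. **Masked-graph contrastive learning.** A second view $x_n'$ of each
   molecule is made by masking a connected region of its graph: starting
   from one random atom, masking expands breadth-first until
   $\lceil \rho \cdot |V| \rceil$ atoms are masked ($\rho$ = 0.25 by
   default), the masked atoms' features are replaced by a reserved mask
   token, and bonds between two masked atoms are removed. The loss is the
   mean Euclidean distance between the latents of the two views:
   $$\mathcal{L}_{MCL} = \frac{1}{N}\sum_n
     \left\lVert f_\theta(x_n) - f_\theta(x_n') \right\rVert_2 .$$

The total objective is the unweighted sum
$\mathcal{L}_{all} = \mathcal{L}_{MLCT} + \mathcal{L}_{MCL}$, minimized with
Adam (lr $10^{-3}$, betas 0.9/0.999, no weight decay). Ablation modes
(`mlct_only`, `mcl_only`, `none`) switch individual terms off.

## The encoder

The encoder is a graph isomorphism network (GIN). Atoms are embedded from
their atomic number and chirality code (unspecified / clockwise /
counter-clockwise / other); bonds from their type (single / double / triple
/ aromatic) and direction code (none / end-upward / end-downward). One
message-passing round computes

$$a_v^{(k)} = \sum_{u \in N(v)} \left(h_u^{(k-1)} + e_{uv}^{(k)}\right),
\qquad
h_v^{(k)} = \mathrm{MLP}_k\!\left((1+\varepsilon)\,h_v^{(k-1)} + a_v^{(k)}\right),$$

with $\varepsilon$ fixed at 0, bond embeddings $e_{uv}$ entering the sum
additively, and $\mathrm{MLP}_k$ a two-layer ReLU network. After five
rounds, mean pooling (READOUT) produces a 512-D graph representation
$h_G$, and a one-hidden-layer projection MLP maps it to the 256-D latent
space used by both losses and by the latent-space analyses. Forward and
backward passes are written directly in matrix algebra (the backward pass
is verified against finite differences in the test suite), so the package
has no deep-learning framework dependency.

Design choices made where the design was genuinely open:

* **No batch normalization in the layer MLPs.** Batch norm makes the
  encoder's output depend on batch composition and differ between training
  and evaluation, which would break the package's determinism and
  permutation-invariance contracts; at desk scale it is not needed for
  optimization either. The update is therefore Linear–ReLU–Linear.
* **Latent vs. representation.** The 256-D projection output is what the
  losses and analyses operate on; the 512-D pooled representation feeds the
  fine-tuning head and is exposed for inspection.
* **Contrastive distance.** Plain (not squared) Euclidean distance, per the
  loss definition above; a squared variant sits behind
  `pretrain_config(mcl_squared = TRUE)`.
* **Mask realization.** Masked atoms are kept in place with a mask-token
  feature (atomic-number code 0, outside the chemical vocabulary) rather
  than deleted, so both views have the same number of atoms and the
  contrastive pair is well defined. Mask quota rounding is `ceiling`; one
  start atom per mask, with a fresh start drawn when a disconnected
  fragment is exhausted; breadth-first neighbours are visited in ascending
  node index so a mask is reproducible from its seed.
* **k-means.** k-means++ initialization, Euclidean metric on the 0/1
  fingerprint vectors, 10 restarts, 300-iteration cap; the three
  granularities are fitted independently, and pseudo-labels are fitted once
  before training and frozen. Assignment ties break to the lowest centroid
  index.
* **Gradient flow.** The contrastive gradient flows through both branches
  (no stop-gradient); classifier heads receive gradients only from their
  own loss.

## Chemistry plumbing

SMILES validation, canonicalization, MACCS keys and the scalar descriptors
(MolLogP, MolWt, TPSA, rotatable bonds) are delegated to OpenBabel, called
in batch. Graphs are built over heavy atoms only (hydrogens implicit);
multi-fragment inputs keep their largest fragment (recorded in the config
as `chem_io.keep_largest_fragment`). Invalid SMILES raise an error in the
single-molecule API and are skipped with a logged count when reading
corpora. A syntactic pre-check rejects inputs such as `C(` that some
toolkits silently "repair".

Two descriptors have no R implementation to delegate to and are computed
in-package: `qed` is a QED-style drug-likeness score — the geometric mean
of trapezoidal desirability functions over MW, logP, H-bond donors and
acceptors, TPSA, rotatable bonds and aromatic-ring count — and `sa` is a
synthetic-accessibility proxy built from molecule size, ring rank and
heteroatom fraction. Both are deterministic and live on the conventional
scales ([0, 1] and [1, 10]) but do not claim numerical equality with other
toolkits' implementations; the latent-space correlation analysis only
requires deterministic, structure-derived values.

## The synthetic corpus

`generate_corpus()` emulates what the pretraining method needs from a real
corpus: latent structural families with clusterable fingerprints, and
property labels computable from structure. Each molecule is one family
scaffold (from a fixed set of fourteen aromatic and saturated rings and
chains) decorated with 0–3 random substituents (halogens, hydroxyl,
methyl, amino, nitro) at H-bearing positions, so every emitted SMILES is
valid by construction. Label rules: aromatic-ring presence (binary),
heteroatom-count threshold (binary), and a linear function of heavy-atom
and heteroatom counts with optional Gaussian noise (regression). The
generator does **not** emulate realistic drug-likeness distributions, ring
assortments or activity cliffs of real corpora, so green tests demonstrate
mechanism, not chemistry-scale performance.

One empirical property of the generator is worth knowing: with decorated
molecules, k-means on MACCS keys at $K =$ number of families splits on
substituent load rather than scaffold (substituents toggle more bits than
a small ring difference), while clusters at finer $K$ are nearly
family-pure. This is precisely the coarse-to-fine behaviour that motivates
clustering at several granularities; the test suite checks exact family
recovery on undecorated scaffolds and high cluster purity at finer $K$ on
decorated ones.

For scaffold-split transfer experiments the substituent set can include
cycloalkyl groups (`default_substituents(rings = TRUE)`); these extend the
Murcko scaffold of the decorated molecule and create the scaffold
diversity (about a hundred distinct scaffolds at $n = 1000$) without which
a scaffold split degenerates into a handful of groups. The aromatic-ring
label remains determined by the parent scaffold.

## Desk-scale study conditions

The package's training-based checks run on one CPU with a fixed,
documented problem size: a corpus of 2000 molecules over 8 families,
granularities (4, 8, 16), mask ratio 0.25, batch size 256, 30 epochs, and
an encoder that keeps the 5-layer depth with desk-scale widths (hidden 48,
graph 64, latent 32). The full-width 5-layer / 512-D / 256-D architecture
is exercised structurally (initialization, encoding shapes, permutation
invariance) but not trained, since training it on a toy corpus would add
cost without adding evidence. Under these conditions pretraining reaches
coarsest-head pseudo-label accuracy around 0.99 (chance 0.25), the total
loss falls monotonically in trend, and the original-vs-masked latent
distance shrinks severalfold from the first epoch.

Fine-tuning attaches a two-layer head to the 512-D (here 64-D)
representation and trains the whole model end-to-end (a frozen-encoder
linear-probe mode exists for representation analyses), early-stopping on
validation AUROC / RMSE with patience 10. On the synthetic aromatic-ring
task under a scaffold split, both pretrained and random initializations
saturate at matched epochs (the rule is linearly exposed in the bond
features), so the transfer check asserts the directional inequality
pretrained $\geq$ random plus an absolute bar of 0.85; the pretrained
encoder's advantage shows more clearly in the latent-space analyses below.

## Latent-space analyses

* `knn_classify()` — majority vote among the k nearest training latents by
  cosine distance; the positive-vote fraction is the ranking score.
* `similarity_profile()` — rank all references by cosine distance to a
  query, cut the ranking into 10 percentile bins, sample up to 1000 per
  bin, and report mean Tanimoto similarity to the query per bin. After
  pretraining the profile decreases with bin index (Spearman correlation
  of bin vs. mean Tanimoto about −0.6 to −0.9 on the two-family corpus);
  an untrained encoder shows no such order.
* `neighbor_descriptor_correlation()` — Spearman correlation between each
  descriptor of a molecule and of its nearest latent-space neighbour.

Numerical conventions used throughout: cosine distance on the 256-D
latent (ranking and kNN alike); ranking ties break by reference order;
bin boundaries by index arithmetic $\lceil (i-1)N/10 \rceil \ldots
\lceil iN/10 \rceil - 1$; zero vectors are given unit norm before cosine;
degenerate all-equal distances raise a warning rather than an error.

## Reproducibility

Every stochastic component (clustering, initialization, shuffling, each
per-epoch mask, splits, sampling) consumes a seed derived from one root
seed by hashing the component name, so a single integer replays a whole
run; `with_local_seed()` restores the caller's RNG state afterwards.
Checkpoints round-trip bit-exactly, and `write_manifest()` records config,
seeds and input digests next to every CLI artifact.

## Known limitations

* OpenBabel's MACCS SMARTS dictionary differs in places from other
  toolkits' MACCS implementations; fingerprints are internally consistent
  but not bit-compatible across toolkits.
* The graph reader covers the canonical SMILES OpenBabel emits (organic
  subset, bracket atoms, ring closures, stereo marks); exotic inputs are
  canonicalized first, never parsed directly.
* Training is plain batched CPU matrix algebra: fine for 10^3–10^4
  molecules, not for 10^6+.
* The synthetic corpus cannot certify benchmark-scale accuracy on real
  assay data; it certifies the algorithmic contracts of the method.
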