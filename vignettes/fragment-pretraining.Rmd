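---
title: "Fragment-guided dual-channel pretraining for molecular graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-guided dual-channel pretraining for molecular graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Labeled molecular property data are scarce, so property-prediction models
are commonly pretrained on large unlabeled SMILES libraries and then
fine-tuned per task. `fragssl` implements a self-supervised pretraining
scheme whose supervisory signal is organized around *molecular
fragments*: chemically meaningful substructures obtained by BRICS
decomposition (the retrosynthetic rule set of Degen and colleagues, which
identifies cleavable bonds from sixteen chemical environments).

The backbone is a GIN message-passing encoder in the widely used
molecular flavor: atom features (atom type, chirality tag) are embedded
and summed to give $h_v^{(0)}$; each of $K$ layers adds self-loops with a
dedicated bond-type slot, forms messages $h_u + e_{uv}$ from embedded
edge features, sum-aggregates them over neighbors, and updates with a
two-layer perceptron followed by batch normalization (ReLU between
layers, none after the last). The molecule embedding $h_g$ is the mean of
final-layer node embeddings (sum readout is available as a config
option; mean is the default because the fragment view is also built from
means, keeping the two views on the same scale).

Pretraining optimizes the unweighted sum $L = L_C + L_G$ of two losses.

**Contrastive channel.** Two views of every molecule are built from one
full-graph encoder pass. The *atom view* is the plain mean readout
$h_g$. The *fragment view* first mean-pools node embeddings within each
BRICS fragment, $h_f^m = \frac{1}{|F^m|}\sum_{v \in F^m} h_v$, then
scores each fragment with a scaled dot-product self-attention logit
$w^m = q_f^m \cdot k_f^m / \sqrt{D}$ (with $q = h_f^m W_q$,
$k = h_f^m W_k$, $v = h_f^m W_v$), softmaxes the logits over the
molecule's own fragments and returns
$\tilde h_g = \sum_m \alpha^m v_f^m$. The two views of the same molecule
are positives, all other atom views in the batch are negatives, and the
InfoNCE objective

$$L_C = \frac{1}{|B|}\sum_{i \in B} -\log
  \frac{\exp(\theta(\tilde h_g^i, h_g^i)/\tau)}
       {\sum_{j \in B}\exp(\theta(\tilde h_g^i, h_g^j)/\tau)}$$

is minimized, with cosine similarity as the critic $\theta$ and the
positive term included in the denominator (so $L_C \ge 0$, with equality
approached when positives dominate, and $L_C = \log|B|$ under total
embedding collapse).

**Generative channel.** A random subset $\hat V$ of atoms
($\max(1, \lfloor m \cdot n \rfloor)$ per molecule with $n \ge 2$ atoms)
has its features replaced by a mask token. The encoder then runs with
message passing *restricted to intra-fragment bonds*, the masked
positions' hidden states are re-masked with a learned decoder token, and
a single-layer GIN decoder (also fragment-restricted) plus a linear
projection produce reconstructions $\hat z_v$. The loss is the scaled
cosine error against the clean embedded atom features $x_v$:

$$L_G = \frac{1}{|B|}\sum_i \frac{1}{|\hat V_i|}
  \sum_{v \in \hat V_i}\bigl(1 - \cos(x_v, \hat z_v)\bigr)^{\gamma},
  \qquad \gamma \ge 1,$$

which down-weights already-aligned (easy) reconstructions as $\gamma$
grows, is invariant to positive rescaling of either argument, and is
bounded per atom by $2^\gamma$.

## Resolved design points

Several aspects of this architecture admit more than one reading; the
package resolves them as follows.

* **Fragments as an atom partition.** BRICS is used in its *cut-bond*
  form: all cleavable bonds are identified and deleted, and the connected
  components of what remains are the fragments, indexed by smallest
  contained atom index. Fragment enumeration with dummy attachment atoms
  would not yield a partition of the original atom set, which the
  pooling and the decoder restriction both require. A molecule with no
  cleavable bond is a single fragment; disconnected SMILES components
  fragment independently.
* **Per-fragment attention logits.** Averaging the attention logit over
  the whole batch would collapse the softmax to uniform weights and
  remove the per-fragment weighting the attention exists to provide;
  the default therefore scores each fragment by its own logit. The
  literal batch-averaged variant is preserved behind
  `attention_logit_mode = "batch_mean"` for comparison.
* **Cosine critic, no projection head.** The critic is cosine similarity
  on the pooled embeddings directly. This is the common default for
  InfoNCE on graphs and keeps the temperature interpretable; a learned
  projection head is a deliberate non-feature.
* **Two encoder passes, shared weights.** The contrastive channel sees
  the full graph; the generative channel sees the masked,
  fragment-restricted graph. The two passes share all encoder weights.
* **Gradients flow through the reconstruction target.** The target
  $x_v$ is the clean *embedded* feature vector (a cosine needs a
  continuous target), and the embedding tables are themselves trained.
  No stop-gradient is applied on the target side: the joint loss is a
  plain differentiable function of all parameters, which keeps its
  analytic gradient exactly equal to the numerical one (this identity is
  asserted by a finite-difference test). Collapse of the embedding
  tables toward trivial alignment is counteracted by the contrastive
  term and was not observed in the training-dynamics checks.
* **Re-masking before decoding** (default on) forces the decoder to
  reconstruct a masked atom from its fragment neighbors rather than from
  the encoder's output at the masked position itself; single-atom
  fragments are then reconstructed from the token alone, which is the
  intended degenerate behavior.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `num_layers` | 5 | GIN message-passing layers |
| `hidden_dim` | 300 | embedding width $D$ |
| `dropout` | 0 (pretraining), 0.5 (downstream) | dropout after each layer |
| `tau` | 0.1 | InfoNCE temperature; smaller values emphasize hard negatives |
| `mask_ratio` | 0.3 | fraction of atoms masked per molecule (interesting range 0.1–0.6) |
| `gamma` | 2 | scaled-cosine-error exponent, $\ge 1$ |
| `batch_size` | 256 | molecules per step; at least 2 (InfoNCE needs a negative) |
| `learning_rate` | 0.001 | Adam step size, pretraining and fine-tuning |
| `seed` | 42 | initialization, shuffling and mask sampling |
| `epochs` | 100 | passes over the library (unspecified upstream; configurable) |

The temperature default sits at the center of the commonly examined
candidate grid; the mask ratio at the midpoint of its interesting range.
All parameters are recorded in the checkpoint together with the
featurization vocabulary (120 atom-type slots with slot 120 reserved for
the mask token, 3 chirality slots, 4 bond types plus a self-loop slot,
3 bond-direction slots), so encoder embedding tables are reproducible
from a checkpoint alone.

## Numerical choices

* Batch normalization uses biased (1/N) variance both for normalization
  and for the running estimates; evaluation mode uses the running
  statistics, so inference is deterministic and independent of batch
  composition. Fresh models start from mean 0, variance 1.
* Softmaxes (attention, InfoNCE) subtract the per-group maximum before
  exponentiation; softmax shift-invariance makes this exact, not an
  approximation.
* Zero-norm vectors inside a cosine are an error, not a silent epsilon:
  they indicate a degenerate state worth surfacing.
* Trailing batches with fewer than two molecules are dropped (no
  negative pair exists); molecules whose SMILES fail to parse are
  dropped at dataset construction with a warning carrying the count.
* Scaffold-split ties (equal group sizes) break by first occurrence, so
  splits are deterministic.
* Adam uses the standard bias-corrected moments
  ($\beta_1 = 0.9, \beta_2 = 0.999, \epsilon = 10^{-8}$); all weights are
  Glorot-initialized under the configuration seed.

Everything differentiable runs on a small package-internal reverse-mode
tape (`R/autograd.R`) whose operations are validated against central
finite differences, including batch normalization in training mode and
the gather/scatter operations message passing is built from.

## Downstream evaluation

`scaffold_split()` groups molecules by Murcko scaffold (ring systems
plus linkers, computed by iteratively pruning non-ring atoms of degree
at most one, then canonicalized as a colored graph so the key is
independent of atom order). Groups are assigned whole, largest first,
to train until it holds 80% of molecules, then to validation until 10%,
remainder to test — the standard out-of-distribution protocol for
molecular benchmarks. `finetune()` puts a linear head on $h_g$ and
trains with masked sigmoid cross-entropy (classification; missing labels
are excluded) or squared error (regression), selecting the epoch with
the best validation metric; `finetune_runs()` repeats over seeds and
reports mean ± standard deviation. ROC-AUC is computed by midranks
(ties count one half), equivalent to trapezoidal integration of the ROC
curve with TPR = TP/(TP+FN) against FPR = FP/(FP+TN).

## The toy library and what passing tests mean

`generate_library()` assembles core–linker–tail products from small
aromatic or aliphatic cores, amide/ester/ether linkers and shared alkyl
tails, with about one bare core in ten. The linkers are deliberately
BRICS-cleavable so the fragment machinery is always exercised, and the
two core families provide a binary label plus a fragment-count-correlated
continuous response. The generator emulates *structure* — fragmentable
topology, scaffold diversity, two separable chemotypes — not chemistry:
no charges, no stereocenters, no realistic property distributions, and a
molecular-weight range far narrower than a real screening library.
Tests passing on it demonstrate that the machinery is correct and that
pretraining extracts structure that transfers to a held-out-scaffold
probe; they say nothing about accuracy on real ADMET panels, which would
require pretraining on a large drug-like library at GPU scale.

Problem sizes used by the shipped checks: unit tests run 1–3-layer
encoders at widths 3–8 on molecules of up to ~20 atoms; the end-to-end
training-dynamics and transfer checks use the full default architecture
(5 layers, width 300) on a 200-molecule library for 20 epochs, the
scale at which a single-process run completes in a few minutes.

## Known limitations

* Formal charges are not tracked (the SDF conversion path drops them);
  BRICS environment matching therefore treats all atoms as neutral,
  which only matters for charged aromatic nitrogens.
* Chirality tags and bond directions occupy vocabulary slots but the
  parser emits the "unspecified" index; stereochemistry is otherwise out
  of scope.
* Aromaticity is re-perceived from ring systems after the OpenBabel
  conversion (which kekulizes); exotic aromatic systems beyond fused
  carbo- and common heteroaromatics may be perceived differently than by
  other toolkits.
* The implementation is plain R on BLAS; it is sized for method study
  and desk-scale experiments, not for pretraining on hundreds of
  thousands of molecules.
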