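---
title: "Cell spatial graphs and interaction-conditioned convolution: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell spatial graphs and interaction-conditioned convolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A pathology image patch is reduced to the set of its nuclei. Each nucleus
carries a position, a cell-type call, a prediction confidence, an axial
orientation, and ten morphology descriptors (area, convex area,
eccentricity, extent, filled area, major/minor axis length,
perimeter²/area, perimeter, solidity). A directed graph is built per
patch: every nucleus points to its $k = 8$ nearest neighbors by Euclidean
centroid distance. Each node carries the 11-vector
$x_n = (\text{confidence}, \text{morphology}_{1..10})$, globally centered
and scaled with statistics fitted on the training corpus. Each directed
edge $(n, m)$ carries three features:

* a categorical **edge type** $t_{n,m} = \mathrm{type}(n)\cdot T +
  \mathrm{type}(m)$, a bijection over the $T^2$ ordered type pairs
  (36 codes for the 6-type lung scheme, 16 for the 4-type oral scheme);
* **closeness** $w_{n,m} = 1 / \lVert p_n - p_m \rVert$ in 1/pixels;
* **parallelism** $a_{n,m} = \lvert \cos(\theta_n - \theta_m) \rvert$,
  the axial concordance of the two nuclear major axes.

One **CSIGC layer** (cell spatial interaction-conditioned graph
convolution) updates node $n$ as follows. For each out-edge $(n, m)$ the
edge type indexes an embedding table $EM \in \mathbb{R}^{T^2 \times
(x \cdot c)}$, reshaped to a modulator $mo_{n,m} \in \mathbb{R}^{x \times
c}$. The continuous pair $(w_{n,m}, a_{n,m})$ feeds two linear maps
producing per-channel scale $\gamma$ and shift $\beta$ (feature-wise
linear modulation), applied as $mo \leftarrow mo \odot (1 + \gamma) +
\beta$. The message is $me_{n,m} = x_{\mathrm{src}} \, mo_{n,m}$, the
self message is $me_n = x_n \theta$, and

$$x^{(i+1)}_n \;=\; me_n + \operatorname{Ave}_m\, me_{n,m},$$

followed by ReLU and dropout on hidden layers. The network stacks 3 such
layers (4 for the oral-epithelium task), with the last layer's width
equal to the number of categories $K$. There is no dense head: the
pooled vector

$$x_{\mathrm{graph},k} = \tfrac{1}{N}\textstyle\sum_{i \in S} x_{\mathrm{nucleus},i,k}$$

over the pooling subgroup $S$ (tumor nuclei; epithelial strata; or all
nodes for global pooling) goes straight into a softmax,
$P_{\mathrm{graph}} = \mathrm{Softmax}(x_{\mathrm{graph}})$. The same
last-layer outputs yield per-cell probabilities $P_{\mathrm{nucleus},i} =
\mathrm{Softmax}(x_{\mathrm{nucleus},i})$, which is what makes the model
interpretable at the cellular level: when all node outputs coincide the
two notions agree exactly, a consistency the test suite asserts.

**Interpretation.** For a presumptive category $k$, the contribution of
any continuous input feature $f$ is the exact partial derivative
$\partial L / \partial f$ with $L = \mathrm{CE}(P_{\mathrm{graph}}, k)$,
computed in one hand-derived backward pass through pooling, all layers,
and (optionally) the normalization. Positive values push *away* from
$k$. The categorical edge type is a lookup, has no derivative, and
serves as a grouping key only.

## Why the gradients are hand-derived

No automatic-differentiation framework is assumed. The CSIGC layer is
the package's core, so its forward pass exists twice — a vectorized
implementation and a deliberately naive per-node/per-edge transcription
of the layer algorithm used purely as a test oracle — and the backward
pass is derived by hand for every parameter block, the node features,
and the continuous edge features. Correctness is established against
central finite differences (train and interpret suites, and acceptance
criteria 2–3), which keeps the check independent of the code it checks.

## Design choices where the design was open

* **Message source.** The layer algorithm as printed computes
  $me_{n,m} = x_n \times mo_{n,m}$, yet titles the step "message from
  neighbors". With $x_n$ the aggregation would never see neighbor
  morphology. Default is the neighbor's features $x_m$;
  `message_source = "self_as_printed"` reproduces the literal text.
* **FiLM form.** Per-output-channel scale/shift,
  $\gamma = W_\gamma (w,a)^\top + b_\gamma$ (likewise $\beta$), applied
  as $(1+\gamma)$ so zero-initialized modulation is the identity. A
  per-element $(x \times c)$ variant is available (`film = "element"`)
  since "feature-wise" is ambiguous. The published ~10k parameter total
  is not recoverable without the unstated widths; `count_parameters()`
  documents this package's own count per configuration.
* **Final layer activation.** The last layer defaults to pass-through:
  ReLU-clamped non-negative logits degenerate the softmax.
  `final_activation = TRUE` restores the literal per-layer ReLU.
* **Hidden widths** default to 16 (3-layer: 16, 16, K; 4-layer: 16, 16,
  16, K), consistent with the published parameter scale; configurable.
* **Dropout rate** is unstated upstream; default 0.2.
* **Aggregation boundaries.** Exact 0.5 patient scores fall in the
  negative group; the cohort-median rule sends ties at the median
  negative; vote ties break by higher mean probability, then lower
  class index. All unstated upstream; fixed for determinism.
* **AdaDelta "scaling factor" = 2** is mapped to the learning-rate
  multiplier of the accumulator update (the term is not defined
  upstream; $\rho = 0.9$, $\epsilon = 10^{-6}$).
* **Checkpoint selection.** Default: highest validation accuracy,
  earliest epoch on ties. On desk-scale separable corpora accuracy
  saturates within a few epochs and the earliest tied checkpoint is far
  from converged — useless for gradient interpretation. The option
  `tie_break = "val_loss"` (used by the synthetic benchmark) picks the
  lowest validation loss among the top-accuracy epochs.
* **Epithelial subgroup** for the oral task includes all three
  epithelial strata (corneum, basale, other strata); configurable.
* **Coincident centroids** make closeness undefined (1/0); the default
  is an error, `coincident = "clamp"` treats them as 1 px apart (the
  generator uses clamp, since simulated positions can collide).
* **Normalization guard.** Columns with sd below $10^{-8}$ get scale 1,
  so a constant column maps to zeros; the raw-scale gradient chain rule
  then divides by 1 rather than exploding.

## What the synthetic generator emulates — and what it does not

The generator produces per-patch cell tables with the schema of real
segmentation output: positions (uniform or parent–offspring clustered),
types from a mixture (lung: 40% tumor, 25% stroma, 20% lymphocyte, 5%
each red blood cell / macrophage / karyorrhexis), per-type morphology
(log-normal sizes; beta eccentricity/solidity; ellipse-consistent axis
lengths and perimeter), confidence $\sim$ Beta(20, 2.5), and axial
orientations. Class 2 receives planted effects: a tumor eccentricity
(or solidity) mean shift, a locally aligned orientation field
(piecewise-constant direction grid plus wrapped-normal noise,
$\mathrm{sd} = 45^\circ(1-s)$; $s = 1$ gives exactly shared orientations
hence parallelism 1 on every edge), and stroma thinning by
$1/\mathrm{scale}^2$ that lowers stroma–stroma closeness — the
elongated-nuclei, structured-architecture, sparse-activated-stroma
phenotypes the method is meant to detect.

Perimeter carries multiplicative log-normal measurement noise
(sd 0.08). Without it, perimeter²/area is a deterministic monotone
function of eccentricity, i.e. a perfectly collinear copy of the planted
signal, and "which feature does the model credit" becomes a coin flip
between the two carriers. Axis lengths remain genuinely correlated with
eccentricity (as in real nuclei), so feature-recovery statements are
about the *dominant* carrier, not exclusivity; over benchmark seeds the
planted eccentricity ranks first in 4 of 5 runs, with the remaining run
crediting a correlated length carrier first.

A green synthetic test therefore establishes that the pipeline's
mechanics — graph construction, convolution, training, aggregation,
attribution — behave as specified on data with known structure. It does
not establish clinical performance: real nuclei are not ellipses, real
type calls are noisy in spatially correlated ways, staining batch
effects do not exist here, and the published AUCs/hazard ratios on
TCGA/NLST/OPMD/LCMC require those restricted cohorts.

## The desk-scale benchmark (stated world)

`run_synthetic_benchmark()` fixes the end-to-end world: 12 patients per
class × 5 patches, 80–120 cells per 1024 px patch, patient-disjoint
6/2/4 train/val/test split; strong world plants eccentricity shift
+0.25 and alignment strength 0.9; null world plants nothing. Training:
SGD momentum 0.9, lr 0.05, 20 epochs, batch 16, `tie_break =
"val_loss"`. The published learning rates (1e-4, 5e-4) belong to
corpora of tens of thousands of graphs; at 60 training graphs they
would move the loss by a rounding error, so the desk-scale rate was set
once at 0.05 and not revisited. Expected behavior, asserted by the
acceptance suite: strong world ≥ 0.90 held-out patch accuracy (median
over 5 seeds; observed 1.0 on most), null world within [0.40, 0.60].

Feature-contribution rankings across features are compared on the
standardized scale (gradients with respect to the z-scored inputs):
per-σ units are the only common scale for features with different
physical units, and dividing by σ to reach raw units inflates whichever
feature happens to have the smallest spread (solidity, σ ≈ 0.04)
regardless of relevance. Raw-scale gradients remain the user-facing
default of `feature_contributions()` because *within* one feature they
read in interpretable units (per unit eccentricity, per pixel).

## Numerical notes

* Softmax is max-shifted; probabilities are floored at 1e-300 inside
  the log for loss bookkeeping.
* kNN distance ties break by ascending cell index (stable `order`),
  making graphs reproducible across platforms.
* Zero-out-degree nodes (possible only in hand-built or merged graphs)
  receive the self message alone; the neighbor average over an empty
  set is zero.
* Dropout is inverted (scaled by $1/(1-p)$) and active only in
  training mode; interpretation always runs with dropout off.
* All randomness — init, shuffling, dropout masks, per-epoch patient
  resampling, generation — flows from explicit integer seeds; the
  resampler is a pure function of (seed, epoch).

## Known limitations

* Batching is sequential gradient accumulation, not a disconnected
  block-diagonal batch graph; results are identical, throughput is not.
* The published 9,912-parameter figure cannot be reconciled without
  the unstated hidden widths and FiLM form; no equality is asserted.
* Scale-downs for test budget: the effect-size monotonicity property
  runs 3 magnitudes × 3 seeds with reduced cohorts/epochs; the
  null-distribution check uses 9,000 cells per class.
* `tki_response` slide-merging and per-epoch OPMD resampling are
  exercised on synthetic data only, at small cohort sizes.
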