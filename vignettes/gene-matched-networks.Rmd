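---
title: "Gene-matched networks: model, methods and design choices"
author: "gmnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-matched networks: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmnet)
```

## The model

A gene-matched network (GMN) is an attribute-driven network: each neuron
expresses GE distinct genes drawn uniformly at random from a repertoire of
GR gene identifiers, and two neurons are connected once per shared gene.
All structure follows from this rule:

* Neurons expressing a common gene are pairwise connected, forming a
  *complete subnetwork* per gene; a network has GR of them, with
  `n * GE / GR` members each on average — exactly, in every realization,
  because every neuron contributes exactly GE memberships. For 1000-neuron
  layers and (GR, GE) = (20, 3), (50, 5), (100, 7), (1000, 22),
  (10000, 71) this gives 150, 100, 70, 22 and 7.1 neurons per subnetwork.
* Because each neuron belongs to GE subnetworks, the subnetworks overlap,
  which produces both high clustering (cliques) and shortcuts; at small GR
  a 100-neuron circular GMN with 500 connections is a small-world graph
  relative to an edge-matched random graph and a ring lattice.
* Between two layers, the expected pairwise weight is the hypergeometric
  overlap mean `GE^2 / GR`, so two 1000-neuron layers carry about
  `10^6 * GE^2 / GR` connections (500,000 at GR = 50, GE = 5).

Signals propagate feed-forward. Layer 1 transmits its raw input values
(image pixels in [0, 1]). Every other layer sums its inputs across
connections (`drive = W x`, with `W` the shared-gene count matrix),
multiplies by the edge polarity (+1 excitatory, -1 inhibitory), mixes
converging edges at normalized combination ratios, and activates exactly
the top `round(AP/100 * n)` neurons by summed input. Active neurons
transmit 1; everything else is discarded, so each layer is a binarizing
nonlinear filter controlled by the activation percentage (AP).

A layer's response is coded two ways: the *active-neuron array* (binary,
"neuron code") and the *active-gene array* (for each gene, how many active
neurons express it — the "gene code"). The gene code reads the relative
activity of the overlapping subnetworks and is the model's transferable
representation of network information.

Reliability of transfer is scored as *cross-layer consistency*: for many
pairs of inputs, the L1 distance between the pair's arrays at a deep layer
is regressed (OLS, intercept fitted, slope reported) on the same pairs'
distance at layer 2. A slope near 1 means dissimilarity is preserved; in a
connection-matched random network the slope collapses toward 0 within a
few layers.

## Parameters that matter

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| GR | gene-repertoire size | 50 | canonical configuration; subnetworks of 100 in a 1000-neuron layer |
| GE | genes per neuron | 5 | with GR = 50 gives 0.5 expected connections per neuron pair |
| AP | % of neurons activated per layer | 50 | faithful-transfer regime; smaller APs sharpen the gene code |
| layer sizes | 144-neuron input + 1000-neuron layers, 10 layers | | the image-transfer architecture |
| polarity | +1 / -1 per edge | +1 | -1 models an inhibitory source layer |
| combination ratio | mixing weights of converging edges | 1 | presets use main:side = 1:2 |
| nPairs | input pairs per consistency slope | 1000 | matches the stated procedure |

## The synthetic photograph

The image experiments need a natural-photograph-like source. The package
generates one: Gaussian white noise low-pass filtered with an isotropic
Gaussian kernel (circular FFT convolution; kernel sd =
`correlationLength/2` pixels) and min–max scaled to [0, 1], default
553 x 737 pixels, from which 12 x 12 patches are cut at uniform random
origins and flattened row-major into 144-vectors.

The correlation length defaults to 6 px — deliberately *below* the 12-px
patch size. The AP rank coding is invariant to a common multiplicative
scaling of a patch (a brighter but otherwise identical patch drives the
same ranking), so a field whose blobs are larger than the patch — patches
that are essentially uniform grays — carries almost no structure the
network can encode, and pixel distances (dominated by luminance) decouple
from gene-code distances. With structure at about half the patch scale,
as natural textures have at this crop size, pixel-space and gene-code
distances correlate (Spearman ≈ 0.5 over random patch pairs) and the
image-search experiments behave as designed. What the generator does *not*
emulate: edges, objects, non-Gaussian intensity statistics and the
multi-scale (1/f) spectrum of real photographs; passing tests show the
coding works on smooth textured fields, not that it is optimal for natural
scenes.

## Numerical and procedural choices

* **Rounding and ties.** The active count is `round(AP/100 * n)` with
  half-up rounding; rank ties at the activation boundary and all search /
  input-order ties break by ascending index. Everything is deterministic
  given seeds; one root seed expands into per-layer / per-edge / per-stage
  child seeds via a documented multiplicative mix (`childSeed()`).
* **Connection granularity.** A "connection" is one shared-gene unit: a
  pair sharing 3 genes contributes 3 connections. Connection replacement
  removes `round(f * total)` uniformly chosen units and adds the same
  number on uniformly random pairs (total conserved exactly); removal only
  deletes. Path-length and clustering calculations collapse multiplicities
  to simple edges.
* **Rotational assignment.** For circular networks with a fixed connection
  budget (500), genes are drawn uniformly and dealt to neurons in rotation,
  skipping within-neuron duplicates, until the budget is reached; budget
  accounting counts multiplicity by default (a `countMode = "unique"`
  switch is provided since either convention is defensible). Rotation
  makes per-neuron gene counts nearly even; it does *not* make per-gene
  subnetwork sizes more even than independent sampling — the stopping rule
  cancels that effect — which is why the test suite asserts the former.
* **Consistency estimation.** Pairs are sampled uniformly without
  replacement from distinct members of a 200-patch corpus per seed; the
  slope is `cov/var` (equivalent to `lm`), reference layer 2, target the
  last layer. Gene-code distances use raw integer counts: at fixed AP the
  active count is constant, so any normalization is a common factor.
* **Degradation experiments.** Neuron removal spares the input layer
  (removing pixels would change the input dimensionality) *and* the
  reference measurement layer. The latter is a deliberate reading of the
  procedure: if the reference layer itself is decimated, its pairwise
  distances collapse to a quantized noise floor and the regression slope
  *inflates* (the denominator variance vanishes faster than the
  covariance), which inverts the curve the experiment is meant to trace.
  Sparing the probe layer isolates damage to the transmission path.
  Removal is nested in the fraction (at a fixed seed the 20%-removal set
  is a subset of the 60% set), so a sweep progressively degrades one
  original network.
* **Gene-space inputs.** Random gene-array inputs (uniform on [0, 1] per
  gene) drive a layer directly through `geneArrayDrive()` — the gene-space
  dual of the weighted sum, identical to propagating through a virtual
  one-neuron-per-gene pre-layer. Polarity applies to the input array
  before thresholding.
* **Degenerate inputs.** Zero-edge graphs have no defined path length
  (error); neurons never activated by any corpus patch yield no optimum
  image (warning + NULL in batch settings); zero-variance reference
  distances make the slope undefined (error).

## Problem sizes used by the shipped tests

The acceptance-style tests run the canonical 10-layer architecture at full
scale — 144-neuron input layer, nine 1000-neuron layers, 200-patch corpus,
1000 pairs, medians over 10 network realizations (20 for the small-world
characterization; the AP/polarity transformation uses 1000 random
gene-array inputs over 10 single-layer networks). Batched propagation (one
matrix product per layer for a whole corpus) keeps the complete suite in a
few minutes on one CPU. A 300-neuron-layer variant was evaluated and
rejected: layer-10 consistency slopes drop to ~0.4 there, which
misrepresents the full-scale behavior.

## Known limitations

* Intra-layer (recurrent) dynamics, learning, and graded inter-layer
  transmission are out of scope; hidden layers transmit binary activations
  only.
* Per-edge polarity only: signs do not compose along paths; multi-edge
  inhibitory cascades are modeled exactly as specified by the architecture.
* The LMMG-style probabilistic link rule (connection probability as a
  product over matched attributes) is not implemented; the linear
  shared-gene count rule is the point of the model.
* Reported consistency slopes depend on the input ensemble; they are
  comparable across networks run on the same corpus, not absolute
  constants of the architecture.
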