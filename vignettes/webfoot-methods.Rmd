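---
title: "Methods: Mk ancestral state reconstruction and section-entropy analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Mk ancestral state reconstruction and section-entropy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(webfoot)
```

webfoot implements the two quantitative stages of a comparative analysis of
webbed-foot evolution and development in waterbirds: maximum-likelihood
ancestral state reconstruction of a five-state foot-morphology character,
and a spatial entropy statistic for proliferating-cell distributions in
histological sections. This vignette is the package's account of both
methods: the models, the defaults and why they were chosen, what the
synthetic-data generator does and does not emulate, and the numerical
decisions a user auditing results will want to know.

## The Mk1 model and its likelihood

Foot morphology is coded as a discrete character with k = 5 states
(0 non-webbed, 1 palmate, 2 semipalmate, 3 totipalmate, 4 lobate). The
evolutionary model is the one-parameter symmetric Mk model: a
continuous-time Markov chain whose rate matrix has every off-diagonal
entry equal to a single rate $r$ and diagonal $-(k-1)r$. Its transition
probabilities have the closed form

$$P_{ii}(t) = \tfrac{1}{k} + \tfrac{k-1}{k}e^{-krt}, \qquad
  P_{ij}(t) = \tfrac{1}{k} - \tfrac{1}{k}e^{-krt},$$

which `transitionMatrix()` uses directly (no matrix exponentiation); the
test suite checks it against a numerical matrix exponential. The model's
stationary distribution is uniform, and we use the uniform $1/k$ vector as
the root prior — the source analysis (a Mesquite-style "Mk1" run) does not
state its prior, and the stationary prior is the standard neutral choice.

`treeLogLik()` evaluates the likelihood by Felsenstein's pruning recursion
in postorder. Three details matter in practice:

* **Unscaled trees.** The reconstruction is defined on a topology-only
  composite tree; "unscaled" is realised as every branch length equal
  to 1. `readNewick()` assigns length 1 to any branch without an explicit
  length, while accepting explicit lengths unchanged so the same code
  reruns on calibrated or alternative topologies.
* **Polytomies** are evaluated natively — a node simply accumulates one
  pruning factor per child — rather than being arbitrarily resolved,
  because composite family-level trees contain genuine polytomies.
  Likelihood is invariant to child order (tested).
* **Missing states** (the `?` code, e.g. a taxon whose foot morphology is
  unrecorded) contribute an all-ones conditional vector, the standard
  ambiguity treatment. This makes the missing tip exactly neutral: the
  likelihood equals that of the tree with the tip pruned and its branch
  lengths merged (tested against `ape::drop.tip()`).

Underflow on large trees is controlled by rescaling each internal node's
conditional vector to unit sum when it is consumed, accumulating the log
scalers per character.

## Rate estimation

`fitRate()` maximises the summed log-likelihood over the single rate by
bounded one-dimensional optimisation on $[0, r_{\max}]$ with
$r_{\max} = 100$ and tolerance $10^{-8}$ — the Mk1 model has exactly one
free parameter, so nothing heavier is warranted. One numerical caveat
drove the implementation: once $rt$ is large every transition row is
nearly uniform, so the profile log-likelihood is flat over most of a wide
bracket, and a plain golden-section search can converge inside the plateau
without ever probing the peak (typically near small $r$ on conserved
characters). The estimator therefore first brackets the optimum with a
coarse log-spaced scan of the bracket, then polishes with `optimize()`
between the scan neighbours, and finally checks the $r = 0$ boundary
explicitly so constant characters return exactly 0. Agreement with a
$10^{-4}$-resolution grid search is part of the test suite.

## Marginal ancestral states

`marginalAsr()` reports, for every internal node, the marginal posterior
probability of each state given all tip data — the quantity displayed as
pie charts in ancestral-state figures. It is computed by the standard
two-pass (up-down) algorithm: the pruning pass gives each node's
conditional subtree likelihoods $D_v(s)$; a tipward pass then propagates
the complement $U_v(s)$ (the likelihood of everything outside $v$'s
subtree, seeded at the root with the prior), and the marginal is the
normalised product $D_v(s)U_v(s)$. Sibling contributions are combined by
explicit products rather than division, so zero conditional likelihoods
(possible at $r = 0$) cannot produce NaNs. The result equals re-rooting
the tree at each node and reading the root state probabilities; under a
uniform prior it also coincides with Mesquite-style "proportional
likelihoods", which is why no separate output mode is needed. Joint
(most-probable-path) reconstruction and stochastic character mapping are
out of scope.

`reconstruct()` composes the two steps — fit the rate on the character,
then compute marginals at $\hat r$ — matching how a Mesquite Mk1 analysis
is actually run. `mostProbableStates()` takes the per-node argmax,
breaking ties (within $10^{-9}$) toward the lowest state index and
flagging them, preferring determinism plus an explicit flag over silent
arbitrariness. `countIndependentOrigins()` counts edges whose child state
is in a target set while the parent state is not; tips count as children,
and edges touching an explicitly unknown state are excluded rather than
guessed.

## The composite tree shipped with the package

The original analysis ran on a composite family-level phylogeny of extant
birds assembled from several published trees; that tree is not deposited
anywhere machine-readable. The files
`inst/extdata/synthetic_composite_tree.nwk` and
`synthetic_composite_states.tsv` are this package's own approximate
transcription: a 103-tip family-level tree assembled once from the
published verbal descriptions of the relevant clades on a Prum-style
backbone, with the webbed clades (Anseriformes, Gruiformes,
flamingos+grebes, Charadriiformes, and the core waterbird clade) at
family or genus resolution and foot-type codings from the same source
(including the unknown-state Magellanic plover). The `synthetic_` prefix
is deliberate: it is a stand-in, not the original tree, and node
probabilities computed on it can differ from the published figures by a
point or two wherever the transcription's topology differs from the
original merge. The reconstruction machinery itself accepts any
user-supplied tree in its place.

## The section entropy statistic

For a binarised section image, the statistic sums over all ordered pairs
of distinct foreground pixels:

$$S = \sum_{(i,j) \ne (k,l)} Z_{i,j}\,Z_{k,l}\,
      \ln\!\frac{\sqrt{(k-i)^2 + (l-j)^2}}{W_{\max}}$$

where $Z$ is the binary mask and $W_{\max}$ the section's maximum
medio-lateral width. Tightly clustered points make the log terms more
negative, so lower $S$ means a more concentrated (less disordered)
distribution; dividing by $W_{\max}$ makes sections of different calibre
comparable. Three conventions had to be fixed where the defining sum is
silent:

* **Self-pairs are excluded.** The literal quadruple sum includes
  $i=k, j=l$, whose $\ln 0$ term is $-\infty$; excluding zero-distance
  self-pairs is the only reading that yields a finite statistic. Ordered
  pairs are retained, so each unordered pair contributes twice.
* **Per-pair normalisation.** $S$ grows like the squared foreground count
  $N$, so sections with different cell numbers are not directly
  comparable on raw $S$; `entropyS()` therefore also reports
  $S / (N(N-1))$, the mean log relative distance per ordered pair.
* **Coordinates** are 0-based pixel centres with Euclidean distances in
  pixel units; $W_{\max}$ is measured along raster rows (images must be
  oriented with the medio-lateral axis horizontal).

The implementation computes $2\sum_{i<j}\ln d_{ij} - N(N-1)\ln W_{\max}$
with a blocked pairwise-distance sum (block size 2048) to bound memory on
dense masks; it is tested to $10^{-9}$ against a literal double loop.
Exact invariances (translation, transposition, joint rescaling of
coordinates and $W_{\max}$) are asserted in the suite.

## The per-section pipeline

`measureSection()` mirrors the laboratory procedure: each channel (a
nuclei counterstain and a proliferation marker) is binarised at its Otsu
threshold; $W_{\max}$ is taken from the *nuclei* mask, which traces the
whole tissue silhouette; $S$ is computed on the *proliferation* mask with
that $W_{\max}$. The channel-role assignment is this package's decision —
the source prepares both channels without stating which feeds which
quantity — and the nuclei channel is the only sensible width reference,
since the proliferating subset need not span the section.

Otsu thresholding is implemented over the 256-bin histogram of the 8-bit
image, maximising between-class variance, with foreground strictly above
the threshold and ties resolved to the lowest maximising value (first
argmax). A constant image has no threshold and is an error. The
implementation is checked against an exhaustive scan of all 256 candidate
thresholds.

An optional centroid mode (off by default) reduces each connected
foreground component to its centroid before the entropy sum, giving one
point per cell blob instead of one per pixel; the default follows the
source in summing over raw pixels.

`summarizeEntropy()` reproduces the nested design: per individual, the
mean over its three section replicates; per species and position, the
mean over three individuals; per species, the joint/phalanx ratio of
those means.

## What the synthetic images emulate — and what they do not

`generatePointPattern()` provides three generating laws with known
disorder ordering: complete spatial randomness, a centred square lattice,
and a Thomas-type cluster process (uniform parents, Gaussian offspring of
sd `radius`), chosen because its two parameters tune disorder
monotonically. `renderSection()` turns a pattern into a paired-channel
image: Gaussian blobs (sd 1.2 px, peak 200) at the pattern points on the
proliferation channel; an elliptical tissue silhouette circumscribing the
pattern region, plus a denser nucleus blob field, on the nuclei channel;
additive Gaussian noise (sd 4 over background 8) on both. The render
returns its ground truth — true centre coordinates and true silhouette
width — which powers oracle tests: the measured per-pair statistic on the
thresholded render must sit within 5% of the statistic computed on the
true centres. The per-pair form is used for that comparison because raw
$S$ scales with the squared number of foreground *pixels* and is not
commensurable between a pixel mask and a centre list.

`makePaperLikeDataset()` emits the full nested design (3 species series x
2 positions x 3 individuals x 3 sections = 54 image pairs) with planted
joint/phalanx entropy ratios of about 5 ("moorhen-like"), 2
("grebe-like") and 1 ("coot-like"), the qualitative structure reported
for the real species. Because $S \approx \alpha n^2 + \beta n$ at a fixed
pattern law and geometry, the ratios are planted through
proliferating-cell abundance: all patterns are uniform draws, phalanx
sections carry 70 cells, and the joint-section counts (164, 100, 67) were
solved from a one-time pilot fit of mean $S$ against $n$ for each section
geometry (`calibratePaperLike()` reruns that pilot). Joint sections are
rendered wider (150 x 95 units) than phalanx sections (110 x 70), so the
$W_{\max}$ normalisation does real work. Sections are rendered at
256 x 256 with 60-220 cells — enough to resolve blob structure while
keeping a 54-image dataset around a few seconds to generate and measure.

These synthetics are deliberately minimal: they emulate blob-like stained
cells, a convex tissue silhouette, and additive noise. They do not
attempt histology texture, uneven illumination, staining artefacts,
non-convex or torn sections, or the real species' absolute entropy
levels. Passing the planted-ratio checks therefore demonstrates that the
pipeline recovers known spatial structure from rendered images — not that
it reproduces the published per-species values, whose raw images are not
deposited.

## Numerical choices and degenerate inputs

* Transition matrices: closed form; $t = 0$ returns the exact identity;
  negative lengths are errors.
* Likelihood scaling: per-node unit-sum rescaling; zero-likelihood
  configurations (conflicting data at $r = 0$) return `-Inf` cleanly.
* Rate fitting: bracket $[0, 100]$, tolerance $10^{-8}$, 50-point
  log-spaced pre-scan, explicit boundary check at 0; entirely missing
  characters are an estimation error.
* Entropy: fewer than two foreground pixels is an error (the statistic is
  undefined), as is a nonpositive $W_{\max}$; coincident *continuous*
  points in `entropyPoints()` are rejected rather than silently dropped.
* Thresholding: strictly-greater convention throughout, so the threshold
  partitions `[0..T]` / `[T+1..255]` consistently between
  `otsuThreshold()` and `binarise()`.
* All generators thread an explicit seed and restore the caller's RNG
  state; a given seed yields byte-identical outputs.

## Problem sizes used in the checks

The shipped verification uses deliberately modest sizes chosen to make
the oracles exact and the runs quick to audit: exhaustive-enumeration
likelihood checks on all-assignment sums for trees of up to 5 tips and
k <= 3 (200 randomised draws); rate recovery on 20 simulated datasets of
500 characters on a 16-tip tree; entropy oracle equivalence on masks of
up to 200 foreground pixels; and 20 seeds of the 54-image synthetic
dataset for the planted-ratio check. Larger inputs run fine — the
pairwise sum is blocked and the pruning pass is vectorised across
characters — but add nothing to the correctness argument.

## Known limitations

* The Mk1 model is symmetric: gains and losses of webbing are forced to
  the same rate, and the uniform root prior is an assumption, not an
  inference. Asymmetric and hidden-rate models are out of scope.
* Marginal probabilities are per-node summaries; they do not describe
  joint histories, and argmax states at adjacent nodes need not form a
  consistent single history.
* The origin count depends on the argmax map and on the tree's
  resolution: collapsing genera into families can merge what were
  independent origins on a finer tree.
* The bundled composite tree is an approximate transcription (see above);
  conclusions that depend on a point or two of node probability should be
  drawn on the user's own tree.
* $W_{\max}$ is a horizontal-extent proxy measured on the binarised
  nuclei channel; images rotated off the medio-lateral axis will
  mis-normalise.
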