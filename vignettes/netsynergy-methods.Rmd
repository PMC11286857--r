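---
title: "Models and methods behind netsynergy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind netsynergy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netsynergy)
```

# The problem

Most diseases are not driven by a single gene but by a *disease module*: a
set of susceptibility genes that sit close together on the molecular
interaction network. Likewise, the genes whose expression responds to a drug
(a *drug module*) occupy a characteristic neighborhood. netsynergy ranks
candidate drug pairs for a query disease by asking, for every unordered pair
of drugs (A, B), whether their modules are in the topological configuration
associated with synergy and whether their transcriptional responses mirror
the disease state.

The prediction score for a pair is

$$\mathrm{score}(A, B) = T_{QAB} + P_{QAB} + C_{QAB} \in [0, 4]$$

with three components, all computed on the giant component of an undirected
gene interaction network:

1. **Localization, $T \in \{0, 2\}$.** Six topological classes are defined
   by the sign pattern of the two disease-drug proximity z-scores and the
   drug-drug separation. Class II, *Complementary Exposure* — both drug
   modules overlap the disease neighborhood ($z_{QA} < 0$, $z_{QB} < 0$)
   while being mutually separated ($s_{AB} > 0$) — receives $T = 2$; every
   other class receives 0.
2. **Proximity, $P \in [0, 1]$.** The closest distance
   $d(Q, A) = \frac{1}{|A|}\sum_{a \in A}\min_{q \in Q} d(q, a)$
   is standardized against a degree-matched permutation null
   ($z = (d - \mu)/\sigma$, 100 repetitions by default, both gene sets
   resampled each repetition), sign-inverted and min–max scaled across the
   drug collection; $P_{QAB}$ is the mean of the two drugs' scaled values.
3. **Correlation, $C \in [0, 1]$.** The cosine coefficient between the
   disease and drug expression signatures, restricted to the genes shared by
   the two modules, averaged as $(|C_{QA}| + |C_{QB}|)/2$. Cosine (no
   centering) is used deliberately: the signatures are signed
   fold-change-like vectors whose origin is meaningful.

The drug–drug separation follows the nearest-neighbor convention:
$s_{AB} = \langle d_{AB}\rangle - (\langle d_{AA}\rangle +
\langle d_{BB}\rangle)/2$, where within-set distances exclude the gene
itself (0 for singleton modules) and shared genes contribute 0 to
$\langle d_{AB}\rangle$. Note a corollary worth knowing: for a multi-gene
module, $s(A, A) = -\langle d_{AA}\rangle < 0$; the often-quoted
"identical modules have zero separation" holds only for the
identical-singleton case.

## A note on the class-II separation sign

Complementary Exposure describes *separated* drug modules, and positive $s$
is what the separation measure assigns to separated modules; published
high-scoring pairs consistently show small positive $s$ together with
scores above 2 (which force $T = 2$). `classify_exposure()` therefore uses
$s_{AB} > 0$ for class II. Because one also encounters the opposite
inequality in print, the convention is exposed as the
`separated_positive` switch.

# Module construction and amplification

Disease and drug modules come from expression signatures by the
top-fraction rule: the union of the $\lfloor f N\rfloor$ most up- and most
down-regulated genes ($f = 0.05$ by default, applied to all signature
genes). Genes with value exactly 0 are never selected, ties at a cutoff are
broken by gene identifier, and a deficit on one sign takes all genes of
that sign with a warning.

Raw disease–drug module overlaps are typically tiny (often below the
three-gene minimum where a cosine is meaningful), which makes the
correlation component uninformative. netsynergy amplifies modules by
PRINCE-style network propagation: iterate
$F_t = \alpha W' F_{t-1} + (1-\alpha) Y$ on the symmetrically normalized
adjacency $W' = D^{-1/2} W D^{-1/2}$ until convergence; the fixed point is
$F^* = (1-\alpha)(I - \alpha W')^{-1} Y$, and the iterative and direct
routes are cross-checked in the test suite. The prior $Y$ is 1 on the
module's own genes and carries similarity-weighted evidence from related
entities elsewhere: network-based disease similarity (sign-inverted,
min–max scaled proximity z between disease gene sets) for the disease
module, and generalized Jaccard similarity of chemical count fingerprints
$J(x,y) = \sum_i \min(x_i, y_i) / \sum_i \max(x_i, y_i)$ for drug modules.
Evidence from several similar entities is combined by maximum
(strongest-evidence; `prior_agg = "sum"` caps at 1 instead). The module
then grows by its top-$k$ propagation-scored network neighbors
($k = |{\rm module}|$ by default; $k = \infty$ reproduces the
all-neighbors variant without priors).

Propagation parameters are deliberately config-surfaced rather than claimed
canonical: $\alpha = 0.5$ balances diffusion and prior retention, tolerance
$10^{-6}$ and a 1000-iteration cap are far past convergence for
$\alpha \le 0.9$ (the contraction factor is $\alpha$).

Running the pipeline with amplification is `mode = "netprop"`; computing
the correlation on raw module overlaps instead is `mode = "base"`. Both
modes share every other statistic, so their comparison isolates the effect
of amplification on the correlation layer.

# Permutation null and degree binning

The proximity z-score controls for module size and degree: each repetition
replaces both gene sets by random sets with the same degree profile. Nodes
are partitioned into exact-degree groups, merged upward (ascending degree)
until each bin holds at least `min_bin_size` nodes (default 100, following
standard practice for this measure family); a trailing undersized bin is
merged into its predecessor. Sampling is uniform within a bin and without
replacement within one draw. A degenerate null ($\sigma = 0$, conceivable
on tiny networks) yields $z = 0$ with a warning rather than an error.
Because all distances live on the giant component, infinite distances
cannot occur; if a caller bypasses giant-component extraction they raise an
error rather than being silently dropped.

One integer seed drives every random stage; per-permutation and per-drug
streams are derived by counter offsets, so results are reproducible and
independent of evaluation order.

# Experimental synergy statistics

For wet-lab validation the package implements the two standard models on
dose–response survival data (effects are $1 - $ survival fraction,
clamped at 0 for stimulated wells):

* **Bliss independent action.** Expected combined effect
  $CI_{mix} = 1 - (1-v)(1-w)$. The synergy call compares the observed
  combined effect against this expectation (observed > expected). The
  printed "greater than 1" rule for $CI_{mix}$ itself is unsatisfiable for
  $v, w \in [0,1]$, so when summarizing published IA score columns the
  call is `ia >= 1`, which reproduces the published bold/synergy marks.
* **Loewe concentration addition.** Toxic unit
  $TU = C_a/EC_u^A + C_b/EC_u^B$ at the combination's observed effect level
  $u$; $TU = 1$ on the additivity line, $TU < 1$ called synergistic
  (strictly — an exactly additive well is not synergy). $EC_u$ is
  interpolated log-linearly between bracketing measured points, with no
  extrapolation (out-of-range effect levels are errors, and such wells are
  reported as `NA`); non-monotone curves are first cleaned by isotonic
  regression, with a warning. No parametric (e.g. four-parameter logistic)
  curve is fitted, because the statistics are defined directly on measured
  points.

# Pathway analytics

Mode-of-action questions are answered with four primitives: a one-sided
hypergeometric over-representation test against a caller-supplied
background universe (raw p-values thresholded at 0.05 by default, matching
common practice for this analysis; `p_adjust` is available), the coverage
of disease-enriched pathways by a drug pair's enriched pathways, the
significance of the largest connected component formed by module genes
inside a pathway's induced subgraph (standardized against uniform
same-size draws from the pathway — degree matching is unnecessary at
pathway scale — significant at $z > 1.95$), and DEG filtering at
$|\log_2 FC| \ge 1$ (the boundary included, per the defining formula).

# The synthetic benchmark

Real inputs for this method (a curated interactome, signature collections,
fingerprints, known-synergy labels) are large external resources. The
generator in `synth_config()` / `synth_bundle()` plants the statistical
structure the method is designed to detect, so the whole pipeline can be
exercised and benchmarked offline:

* **Network**: Barabasi–Albert preferential attachment (2,000 genes,
  $m = 2$ by default) — connected, heavy-tailed degrees like a real
  interactome, but without its motif structure or annotation biases.
* **Disease module**: an 80-gene breadth-first neighborhood of the most
  connected node.
* **Planted synergistic pairs** (10 by default): each drug module is a
  cohesive "ball" — the genes nearest to an anchor node adjacent to the
  disease module — plus a small slice (10%) of the disease module itself.
  Balls are pairwise disjoint and grown around distinct anchors, so the
  two modules of a pair are internally tight but mutually separated
  (positive $s$) while both hug the disease neighborhood (negative $z$):
  Complementary Exposure by construction.
* **Decoy drugs** (30): uniform random gene sets.
* **Signatures**: defined on the full gene universe with low-amplitude
  background noise (sd 0.2); the disease signature carries unit-scale
  values on its module and the planted neighborhood, and planted drug
  signatures are $\rho$-correlated with it there ($\rho = 0.6$). The
  correlation is planted on the *neighborhood*, not just each drug's own
  module, so raw module overlaps stay small (below ten genes, as observed
  for real signature pairs) and the correlation becomes measurable only
  after propagation-based amplification — the property the two pipeline
  modes are meant to contrast.
* **Fingerprints**: sparse Poisson count blocks; partners share a feature
  block, giving planted pairs high chemical similarity for the propagation
  prior.
* **Plates**: survival $2^{-(c/EC_{50})^h}$ on a 7-point twofold dilution
  series, five combination wells at matched half-doses, Gaussian noise
  (sd 0.03) on survival. Combination survival is the Bliss prediction,
  multiplied by $1 - \varepsilon$ ($\varepsilon = 0.3$) for planted
  synergy. With $h = 1$ and no noise an additive combination is an exact
  sham mixture, so the Loewe toxic unit is exactly 1 — a sharp additivity
  control. The plate-level CA call is conservative (every evaluable well
  below the additivity line), keeping the false call rate on additive
  noisy plates low (measured 2.5% over 200 seeds) at some cost in per-plate
  sensitivity.

With 10 planted pairs (20 drugs) and 30 decoys there are
$\binom{50}{2} = 1{,}225$ candidate pairs. Because every planted drug is
close to the disease and disease-correlated, combos of planted drugs from
*different* pairs are legitimately strong-looking negatives; they bound the
achievable AUC well below 1 and make the benchmark non-trivial.

**What passing the benchmark does and does not show.** It shows the
statistics recover planted topological and transcriptional structure at
realistic noise, and that amplification helps exactly through the
correlation layer. It does not certify performance on real interactomes
(whose degree correlations, ascertainment biases and annotation structure
the generator does not emulate) nor on real label sets, which are far
sparser and noisier than planted labels.

# Problem sizes and numerical choices

The shipped benchmark runs 20 seeds of the full two-mode pipeline at the
2,000-gene scale with 100 permutations per proximity score — about 10
seconds per seed, because all proximity and separation statistics reduce to
submatrix operations on one cached all-pairs BFS distance matrix (32 MB at
this scale; recomputed per network, never stored). Oracle cross-checks use
graphs of up to 50 nodes, where Floyd–Warshall and exhaustive enumeration
are exact and cheap. Degenerate inputs are handled explicitly: empty
modules, all-zero signatures or priors, and out-of-range effect levels are
errors; undefined cosines (overlap below `min_overlap = 3`) are `NA`,
imputed to 0 and flagged at scoring; ties are always broken by identifier
so every ranking is deterministic.

# Known limitations

* Identifiers are opaque strings; any symbol/ID mapping is a preprocessing
  concern.
* The interactome is consumed as an edge list; building one from source
  databases is out of scope, as are fingerprint computation and signature
  retrieval.
* The min–max scaling of proximity z-scores depends on the drug collection
  supplied for one query disease; scores are comparable within, not
  across, collections.
* The six-class localization scheme is a sign-pattern discretization;
  pairs near $z = 0$ or $s = 0$ can change class under resampling noise.
* Full response-surface synergy models (ZIP, HSA, Chou–Talalay across dose
  grids) are out of scope; the CA/IA statistics operate on the measured
  wells only.
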