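---
title: "Network energy of signed functional networks: model, design and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network energy of signed functional networks: model, design and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netenergy)
```

## The model

A functional connectivity matrix assigns every pair of brain regions a
signed weight $S_{ij} \in [-1, 1]$, typically a Pearson correlation of
regional activity. Structural balance theory classifies each triple of
regions by the sign of its triangle product $S_{ij} S_{ik} S_{jk}$:
positive products are balanced (a coordinated triad), negative
products imbalanced (a frustrated triad). The network energy

$$U = -\frac{1}{\binom{N}{3}} \sum_{\langle i,j,k\rangle}
  \sqrt[3]{S_{ij} S_{ik} S_{jk}}$$

is the negative mean cube-rooted triangle product over all
$\binom{N}{3}$ triples. The statistic rests on three choices:

* **Real cube root.** The cube root must be the signed real root
  $\mathrm{sign}(x)\,|x|^{1/3}$; a naive fractional power is undefined
  for negative products. Because the real cube root is multiplicative,
  the cube root of the product equals the product of the edge-wise
  cube roots, which is what makes the fast trace computation exact.
* **Binomial normalisation.** Dividing by the triangle count of the
  complete graph bounds $U$ in $[-1, 1]$, with the bounds attained by
  complete unit-weight networks of uniform sign. Zero-weight edges
  contribute zero product but the denominator stays $\binom{N}{3}$,
  so sparser coherence moves $U$ toward 0 rather than rescaling it.
* **Endpoint differences.** A state transition is summarised by
  $\Delta U = U_{task} - U_{rest}$ alone. Treating the transition as a
  conservative process, the endpoint difference carries the full
  information; no force term or path integral is modelled anywhere in
  the package, deliberately.

### Numerical route and tolerances

`network_energy()` computes $-\mathrm{tr}(T^3)/(N(N-1)(N-2))$ where
$T$ is the element-wise signed cube root with zero diagonal;
$\mathrm{tr}(T^3)$ counts each unordered triangle six times. The
explicit $O(N^3)$-loop `brute_force_energy()` is kept as a first-class
oracle and the two must agree to 1e-10 (tested on random matrices up
to $N = 229$, about 1.97 million triangles).

Ingest rules (all tested): matrices must be square with $N \ge 3$ and
finite off-diagonal entries; asymmetry up to 1e-8 is averaged away,
anything larger is an error rather than a silent fix; the diagonal is
zeroed (correlation matrices carry 1s; self-loops form no triangle but
would corrupt the trace); off-diagonal weights outside $[-1, 1]$ error
unless explicitly allowed (`allow_out_of_range = TRUE`, e.g. for
Fisher-z-transformed input — the formula does not need the bound, the
$[-1,1]$ energy guarantee does). Triangles containing an exactly-zero
edge are counted as neither balanced nor imbalanced in
`triangle_census()`, a convention the energy identity
$-(I_{bal}-I_{imb})/\binom{N}{3} = U$ is insensitive to.

## Null models

The validity analysis compares each network against surrogates with
"random topology". For complete signed weighted graphs,
degree-preserving rewiring is ill-defined, so the default surrogate
permutes the $\binom{N}{2}$ upper-triangle weights uniformly over edge
positions: the weight multiset (hence density and weight distribution)
is conserved exactly, while the placement of signs and magnitudes —
the thing the energy statistic measures — is destroyed. A
`sign-shuffle` variant keeps every magnitude in place and permutes
only the signs. Surrogates are deterministic given their seed. One
surrogate per network mirrors the paired plotting convention;
ensembles (`n_perms` of 100 or more) are recommended for inference,
and both are supported since the upstream convention is not fixed.

## Comparator graph measures

The competing feature types handle signed weights by the dominant
conventions of weighted brain-network toolkits: absolute weights
rescaled by the global maximum for the geometric-mean (Onnela)
clustering coefficient; lengths $1/|w|$ for shortest-path global
efficiency with disconnected pairs contributing zero; and Louvain
modularity on the positive subgraph. The signed information is
exactly what the energy statistic contributes, which keeps the
feature comparison meaningful. Each measure is pinned by a naive
brute-force reference in the tests; these pin *this package's*
definitions, since the exact variants used by any given upstream
toolkit are generally unrecorded. The Louvain optimiser is stochastic,
so its seed is an explicit argument and is recorded in pipeline
outputs; exact relabeling invariance is only guaranteed when the
optimum is unambiguous.

## Inference

Group-level inference is nonparametric throughout: Friedman's test for
the omnibus condition effect (asymptotic chi-square by default, with
an exact $(k!)^n$ enumeration path for small blocks), Wilcoxon
signed-rank for pairwise and actual-vs-null comparisons, and ICC for
cross-atlas reliability. Decisions where the upstream description is
silent:

* **Correction.** Holm by default — it controls the family-wise error
  rate with no independence assumptions; Benjamini–Hochberg is
  selectable.
* **Zero differences.** Dropped (Wilcoxon's original treatment) by
  default; Pratt's zero-retaining variant is available. An all-zero
  difference vector is reported as degenerate with $p = 1$ rather
  than an error.
* **Exact vs approximate.** Exact signed-rank p-values when the
  effective $n \le 25$ and $|d|$ has no ties, else the normal
  approximation with continuity correction.
* **ICC model.** "Average fixed raters" is read as ICC(3,k): two-way
  mixed effects, consistency, average measures over $k = 2$ raters
  (the two parcellation atlases), with the F-based confidence
  interval. Note that consistency ICC is invariant to additive rater
  shifts but *not* to multiplicative rescaling: $b = 2a + 3$ gives
  ICC(3,2) of exactly $8/9$, not 1. The package follows the standard
  ANOVA definition.

## Predictive models

No SVM implementation ships with the supported environment, so the
package carries its own: a dense SMO solver (maximal-violating-pair
working sets, LIBSVM-style two-variable updates) for the soft-margin
classifier and $\varepsilon$-insensitive regression, with one-vs-one
multiclass voting, ties broken by summed decision values. It was
validated against scikit-learn during development (decision values
agree to the duality-gap tolerance) and is pinned in the tests by a
closed-form two-point dual solution and separable-limit behaviour.

The cross-validation protocol: the outer loop holds out all samples of
one subject; features (and the regression target) are z-scored with
training-fold statistics only; the RBF bandwidth is held fixed per
fold at the median pairwise distance (a fixed-sigma rule that mirrors
"holding sigma constant" without copying an unstated value); C is
tuned over powers of two $2^{-2} \dots 2^7$ by five repeated
subject-wise holdouts, maximising accuracy for classification and
minimising MAE for regression. Reported metrics: balanced accuracy
(mean per-class recall) with a row-normalised confusion matrix;
regression $R^2$ as the squared Pearson correlation between held-out
predictions and truth (matching the predicted-vs-actual scatter
convention), with the $1 - SSE/SST$ variant reported alongside, and
MAE in years.

"Feature importance from standardised coefficients" has no meaning for
an RBF kernel; the package substitutes permutation importance (metric
drop when one feature column is shuffled, averaged over at least 20
seeded shuffles, reusing the fitted fold models) and documents this as
a deliberate deviation.

## The synthetic cohort generator

The generator emulates the *shape* of a cognitive-control FC dataset:
per subject, seven condition matrices (0/1/2-back, go/no-go initiation
and inhibition, shifting, rest) over 229 regions in ten canonical
networks, ages uniform on 20–86. Region signals are built from
latent per-network Gaussian time series ($t = 200$ points by default,
balancing correlation sampling noise against runtime), a fixed signed
cross-network mixing matrix (alternating-sign coupling, so
anti-correlated network pairs — and hence negative edges — exist even
in the fully coherent state), and regional noise (`noise_sd = 1`
relative to a unit-variance latent, giving realistic dispersion of
$|r|$). The output is the regional Pearson correlation matrix, so
every generated matrix is a true (positive semidefinite) correlation
matrix.

### Why conflict phases, not polarity flips

A tempting mechanism for planting imbalance is to flip the sign of a
region's whole signal. It cannot work: sign flips are a *gauge
transformation*. If region $i$ carries polarity $s_i \in \{\pm 1\}$,
every edge weight becomes $s_i s_j \rho_{ij}$ and every triangle
product acquires the factor $(s_i s_j s_k)^2 = 1$ — balance, the
census, and the energy are exactly unchanged. (This is the classical
switching equivalence of signed graphs.)

Instead, a region chosen as "conflicting" (with per-condition
probability `conflict_kappa`) loads on its network's *two* latent
signals at a $\pm 120^\circ$ phase angle. Correlations then behave
like cosines of angle differences, and a triple of regions with
mutually distinct angles in $\{0^\circ, 120^\circ, 240^\circ\}$ has
triangle product $(\cos 120^\circ)^3 = -1/8 < 0$: a genuinely
frustrated triad, while the matrix remains a true correlation matrix.
$\kappa = 0$ yields sign-coherent blocks and strongly negative $U$;
increasing $\kappa$ raises the planted imbalance and moves the median
$U$ monotonically toward 0 (a tested invariant).

Default condition profile: rest $\kappa = 0.05$ (most coherent, lowest
energy), shifting $0.15$, the working-memory and inhibitory-control
tasks $0.25$ — reproducing the qualitative ordering in which rest is
the energy minimum and the shifting task sits between rest and the
other tasks. The optional age effect shifts $\kappa$ linearly with age
(`age_effect_beta`, per year relative to the midpoint, default 0 so
that age carries no signal unless requested).

`reparcellate()` rebuilds a cohort under a second parcellation from
the *same* latent signals with fresh region phases and noise,
emulating two atlases applied to one underlying brain; this is the
input of the ICC reliability analysis. With independently redrawn
latents the pairing is null and the ICC collapses toward 0. At the
realistic scales (229/200 regions) the shared latent component
dominates region-level sampling noise and shared-latent ICC(3,k)
exceeds 0.8; below roughly 100 regions per matrix it need not, which
is why the unit tests use 150 regions and the acceptance test the full
scale.

### What a green test establishes — and what it does not

The generator matches the analysis assumptions (signed symmetric
correlation matrices, community structure, condition-graded
imbalance, an age covariate) but *not* several features of real FC
data: no hemodynamics or autocorrelated time series, no spatial
geometry or distance-dependent connectivity, no heterogeneous network
sizes, no site or motion artefacts, and no Fisher-z transformation
(the ingest path accepts z-transformed input via an explicit flag).
Green pipeline tests therefore establish internal correctness and
qualitative directionality — not that real-data effect sizes or the
published headline accuracies would be reproduced, which depend on
the source dataset and are out of scope by design.

## Pipeline and configuration

All randomness flows from one root seed split per stage, making reruns
byte-identical (tested via manifest checksums). Outputs are
long-format CSV so scopes and conditions extend without schema
changes; the manifest lists every artifact with its MD5. Stage
failures (e.g. a subject without a rest scan breaking $\Delta U$) are
recorded and do not abort independent stages. Configuration is plain
JSON (`jsonlite`); YAML was not adopted because no YAML parser is part
of the supported dependency set.

## Known limitations

* The energy landscape itself — attractors, saddle points, barriers —
  is not modelled; only endpoint energies and their differences.
* Null surrogates are weight permutations; no spatially constrained
  (distance-matched) or degree-preserving binary nulls.
* The SMO solver targets small dense problems (hundreds of samples);
  it is not a general-purpose SVM.
* Exact Friedman enumeration is limited to $(k!)^n \le 2 \times 10^6$.
* The comparator graph measures implement one defensible convention
  each; other toolkits' variants will differ in detail.
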