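---
title: "Comparing essential dynamics across enzyme variants"
author: "e2dyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing essential dynamics across enzyme variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(e2dyn)
```

## The scientific question

E2 ubiquitin-conjugating enzymes receive ubiquitin on a catalytic cysteine
and transfer it to a substrate lysine.  A conserved position in the catalytic
cleft — the conserved E2 Ser/Asp (CES/D) site, Ser120 in hHR6A, Asp127 in
Ube2I — carries either a constitutive aspartate or a phosphorylatable serine,
and mutations there (S120A, S120T, S120E, S120D, phospho-S120) change
conjugation activity from abolished to several-fold enhanced.  Two kinds of
evidence connect the site to function: (i) whether a variant preserves the
*native collective dynamics* of the free enzyme, and (ii) whether the
substrate lysine stays *geometrically aligned* with the catalytic cysteine in
the enzyme–substrate complex.

This package implements the comparative-analysis machinery for both:
essential-dynamics PCA of conformational ensembles on an alignment-mapped
common core, subspace comparison (inner products, eigenvalue crossing-over,
RMSIP, cosine content), per-frame geometry (solvent accessibility, side-chain
distances, contact persistence), CES/D-site motif classification across an E2
alignment, and the exponential model linking catalytic-geometry distance to
measured activity.

## Essential dynamics on a common core

For each system the equilibrated portions of its replicates are concatenated
into a *macro-trajectory* (`preprocessMacroTrajectory()`; the leading frames
of every replicate are discarded as equilibration, by count or fraction —
callers convert a time window via their frame spacing).  Frames are
superposed by weighted least squares (`kabschSuperpose()`, proper rotations
only) onto an iterated mean: fit to the first frame, compute the mean, refit
to that mean, recompute.  The covariance of positional fluctuations about the
final mean is then

$$C = \frac{1}{T}\sum_t (x_t - \bar x)(x_t - \bar x)^\top,$$

so that $\mathrm{tr}(C)$ equals the mean squared fluctuation exactly.  The
`massWeighting` flag multiplies fluctuation components by $\sqrt{m}$ per
element; on a C$\alpha$-only selection all masses are equal, so weighting is
a uniform rescale of the spectrum and the default is unweighted, keeping
eigenvalues in nm².

Cross-system comparability comes from the alignment map
(`commonCoreMap()`): only alignment columns ungapped in *all* systems are
retained, and each system contributes the C$\alpha$ atom of the residue at
each such column, so every system's subspace lives in the same
$3M$-dimensional space.  Column indices are 1-based throughout, following R
convention.  Each system is decomposed separately on this common core
(per-system PCA); a single joint decomposition of the pooled trajectory is a
possible alternative, but per-system subspaces are what per-PC crossing
tables and pairwise RMSIP require, so that is the implemented design.

`pcaDecompose()` performs the full symmetric eigendecomposition in
descending order, clamps eigenvalues in $[-10^{-10}\lambda_1, 0)$ to zero,
and applies a deterministic sign convention (largest-magnitude component of
each eigenvector positive), so repeated runs and degenerate blocks are
reproducible.  Downstream comparisons use subspace overlaps, which are
invariant to rotations inside a degenerate block.

## Comparing subspaces

Naive per-PC comparison of homologous variants is confounded by *eigenvalue
crossing-over*: the motion that is PC 1 in one system may appear at PC 4 in
another.  `bestMatchPC()` makes this visible by reporting the squared inner
product of a chosen reference eigenvector with each of the first `kMax`
(default 10) eigenvectors of the other system.  Robust similarity is then
quantified by the root mean square inner product over the first $D$ modes
(default 20),

$$\mathrm{RMSIP}(V, W) = \sqrt{\frac{1}{D}\sum_{i=1}^{D}\sum_{j=1}^{D}
(v_i \cdot w_j)^2},$$

which is symmetric, equals 1 for identical spans and 0 for orthogonal ones,
and has expectation $\sqrt{D/N}$ for random $D$-dimensional subspaces of an
$N$-dimensional space — the package verifies this analytic baseline by
simulation.  Class-level summaries (`groupBoxplotStats()`) use the
linear-interpolation quantile convention with 1.5 × IQR whiskers clipped to
the data.

Sampling quality is checked per replicate with the cosine content of the PC
projections,

$$c_i = \frac{2}{T}\,
\frac{\left(\int p_i(t)\cos(i\pi t/T)\,dt\right)^2}{\int p_i(t)^2\,dt},$$

integrated by the trapezoid rule over the frame index and clamped to
$[0,1]$; values near 1 mean the projection looks like free diffusion
(undersampling).  One mathematical caveat discovered while testing: the
"orthogonal" control $p(t)=\sin(2i\pi t/T)$ has cosine content zero only for
*even* $i$ (for odd $i$ the product integral is $4/(3\pi i)$), so the
orthogonality checks in the test-suite use $i=2$.  The diffusion control
applies PCA to a freely diffusing particle (each coordinate an unconstrained
random walk) and takes the first-PC projection; its mean cosine content over
seeds is about 0.67, comfortably above the 0.5 discrimination line, whereas
the *raw* centered 1-D walk series (no PCA step) averages about 0.42.

## Geometry of the catalytic cleft

`sasaShrakeRupley()` implements the classic sphere-point algorithm on a
deterministic golden-spiral point set: for each selected atom, the fraction
of `nPoints` (default 960) points on its solvent-extended sphere
($r_\mathrm{vdW}+$ probe) lying strictly outside every other atom's extended
sphere, times $4\pi(r+p)^2$.  Radii are C 0.170, N 0.155, O 0.152, S 0.180,
H 0.120, P 0.180 nm with a 0.14 nm water probe (a standard set; no specific
radii convention is canonical for this analysis).  Points exactly on an
occluder's surface count as buried, so coincident atoms shadow each other
completely.  On an isolated atom the spiral set reproduces the analytic
sphere area to well under 2% at 960 points.

`distanceSeries()` measures, per frame, either the minimum heavy-atom
distance between two side-chain groups (the ion-pair convention, e.g. Lys NZ
versus Asp OD1/OD2 or phospho-Ser phosphate oxygens) or a named atom pair
(catalytic Cys SG versus substrate Lys NZ).  `contactPersistence()` converts
distances to per-frame contacts below a cutoff — 0.48 nm by default, the
ion-pair threshold used for the CES/D–lysine interaction — optionally gated
by a hydrogen-bond criterion (donor–acceptor < 0.35 nm and
donor–H–acceptor angle ≥ 120°, a standard geometric convention), and
reports persistence as the fraction of frames in contact.

## The activity–distance model

Across variants, measured conjugation activity falls off with the mean
catalytic-Cys-to-substrate-Lys distance as
$f(x) = b\,e^{-c x}$.  `fitExponentialActivity()` fits this by unweighted
nonlinear least squares (Levenberg–Marquardt), initialized from the
log-linear closed form on positive activities, and reports the Pearson
correlation between observed and fitted activities; replicate uncertainties
are carried into the report but do not weight the fit.  Degenerate inputs
(constant activities) return decay 0 and correlation 0 with an explicit
flag.  On noiseless points generated from $b = 136.28$, $c = 9.12$ the fit
recovers both parameters to $10^{-6}$; under 5% multiplicative noise the
median recovered parameter over 100 seeds stays within 10% of truth.  (The
*per-seed* error on $b$ is intrinsically larger: with four points on
$x \in [0.3, 0.7]$, an unweighted raw-scale fit is dominated by the
largest-activity points and extrapolates to $x = 0$, which amplifies their
noise by the two-point leverage; this is a property of the design, not of
the optimizer.)

## CES/D motif classification

`classifyCesSite()` locates the alignment column of a reference residue
(e.g. hHR6A Ser120) and reports, per sequence, the site residue, the next
non-gap residue *of that sequence* (+1 is counted in sequence space so
insertions elsewhere cannot break the call), a motif class in
{DP, SP, EP, SA, EA, E, other}, and the Cdk-consensus flag (Ser/Thr
immediately followed by Pro).  Glutamate classifies as EP/EA only with
Pro/Ala at +1 and as E otherwise; `X` and gaps classify as `other`;
sequences are handled case-insensitively.  A Thr–Pro pair satisfies the Cdk
consensus while carrying class `other`, since Thr motifs are not part of the
named class set.  Family-level aggregation of per-sequence calls (labels
like "SP/DP") is left to the user.

## What the synthetic generator emulates — and what it does not

No trajectory data are distributed with the studies this methodology serves,
so the package ships a generator whose ensembles have *exact* second-order
ground truth:

* `makeToyStructure()` builds a compact self-avoiding C$\alpha$/CB fold
  (0.38 nm spacing on a boustrophedon lattice walk, minimum separation
  > 0.2 nm).  Compactness matters: on an elongated toy fold, least-squares
  superposition can absorb transverse fluctuations into fitted rotations and
  distort a prescribed spectrum by tens of percent; on the compact fold the
  distortion is far below sampling noise.
* `sampleGaussianEnsemble()` draws frames $\bar x + \sum_i
  \sqrt{\lambda_i} z_i v_i$ with prescribed eigenvalues along a prescribed
  orthonormal basis.  Bases are drawn orthogonal to the mean structure's six
  rigid-body modes (`randomOrthonormalBasis(orthogonalTo = ...)`), so the
  prescribed spectrum is what the superposition-PCA pipeline should recover.
* `makeVariantFamily()` emulates wild-type-versus-mutant families: variants
  share the reference spectrum but their bases are rotated by a controlled
  angle into directions orthogonal to the whole spectrum and/or
  column-swapped.  The exact RMSIP against the reference is emitted
  alongside; a swap of PCs 1 and 4 reproduces the crossing-over phenomenon
  by construction, and RMSIP decreases as $|\cos a|$ with the rotation
  angle, giving a monotone ground-truth ordering for class comparisons.
* `makeCosineTrajectory()` and `makeContactSeries()` are single-purpose
  fixtures for the cosine-content formula and for persistence fractions.
* `makeHomologSet()` builds homolog sequence/structure sets with designed
  insertions and deletions and emits the shared-column/atom-index ground
  truth that `commonCoreMap()` must reproduce.

Default study conditions mirror a multi-replicate comparative design: decaying
spectra $\lambda_i = 0.1\,e^{-(i-1)/8}$ nm² (top eigenvalue 0.1 nm², per-atom
RMSF around 0.1 nm — the scale of a stable fold's equilibrium fluctuations),
2 replicates per system, hundreds of frames per replicate, 10% equilibration
trim.  Gaussian ensembles reproduce everything the downstream statistics
consume (second moments, per-frame geometry) but none of what they do not:
no anharmonicity, no kinetics, no force field, no solvent.  Passing tests
therefore validate the *analysis machinery*, not any claim about real
protein energetics.

## Numerical choices and problem sizes

* Eigenvalue estimates from a $T$-frame ensemble carry a relative standard
  error of about $\sqrt{2/T}$ ($\approx 2\%$ at $T = 5000$), so the
  spectrum-recovery check averages estimated spectra over three replicate
  ensembles before applying its 5% bound — a single draw would breach that
  bound by chance roughly one run in eight even for a perfect implementation.
* The test-suite and the acceptance script run end-to-end problems at
  40 atoms / 24 modes / 2 × 500 frames, and estimator checks at 60 atoms /
  60 modes / 5000 frames; on one CPU the full suite completes in about a
  minute.
* Orthonormality is validated at $10^{-8}$, symmetry of covariance inputs at
  $10^{-8}$, eigenvalue clamping at $-10^{-10}\lambda_1$; the PDB round-trip
  preserves coordinates to $10^{-4}$ nm (file precision).
* Report tables serialize numbers at 6 significant digits and are
  byte-reproducible for identical inputs; all randomness flows from explicit
  integer seeds, and the RNG state of the caller is never touched.

## Known limitations

* Gaussian ensembles cannot test sensitivity to anharmonic or multi-basin
  dynamics; crossing-over is emulated by construction, not emergent.
* The SASA implementation is $O(\text{selection} \times \text{atoms})$ per
  frame — appropriate for side-chain selections over thousands of frames,
  not for whole-proteome scans.
* `runPipeline()` compares systems without an alignment only when their
  mapped atom counts agree; heterogeneous systems require an MSA.
* Binary trajectory formats are out of scope; multi-model PDB is the
  interchange format.
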