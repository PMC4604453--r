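# e2dyn — cross-variant essential dynamics comparison

`e2dyn` compares the collective dynamics of homologous protein
conformational ensembles — typically wild-type, point-mutant and
phosphorylated variants of the same enzyme — and measures the
catalytic-cleft geometry that links those dynamics to function.  It was
built around the comparative analysis of E2 ubiquitin-conjugating enzymes,
where a conserved Ser/Asp position in the catalytic cleft (the CES/D site;
Ser120 in hHR6A, Asp127 in Ube2I) tunes how the substrate lysine aligns
with the catalytic cysteine, but every component is generic.

**Who it is for:** structural bioinformaticians with multi-replicate
conformational ensembles (multi-model PDB) of several related systems, a
multiple sequence alignment relating them, and per-variant activity data,
who want a reproducible, tested pipeline from raw frames to class-level
comparisons.

## What it computes

* **Essential dynamics on a common core.**  Replicates are trimmed and
  joined into a macro-trajectory; frames are superposed (Kabsch, weighted,
  two-pass iterated mean); the covariance of positional fluctuations
  `C = (1/T) Σ (x−x̄)(x−x̄)ᵀ` is decomposed per system on the Cα atoms of
  alignment columns ungapped in *all* systems, so every subspace lives in
  the same 3M-dimensional space.
* **Subspace comparison.**  Squared inner-product overlap matrices; an
  eigenvalue *crossing-over* diagnostic (`bestMatchPC`) that finds where a
  reference PC reappears in another system's spectrum; the root mean square
  inner product over the first D = 20 modes,
  `RMSIP = sqrt( (1/D) Σᵢⱼ (vᵢ·wⱼ)² )`, with class-wise boxplot statistics;
  and per-replicate cosine contents `cᵢ = (2/T)(∫pᵢ(t)cos(iπt/T)dt)²/∫pᵢ²dt`
  as a sampling-quality check.
* **Catalytic-cleft geometry.**  Shrake–Rupley solvent accessible surface
  of the catalytic cysteine side chain (960 golden-spiral points, 0.14 nm
  probe); per-frame minimum heavy-atom or named-pair distances between the
  substrate lysine and the CES/D residue or catalytic cysteine; ion-pair /
  hydrogen-bond persistence fractions (default cutoff 0.48 nm).
* **Activity model.**  Unweighted nonlinear least-squares fit of
  `activity = b·exp(−c·distance)` with the Pearson correlation of observed
  vs fitted activities.
* **CES/D motif scan.**  Per-sequence classification of the site into
  {DP, SP, EP, SA, EA, E, other} plus the Cdk phosphorylation consensus
  flag (Ser/Thr immediately followed by Pro).
* **Synthetic ground truth.**  A generator of Gaussian ensembles with
  prescribed eigen-spectra, controlled subspace rotations/swaps between
  "variants", designed contact occupancies, and homolog sets with known
  alignment cores — so the whole pipeline is testable without trajectories.

## Worked example

Build a synthetic family — one reference plus three variants whose
essential subspaces are rotated by 0.4 rad, rotated by 1.2 rad, and
PC-swapped (PC1 ↔ PC4) — then run the full pipeline:

```r
library(e2dyn)

spec <- spectrumSpec(0.1 * exp(-(0:11) / 8), nAtoms = 20, seed = 1)
fam <- makeVariantFamily(
  spec,
  list(perturbationSpec(angle = 0.4),
       perturbationSpec(angle = 1.2),
       perturbationSpec(angle = 0, swapMap = list(c(1, 4)))),
  nFrames = 1500, nReplicates = 2, seed = 2, D = 12)
round(fam$groundTruthRmsip, 3)
#> [1] 1.000 0.921 0.362 1.000

config <- list(
  systems = list(
    list(id = "wt",        replicates = fam$ensembles[[1]], class = "wild-type"),
    list(id = "mildMut",   replicates = fam$ensembles[[2]], class = "mild"),
    list(id = "severeMut", replicates = fam$ensembles[[3]], class = "severe"),
    list(id = "crossMut",  replicates = fam$ensembles[[4]], class = "crossed")),
  referenceId = "wt", D = 12L, kMax = 10L, trim = 0.1, seed = 2L)
report <- runPipeline(config)

report$rmsipPairwise[report$rmsipPairwise$systemA == "wt", ]
#>   systemA   systemB rmsip
#> 1      wt   mildMut 0.921
#> 2      wt severeMut 0.362
#> 3      wt  crossMut 1.000
```

The estimated pairwise RMSIP values reproduce the constructed ground truth:
the mild 0.4 rad rotation barely perturbs the subspace (0.921), the severe
1.2 rad rotation disrupts it (0.362), and the PC swap leaves the *span*
identical (1.000) while relocating the leading motion — which is exactly
what the crossing diagnostic reports:

```r
cr <- report$crossing[["crossMut"]]
cat("reference PC1 best matches variant PC", cr$bestMatch,
    "with overlap", round(cr$bestOverlap, 3), "\n")
#> reference PC1 best matches variant PC 4 with overlap 0.828

max(report$cosineContent$cosineContent)
#> [1] 0.003
```

The low cosine content (≪ 0.30) says the synthetic replicates are
well-converged rather than diffusive.  With per-variant activities in the
configuration the pipeline also fits the exponential activity–distance
model; standalone:

```r
fit <- fitExponentialActivity(
  distances  = c(0.34, 0.38, 0.45, 0.55, 0.72),   # nm
  activities = c(400, 300, 100, 35, 2))
fit
#> ActivityFit: activity = b * exp(-c * x)
#>   b = 17907.5  c = 11.0763 nm^-1  correlation = 0.992
```

`runPipeline(config, outDir = "results/")` additionally writes a
deterministic TSV/JSON report bundle (pairwise RMSIP, crossing tables,
class statistics, cosine contents, SASA, distances, persistence, activity
fit, CES calls, and a structured log); identical configuration and inputs
give a byte-identical bundle.

## See also

The methods vignette (`vignettes/essential-dynamics-comparison.Rmd`)
documents the model, the numerical conventions, what the synthetic
generator does and does not emulate, and the package's design decisions.
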