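---
title: "Methods: clone-resolved single-cell exome analysis with scExome"
author: "scExome authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clone-resolved single-cell exome analysis with scExome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scExome)
```

# Overview

`scExome` implements a clone-resolved analysis of single-cell whole-exome
sequencing (scWES) of tumors, together with a clone-structured simulator
that provides ground truth for every stage. The pipeline has five
analytic layers:

1. **Somatic SNV calling** — a one-sided Fisher exact somatic test per
   site against a matched normal, followed by a multi-stage filter
   cascade ending in a ternary (mutant / wild-type / no-coverage)
   per-cell mutation matrix.
2. **Copy-number inference** — exonic RPKM per gene, genome-ordered,
   smoothed with a 100-gene moving average, centrally scaled, masked,
   and summarized per chromosome with the strict `mean(a) > mean(t)`
   amplification rule.
3. **Clonality** — normalized Hamming distances, neighbor joining,
   Fitch parsimony with acctran-style branch mutation counts, a
   parsimony-ratchet search, subclone identification, and mutation
   saturation (rarefaction) curves.
4. **Mutational signatures** — 96-channel trinucleotide spectra in the
   pyrimidine-strand convention and non-negative least-squares exposure
   fitting against a user-supplied reference catalog.
5. **Reporting** — three-group driver classification against
   tumor-suppressor / oncogene lists and oncoplot matrix exports.

# The somatic SNV model

Each site in each sample is a pair of read counts `(ref_reads,
alt_reads)`; the variant allele fraction is VAF = alt / (ref + alt).
The somatic test conditions on the margins of the 2×2 table
(normal/tumor × ref/alt) and computes the exact hypergeometric tail
probability that the tumor is at least as alt-enriched as observed —
the test used by VarScan-style somatic callers. `somaticFisherP()`
evaluates the tail in closed form through `stats::phyper`; the test
suite checks it against full enumeration of all margin-fixed tables to
1e-12.

The cascade retains a site when (defaults from `filterThresholds()`):

| stage | rule | default |
|---|---|---|
| bulk coverage | depth ≥ `bulkMinCov`, alt ≥ `bulkMinVar` | 20, 5 |
| cell coverage | depth ≥ `cellMinCov`, alt ≥ `cellMinVar` | 10, 3 |
| somatic status | normal VAF ≤ `maxNormalVaf`, tumor VAF ≥ `minTumorVaf`, p < `pMax` | 0.10, 0.10, 5e-3 |
| recurrence | candidate in ≥ `minCells` distinct cells | 3 |
| uniqueness | (site, allele) private to one individual | — |
| rescue | alt ≥ `rescueMinVar` re-asserts mutant in any cell | 2 |

Design points worth making explicit:

* **No multiple-testing correction.** The 5e-3 cut is applied to raw
  p-values; the recurrence and uniqueness stages do the false-positive
  control that a per-site FDR would otherwise attempt.
* **Uniqueness is per (site, allele).** Whether the cross-individual
  filter should compare positions or position+allele is genuinely open;
  comparing the allele is the stricter, more mechanistic contract and is
  what `uniquenessFilter()` does.
* **`wtAssertMinDepth = 5`.** The ternary matrix distinguishes asserted
  wild type from no coverage. A rescue-stage cell with fewer than 2 alt
  reads is only called wild type when its depth reaches 5; below that
  the site is unknowable in that cell and is encoded ".". The threshold
  is exposed in `filterThresholds()`, not hidden.
* **Multi-allelic sites.** Only the listed alternate allele is tested;
  reads supporting other bases count as neither ref nor alt.
* **Monotonicity.** Tightening any single threshold can only shrink the
  surviving-site set; this is property-tested across the cascade.

# Copy-number inference

Gene-level counts are normalized to RPKM — reads / (exonic kb × library
millions) — ordered by (chromosome rank, start) with X after the
autosomes, smoothed with a centered 100-gene moving average, and
centrally scaled. The per-cell, per-chromosome summary `mean(a)` is the
mean scaled value of the chromosome's genes in that cell; `mean(t)` is
the mean of `mean(a)` over tumor cells; a cell is called amplified when
strictly `mean(a) > mean(t)`.

Several steps of that recipe required interpretation:

* **"Centrally scaled"** is implemented per-gene across cells
  (z-score), because the [−1, 1] removal band and heat-map convention
  both presuppose values on a cohort-standardized scale; per-cell
  centering is available via `cnvParams(scaling = "cell")`.
* **Window boundaries.** The 100-gene window runs over one
  genome-ordered list by default, so windows may span chromosome
  junctions (the single ordered list is what the smoothing is defined
  on); `cnvParams(boundary = "chromosome")` restarts windows at each
  chromosome. At the ends of the list the window truncates to the
  available genes. A truncated centered window does **not** preserve
  the plain per-cell mean; the conserved identity, which the tests
  assert, is the truncation-aware weighted form
  `sum(n_i * smoothed_i) = sum(c_i * raw_i)` where `n_i` is the window
  size at gene i and `c_i` the number of windows covering gene i (for
  symmetric odd windows `n_i = c_i`).
* **Mask semantics.** The low-amplitude band [−1, 1] (closed) and the
  wild-type-control round-off mask (half-away-from-zero rounding,
  |rounded| ≥ 1) are display/selection masks: they suppress entries in
  the exported heat-map matrix. `mean(a)` is computed from scaled
  values of all chromosome genes *excluding only control-masked genes*,
  which are removed from the analysis entirely. Excluding
  low-amplitude-masked entries as well would make the call undefined
  for exactly the cells one wants to call whenever a whole chromosome
  smooths to a common value inside the band (the window is of the same
  order as a chromosome's gene count), because z-scores of the carrier
  majority sit inside [−1, 1] by construction.
* **Rounding.** "Round-off" in the control mask is half-away-from-zero
  (1.5 → 2, −1.5 → −2), not banker's rounding.
* **Null behavior.** Because the call is a strict comparison with the
  cohort mean, any symmetric coverage noise flags about half the cells
  of a truly neutral cohort. The meaningful null guarantee is the
  noise-free one — identical cells produce no calls — and detection
  claims are therefore made (and tested) only at stated effect sizes:
  at total copy 4, WGA sigma 0.3 and 100 genes per chromosome, carrier
  cells are recovered with accuracy ≥ 0.95.
* **No log transform by default**; `cnvParams(logTransform = TRUE)`
  applies log2(x + 1) to RPKM before smoothing.
* The high-amplitude retention mode (`retainHighAmplitude()`, band
  ±1.5, strict) reproduces the xenograft-comparison display rule.

# Clonality

The ternary matrix maps to presence/absence/missing. Distances are
normalized Hamming over pairwise-complete sites — the treatment of
no-coverage entries in tree building is not standardized anywhere, so
the package makes the conservative pairwise-complete choice and raises
an error when two cells share no informative site.

`neighborJoining()` is a from-scratch Saitou–Nei implementation with
two determinism rules: Q-criterion ties break toward the lowest (row,
column) pair, and negative branch lengths clamp to zero with the
deficit shifted to the sister branch. On additive matrices it provably
recovers the generating topology (property-tested against random trees
up to 8 leaves, cross-checked against `ape::nj`).

`fitchParsimony()` counts state changes bottom-up (missing leaves are
uninformative) and resolves states top-down: the root prefers absence
(the ancestral somatic state) and each node keeps its parent's state
whenever its state set allows, so forced changes land on the most
root-proximal branch — an acctran-style resolution that yields
per-branch mutation counts summing exactly to the parsimony score.
Mutations carried by every cell are invariant characters and cost 0;
branch lengths therefore count mutations *arising within* the sampled
tree.

`ratchetSearch()` alternates NNI hill climbing under perturbed weights
(a random 10% of characters doubled — the classic ratchet perturbation)
with hill climbing under original weights, from a neighbor-joining
start, 25 iterations by default, seed mandatory. On 7-leaf instances it
attains the optimum over all 945 unrooted topologies scored by an
independent implementation.

Subclones are bipartition sides of mutation-supported internal edges
with at least 5 cells ("more than four cells"), maximal under
containment. Saturation curves report the Monte-Carlo mean and SD of
cumulative unique SNVs over random cell orderings next to the
closed-form rarefaction expectation
`E[U_k] = sum_s (1 − C(n−c_s, k) / C(n, k))`.

**Percent formatting.** Incidence percentages round to the nearest
integer except when the truncated first decimal is exactly 5, in which
case one decimal is kept (10/18 prints as 55.5%, not 56%); the raw
fraction is always returned alongside. The denominator is every cell of
the group, including no-coverage cells.

# Mutational signatures

Spectra live on the 96 channels (6 pyrimidine substitution classes × 16
flanking contexts); purine-reference substitutions are
reverse-complemented, context included. Exposure fitting minimizes the
squared error between the normalized spectrum and a non-negative
combination of catalog rows using Lawson–Hanson active-set NNLS
(`pracma::lsqnonneg`), then zeroes exposures below the 0.06 reporting
cutoff and renormalizes — the cutoff mirrors the default of the
standard refitting tool in this space. The fit is scale-invariant,
nested (adding a signature never increases the residual), and recovers
well-separated synthetic mixtures to 1e-6. Trinucleotide contexts must
arrive with the input SNVs (the simulator provides them); the package
does not extract them from a reference genome, and no reference catalog
is bundled — the catalog is an input (`readSignatureCatalog()`).

# What the simulator emulates — and what it does not

`buildCloneTree()` + `simulateExperiment()` generate: a rooted clone
genealogy with disjoint edge SNV sets (so a clone's genotype is the
union along its root path), per-clone copy-number segments inherited by
descendants, multinomial cell sampling from per-sample clone fractions,
and per-cell read counts under a WGA noise model:

* depth per site: Poisson(meanDepth × lognormal(0, wgaSigma)) — the
  lognormal multiplicative factor is the standard surrogate for
  MDA/WGA over-dispersion; default sigma 0.5;
* allelic dropout: each chromosomal copy drops independently with
  probability `adoRate` (default 0.1), the simplest model that exposes
  the cascade's false-negative behavior; surviving allele fractions are
  dosage-weighted;
* sequencing error: reads miscall to the listed alternate base with
  probability `seqErrorRate` (default 1e-3), so wild-type sites have an
  error-floor VAF of exactly `seqErrorRate` in expectation;
* gene counts: expected reads ∝ (copy number / 2) × exonic length ×
  library size × lognormal noise, against a fixed neutral-genome
  length denominator, so a copy-4 chromosome doubles its genes'
  expected coverage exactly;
* bulk samples: purity-weighted sums of cell counts blended with an
  equal-depth copy-neutral, reference-only (plus error) matched-normal
  contaminant; a deterministic-mixture switch returns expected counts
  without Poisson resampling so conservation is exact, and a pure
  matched normal is always emitted as the control.

Default conditions (4 clones, 20 SNVs per edge, 20 cells per sample,
200× site depth) put per-cell somatic burdens in the 20–80 range, inside
the 17–104 per-cell span reported for the study system this emulates.

Not modeled: read-level artifacts (FASTQ, alignment, mappability, GC
bias), doublets, chimeric WGA reads, copy-number breakpoints within
genes, and locus-correlated dropout. Passing tests on these simulations
therefore demonstrate the *algorithmic* correctness of the cascade and
callers under a plausible noise model, not robustness to every real
scWES artifact.

# Numerical choices and problem sizes

* Fisher tail probabilities: closed hypergeometric form; exactness
  asserted to 1e-12 against enumeration for margins ≤ 60.
* Moving-average: cumulative-sum implementation; even windows put the
  extra gene 3'.
* z-scoring guards constant genes (mapped to 0) and requires ≥ 2 cells.
* NJ tie-break and clamping as above; ratchet and all simulations take
  explicit seeds, and every stage is byte-deterministic given them.
* Test and validation problem sizes were chosen to exercise each
  property at desk scale: 20–50 cells, 16–80 SNVs, 600 genes over 6
  chromosomes for CNV recovery, 945-topology exhaustive parsimony at 7
  leaves, 2×2 enumeration at margins ≤ 60. The full suite runs in well
  under a minute on one core.

# Known limitations

* The amplification rule is relative to the analyzed cohort: it cannot
  label a cohort-wide gain, and in a truly neutral noisy cohort it
  flags ~half the cells; interpret calls only where a carrier
  subpopulation plausibly exists.
* Parsimony search is heuristic beyond ~8 cells; the ratchet guarantees
  only score ≤ the NJ start.
* The uniqueness filter needs ≥ 2 individuals; with one it passes
  through with a warning.
* Exposure fitting inherits the identifiability limits of NNLS:
  near-collinear catalog signatures trade weight freely; the grid-search
  agreement is only asserted for well-separated synthetic signatures.

# A worked run

```{r example, eval = FALSE}
gm <- simGeneModel(genesPerChrom = 30)
tree <- buildCloneTree(2, snvsPerEdge = 8, geneModel = gm, seed = 11,
                       fractions = list(S1 = c(C1 = 0.5, C2 = 0.5)))
cfg <- simConfig(nCellsPerSample = 20, meanDepth = 60, wgaSigma = 0.3,
                 adoRate = 0, seqErrorRate = 1e-3, seed = 12)
sim <- simulateExperiment(tree, cfg, gm)
res <- runSnvPipeline(sim$siteCounts, sim$bulk$S1$normalSites,
                      bulk = sim$bulk$S1$bulkSites)
rs <- ratchetSearch(asBinaryMatrix(res$matrix), nIters = 5, seed = 13)
findSubclones(rs$tree)
```

The same orchestration, with all outputs written to disk and a JSON run
manifest, is available as `runAll(config, outdir)`.
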