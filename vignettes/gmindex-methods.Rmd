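---
title: "Gene Marker Indices: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene Marker Indices: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Laboratory stress experiments on isolated organisms tell us how a species
*can* respond to cold or desiccation; they do not tell us what it is
experiencing inside a natural community. For organisms such as
*Klebsormidium* in polar biocrusts, metatranscriptomic sequencing of the
whole community offers a window: if the organism's transcripts can be
recognized in the mixed read pool, their expression pattern can be compared
with lab-calibrated stress signatures. `gmindex` implements that comparison
in two complementary ways — a per-pair ratio statistic (the Gene Marker
Index) and a whole-gene-set profile comparison (Bray–Curtis / Ward.D2 /
SIMPROF).

# Marker selection

From a replicated lab count table with conditions control, cold and
desiccated, `classifyRegulation()` labels each transcript per stressor as
`up`, `down` or `not_regulated` using three simultaneous thresholds: fold
change above 2, p below 0.05, and Benjamini–Hochberg FDR below 0.05 (the FDR
family is all transcripts tested for that stressor). The classifier is
deliberately lightweight: log2 fold change of condition means (pseudocount
0.5 against zeros) and a Welch two-sample test on `log2(scaled abundance +
1)`, with abundances first scaled to a common library size. The tests
operate on a count-like scale because both the pseudocount and the `+ 1`
transform are meaningless on sum-to-one relative abundances; all downstream
ratio quantities are scale-invariant, so this choice affects presentation
only. The framework's contribution is downstream of differential expression,
so users with a full negative-binomial DE analysis can inject its output via
`readRegulationTable()` — the catalog logic is unchanged.

Constantly expressed transcripts (`findConstant()`) are the ratio
denominators, in the spirit of housekeeping-gene normalization. "Constant"
is not defined quantitatively in common usage, so the package fixes it as:
`not_regulated` under both stressors, |log2 fold change| below 0.5 under
both, and nonzero mean abundance in every condition. The 0.5 bound (a fold
change of about 1.4) is strict enough that denominator drift contributes
little to the pair ratio, yet loose enough to retain a usable set under
replicate noise.

`buildCatalog()` partitions regulated transcripts into cold-specific,
desiccation-specific and dual-regulated sets. Only single-stressor
transcripts enter index calculation — a dual-regulated transcript cannot
attribute its signal to one cause — but the dual set is kept because the
wider profile comparison (dataset 2 below) includes it.

# The Gene Marker Index

For pair *i* = (regulated *r*, constant *c*), the lab bounds are

$$X_{i,\min} = \frac{\bar r_{\mathrm{ctrl}}}{\bar c_{\mathrm{ctrl}}},
\qquad
X_{i,\max} = \frac{\bar r_{\mathrm{stress}}}{\bar c_{\mathrm{stress}}},$$

with means over the replicates of the named condition, and the index of a
field sample with ratio \(X_i\) is

$$\mathrm{GMI}_i = \frac{X_i - X_{i,\min}}{X_{i,\max} - X_{i,\min}} \times 100 .$$

Numerical and design choices:

* **Mean-then-ratio.** Bounds are ratios of replicate-mean abundances, not
  means of per-replicate ratios. Ratios of small counts are heavy-tailed;
  averaging first is stabler, and it makes the linear recovery property
  below exact in expectation.
* **Degeneracy guard.** Pairs with a zero denominator mean, a nonpositive
  or nonfinite bound, or \(|X_{\max} - X_{\min}| < \delta\) (default
  \(\delta = 10^{-9}\) on relative abundances) are dropped with a recorded
  reason rather than producing unstable indices.
* **Skip, don't pseudocount.** In a field sample where the constant
  transcript has zero abundance the record is skipped (with a reason
  distinct from "transcript absent"). A pseudocount would break the exact
  invariance of the index under per-sample rescaling of raw counts — a
  property worth keeping, since sequencing depth varies wildly between
  field replicates.
* **Down-regulated markers** need no special casing: \(X_{\max} <
  X_{\min}\) simply reverses the affine map, so a treatment-like field
  ratio still scores 100.
* **Categories.** Values outside [0, 100] are classed `below_range` /
  `above_range`; in-range values fall into quartile bins [0,25), [25,50),
  [50,75), [75,100], a readable discretization of effect strength. The bin
  edges are a package choice; nothing downstream depends on them.
* **Normalization base.** All abundances are normalized per sample over the
  organism-assigned transcripts (`normalizeRelative()`). Whole-dataset
  totals differ from this by a per-sample scalar, which cancels in every
  ratio, so the choice is immaterial for the indices; it does matter for
  Bray–Curtis, where the organism-subset base is the ecologically sensible
  one.

# Field matching

Field contigs are matched to the reference transcript set by a precomputed
BLAST tabular file. `filterHits()` retains hits with at least 98% identity
and e-value at most 1e-50 — the conventional thresholds for recognizing
conspecific transcripts across strains — then keeps the best hit per contig
(bit score, then identity, then lexicographically smallest subject, so ties
resolve deterministically). The 1e-50 default can be tightened (e.g. to
1e-66) through the threshold arguments. Abundances of several contigs
matching one reference transcript are summed by `mapToReference()`:
fragmented assemblies of one gene partition its reads, and summing restores
them; taking the maximum would discard reads. Any further manual curation of
the matched set is the user's responsibility; the package implements only
the stated quantitative filters.

# Profile comparison

`buildDataset()` combines lab control and stress replicates with the field
replicates over a marker set and renormalizes each column. Dataset 1 holds
only the stressor-specific transcripts used for the indices; dataset 2 adds
the other stressor's and the dual-regulated transcripts. Comparing the two
is informative: dual-regulated genes dilute a stressor-specific signal.

`brayCurtis()` and `wardCluster()` delegate to vegan and stats — these are
standard steps; the package's tests nevertheless verify them against a
brute-force double loop and a hand-written Lance–Williams agglomerator.
Ward.D2 on Bray–Curtis input is technically improper (Bray–Curtis is not
Euclidean) but is the established practice this package follows; heights
should be read as merge costs, not variances.

`simprof()` is implemented in the package. For a group of samples the
observed profile is the sorted vector of pairwise Bray–Curtis similarities;
the null hypothesis of no internal structure is emulated by permuting each
transcript's values independently across the group's samples. The statistic
\(\pi\) is the summed absolute departure of the observed profile from the
mean of `nExpected` null profiles, and its p-value comes from `nSimulated`
further permutations with the add-one rule, so p is never exactly zero.
Defaults are 999 + 999 permutations at \(\alpha = 0.05\), applied per node
without multiplicity correction — standard SIMPROF practice. The recursion
tests the dendrogram root first and descends only into significant nodes;
groups smaller than three samples are terminal, since two samples admit only
one pairwise similarity and no profile. Two implementation details worth
knowing:

* Each tested group draws its permutations from a stream derived from the
  global seed and the group's sorted member names, and the group's submatrix
  is canonicalized (rows and columns sorted by name) before permuting.
  Results are therefore identical for any input column order.
* The per-node test is exact under exchangeability; the suite includes a
  500-replicate simulation confirming the root-level type-I error sits at
  the nominal 5% within binomial error.

# The synthetic-data generator

`SyntheticScenario` / `simulateLabExperiment()` emulate the *output* of a
quantified RNA-seq stress experiment — not reads, alignments or assemblies.
Counts are negative-binomial with variance \(\mu + \phi\mu^2\), the standard
overdispersion model for RNA-seq; \(\phi = 0\) degenerates to Poisson.
Regulated transcripts multiply their baseline mean by a true fold change
drawn from `foldChangeRange` (default [4, 8]; the lower bound must exceed
the detection threshold of 2, otherwise the truth labels would be
undecidable by construction). Defaults follow the shape of a modest algal
stress experiment: 2000 transcripts, 60 up- and 60 down-regulated per
stressor, 100 constant transcripts, 3 replicates per condition, library
sizes near 10^6. The dual-regulated set is sized so that one third of the
union of regulated transcripts responds to both stressors — the overlap
level reported for cold and desiccation response in *Klebsormidium* — e.g.
11 + 11 single-stressor transcripts imply 11 dual ones.

Field samples interpolate: at latent stress \(s\), expected abundance is
\((1-s)\,E[\mathrm{control}] + s\,E[\mathrm{stress}]\), rescaled to a drawn
library size and re-drawn with a separate field dispersion (field replicates
of environmental samples are noisier than clonal lab cultures; the default
reuses the lab value since no field noise characterization exists to copy).
Arithmetic interpolation is a deliberate choice over geometric: with a
constant denominator it makes the population pair ratio exactly
\((1-s)X_{\min} + sX_{\max}\), hence expected index \(100s\) — an
analytically grounded recovery target that the acceptance suite checks at
\(s \in \{0, 0.25, 0.5, 0.75, 1\}\) within ±10 index points. Default latent
levels (0.25, 0.5, 0.75) span the range with three field replicates,
mirroring typical per-site replication.

`simulateIdentityHits()` fabricates the BLAST stage's output: every true
transcript gets a passing hit (identity in [98, 100], e-value ≤ 1e-60) and
decoys fail either the identity or the e-value filter, straddling both
thresholds so the filter logic is exercised on both sides.

All three simulators derive their RNG streams from the scenario seed by a
fixed splitting rule (stream \(8\,\mathrm{seed} + k\) with a fixed small
\(k\) per simulator), so adding a simulator never perturbs existing streams
and identical scenarios are bit-reproducible.

**What passing tests do and do not show.** The generator produces clean,
exchangeable replicates, linear lab-to-field mixing, and an identity table
whose truth is recoverable by thresholding. Real metatranscriptomes violate
all three: community composition shifts between replicates, field stress is
neither scalar nor linear in expression, and cross-species BLAST hits are
not cleanly separable at 98%. Passing tests therefore validate the
*machinery* — classification honors its thresholds, the index recovers a
known latent signal, SIMPROF holds its size — not the ecological claim that
any particular field community is stressed.

# Problem sizes

The test suite runs scenarios of 300–2000 transcripts with 3–5 replicates,
and the SIMPROF calibration uses 500 replicate runs of 8 samples with
99 + 99 permutations — sizes at which every property being tested is already
stable, keeping the default suite under a minute. The acceptance script's
quantities (pair counts from the per-site catalog sizes; endpoint indices on
noise-free profiles) are deterministic and run in seconds.

# Known limitations

* The differential-expression classifier is a two-sample Welch test on
  transformed abundances, not a count-model GLM; at 2–3 replicates and
  moderate overdispersion it is conservative. Use `readRegulationTable()`
  to substitute a dedicated DE analysis when available.
* Indices from pairs with near-degenerate bounds are dropped, not shrunk;
  there is no variance estimate attached to an individual GMI. Interpret
  single indices only in aggregate (`summarizeGMI()`).
* SIMPROF p-values are per node and uncorrected; with deep dendrograms the
  family-wise error across nodes grows. This mirrors standard usage but
  should temper over-reading of marginal clusters.
* The field matcher trusts the provided identity table; it cannot detect a
  reference transcript captured by a paralog from another community member.
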