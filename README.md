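# gmindex

Detecting environmental stress *in situ* from metatranscriptomic data.

Communities such as polar biocrusts contain organisms — e.g. the filamentous
green alga *Klebsormidium* — whose stress physiology is well characterized in
the laboratory but essentially unobserved in the field. `gmindex` implements
a framework that bridges that gap: transcripts that are stress-regulated or
constantly expressed in replicated lab experiments (control, cold,
desiccated) become markers, and their expression ratios in field
metatranscriptomes are read against the lab-calibrated range.

## The statistic

For every pair *i* of one stress-regulated transcript and one constantly
expressed (housekeeping-like) transcript, let *X* be the ratio of their
abundances. With *X*<sub>i,min</sub> the ratio in the lab control,
*X*<sub>i,max</sub> the ratio in the lab treatment and *X*<sub>i</sub> the
ratio in a field sample, the Gene Marker Index is

&nbsp;&nbsp;&nbsp;&nbsp;GMI<sub>i</sub> = (X<sub>i</sub> − X<sub>i,min</sub>) / (X<sub>i,max</sub> − X<sub>i,min</sub>) × 100,

the field ratio as a percentage of the maximal lab effect: 0 means
control-like, 100 means treatment-like, values outside [0, 100] mean the
field fell below the lab control or beyond the lab treatment. The same
formula serves down-regulated markers (there X<sub>max</sub> < X<sub>min</sub>).

Because single indices are noisy in the wild, the package also compares whole
marker-gene-set expression profiles: Bray–Curtis dissimilarity between
relative-abundance profiles, Ward.D2 hierarchical clustering, and a
similarity-profile (SIMPROF) permutation test applied recursively down the
dendrogram to find statistically supported clusters — field samples joining
the lab stress cluster indicate that stress *in situ*.

A synthetic-data module generates lab and field count tables with known
regulation labels and known latent field stress fractions, so the entire
pipeline is testable without sequencing data.

## Worked example

```r
library(gmindex)

scn <- SyntheticScenario(nTranscripts = 1000, nReplicates = 3,
                         fieldStressLevels = c(0.8, 0.9, 0.85), seed = 42)
sim <- simulateLabExperiment(scn)
recCold <- classifyRegulation(sim$counts, "cold")
recDes  <- classifyRegulation(sim$counts, "desiccation")
catalog <- buildCatalog(recCold, recDes,
                        findConstant(recCold, recDes, sim$counts))
catalog
#> MarkerCatalog
#>   cold       : 135 regulated, 119 constant
#>   desiccation: 129 regulated, 119 constant
#>   dual-regulated: 107

field  <- simulateFieldSamples(scn, sim$counts, sim$truth, "cold")
bounds <- computePairBounds(normalizeRelative(sim$counts), catalog, "cold")
gmi    <- computeGMI(bounds, normalizeRelative(field))
summarizeGMI(gmi)
#> GMI summary: 48195 records, 37075 in range (mean 75.3%, SD 20.0%)
#>   out of range: 2.6% below control, 20.5% above treatment

ds <- buildDataset(catalog, normalizeRelative(field), sim$counts,
                   "dataset1", "cold")
simprof(ds, nExpected = 999, nSimulated = 999, seed = 42)
#> SimprofResult: 9 samples, 3 node(s) tested, alpha = 0.05
#>   2 significant cluster group(s):
#>    - ctrl_3, ctrl_1, ctrl_2
#>    - cold_2, cold_3, cold_1, field_2, field_1, field_3
```

The three field replicates were simulated at latent stress 0.8–0.9: the mean
in-range index (75.3%) points well toward the treatment end of the lab range,
and in the profile comparison the field samples form a statistically
significant cluster with the lab cold-stress replicates while the controls
stay apart — the same two readouts the framework provides on real field data.

`runPipeline()` chains all stages from a YAML config (or an R list) and
writes the marker catalog, pair bounds, GMI records and summaries, annotated
Newick dendrograms, a stage log and a provenance manifest; identical
config + seed reproduce outputs byte for byte.

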