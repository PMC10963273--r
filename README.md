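# fosmap

Whole-brain Fos density mapping and immediate-early-gene (IEG) activation
scoring for chemogenetic activation studies.

When hypothalamic feeding circuits are manipulated (e.g. AgRP-neuron
stimulation combined with POMC-neuron inhibition), downstream activation is
read out in two complementary ways: Fos immunolabelling across a cleared,
registered whole brain, and IEG induction in single-nucleus RNA-seq
clusters of the affected region. `fosmap` implements both computational
readouts as a tested, reusable R package, together with seeded
synthetic-data generators that make every stage verifiable with known
ground truth.

## The methods

**Fos mapping.** On a registered intensity volume (canonically 25 µm
isotropic), a voxel is Fos-candidate when its value is at least
(1 + *f*) times each of its 26 surrounding voxels (*f* = 0.20 by default)
and its full neighbourhood lies inside the tissue mask. Connected
components of 1–8 candidate voxels count as one Fos⁺ cell; larger
components are artefacts. Local density is the cell count in a sliding
uniform 20×20×20-voxel window (0.125 µl) in cells/µl, and groups of
density maps are compared by a voxelwise two-sided two-sample *t*-test
(Student by default, Welch available), with region summaries over a label
volume.

**IEG activation score.** After QC (cells with < 800 UMIs, < 500 genes or
> 10 % mitochondrial reads are removed) and per-cluster differential
expression between stimulated and control conditions (pseudobulk *t* by
default, per-cell Wilcoxon as an alternative; Holm correction within
cluster), each cluster is scored from a 10-gene IEG panel (Fos, Fosl2,
Homer1, Nr4a3, Nr4a1, Gem, Jun, Junb, Btg1, 1700016P03Rik). Panel genes
expressed in ≥ 5 % of the cluster's cells with raw *p* < 0.05 are combined
by Fisher's method (−2 Σ ln *p* ~ χ² with 2*k* df); the score is
−log₁₀(combined *p*), negated when the mean log2 fold change of those genes
is negative, and exactly 0 for clusters with no qualifying gene. Clusters
are ranked by score; the top four are the activation candidates.

## Worked example

```r
library(fosmap)

## --- imaging stage on a synthetic ground-truthed volume ---------------
sim <- simulateVolume(VolumeSimSpec(shape = c(40, 40, 40),
                                    regionDensities = c(`1` = 80, `2` = 10),
                                    seed = 42))
cells <- findCells(detectFosVoxels(sim$volume, sim$mask))
cells
#> CellSet: 50 cells (sizes 1-1), 0 artefacts
dens <- localDensity(cellsToCounts(cells, voxelSize = voxelSize(sim$volume)))
summarizeRegions(dens, sim$labels)
#>   label     name nVoxels meanDensity
#> 1     1 region_1   32000    56.23675
#> 2     2 region_2   32000    15.56050

## --- transcriptomic stage ---------------------------------------------
sce    <- simulateSnRnaSeq(SnRnaSimSpec(seed = 42))   # cluster 1 activated, 2 inhibited
scores <- scoreClusters(clusterDE(sce))
scores
#>   cluster      score n_iegs_used   combined_p mean_log2fc sign
#> 1       1  15.495680          10 3.193887e-16  1.37610213    1
#> 2       2 -17.586953          10 2.588494e-18 -1.32344350   -1
#> 3       3   0.000000           0           NA          NA    0
#> 4       4  -1.748311           1 1.785209e-02 -0.11723991   -1
#> 5       5   1.676341           1 2.106973e-02  0.07771131    1
#> 6       6   1.490276           1 3.233878e-02  0.11277242    1
rankClusters(scores, topN = 4)
#> [1] 1 5 6 3
```

The detector recovers all 50 planted cells; region 1 (planted at
80 cells/µl) shows about four times the mean local density of region 2
(10 cells/µl — edge attenuation of the kernel pulls both means below the
planted rates). In the transcriptomic stage the planted activated cluster
(1) gets the top positive score with all 10 panel genes used, the
inhibited cluster (2) a strongly negative one; clusters 4–6 show the
small raw-*p* false positives the score's documented use of unadjusted
p-values admits.

Both stages can also be driven from a YAML configuration through
`runPipeline()`, which writes every artifact with a manifest of content
hashes and an event log; see `?runPipeline`.

## Package layout

* `R/` — S4 classes (`Volume3D`, `CellSet`, `DensityMap`, `StatMap`, …),
  detection, density and test stages, IEG scoring, simulators, pipeline.
* `tests/testthat/` — unit, property and acceptance suites with literal
  brute-force oracles in `helper-oracles.R`.
* `vignettes/fosmap-methods.Rmd` — the methods vignette: model
  assumptions, parameter semantics, numerical conventions, limitations.
* `scripts/acceptance.R` — the reproduction script described above.
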