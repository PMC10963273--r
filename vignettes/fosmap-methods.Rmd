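---
title: "Methods: Fos density mapping and IEG activation scoring"
author: "fosmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Fos density mapping and IEG activation scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fosmap)
```

# Overview

`fosmap` implements two analysis stages used in whole-brain activity-mapping
studies of feeding circuits, where chemogenetic stimulation of hypothalamic
AgRP neurons (with simultaneous inhibition of POMC neurons) drives Fos
expression in downstream regions such as the NTS and area postrema:

1. an **imaging stage** that detects Fos-positive cells in registered
   cleared-brain light-sheet volumes, converts them to local densities in
   cells per microlitre, and compares groups of animals voxel by voxel;
2. a **transcriptomic stage** that scores single-nucleus RNA-seq neuronal
   clusters for immediate-early-gene (IEG) activation from per-cluster
   differential-expression results.

Both stages are driven by seeded synthetic-data generators with known ground
truth, so every claim the package makes about itself is checkable at desk
scale.

# The imaging stage

## Detection model

The canonical input is a registered 630-nm Fos channel on a 25 µm isotropic
grid (the full-brain grid is 440 × 320 × 520 voxels; the package accepts any
grid with all dimensions ≥ 3 and any positive anisotropic voxel size).
Arrays are indexed `[x, y, z]`, matching how `RNifti` returns NIfTI data in
R, so volumes pass through I/O without transposition; TIFF pages map to z.

A voxel is *Fos-candidate* when its intensity is at least
$(1 + f)$ times that of **every** one of its 26 surrounding voxels, with
$f = 0.20$ by default, and when the voxel and all 26 neighbours lie inside
the tissue mask (so no detection is possible on the array edge or at the
tissue border). Two readings of "20 % above the 26 surrounding voxels" are
possible — above each neighbour, or above their mean — and both are
implemented (`comparisonMode`); the each-neighbour reading is the default
because it is the one under which flagged-voxel clusters larger than one
voxel are rare and an eight-voxel artefact cap is meaningful. The threshold
is inclusive: a voxel exactly 20 % above every neighbour is detected.
Because the rule is a ratio, detection is invariant to any positive global
rescaling of intensities — the bit depth and normalisation of the source
images are irrelevant — but *not* to additive offsets, which the test suite
asserts with a counterexample.

Flagged voxels are grouped into connected components (26-connectivity by
default, consistent with the detection neighbourhood; 6 and 18 are
available since the original choice is not documented). Components of 1–8
voxels count as one Fos⁺ cell; larger components are recorded as artefacts
and excluded. Centroids are unweighted voxel-coordinate means; when a cell
is rasterised into the count volume, half-way ties round toward the lower
index (a centroid z of 2.5 lands at z = 2).

## Density and group comparison

Local density is a plain box convolution: the count volume is summed over a
sliding uniform window of 20³ voxels (0.125 µl at 25 µm isotropic) and
divided by the *full* window volume, giving cells/µl. Two conventions
needed fixing:

* **Even kernel extent.** A 20-voxel window has no central voxel; the
  window spans offsets $[-10, +9]$ per axis. Any consistent choice shifts
  the map by at most one voxel.
* **Edges.** Windows are zero-padded at the array edge but still divided by
  the full 0.125 µl, so densities within one window width of the edge are
  biased low. This matches the "uniform kernel" description as a plain
  convolution; interior totals are conserved exactly (to 1e-9 relative),
  which the tests verify by direct summation.

Groups of density maps are compared per voxel with a two-sided two-sample
t-test. The variant, sidedness and degenerate-voxel handling are not
documented in the original description, so the package declares defaults
rather than inferring them: Student's pooled-variance test (groups of n = 4
animals are too small for Welch's approximation to help), two-sided, and a
dedicated undefined marker (`NA` plus a validity mask — never a silent
p = 1) for voxels with zero variance in both groups and equal means. Zero
variance with unequal means yields an infinite statistic and p = 0. No
multiple-testing correction is applied to the p-map by default, matching
the practice of displaying raw p-value images; region summaries report mean
and minimum p and the fraction of voxels below a chosen α per label of a
supplied label volume.

# The transcriptomic stage

## QC and differential expression

Cells with fewer than 800 UMIs, fewer than 500 detected genes, or more than
10 % mitochondrial reads are removed. The bounds follow the wording
"fewer than" / "above" literally, so the thresholds themselves are
retained: a cell at exactly 800 UMIs, 500 genes and 10 % mito passes.

Upstream of the activation score the original analysis uses a
negative-binomial mixed model with sample-level effects (nebula). That
engine is deliberately out of scope here; the stable interface is the
differential-expression table (cluster, gene, raw p, Holm-adjusted p, log2
fold change, expressing-cell fraction), and two reference producers are
shipped behind it:

* `pseudobulk_t` (default): counts are normalised to counts-per-10k,
  averaged within each (cluster, sample), and per-sample means are compared
  between conditions by a Student t-test. With 2 samples per condition this
  is a 2-vs-2 test with 2 degrees of freedom — conservative, but it
  respects sample-level replication.
* `percell_wilcoxon`: rank-sum across individual cells. Anti-conservative
  when cells within a sample are correlated; provided for comparison and
  labelled as such.

Log2 fold changes use a pseudocount of 1 on the CP10K scale. Holm
adjustment is applied within each cluster (delegated to `stats::p.adjust`).

## The activation score

For each cluster, the panel genes (default: the 10 IEGs Fos, Fosl2,
Homer1, Nr4a3, Nr4a1, Gem, Jun, Junb, Btg1, 1700016P03Rik) that are
expressed in at least 5 % of the cluster's cells (inclusive) *and* have raw
p < 0.05 (strict) enter Fisher's combination
$X = -2\sum_i \ln p_i \sim \chi^2_{2k}$. Raw p-values are used
deliberately — with weak overall IEG signal, adjusted p-values would zero
out nearly all clusters — at the documented cost of retaining false
positives. Clusters with no usable panel gene score exactly 0, never a
small residue.

The phrase "negative logarithm of the chi-squared test statistic" is
ambiguous as a magnitude: read literally it *shrinks* as evidence grows.
The package's default score is therefore $-\log_{10}$ of the **combined
p-value**, which increases with evidence and behaves as an activation score
should; the literal statistic-based reading is available as
`scoreMode = "neglog_chi2_statistic"`. Base 10 is used for reporting. The
sign is flipped to negative when the mean log2 fold change of the usable
genes — the same filtered set that entered the combination — is negative,
indicating potential inhibition. Clusters are ranked by score (descending),
with ties broken by combined p (ascending) then cluster id; the default
report returns the top four.

# Synthetic data: what it emulates, and what it does not

The generators define the study conditions under which the package's
statistical properties are verified; their defaults are fixed once and are
not tuning knobs.

**Volumes** (`simulateVolume`): a smooth background field (a ±5 %
sinusoidal modulation of the background level with random phases) plus
white Gaussian noise, partitioned into slab regions along z. Cells arrive
by a per-region Poisson process at the requested density (cells/µl of
region volume) and are planted as 26-connected clusters whose voxels sit at
$(1 + \text{cellMargin})$ times the local (3×3×3 maximum) background
*before* noise. A margin above the detector threshold therefore guarantees
detection of isolated interior single-voxel cells; a margin below it is a
negative control. Two honest artefacts are left in rather than hidden:
overlapping or adjacent planted cells can merge (a measurable
false-negative source under the 8-voxel cap and the tie rule), and
multi-voxel plateau cells are invisible to the each-neighbour detector —
which is why the default planted cell size is 1 voxel, with 1–8 available
for studying exactly that failure mode. Not modelled at all: optics (PSF,
attenuation, stripes), registration error, autofluorescence structure. A
pass on these fixtures validates the pipeline's logic, not its robustness
to real optical artefacts.

**Cohorts** (`simulateCohort`): n = 4 mice per group by default, matching
the study design the voxelwise test targets; per-mouse seeds are derived as
`seed + 1000*(group-1) + mouse`. Default volumes are 48³ voxels at 25 µm
with three slab regions at 40 cells/µl baseline — large enough to hold
several 20³ kernel windows, small enough that a 200-replicate null
calibration runs in minutes.

**snRNA-seq** (`simulateSnRnaSeq`): negative-binomial counts
(dispersion 0.15) for 1000 genes × 6 clusters × 400 cells, 2 samples per
condition, library sizes uniform in 2000–8000, the IEG panel pinned to an
elevated baseline so the 5 % expression filter is met, a planted
+1.5 log2FC on panel genes in the activated cluster and −1.5 in the
inhibited one. Cluster structure is mild (4-fold enrichment of a random 5 %
of filler genes per cluster). Not modelled: ambient RNA, doublets,
batch effects beyond a lognormal per-sample scale factor, or the extra
variance from pooling animals within a sample.

# Numerical choices

* Box sums use separable cumulative-sum filters; tiny negative
  floating-point dust is clipped to zero before densities are formed.
* Fisher's statistic uses `stats::pchisq` upper tails; the tests
  cross-check it against the closed-form even-df series
  $e^{-x/2}\sum_{j<k}(x/2)^j/j!$.
* p-values that underflow to 0 upstream of the score are clamped to the
  smallest positive double, with a warning.
* All generators restore the caller's RNG state; identical specs give
  bit-identical output.

# Calibration checks and their problem sizes

The acceptance suite re-derives the pipeline's constants operationally
(neighbourhood size by probing which positions can veto a detection;
threshold by a 1 %-step sweep; cluster cap by growing runs of flagged
voxels; QC bounds by sweep fixtures) and runs two Monte-Carlo studies at
the default study conditions: a 200-replicate null calibration of the
voxelwise test (4 vs 4, 48³ volumes) and 50-replicate recovery studies for
the planted region effect and the planted cluster activation. For the null
calibration the pooled fraction of p < 0.05 voxels is compared with 0.05
within ±2 binomial standard errors, counting **one effectively independent
test per 20³ kernel window**: the uniform kernel makes neighbouring voxel
tests almost perfectly correlated, and a raw voxel count would understate
the standard error by three orders of magnitude.

# Known limitations

* The each-neighbour detector cannot flag intensity plateaus; extended
  bright objects are found only via their local maxima.
* Density maps are biased low within one kernel width of the volume edge.
* The pseudobulk t-test with 2 samples per condition has low power per
  gene; the activation score compensates by pooling the panel.
* The per-cell Wilcoxon route ignores sample-level correlation and should
  not be used for inference, only for comparison.
* Region summaries weight voxels, not physical volume — identical here
  because voxels are uniform, but worth noting for anisotropic use.
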