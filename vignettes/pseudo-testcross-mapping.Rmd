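---
title: "Pseudo-testcross linkage mapping from GBS data: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-testcross linkage mapping from GBS data: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmapr)
```

## The problem

Genetic maps for outcrossing, highly heterozygous species (grapevine is the
archetype) are built from F1 families: a cross between two heterozygous
parents in which every parent transmits one of two haplotypes per
chromosome.  Genotyping-by-sequencing (GBS) delivers tens of thousands of
SNPs per family at low cost, but at shallow coverage, with three
consequences that break naive map construction:

* **missing data** — many sites are simply not sequenced in many progeny;
* **heterozygote under-calling** — a true AB genotype sequenced at depth
  *d* shows only one allele with probability $2 \cdot 0.5^d$, so shallow
  heterozygotes are systematically called homozygous;
* **absent or unreliable parental genotypes** — the parents are often not
  sequenced deeply enough to anchor marker phase.

`ptmapr` reconstructs phased, parent-separated maps from the progeny alone,
using the *pseudo-testcross* (Pt) configuration: a biallelic site
heterozygous in exactly one parent (AB × AA) segregates 1:1 AB:AA in the
progeny (3:1 alleles, minor allele frequency 0.25) and can be mapped as a
backcross marker for the informative parent.

## Pipeline overview

1. **Family QC** — selfs, pollen contaminants and mislabelled progeny are
   detected from the intersection of a relatedness statistic and the
   male/female Mendelian-incompatibility ratio.
2. **Pt identification** — parent-independent selection of Pt sites from
   progeny segregation, with GQ-driven masking and correction of
   under-called heterozygotes.
3. **Linkage-group (LG) formation** — either reference-guided (group by
   chromosome, screen mis-assignments, split parents) or reference-free
   (global clustering with a parameter sweep); both run on the topological
   overlap of a squared-correlation adjacency.
4. **Phasing** — within each LG, positively truncated correlation
   adjacency separates the two parental haplotypes.
5. **Ordering and mapping** — minimum-spanning-tree ordering, redundancy
   and double-crossover filters, Kosambi distances.
6. **Curation** — missing-data/crossover filters, a phase HMM estimating
   the genotyping error rate, a drop-one-marker scan, gap inspection and
   rippling.

## Statistical machinery

### Binary encoding and correlation

After correction, every Pt site has calls in {AA, AB, missing}; the binary
value is presence (1) or absence (0) of the minor allele.  Markers on the
same parental haplotype are positively correlated across progeny, markers
on opposite haplotypes of the same parent negatively, and markers of
different parents or chromosomes are uncorrelated.  Correlations use
pairwise-complete progeny with a floor (`min_pairs = 20`, our addition) to
suppress spurious ±1 estimates from tiny overlaps.

### Topological overlap

LG formation clusters a dissimilarity of the topological overlap measure

$$\mathrm{TOM}_{ij} = \frac{\sum_u a_{iu}a_{uj} + a_{ij}}
                           {\min(k_i, k_j) + 1 - a_{ij}},
\qquad d_{ij} = 1 - \mathrm{TOM}_{ij},$$

with adjacency $a = r^2$ for LG formation and $a = \max(r, 0)$ for phasing
(same-phase markers can only be positively correlated).  Shared neighbours
let whole chromosomes cohere even when distal marker pairs are nearly
uncorrelated.  Trees are average-linkage (UPGMA) and cut at a static
height; groups below a minimum size dissolve to "unassigned".

### The "diff" mis-assignment filter

Each marker's mean (squared) correlation with every candidate group is
ranked; the marker *agrees* with its assignment only when its own group
ranks first by at least a factor `diff = 2` over the runner-up; rank
inversion is *disagree*, an insufficient margin *unresolved*.  Disagree
requires only the inversion, no ratio — the two categories are counted
separately in the audits.

### De novo parameter sweep

The tree over all Pt markers is built once and cut at every combination of
heights {0.95 … 0.85} and minimum sizes {50 … 300}.  The selected pair must
produce at least $2 \times$ `n_chrom` LGs (two parental maps) and maximises
the assigned marker fraction; ties prefer the larger minimum size (fewer
spurious LGs) and then the lower height.  The grid is user-configurable
because appropriate heights shift with family structure and data quality.

### Ordering and distances

Within a phased LG the rows are phase-encoded (phase-1 markers
complemented) so that 1 always means "phase-0 haplotype inherited"; this is
what makes the backcross/doubled-haploid two-point machinery valid.  The
recombination fraction is the discordant fraction of informative pairs and
the two-point LOD is $R\log_{10}2\hat r + (n-R)\log_{10}2(1-\hat r)$.  The
order is the weighted diameter path of the minimum spanning tree of the rf
graph, with off-path markers inserted at their attachment and a sliding
window (5 markers, exhaustive permutation) polish minimising obligate
crossovers.  Markers above 50% missing are excluded before ordering and
essentially unlinked markers (all rf ≈ 0.5) are split off.  Distances use
the Kosambi function $d = 25\ln\frac{1+2r}{1-2r}$.

### The curation HMM

Per progeny, the hidden state is the inherited parental phase along the
ordered LG; transitions between adjacent markers switch with probability
equal to the inter-marker rf, and the observed call equals the hidden phase
with probability $1-\varepsilon$.  The genotyping error rate
$\hat\varepsilon$ maximises a *profile* likelihood over a log-spaced grid
($10^{-4}$–$0.2$, 13 points): at each candidate the rfs are re-estimated by
bounded EM before scoring.  Evaluating the grid at the raw rf estimates
would bias $\hat\varepsilon$ low, because error-inflated transition
probabilities absorb isolated flips as crossovers.  After estimation the
error-corrected rfs shrink the map — this re-estimation, together with the
drop-one scan, is what removes most of the inflation of uncurated maps.

The drop-one scan (window 9) compares the window likelihood with the focal
marker's column masked against the likelihood without the marker (direct rf
between the new neighbours re-estimated), so both terms score the same
observations; removal requires a map shortening over 2 cM *and* a LOD
difference above the 95th percentile of the scan's own distribution (the
"upper tail of the histogram" rule).  Terminal markers are never removed,
avoiding unnecessary trimming of chromosome ends.  Rippling (window 7)
minimises total obligate crossovers, and LGs anticorrelated with physical
position are inverted.

## The simulator and what it does (not) capture

`simulate_gbs_family()` generates an F1 family with full truth: marker
positions on `n_chrom` chromosomes (default 19 of 100 cM, grapevine-like),
Pt loci for each parent plus AB×AB loci that downstream stages must reject,
meioses with a no-interference Poisson crossover process, and a read-level
sequencing model: depth Poisson around `mean_depth` scaled by a per-site
lognormal tag-depth factor (`depth_sdlog = 1.5`, spanning roughly a 20-fold
range — GBS tag depth varies over orders of magnitude between restriction
fragments), per-read miscalls at `seq_error = 0.01`, maximum-likelihood
genotype calls under a uniform prior, and a phred GQ equal to the gap
between the best and second-best genotype log-likelihood, capped at 99.
Anomalies with truth records: selfed-mother progeny (the dominant observed
contamination) and tandem-duplicate loci whose reads collapse with an
invariant second copy, halving the pooled minor-read fraction from 1/4 to
1/8.

Two analytic facts about this GQ model shape every downstream default:

* a true homozygote gains ≈ 3 phred per concordant read, so the GQ ≥ 98
  gate opens only around depth 33.  At shallow coverage the "mask AA with
  GQ < 98" rule therefore converts most homozygous calls to missing, and a
  site's post-correction call rate plateaus just below the 50% retention
  gate unless its tag is deep.  This reproduces the heavy attrition of the
  post-correction rate filter seen on real data, and it means marker
  *retention* at shallow depth is driven by tag depth — which is why the
  tag-depth dispersion is part of the model and not a nuisance;
* sites retained through the rate gate by sampling luck rather than depth
  carry a conditioned excess of called heterozygotes, so the mean measured
  MAF of retained markers at mean depth 6 sits roughly 1–1.5 points above
  the unconditional 25% (the acceptance script reports the value it
  computes; depth-saturated retained sites sit at 25.0–25.3%).

Consequently, analyses that probe *linkage structure* (LG counts, phasing,
ordering, curation) are simulated at saturating flat coverage
(`mean_depth = 40`, `depth_sdlog = 0`), isolating the clustering machinery
from shallow-coverage attrition, while analyses of the error-correction
stage itself use the shallow heterogeneous regime.

Not modelled: read-level FASTQ artefacts, restriction-site/tag positional
structure, PCR duplicates, crossover interference (the Poisson model is
interference-free; at the sub-2 cM marker spacings mapped here the
difference between Kosambi and Haldane is below 2%), and segregation
distortion from selection.  Passing tests therefore demonstrate the
pipeline's behaviour under its own stated error model, not robustness to
every artefact of real libraries.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `allele_freq_min` | 0.05 | alleles under 5% are erased as sequencing errors |
| `genotype_rate_min` | 0.5 | per-site call-rate gate (before and after correction) |
| `maf_center ± maf_halfwidth` | 0.25 ± 0.125 | closed acceptance band for Pt MAF |
| `gq_threshold` | 98 | phred gate separating trusted from suspect calls |
| `site_error_max` | 0.05 | max fraction of high-GQ BB calls per site |
| `cut_height` | 0.9 (synteny), sweep (de novo) | static dendrogram cut |
| `min_cluster_size` | 30 / sweep grid | minimum LG size |
| `diff` | 2 | mis-assignment ratio threshold |
| `min_phase_size` | 10 | minimum phase cluster (30 in chromosome-scale data) |
| `crossover_multiple` | 2 | individual crossover-excess filter (strict >) |
| `dropone_window`, `ripple_window` | 9, 7 | curation scan windows |
| `gap_max_cM` | 2 | map-shortening / gap threshold |

GQ comparisons use ≥ 98 uniformly (the quality filter is described both as
"≥ 98" and "> 98" in different places in the literature; we standardise).
The allele-frequency erasure uses allele copies (2N denominator).  The
error-rate denominator is the site's non-missing pre-correction calls.
Where parents are absent, parent labels are provisional (`unknown-A/B`) per
chromosome; with parents, an LG belongs to the parent whose high-GQ calls
at its markers are majority-heterozygous, female LGs are numbered
1–`n_chrom` and male LGs `n_chrom+1`–`2·n_chrom`.

## Numerical and degenerate-input choices

* Missing correlations and negative phasing correlations enter adjacencies
  as 0 (no evidence of linkage).
* rf estimates are clamped to $[10^{-6}, 0.5-10^{-6}]$ inside the HMM;
  rf ≥ 0.5 maps to a capped 50 cM with a warning.
* Cluster labels are deterministic given input order (renumbered by size,
  ties by first member); phasing is label-symmetric and tests compare up to
  relabelling.
* Joining split LGs tries both phase orientations and keeps the shorter
  map; a join is refused when even the better orientation exceeds the
  summed part lengths by more than 100 cM.
* Fewer than 10 progeny: QC refuses automatic flagging and reports
  statistics only.  Sites monomorphic after rare-allele erasure, and sites
  invariant after sample removal, are dropped and counted.

## Desk-scale problem sizes

Simulated studies in the tests and the acceptance script use 19
chromosomes × (55 + 55 + 10) markers × 200 progeny for genome-scale checks
(a few thousand markers, seconds to minutes per stage) and 2–6 chromosome
families elsewhere; these sizes were chosen so the whole battery documents
the pipeline's behaviour while remaining quick to re-run during
development.

## Known limitations

* The GQ gate semantics are tied to the phred-gap model; callers with
  different GQ scales will shift the effective depth at which the
  masking/correction rules fire.
* The de novo sweep's published minimum-size grid (50–300) presumes LGs of
  at least 50 markers; sparser families need a scaled grid.
* Step 2 of curation automates the published decision rules (flag adjacent
  pairs with rf > 0.4 or LOD < 1, re-polish); the fully manual
  rf/LOD-plot inspection it replaces cannot be automated completely.
* Map lengths inherit ~1 cM of sampling noise per interval at 200 progeny;
  totals per parent are the stable quantity, individual LG lengths less so.
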