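# ptmapr

Phased, parent-separated genetic linkage maps for F1 families of highly
heterozygous outcrossing species (grapevine and other woody perennials are
the motivating case), built from shallow-coverage genotyping-by-sequencing
(GBS) genotype calls — **without requiring parental genotypes**.

## The problem and the approach

GBS yields hundreds of thousands of SNPs per family, but shallow coverage
brings heavy missing data and systematic heterozygote under-calling (a true
AB genotype sequenced at depth *d* shows a single allele with probability
2·0.5^*d*), and parental genotypes are often missing or unreliable.
`ptmapr` works from the progeny alone using the pseudo-testcross (Pt)
configuration: a site heterozygous in exactly one parent (AB × AA)
segregates 1:1 AB:AA in the F1 (3:1 alleles, minor allele frequency 0.25)
and maps as a backcross marker for its informative parent.

The pipeline:

1. **Family QC** — selfs/pollen contaminants flagged by the intersection of
   a Yang-type relatedness statistic and the male/female
   Mendelian-incompatibility ratio.
2. **Pt marker identification** — segregation-based selection
   (MAF 0.25 ± 0.125, genotype classes ≥ 5%), then phred-GQ driven
   correction: AA with GQ < 98 masked, BB with GQ ≥ 98 flagged as error, BB
   with GQ < 98 corrected to AB; sites re-filtered on call rate and error
   rate.
3. **Linkage groups** — markers encoded as presence/absence of the minor
   allele; clustering on the topological-overlap dissimilarity
   TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i,k_j) + 1 − a_ij) of the r²
   adjacency, with a static dendrogram cut.  Reference-guided (per
   chromosome, mis-assignments removed by a ratio filter with diff = 2) or
   de novo (global sweep over cut heights × minimum cluster sizes selecting
   ≥ 2 × n_chrom LGs while maximising assignment).
4. **Phasing** — within each LG, adjacency max(r, 0) separates the two
   parental haplotypes.
5. **Ordering & distances** — minimum-spanning-tree ordering with windowed
   polish, redundancy and double-crossover filters, Kosambi distances
   d = 25·ln((1+2r)/(1−2r)).
6. **Curation** — missing/crossover filters; a two-state phase HMM whose
   profile likelihood estimates the genotyping error rate ε and re-estimates
   recombination fractions at ε̂; a 9-marker drop-one scan with a
   histogram-tail LOD threshold; gap flags, 7-marker ripple, physical
   orientation.

A synthetic F1 GBS simulator (`simulate_gbs_family()`) with complete truth
(parental phases, crossovers, selfed contaminants, tag-collapsed tandem
duplicates) makes every stage testable at desk scale.

## Worked example

```r
library(ptmapr)

cfg <- sim_config(n_chrom = 3, n_progeny = 150, mean_depth = 40,
                  depth_sdlog = 0, n_contaminants = 2, seed = 42)
sim <- simulate_gbs_family(cfg)
sim$calls
#> genotype_matrix: 360 sites x 152 samples
#>   roles: father=1, mother=1, progeny=150
#>   call rate: 1.000

qc <- flag_suspect_progeny(relatedness_matrix(sim$calls),
                           mendelian_incompatibilities(sim$calls))
qc$id[qc$flagged]                   # the two injected selfs, recovered
#> [1] "P081" "P107"

clean <- remove_flagged_samples(sim$calls, qc$id[qc$flagged])
pt <- identify_pt_markers(clean)
pt$audit                            # 330 = the 3 x (55+55) true Pt loci;
#>                   initial                  low_rate               monomorphic
#>                       360                         0                         0
#>           bad_segregation low_rate_after_correction                high_error
#>                        30                         0                         0
#>                  retained
#>                       330
                                    # the 30 AB x AB loci fail segregation

sw <- sweep_and_select(pt$binary, n_chrom = 3)
sw
#> lg_sweep: 54 grid points; selected height 0.8625 min size 50 -> 6 LGs, 100.0% assigned

dn <- build_denovo_lgs(pt$binary, sw)
lgs <- assign_parent_and_name(dn$lgs, pt$binary$sites,
                              progenitors = pt$progenitors, n_chrom = 3)
map <- build_genetic_map(lgs, pt$binary)
cur <- curate_map(map, pt$binary, sites = pt$binary$sites)
round(map_lengths(cur$map), 1)      # six LGs (3 chromosomes x 2 parents),
#>   LG1   LG2   LG3   LG4   LG5   LG6
#> 101.8  84.5  96.4  90.4 103.8  86.6
                                    # each simulated at 100 cM
round(cur$report$eps_hat, 4)        # near-zero genotyping error recovered
#>    LG1    LG2    LG3    LG4    LG5    LG6
#> 0.0007 0.0013 0.0007 0.0007 0.0007 0.0013
```

Maps export to R/qtl's rotated "csvsr" cross format (`write_crossfile()`,
backcross or 4-way coding) for downstream QTL work, and to VCF/TSV
(`write_marker_vcf()`, `write_binary_table()`).

A thin command-line front end with `simulate`, `qc`, `pt`, `synteny`,
`denovo`, `order`, `curate` and `diagnose` subcommands lives at
`inst/cli/ptmapr.R`:

```sh
Rscript inst/cli/ptmapr.R simulate --n-chrom 2 --n-progeny 60 --seed 3 --out fam
Rscript inst/cli/ptmapr.R pt --vcf fam.vcf --mother mother --father father --out fam_pt
```

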