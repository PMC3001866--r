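# laminascan

Lamin A/C (*LMNA*) mutations cause cardiomyopathy and muscular dystrophy,
and one proposed mechanism runs through the nuclear lamina's grip on
chromatin: mutant lamina, mispositioned chromosomal domains, misexpressed
genes. `laminascan` is an R package for the computational side of testing
that chain. It is aimed at groups analyzing paired expression profiles
(mutant vs control under two normalizations) together with 3D immuno-FISH
image stacks of the same cells.

## What it computes

**Misexpression calling.** For probesets with mutant/control values
*m*, *c*, the signed fold change is *r = m/c* (reported as *r* or *−1/r*).
Probesets are ranked per normalization variant with the rank-products
statistic — RP(*g*) = (∏ᵢ rᵢ(*g*))^(1/k) over comparisons *i* — and the
call in each direction is the intersection of the two variants' top-K
lists, collapsed from probesets to genes (concordant, or flagged
discordant).

**Genomic clusters.** A 500 kb window sliding by 100 kb qualifies when
misexpressed genes are ≥ 75% of the chip genes it contains and it holds
≥ 2 misexpressed genes; overlapping qualifying windows merge into
clusters. Significance: an empirical null over random probeset lists of
the observed size, with *p = (b+1)/(N+1)* for *b* exceedances in *N*
simulations (rendered `<1/N` when *b* = 0).

**Per-chromosome enrichment.** Each chromosome's misexpressed percentage
against the genome-wide fraction of chip genes,
χ² = Σ(obs − exp)²/exp with df = categories − 1.

**3D FISH quantification.** Per-slice anisotropic Euclidean distance maps
of the nucleus mask give the minimum territory-to-edge distance (x-y pass,
then an x-z reslice; minimum of both). Inter-locus distance is
√(Δx²+Δy²+Δz²) between signal centroids; lamina contact is a binary
26-adjacency score against the lamin shell; territory volumes are voxel
counts normalized to nuclear volume; Ki-67 indices classify cultures
(< 0.02 senescent, > 0.4 young).

**Synthetic data.** Generators for annotated gene maps, paired expression
tables with planted DE/clusters/enrichment, and multi-channel 3D nucleus
stacks (DAPI, lamin shell, territories, FISH spots) with analytic ground
truth — every stage is testable without downloads.

## Worked example

```r
library(laminascan)

u <- make_gene_map(3, c(12e6, 10e6, 8e6), genes_per_mb = 8, seed = 101)
tr <- make_expression_truth(u, n_de = 20, noise_sd = 0.1,
                            normalization_corr = 0.95,
                            planted_clusters = list(
                              list(chromosome = "1", start = 1.1e6, end = 1.6e6)),
                            seed = 7)
ex <- make_expression(u, tr)
de <- de_from_tables(ex$variant_a, ex$variant_b, k = 25, u)
cl <- merge_windows(scan_windows(u, de, scan_config()))
nd <- null_cluster_distribution(u, list_size = 20, n_sims = 1000, seed = 11)
empirical_p(nrow(cl), nd)
chi_square_uniformity(chromosome_fractions(u, de))
```

prints

```
de_gene_set: 41 genes ( 19 over, 22 under, 0 discordant ) from 43 probesets
  chromosome   start     end n_de_genes peak_ratio                de_genes
1          1  900000 1400000          2       1.00         G1_0009,G1_0010
2          1 8900000 9400000          3       0.75 G1_0065,G1_0066,G1_0068
null_cluster_distribution: 1000 sims of 20 probesets; mean 0.35, range 0-3
empirical P 0.049 (48 of 1000 simulations >= observed 2)
chrom_enrichment: 41 of 236 genes misexpressed (17.37%) on 3 chromosomes
  chi-square 3.71, df 2, p 0.156
```

— the planted cluster on chromosome 1 is detected (the 2-gene window at
0.9–1.4 Mb, density ratio 1.0), two clusters beat 95.1% of random lists,
and with DE spread across all three chromosomes the enrichment test is,
correctly, unimpressed.

The imaging side, on a simulated nucleus with known geometry:

```r
tr2 <- nucleus_truth(semi_axes_um = 2.4,
                     territory_specs = list(list(offset_um = c(0.9, 0, 0),
                                                 radius_um = 0.8)),
                     signal_specs = list(
                       list(pos_um = c(-1, -1.1, 0), channel = "probe1"),
                       list(pos_um = c(0.7, 0.9, 0.2), channel = "probe2")),
                     seed = 5)
st <- make_nucleus_stack(tr2)   # 0.08/0.08/0.12 um voxels
measure_fish(st$grid, dapi = "dapi", lamin = "lamin",
             territories = "terr1", probes = c("probe1", "probe2"))
```

gives (planted truth: edge 0.700 µm, pair 2.632 µm, volume ratio 0.0370)

```
  channel min_edge_um volume_um3 volume_ratio contact
1   terr1        0.72   2.163456   0.03738206       0
measured pair distance: 2.641 um
```

— recovery well within one voxel diagonal (≈ 0.165 µm) and 5% on the
volume ratio.

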