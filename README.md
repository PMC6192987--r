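# welldge

Plate-based, well-barcoded 3' digital gene expression (DGE) screening:
simulation, demultiplexing, UMI counting, QC and compound-profiling
analytics, in one R package.

## The problem

High-throughput transcriptional screens treat cells in 384- or 1536-well
plates, lyse them in place, and reverse-transcribe with a poly(dT) primer
carrying a well-specific 10-mer barcode and a random 10-mer UMI. All wells
are pooled into one library; read 1 reports `barcode + UMI`, read 2 a 3'
cDNA fragment. The computational task is to turn the paired FASTQ plus a
transcriptome alignment into a UMI-deduplicated wells x genes molecule
matrix,

```
count(well w, gene g) = #{ distinct UMIs among unique-gene reads tagged w, g },
```

and then into screening analytics: two-species ("barnyard") purity for
cross-well contamination, well-well correlation, gene-detection saturation
under downsampling, ROC benchmarking against a reference platform, CRISPR
indel frame binning, and compound mechanism-of-action profiling — potent
compounds (> 50 genes at padj < 0.05 and |log2FC| > 1), per-compound
candidate genes (up to 200, ranked), a quantile-normalised log2FC feature
matrix over the candidate union, Euclidean hierarchical clustering and
seeded tSNE. A meta-clustering module compares platforms measuring the same
samples: per-dataset Fisher-Z correlations `z = atanh(r)` (variance
`1/(n-3)`) are combined by DerSimonian-Laird random-effects summary and
agglomerated by similarity-maximising average linkage, with dendrogram
heights `tanh(z)` back on the correlation scale.

Every pipeline input can also be *simulated* with exact per-molecule ground
truth (PCR duplication, substitution errors, cross-well contamination,
two-species plates, Hill dose-response compound effects), so each stage is
validated against a known answer. The package is aimed at method developers
and screening informaticians who need a transparent, testable reference
implementation of this processing chain.

## Worked example

Simulate a 96-well human/mouse checkerboard plate with realistic noise,
run the full pipeline, and check purity:

```r
library(welldge)
tx <- build_transcriptome(c(human = 60, mouse = 60, ERCC = 6),
                          mean_length = 500, seed = 2)
by <- simulate_barnyard_plate(tx, plate_geometry(96),
                              molecules_per_well = 500,
                              pcr_duplication_rate = 0.3,
                              base_error_rate = 0.001,
                              cross_contamination_rate = 0.005, seed = 9)
res <- pipeline_count(by$reads, by$barcode_set, tx, by$plate)
res$demux_stats
#> demux: 67404 reads; 67400 assigned (672 corrected), 4 unassigned (0 truncated), 0 ambiguous
res$cm
#> count_matrix: 96 wells x 126 genes, 5495 nonzero, 47729 UMIs
species_purity(res$cm)
#> purity: 100.0% of 96 nonempty wells > 0.96
```

67k reads collapse to 48k UMIs (the 30% PCR duplication is removed by UMI
deduplication); 672 reads carried a 1-base barcode error and were corrected
against the distance-3 whitelist; every well's UMIs are > 96%
species-specific despite the injected 0.5% cross-well contamination.

The analytic core in two lines: the quantile-normalisation worked example
and a meta-clustering merge,

```r
quantile_normalize(cbind(a = c(5, 1), b = c(2, 4)))
#>        a   b
#> [1,] 4.5 1.5
#> [2,] 1.5 4.5
```

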