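---
title: "Methods: a plate-based 3' DGE screening pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a plate-based 3' DGE screening pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(welldge)
```

## The experiment this package models

In a well-barcoded 3' counting screen, cells are treated in a 384- (or
1536-) well plate, lysed in place, and reverse-transcribed with a
poly(dT) primer that carries two extra elements: a **well barcode** (a fixed
10-mer identifying the well) and a **UMI** (a random 10-mer identifying the
cDNA molecule). Because every first-strand cDNA is already labeled, all
wells are pooled into a single library; sequencing read 1 reports
barcode + UMI, read 2 reports a fragment from the 3' end of the transcript.
Computationally the assay reduces to: extract barcode and UMI from read 1,
attach them to read 2's identifier, align read 2 to the transcriptome, keep
reads that map uniquely to one gene, and count **distinct UMIs per (well,
gene)** — PCR duplicates collapse because re-amplified molecules share a
UMI. The result is a wells x genes molecule-count matrix feeding
differential expression and compound-signature analytics.

`welldge` implements that entire computational chain, plus a simulator that
generates every input with exact per-molecule ground truth, so each stage
can be validated against a known answer rather than against another tool.

## The simulator defines the study conditions

`build_transcriptome()` draws i.i.d.-base transcripts for any mixture of
species (ERCC spike-ins are a species of their own and stay flagged through
the pipeline). Expression is negative binomial per gene:
`mu` from a log-normal profile rescaled to the expected molecules per well,
variance `mu + mu^2 / dispersion` (so `dispersion` is the NB size; `Inf`
recovers Poisson). Three noise processes are modeled, each independently
switchable:

* **PCR duplication** — each molecule is re-emitted `Geometric(1 - rate)`
  extra times with the same barcode, UMI and fragment. The default study
  condition is rate 0.3.
* **Sequencing error** — i.i.d. per-base substitutions at `base_error_rate`
  (default condition 0.1%), applied to both reads after assembly. Indel
  errors and quality-dependent error profiles are deliberately not modeled;
  substitutions are what exercises barcode correction and UMI inflation.
* **Cross-well contamination** — with probability
  `cross_contamination_rate` (default condition 0.5%) a molecule is emitted
  under a uniformly chosen *other* well's barcode and flagged in the truth
  table. This emulates material exchange during pooling, the quantity the
  two-species ("barnyard") design measures.

Compound action is a Hill curve on the log2 fold-change scale:
`lfc = lfc_max * dose^h / (dose^h + EC50^h)`, applied multiplicatively to
target-gene means (`simulate_compound_plate()`). The functional form is a
modeling choice — standard pharmacology, used only to generate test data
with dose-dependent structure; nothing downstream assumes it.

Because every read pair has a truth row (read id, source well, gene, UMI,
duplicate and contaminant flags, barcode-of-record well), acceptance tests
can be exact: zero-noise runs must reproduce truth *identically*, not
approximately. What the simulator does **not** emulate — mappability
structure, 3' bias within the window, isoform complexity, ambient RNA,
batch effects — bounds what passing tests show about real data: they
validate the bookkeeping and the mathematics, not biological fidelity.

## Demultiplexing and counting rules

* Barcode whitelists are generated with pairwise Hamming distance >= 3
  (`generate_barcode_set()`), which makes 1-mismatch correction
  unambiguous: an observed barcode is assigned to the unique whitelist
  entry within `max_mismatch` (default 1), flagged `corrected` when not
  exact; zero or several candidates leave the read unassigned. `N` bases
  mismatch everything. The accounting identity
  `assigned + unassigned + ambiguous = total` is asserted in tests.
* The tag format is `<id>_<barcode>_<umi>` appended to the read-2 query
  name — underscore-delimited so it survives SAM QNAME rules — and parsed
  from the right, so original ids may contain underscores.
* Uniqueness is decided **at gene level after transcript collapse**: a read
  hitting two transcripts of one gene is unique; a read hitting two genes
  is dropped. Transcript-level uniqueness would discard most 3' reads of
  multi-isoform genes, which is why the gene-level rule is the default.
  MAPQ is not consulted for simulated data (the simulator marks multimapped
  reads with secondary records); a `min_mapq` option exists for real
  aligner output where MAPQ 255 marks unique hits.
* UMI collapse is **exact** by default — the count is the number of
  distinct (well, gene, UMI) triples, matching a plain distinct-UMI count.
  A `directional` mode additionally merges a UMI into a Hamming-1 neighbour
  when `count(parent) >= 2 * count(child) - 1`, absorbing error-derived
  UMIs; it is off by default because the exact rule is the documented
  baseline behaviour. UMIs containing `N` are discarded. UMI collisions are
  not corrected for: for `m` molecules in a (well, gene) cell the collision
  probability is bounded by `m^2 / (2 * 4^10)`, negligible at the
  per-cell depths simulated here.

## QC analytics

**Barnyard purity.** For a plate interleaving human-only and mouse-only
wells in a checkerboard, per-well purity is the dominant species' share of
endogenous UMIs. The headline statistic is the fraction of nonempty wells
with purity strictly above 0.96 (strict because the reference claim is
"> 96%"); wells with zero UMIs are excluded from the denominator because
purity is undefined there. Under the default noise conditions
(contamination 0.5%, error 0.1%, duplication 30%) essentially every well
passes; the acceptance bound is >= 98% of wells.

**Correlation and saturation.** Well-well Pearson correlation uses
log(1 + CPM) over endogenous genes — a transform choice documented here
because nothing upstream prescribes it. Depth comparisons use binomial
thinning (`downsample()`): each UMI is kept independently with probability
`fraction`, the exact analogue of resequencing shallower, and
`genes_detected()` counts genes strictly above each threshold per well.

**ROC.** Scores from the plate assay are benchmarked against an external
reference's fold changes; positives are genes with reference |log2FC|
above the cutoff (default 2). Absolute value is the default so
down-regulated genes count as positives; a `signed` mode restricts to
up-regulation. The sweep groups tied scores, and the trapezoid AUC is — by
construction, and asserted to 1e-12 in tests — the Mann-Whitney U statistic
normalised by `n_pos * n_neg`.

**Indel binning.** CRISPR genotype tallies are binned by net indel length:
0 wild type, a nonzero multiple of 3 in-frame, otherwise frameshift,
weighted by read count.

## Compound profiling

The differential-expression interface is a `de_table` (gene, log2fc, padj);
tables from DESeq2 or any other fitter can be read in directly. The
built-in `internal_de()` is a deliberately simple routine — median-of-ratio
size factors, pseudocounted log2 ratio of group means, Welch t-test on
log(1 + normalised) counts, BH adjustment — adequate for truth-controlled
simulation, not a DESeq2 replacement; reproducing published figures from
real data requires importing real DE tables. Its simulation-backed
guarantees (tested): on permuted-label null data the padj < 0.05 fraction
stays at or below 0.05, and planted |log2FC| = 2 genes are recovered with
sensitivity >= 0.8 at 3 vs 3. The recovery guarantee is stated for
well-covered, low-dispersion genes (the simulations use NB mean 200, size
100): a 3-versus-3 Welch comparison has no power on sparse or highly
dispersed genes, and no rank-based fix inside this routine would change
that.

Downstream selection applies strict cutoffs throughout: *significant* means
`padj < 0.05` **and** `|log2FC| > 1`; *potent* means strictly more than 50
significant genes at the top dose. Per-compound candidate lists take up to
200 genes (1000 for focused pairwise comparisons) ranked by ascending padj,
ties broken by descending |log2FC|, then gene id — the ranking rule is a
design decision fixed here, since "top of the table" needs a
deterministic definition. The feature matrix is the union of candidate
lists (rows) by compounds (columns), filled with log2FC, genes untested for
a compound imputed as 0 *before* normalisation, then **quantile normalised
across compounds** (classic sorted-value-means algorithm, ties averaged,
delegated to `limma::normalizeQuantiles`). Column-wise normalisation makes
compounds comparable, which is the point of the matrix; normalising genes
instead would destroy each signature's shape. Clustering is Euclidean
agglomeration over compounds (`hclust`; complete linkage by default —
configurable, and `average`/`ward` are available) and a seeded tSNE wrapper
(`Rtsne`, up to 3000 iterations) for 2-D maps.

## Meta-clustering across platforms

To compare platforms measuring the same samples (e.g. a plate assay versus
population RNA-seq), per-dataset sample-sample Pearson correlations are
Fisher-Z transformed (`z = atanh(r)`, variance `1/(n - 3)` with `n` the
feature count; |r| is clamped to `1 - 1e-6` so z stays finite, and the
diagonal carries an `Inf` sentinel excluded from every average). Per-pair z
values are combined across datasets with the **DerSimonian-Laird
random-effects summary**: `tau^2 = max(0, (Q - (k-1)) / (sum(w) -
sum(w^2)/sum(w)))` with fixed-effect weights `w = n - 3`, then an
inverse-variance weighted mean with weights `1 / (1/w + tau^2)`. DL with
the Fisher variance is the standard estimator choice; the upstream
description cites a random-effects summary without formulas, so this is an
interpretation, documented as such, and cross-checked against
`metafor::rma(method = "DL")` in the tests.

Clustering then *maximises similarity*: average linkage where
cluster-cluster similarity is the unweighted mean of member-pair z values
(maintained by the UPGMA Lance-Williams update; an independent
recompute-from-scratch oracle in the tests confirms the update), ties
broken on the lowest-index pair. Each merge's display height is
`tanh(linkage z)` — a correlation again — so the tree reads as "these
branches agree at r = 0.8". Exports use `1 - r` heights for Newick/hclust
viewer compatibility. Row ordering for stratified heatmap display comes
from clustering the pooled (column-concatenated) matrix once and applying
that leaf order to every per-dataset panel; rows are pre-sorted
lexicographically so the order is input-permutation invariant.

## Numerical and scale choices

Problem sizes in the tests and the acceptance script are desk scale: the
barnyard acceptance run uses a 500-gene two-species transcriptome, 384
wells x 2000 molecules (~1.1 M read pairs end to end, about a minute of
runtime); unit tests use 96-well plates with 80-gene transcriptomes. All
randomness is seeded; identical seeds give byte-identical FASTQ/SAM/truth
outputs. Degenerate inputs are defined, not crashed on: empty molecule
tables give valid empty outputs, empty record streams give all-zero
matrices with full metadata, zero-UMI wells give NA purity, zero-variance
wells give NA correlations, and all-zero genes are excluded from testing
with NA padj.

## Known limitations

* The simulator's reads are error-free in structure (no indels, no adapter
  read-through, no quality strings worth modeling); barcode correction is
  therefore only exercised for substitutions.
* `internal_de()` is not a shrinkage estimator; at n = 3 its fold changes
  are noisy for low-count genes and its power claim is limited to the
  regime stated above.
* The random-effects estimator behind the meta-clustering is the package's
  documented choice of DL; other estimators (REML, Paule-Mandel) would give
  slightly different combined z values.
* tSNE coordinates are only as reproducible as the wrapped implementation
  under a fixed seed; no stability across perplexities is implied.
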