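# Shared fixture builders for the test suite. Everything is generated in
# code at test time; no binary fixtures.

# count_matrix from a dense wells x genes matrix
make_cm <- function(mat, species = rep("human", ncol(mat)),
                    wells = rownames(mat), genes = colnames(mat)) {
  if (is.null(wells)) wells <- sprintf("A%02d", seq_len(nrow(mat)))
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(ncol(mat)))
  dimnames(mat) <- list(wells, genes)
  structure(list(
    counts = methods::as(Matrix::Matrix(mat, sparse = TRUE), "CsparseMatrix"),
    wells = data.frame(well = wells, treatment = "cells", dose_um = NA_real_,
                       replicate = seq_along(wells), species = "human",
                       cell_line = "x", stringsAsFactors = FALSE),
    genes = data.frame(gene_id = genes, species = species,
                       is_ercc = species == "ERCC",
                       stringsAsFactors = FALSE)),
    class = "count_matrix")
}

# hand-built de_table
make_de <- function(gene, log2fc, padj, base_mean = 100) {
  structure(data.frame(gene = gene, log2fc = log2fc, pvalue = padj,
                       padj = padj, base_mean = base_mean,
                       stringsAsFactors = FALSE),
            class = c("de_table", "data.frame"))
}

# small two-species transcriptome shared by several tests
tiny_barnyard_tx <- function(seed = 5) {
  build_transcriptome(c(human = 40, mouse = 40, ERCC = 4),
                      mean_length = 400, seed = seed)
}

# small simulated plate (96-well) with configurable noise
tiny_barnyard <- function(tx = tiny_barnyard_tx(), molecules = 200,
                          dup = 0, err = 0, contam = 0, seed = 7) {
  simulate_barnyard_plate(tx, plate_geometry(96),
                          molecules_per_well = molecules,
                          pcr_duplication_rate = dup,
                          base_error_rate = err,
                          cross_contamination_rate = contam, seed = seed)
}

# compare a count_matrix against truth-table brute-force counts
expect_matches_truth <- function(cm, truth, by = "barcode") {
  tru <- truth_umi_counts(truth, by = by)
  idx <- cbind(match(tru$well, rownames(cm$counts)),
               match(tru$gene, colnames(cm$counts)))
  expect_false(anyNA(idx))
  expect_true(all(cm$counts[idx] == tru$n))
  expect_equal(sum(cm$counts), sum(tru$n))
}
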