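test_that("synthetic transcriptomes are deterministic and well-formed", {
  f <- tempfile(fileext = ".fa"); a <- tempfile(fileext = ".tsv")
  tx <- build_transcriptome(c(human = 100, mouse = 100, ERCC = 10),
                            mean_length = 1000, seed = 7,
                            fasta = f, annotation = a)
  expect_equal(nrow(tx$genes), 210)
  expect_equal(length(Biostrings::readDNAStringSet(f)), 210)
  expect_true(all(grepl("^[ACGT]+$", tx$seq)))
  expect_equal(sum(tx$genes$is_ercc), 10)

  ann <- read_gene_annotation(a)
  expect_equal(ann$gene_id, tx$genes$gene_id)

  f2 <- tempfile(fileext = ".fa")
  build_transcriptome(c(human = 100, mouse = 100, ERCC = 10),
                      mean_length = 1000, seed = 7, fasta = f2)
  expect_identical(readLines(f), readLines(f2))
  expect_error(build_transcriptome(c(human = 10), mean_length = 50),
               "minimum fragment length")
})

test_that("well molecule counts follow the configured distribution", {
  tx <- tiny_barnyard_tx()
  prof <- expression_profile(tx, total_molecules = 0)
  expect_true(all(simulate_well_molecules(prof, seed = 1) == 0))

  # dispersion -> Inf behaves as Poisson: sample mean within 3 s.e.
  prof2 <- data.frame(gene_id = sprintf("g%04d", 1:1000), mu = 100,
                      dispersion = Inf)
  x <- simulate_well_molecules(prof2, seed = 2)
  expect_lt(abs(mean(x) - 100), 3 * sd(x) / sqrt(1000))

  prof3 <- expression_profile(tx, total_molecules = 500, seed = 3)
  expect_identical(simulate_well_molecules(prof3, seed = 4),
                   simulate_well_molecules(prof3, seed = 4))
})

test_that("read simulation writes barcode, UMI and fragment by construction", {
  tx <- tiny_barnyard_tx()
  bs <- generate_barcode_set(4, length = 10, min_hamming = 3, seed = 1)
  mol <- data.frame(well = "A01", gene = tx$genes$gene_id[1], count = 1)
  sim <- simulate_reads(mol, tx, bs, seed = 5)
  expect_equal(length(sim$r1$id), 1)
  expect_equal(substr(sim$r1$seq, 1, 10), bs$barcode[bs$well == "A01"])
  expect_equal(substr(sim$r1$seq, 11, 20), sim$truth$umi)
  expect_true(grepl(sim$r2$seq, tx$seq[1], fixed = TRUE))
  expect_false(sim$truth$is_duplicate)

  # empty molecule table is valid and empty
  empty <- simulate_reads(mol[0, ], tx, bs, seed = 1)
  expect_equal(length(empty$r1$id), 0)
  expect_equal(nrow(empty$truth), 0)
})

test_that("PCR duplicates re-emit the same barcode, UMI and fragment", {
  tx <- tiny_barnyard_tx()
  bs <- generate_barcode_set(4, length = 10, min_hamming = 3, seed = 1)
  mol <- data.frame(well = "A01", gene = tx$genes$gene_id[1], count = 1)
  sim <- NULL
  for (s in 1:50) {   # find a seed where the geometric draw emits 1 duplicate
    cand <- simulate_reads(mol, tx, bs, pcr_duplication_rate = 0.5, seed = s)
    if (nrow(cand$truth) == 2) { sim <- cand; break }
  }
  expect_false(is.null(sim))
  expect_equal(sum(sim$truth$is_duplicate), 1)
  expect_equal(sim$truth$umi[1], sim$truth$umi[2])
  expect_equal(sim$r1$seq[1], sim$r1$seq[2])
  expect_equal(sim$r2$seq[1], sim$r2$seq[2])
})

test_that("contamination flags occur at the configured rate", {
  tx <- tiny_barnyard_tx()
  bs <- generate_barcode_set(16, length = 10, min_hamming = 3, seed = 2)
  mol <- data.frame(well = rep(bs$well, each = 625),
                    gene = tx$genes$gene_id[1], count = 1)  # 10,000 molecules
  sim <- simulate_reads(mol, tx, bs, cross_contamination_rate = 0.01,
                        seed = 3)
  frac <- mean(sim$truth$is_contaminant)
  ci <- 2.576 * sqrt(0.01 * 0.99 / 10000)
  expect_lt(abs(frac - 0.01), ci)
  # contaminants carry a different barcode well than their source well
  cont <- sim$truth[sim$truth$is_contaminant, ]
  expect_true(all(cont$barcode_well != cont$well))
  same <- sim$truth[!sim$truth$is_contaminant, ]
  expect_true(all(same$barcode_well == same$well))
})

test_that("FASTQ/truth outputs are paired, deterministic and conserved", {
  tx <- tiny_barnyard_tx()
  bs <- generate_barcode_set(8, length = 10, min_hamming = 3, seed = 2)
  mol <- data.frame(well = rep(bs$well, each = 5),
                    gene = rep(tx$genes$gene_id[1:5], 8), count = 2)
  d1 <- tempfile(); d2 <- tempfile()
  paths <- function(d) list(r1 = paste0(d, "_R1.fastq"),
                            r2 = paste0(d, "_R2.fastq"),
                            tr = paste0(d, "_truth.tsv"))
  p1 <- paths(d1); p2 <- paths(d2)
  s1 <- simulate_reads(mol, tx, bs, pcr_duplication_rate = 0.2,
                       base_error_rate = 0.01, seed = 11,
                       r1_path = p1$r1, r2_path = p1$r2, truth_path = p1$tr)
  simulate_reads(mol, tx, bs, pcr_duplication_rate = 0.2,
                 base_error_rate = 0.01, seed = 11,
                 r1_path = p2$r1, r2_path = p2$r2, truth_path = p2$tr)
  expect_identical(readLines(p1$r1), readLines(p2$r1))
  expect_identical(readLines(p1$r2), readLines(p2$r2))
  expect_identical(readLines(p1$tr), readLines(p2$tr))
  # row parity between FASTQ and truth
  expect_equal(length(readLines(p1$r1)) / 4, nrow(s1$truth))
  expect_equal(length(s1$r2$id), nrow(s1$truth))
  back <- read_sim_truth(p1$tr)
  expect_equal(back, s1$truth)

  # conservation: no duplication/contamination, distinct triples = molecules
  s0 <- simulate_reads(mol, tx, bs, seed = 12)
  triples <- unique(s0$truth[, c("well", "gene", "umi")])
  expect_equal(nrow(triples), sum(mol$count))
})

test_that("Hill dose-response has the right midpoint and limits", {
  expect_equal(hill_log2fc(1, lfc_max = 3, ec50_um = 1, hill = 2.5), 1.5)
  expect_equal(hill_log2fc(0, lfc_max = 3, ec50_um = 1), 0)
  expect_lt(abs(hill_log2fc(1e6, lfc_max = 3, ec50_um = 1) - 3), 1e-5)
})

test_that("compound plates scale target-gene means dose-dependently", {
  tx <- build_transcriptome(c(human = 50), mean_length = 300, seed = 1)
  prof <- expression_profile(tx, total_molecules = 5000, sd_log = 0,
                             dispersion = 50, seed = 1)
  wells <- well_addresses(plate_geometry(96))[1:9]
  pm <- plate_map(data.frame(
    well = wells,
    treatment = rep(c("DMSO", "cmpA", "cmpA"), each = 3),
    dose_um = rep(c(NA, 0.001, 10), each = 3),
    replicate = rep(1:3, 3), species = "human", cell_line = "x"),
    plate_geometry(96))
  targets <- tx$genes$gene_id[1:10]
  eff <- list(cmpA = compound_effect(targets, lfc_max = 2, ec50_um = 0.1))
  counts <- simulate_compound_plate(pm, prof, eff, seed = 2)
  lo <- colMeans(counts[4:6, targets])   # dose << EC50: ~baseline
  hi <- colMeans(counts[7:9, targets])   # dose >> EC50: ~4x
  base <- colMeans(counts[1:3, targets])
  expect_lt(abs(mean(lo) / mean(base) - 1), 0.15)
  expect_lt(abs(mean(hi) / mean(base) - 2^hill_log2fc(10, 2, 0.1)), 0.5)
  expect_error(simulate_compound_plate(pm, prof, list(), seed = 1),
               "no compound_effect")
})

test_that("stand-in aligner emits parseable SAM with 11 mandatory fields", {
  tx <- tiny_barnyard_tx()
  by <- tiny_barnyard(tx, molecules = 50, seed = 21)
  tg <- tag_reads(by$reads$r1, by$reads$r2, by$barcode_set)
  sam <- tempfile(fileext = ".sam")
  simulate_alignments(tg$tagged, by$reads$truth, tx, sam_path = sam)
  lines <- readLines(sam)
  body <- lines[!startsWith(lines, "@")]
  expect_true(all(lengths(strsplit(body, "\t")) == 11))
  rec <- parse_tagged_sam(sam, tx)   # Rsamtools accepts it
  expect_equal(nrow(rec), nrow(tg$tagged))
  expect_true(all(rec$mapq == 255))

  # multimap_rate = 1: everything dropped by unique-gene filtering
  sam2 <- tempfile(fileext = ".sam")
  simulate_alignments(tg$tagged, by$reads$truth, tx, multimap_rate = 1,
                      seed = 2, sam_path = sam2)
  uniq <- filter_unique(parse_tagged_sam(sam2, tx))
  expect_equal(nrow(uniq), 0)
})

test_that("barnyard plates interleave species in a checkerboard", {
  tx <- tiny_barnyard_tx()
  by <- tiny_barnyard(tx, molecules = 30, seed = 31)
  expect_equal(sum(by$plate$species == "human"), 48)
  expect_equal(sum(by$plate$species == "mouse"), 48)
  # each well's molecules touch only its own species (plus ERCC)
  sp_of_gene <- setNames(tx$genes$species, tx$genes$gene_id)
  for (w in by$plate$well[c(1, 2, 95)]) {
    g <- colnames(by$molecules)[by$molecules[w, ] > 0]
    expect_true(all(sp_of_gene[g] %in% c(by$plate$species[by$plate$well == w],
                                         "ERCC")))
  }
})
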