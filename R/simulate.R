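# Synthetic-data generation: transcriptome fixtures, negative-binomial
# expression, barcoded paired reads with exact per-molecule ground truth, and
# a stand-in transcriptome "aligner" emitting SAM at desk scale.

#' Build a synthetic multi-species transcriptome
#'
#' Generates one transcript per gene with i.i.d. bases, for any mixture of
#' species labels (ERCC spike-ins are a species label of their own and are
#' flagged distinctly). Transcript lengths are drawn around `mean_length` and
#' floored at `min_length` so every transcript accommodates a 3' read.
#'
#' @param n_genes Named integer vector, genes per species, e.g.
#'   `c(human = 100, mouse = 100, ERCC = 10)`.
#' @param mean_length,min_length Transcript length distribution (bases).
#' @param seed RNG seed; output is deterministic given the seed.
#' @param fasta,annotation Optional output paths: reference FASTA (records
#'   named by transcript id) and a tab-separated annotation
#'   `transcript_id  gene_id  species`.
#' @return A `transcriptome`: list with `genes` (data.frame: gene_id,
#'   transcript_id, species, length, is_ercc) and `seq` (named character,
#'   keyed by transcript id).
#' @export
build_transcriptome <- function(n_genes = c(human = 100, mouse = 100, ERCC = 10),
                                mean_length = 1000, min_length = 200,
                                seed = 1L, fasta = NULL, annotation = NULL) {
  if (!length(n_genes) || all(n_genes < 1))
    stop("need at least one gene for at least one species")
  if (mean_length < min_length)
    stop("mean_length below the minimum fragment length ", min_length)
  n_genes <- n_genes[n_genes >= 1]
  set.seed(seed)
  species <- rep(names(n_genes), n_genes)
  idx <- unlist(lapply(n_genes, seq_len), use.names = FALSE)
  gene_id <- sprintf("%s_g%04d", species, idx)
  lens <- pmax(as.integer(min_length),
               as.integer(round(rnorm(length(gene_id), mean_length,
                                      mean_length / 5))))
  seqs <- vapply(lens, function(L)
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = ""), character(1))
  genes <- data.frame(gene_id = gene_id,
                      transcript_id = paste0(gene_id, ".t1"),
                      species = species, length = lens,
                      is_ercc = species == "ERCC",
                      stringsAsFactors = FALSE)
  names(seqs) <- genes$transcript_id
  tx <- structure(list(genes = genes, seq = seqs), class = "transcriptome")
  if (!is.null(fasta)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta)
  }
  if (!is.null(annotation)) write_gene_annotation(tx, annotation)
  tx
}

#' Write / read the transcript-to-gene annotation table
#'
#' Tab-separated columns `transcript_id`, `gene_id`, `species` with header.
#'
#' @param tx A `transcriptome` (or its `genes` data.frame).
#' @param path Output path.
#' @export
write_gene_annotation <- function(tx, path) {
  genes <- if (inherits(tx, "transcriptome")) tx$genes else tx
  write.table(genes[, c("transcript_id", "gene_id", "species")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_annotation
#' @export
read_gene_annotation <- function(path) {
  df <- read.delim(path, colClasses = "character")
  need <- c("transcript_id", "gene_id", "species")
  if (!all(need %in% names(df)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  df$is_ercc <- df$species == "ERCC"
  df
}

#' Per-gene negative-binomial expression profile
#'
#' Expected molecule counts are log-normal across genes (a crude but standard
#' emulation of an expression distribution), rescaled so the expected total
#' per well equals `total_molecules`. ERCC spike-ins receive a fixed share
#' `ercc_fraction` of the total, mimicking a constant per-well spike-in mix.
#'
#' @param tx A `transcriptome`.
#' @param total_molecules Expected mRNA molecules captured per well.
#' @param dispersion Negative-binomial size parameter (variance =
#'   mu + mu^2 / dispersion; `Inf` gives Poisson).
#' @param sd_log Standard deviation of log expression across genes.
#' @param species If given, only genes of these species (plus ERCC) express.
#' @param ercc_fraction Share of the total given to ERCC genes (0 if none).
#' @param seed RNG seed for the gene-level means.
#' @return An `expression_profile` data.frame: gene_id, mu, dispersion.
#' @export
expression_profile <- function(tx, total_molecules = 2000, dispersion = 2,
                               sd_log = 1, species = NULL,
                               ercc_fraction = 0.02, seed = 1L) {
  genes <- tx$genes
  set.seed(seed)
  raw <- exp(rnorm(nrow(genes), 0, sd_log))
  endog <- !genes$is_ercc
  if (!is.null(species)) endog <- endog & genes$species %in% species
  has_ercc <- any(genes$is_ercc)
  ercc_share <- if (has_ercc) ercc_fraction else 0
  mu <- numeric(nrow(genes))
  if (any(endog))
    mu[endog] <- raw[endog] / sum(raw[endog]) * total_molecules * (1 - ercc_share)
  if (has_ercc)
    mu[genes$is_ercc] <- raw[genes$is_ercc] / sum(raw[genes$is_ercc]) *
      total_molecules * ercc_share
  structure(data.frame(gene_id = genes$gene_id, mu = mu,
                       dispersion = dispersion, stringsAsFactors = FALSE),
            class = c("expression_profile", "data.frame"))
}

#' Draw true molecule counts for one well
#'
#' @param profile An `expression_profile`.
#' @param seed RNG seed.
#' @param scaling Well-specific scaling factor applied to all means.
#' @return Named integer vector of molecule counts per gene.
#' @export
simulate_well_molecules <- function(profile, seed = 1L, scaling = 1) {
  stopifnot(all(profile$mu >= 0), all(profile$dispersion > 0))
  set.seed(seed)
  mu <- profile$mu * scaling
  n <- length(mu)
  counts <- integer(n)
  pois <- is.infinite(profile$dispersion)
  if (any(pois)) counts[pois] <- rpois(sum(pois), mu[pois])
  if (any(!pois)) counts[!pois] <- rnbinom(sum(!pois), mu = mu[!pois],
                                           size = profile$dispersion[!pois])
  names(counts) <- profile$gene_id
  counts
}

#' Hill dose-response on the log2 fold-change scale
#'
#' Applied log2FC = `lfc_max * dose^h / (dose^h + ec50^h)`: 0 at dose 0,
#' `lfc_max / 2` at the EC50, saturating at `lfc_max`.
#'
#' @param dose_um Dose (micromolar), >= 0.
#' @param lfc_max Maximal log2 fold change.
#' @param ec50_um EC50 in micromolar (> 0).
#' @param hill Hill coefficient (> 0).
#' @return Applied log2 fold change(s).
#' @export
hill_log2fc <- function(dose_um, lfc_max, ec50_um, hill = 1) {
  stopifnot(ec50_um > 0, hill > 0, all(dose_um >= 0))
  lfc_max * dose_um^hill / (dose_um^hill + ec50_um^hill)
}

#' Describe a compound's transcriptional effect
#'
#' @param targets Character vector of target gene ids.
#' @param lfc_max Maximal log2 fold change, scalar or one value per target
#'   (signed; negative for repression).
#' @param ec50_um EC50 in micromolar.
#' @param hill Hill coefficient.
#' @return A `compound_effect` list.
#' @export
compound_effect <- function(targets, lfc_max = 2, ec50_um = 1, hill = 1) {
  stopifnot(length(targets) >= 1, ec50_um > 0, hill > 0)
  lfc_max <- rep_len(lfc_max, length(targets))
  structure(list(targets = targets, lfc_max = lfc_max,
                 ec50_um = ec50_um, hill = hill),
            class = "compound_effect")
}

#' Simulate true molecule counts for a treated plate
#'
#' For each well, target-gene negative-binomial means of the base profile are
#' scaled by `2^hill_log2fc(dose, ...)` for that well's compound; control
#' wells use the base profile unchanged.
#'
#' @param plate A `plate_map`.
#' @param base_profile An `expression_profile` (the DMSO state).
#' @param effects Named list of [compound_effect()], keyed by treatment label;
#'   every non-control treatment on the plate must have an entry.
#' @param control_labels Treatments regarded as controls (default "DMSO").
#' @param seed RNG seed.
#' @return Integer matrix wells x genes (dimnames set).
#' @export
simulate_compound_plate <- function(plate, base_profile, effects,
                                    control_labels = "DMSO", seed = 1L) {
  trts <- setdiff(unique(plate$treatment), control_labels)
  miss <- setdiff(trts, names(effects))
  if (length(miss))
    stop("no compound_effect configured for treatment(s): ",
         paste(miss, collapse = ", "))
  set.seed(seed)
  ng <- nrow(base_profile)
  mu <- matrix(rep(base_profile$mu, each = nrow(plate)), nrow(plate), ng,
               dimnames = list(plate$well, base_profile$gene_id))
  for (i in seq_len(nrow(plate))) {
    trt <- plate$treatment[i]
    if (trt %in% control_labels) next
    eff <- effects[[trt]]
    lfc <- hill_log2fc(plate$dose_um[i], eff$lfc_max, eff$ec50_um, eff$hill)
    mu[i, eff$targets] <- mu[i, eff$targets] * 2^lfc
  }
  counts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                           size = base_profile$dispersion),
                   nrow(plate), ng, dimnames = dimnames(mu))
  storage.mode(counts) <- "integer"
  counts
}

# base-4 decode of integers (0 .. 4^L - 1) into DNA strings
int_to_dna <- function(ints, L) {
  cols <- vector("list", L)
  x <- ints
  for (j in L:1) {
    cols[[j]] <- DNA_BASES[(x %% 4L) + 1L]
    x <- x %/% 4L
  }
  do.call(paste0, cols)
}

# i.i.d. per-base substitution errors on a character vector of sequences
apply_substitutions <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  len <- nchar(seqs)
  total <- sum(len)
  k <- rbinom(1L, total, rate)
  if (k == 0L) return(seqs)
  pos <- sort(sample.int(total, k))
  ends <- cumsum(len)
  read <- findInterval(pos - 1L, ends) + 1L
  off <- pos - c(0L, ends)[read]
  cur <- substr(seqs[read], off, off)
  newb <- DNA_BASES[((match(cur, DNA_BASES) - 1L +
                        sample.int(3L, k, replace = TRUE)) %% 4L) + 1L]
  # apply in rounds so reads with several errors are handled correctly
  while (length(read)) {
    first <- !duplicated(read)
    idx <- read[first]
    s <- seqs[idx]
    substr(s, off[first], off[first]) <- newb[first]
    seqs[idx] <- s
    read <- read[!first]; off <- off[!first]; newb <- newb[!first]
  }
  seqs
}

write_fastq <- function(ids, seqs, path) {
  qual <- strrep("I", nchar(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(rbind(paste0("@", ids), seqs, "+", qual)), con)
  invisible(path)
}

read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  list(id = sub("\\s.*$", "", names(x)), seq = as.character(x))
}

#' Simulate barcoded paired reads with exact ground truth
#'
#' Each true molecule receives a UMI drawn uniformly from the 4^umi_length
#' space. With probability `cross_contamination_rate` a molecule is emitted
#' under a uniformly chosen *other* well's barcode and flagged as a
#' contaminant. PCR duplication re-emits the same (barcode, UMI, fragment)
#' a geometric number of extra times. Substitution errors hit every written
#' base independently at `base_error_rate`. Read 1 is barcode + UMI + poly-T
#' fill; read 2 is a fragment drawn from the 3'-terminal `window` of the
#' transcript.
#'
#' @param molecules Integer matrix wells x genes of true molecule counts
#'   (dimnames required), or a data.frame with columns well, gene, count.
#' @param tx A `transcriptome`.
#' @param barcode_set A `barcode_set` covering every well present.
#' @param structure A [read_structure()].
#' @param read1_length,read2_length Read lengths in bases.
#' @param window 3' window (bases) from which read-2 fragments are drawn.
#' @param pcr_duplication_rate,base_error_rate,cross_contamination_rate
#'   Probabilities in [0, 1).
#' @param seed RNG seed; all outputs are deterministic given it.
#' @param r1_path,r2_path,truth_path Optional output paths (FASTQ, FASTQ,
#'   tab-separated truth table).
#' @return A `sim_reads` list: `r1` and `r2` (each `list(id, seq)`) and
#'   `truth`, a data.frame with columns read_id, well (true source well),
#'   gene, umi, is_duplicate, is_contaminant, barcode_well (the well whose
#'   barcode was written; differs from `well` only for contaminants).
#' @export
simulate_reads <- function(molecules, tx, barcode_set,
                           structure = read_structure(),
                           read1_length = NULL, read2_length = 50L,
                           window = 400L,
                           pcr_duplication_rate = 0, base_error_rate = 0,
                           cross_contamination_rate = 0, seed = 1L,
                           r1_path = NULL, r2_path = NULL, truth_path = NULL) {
  if (is.matrix(molecules)) {
    nz <- which(molecules > 0L, arr.ind = TRUE)
    mol <- data.frame(well = rownames(molecules)[nz[, 1]],
                      gene = colnames(molecules)[nz[, 2]],
                      count = molecules[nz], stringsAsFactors = FALSE)
  } else mol <- as.data.frame(molecules)
  if (is.null(read1_length))
    read1_length <- min_read1_length(structure) + 6L
  stopifnot(read1_length >= min_read1_length(structure))
  if (nrow(mol)) {
    bad <- setdiff(unique(mol$well), barcode_set$well)
    if (length(bad))
      stop("wells absent from the barcode set: ", paste(head(bad), collapse = ", "))
  }
  set.seed(seed)
  empty <- list(id = character(0), seq = character(0))
  truth_cols <- c("read_id", "well", "gene", "umi", "is_duplicate",
                  "is_contaminant", "barcode_well")
  if (!nrow(mol) || sum(mol$count) == 0L) {
    truth <- as.data.frame(setNames(
      list(character(0), character(0), character(0), character(0),
           logical(0), logical(0), character(0)), truth_cols))
    out <- structure(list(r1 = empty, r2 = empty, truth = truth),
                     class = "sim_reads")
    return(finish_sim_reads(out, r1_path, r2_path, truth_path))
  }

  # one row per true molecule
  rep_idx <- rep(seq_len(nrow(mol)), mol$count)
  well <- mol$well[rep_idx]
  gene <- mol$gene[rep_idx]
  n_mol <- length(well)
  umi <- int_to_dna(sample.int(4L^structure$umi_length, n_mol,
                               replace = TRUE) - 1L, structure$umi_length)
  # cross-well contamination: emitted under another well's barcode
  barcode_well <- well
  contam <- runif(n_mol) < cross_contamination_rate
  if (any(contam)) {
    k <- nrow(barcode_set)
    own <- match(well[contam], barcode_set$well)
    other <- sample.int(k - 1L, sum(contam), replace = TRUE)
    other <- other + (other >= own)
    barcode_well[contam] <- barcode_set$well[other]
  }
  # 3'-window fragment per molecule (duplicates re-emit the same fragment)
  gi <- match(gene, tx$genes$gene_id)
  if (anyNA(gi)) stop("molecule table references unknown genes")
  L <- tx$genes$length[gi]
  lo <- pmax(1L, L - as.integer(window) + 1L)
  hi <- L - as.integer(read2_length) + 1L
  if (any(hi < lo)) hi <- pmax(hi, lo)
  start <- lo + as.integer(floor(runif(n_mol) * (hi - lo + 1L)))
  frag <- substr(tx$seq[tx$genes$transcript_id[gi]], start,
                 start + read2_length - 1L)
  # PCR re-emission: 1 + Geometric(1 - rate) copies of each molecule
  copies <- 1L + rgeom(n_mol, prob = 1 - pcr_duplication_rate)
  take <- rep(seq_len(n_mol), copies)
  is_dup <- sequence(copies) > 1L
  n_reads <- length(take)
  bc_seq <- barcode_set$barcode[match(barcode_well[take], barcode_set$well)]
  r1 <- rep.int(strrep("T", read1_length), n_reads)
  substr(r1, structure$barcode_offset + 1L,
         structure$barcode_offset + structure$barcode_length) <- bc_seq
  substr(r1, structure$umi_offset + 1L,
         structure$umi_offset + structure$umi_length) <- umi[take]
  r2 <- frag[take]
  r1 <- apply_substitutions(r1, base_error_rate)
  r2 <- apply_substitutions(r2, base_error_rate)
  ids <- paste0("rd", formatC(seq_len(n_reads), width = 8, flag = "0"))
  truth <- data.frame(read_id = ids, well = well[take], gene = gene[take],
                      umi = umi[take], is_duplicate = is_dup,
                      is_contaminant = contam[take],
                      barcode_well = barcode_well[take],
                      stringsAsFactors = FALSE)
  out <- structure(list(r1 = list(id = ids, seq = r1),
                        r2 = list(id = ids, seq = r2),
                        truth = truth), class = "sim_reads")
  finish_sim_reads(out, r1_path, r2_path, truth_path)
}

finish_sim_reads <- function(out, r1_path, r2_path, truth_path) {
  if (!is.null(r1_path)) write_fastq(out$r1$id, out$r1$seq, r1_path)
  if (!is.null(r2_path)) write_fastq(out$r2$id, out$r2$seq, r2_path)
  if (!is.null(truth_path)) write_sim_truth(out$truth, truth_path)
  out
}

#' Write / read a simulation ground-truth table
#'
#' Tab-separated with header `read_id well gene umi is_duplicate
#' is_contaminant barcode_well`.
#' @param truth Truth data.frame from [simulate_reads()].
#' @param path File path.
#' @export
write_sim_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  df <- read.delim(path, colClasses = c(
    read_id = "character", well = "character", gene = "character",
    umi = "character", is_duplicate = "logical",
    is_contaminant = "logical", barcode_well = "character"))
  df
}

#' Emit tagged transcriptome alignments as SAM (stand-in aligner)
#'
#' Each tagged read 2 becomes one SAM record against its true gene's
#' transcript. With probability `multimap_rate` a read is reported as
#' multi-mapped: its primary record gets MAPQ 0 and a secondary record
#' (FLAG 0x100) against a transcript of a different gene is added. All other
#' reads map uniquely with MAPQ 255.
#'
#' @param tagged data.frame with columns `qname` (demux-tagged read id),
#'   `read_id` (original id), `seq` (read-2 sequence) — as produced by
#'   [tag_reads()] — plus the truth table to look up true genes.
#' @param truth Truth data.frame from [simulate_reads()].
#' @param tx The `transcriptome` the reads came from.
#' @param multimap_rate Probability a read is reported multi-mapped.
#' @param seed RNG seed.
#' @param sam_path Output SAM path.
#' @return `sam_path`, invisibly.
#' @export
simulate_alignments <- function(tagged, truth, tx, multimap_rate = 0,
                                seed = 1L, sam_path) {
  set.seed(seed)
  gene <- truth$gene[match(tagged$read_id, truth$read_id)]
  if (anyNA(gene)) stop("tagged reads not present in the truth table")
  gi <- match(gene, tx$genes$gene_id)
  rname <- tx$genes$transcript_id[gi]
  n <- nrow(tagged)
  mm <- runif(n) < multimap_rate
  mapq <- ifelse(mm, 0L, 255L)
  cig <- paste0(nchar(tagged$seq), "M")
  qual <- strrep("I", nchar(tagged$seq))
  lines <- paste(tagged$qname, 0L, rname, 1L, mapq, cig, "*", 0L, 0L,
                 tagged$seq, qual, sep = "\t")
  if (any(mm)) {
    # secondary hit on a transcript of a different gene
    ng <- nrow(tx$genes)
    alt <- sample.int(ng - 1L, sum(mm), replace = TRUE)
    alt <- alt + (alt >= gi[mm])
    sec <- paste(tagged$qname[mm], 256L, tx$genes$transcript_id[alt], 1L, 0L,
                 cig[mm], "*", 0L, 0L, "*", "*", sep = "\t")
    lines <- c(lines, sec)
  }
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           paste0("@SQ\tSN:", tx$genes$transcript_id, "\tLN:",
                  tx$genes$length),
           "@PG\tID:welldge\tPN:welldge")
  con <- file(sam_path, "w")
  on.exit(close(con))
  writeLines(c(hdr, lines), con)
  invisible(sam_path)
}

#' Simulate a two-species barnyard plate
#'
#' Interleaves human-only and mouse-only wells in a checkerboard across the
#' plate and simulates reads with the given noise rates. Reads mapping to the
#' "wrong" species downstream quantify cross-well contamination.
#'
#' @param tx A two-species `transcriptome` (ERCC allowed as a third label).
#' @param geometry Plate geometry.
#' @param molecules_per_well Expected true molecules per well.
#' @param dispersion Negative-binomial size parameter.
#' @param barcode_set Optional pre-built `barcode_set`; generated (distance
#'   >= 3) when NULL.
#' @param structure A [read_structure()].
#' @param pcr_duplication_rate,base_error_rate,cross_contamination_rate
#'   Simulation noise rates.
#' @param seed RNG seed.
#' @param dir Optional directory to also write R1/R2 FASTQ, truth TSV, plate
#'   map CSV and barcode whitelist TSV into.
#' @return List: `plate` (plate_map), `barcode_set`, `molecules`
#'   (wells x genes matrix), `reads` (`sim_reads`).
#' @export
simulate_barnyard_plate <- function(tx, geometry = plate_geometry(384),
                                    molecules_per_well = 2000,
                                    dispersion = 2,
                                    barcode_set = NULL,
                                    structure = read_structure(),
                                    pcr_duplication_rate = 0,
                                    base_error_rate = 0,
                                    cross_contamination_rate = 0,
                                    seed = 1L, dir = NULL) {
  sp <- setdiff(unique(tx$genes$species), "ERCC")
  if (length(sp) < 2L)
    stop("barnyard simulation needs a two-species transcriptome")
  sp <- sp[1:2]
  plate <- checkerboard_plate_map(geometry, species = sp)
  if (is.null(barcode_set))
    barcode_set <- generate_barcode_set(nrow(plate),
                                        length = structure$barcode_length,
                                        min_hamming = 3L, seed = seed,
                                        geometry = geometry)
  profiles <- lapply(sp, function(s)
    expression_profile(tx, total_molecules = molecules_per_well,
                       dispersion = dispersion, species = s, seed = seed))
  names(profiles) <- sp
  set.seed(seed + 1L)
  ng <- nrow(tx$genes)
  mu <- matrix(0, nrow(plate), ng,
               dimnames = list(plate$well, tx$genes$gene_id))
  for (s in sp) mu[plate$species == s, ] <-
    matrix(profiles[[s]]$mu, sum(plate$species == s), ng, byrow = TRUE)
  molecules <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                              size = dispersion),
                      nrow(plate), ng, dimnames = dimnames(mu))
  storage.mode(molecules) <- "integer"
  paths <- list(r1 = NULL, r2 = NULL, truth = NULL)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(r1 = file.path(dir, "R1.fastq"),
                  r2 = file.path(dir, "R2.fastq"),
                  truth = file.path(dir, "truth.tsv"))
    write_plate_map(plate, file.path(dir, "plate.csv"))
    write_barcode_whitelist(barcode_set, file.path(dir, "barcodes.tsv"))
  }
  reads <- simulate_reads(molecules, tx, barcode_set, structure,
                          pcr_duplication_rate = pcr_duplication_rate,
                          base_error_rate = base_error_rate,
                          cross_contamination_rate = cross_contamination_rate,
                          seed = seed + 2L,
                          r1_path = paths$r1, r2_path = paths$r2,
                          truth_path = paths$truth)
  list(plate = plate, barcode_set = barcode_set, molecules = molecules,
       reads = reads)
}
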