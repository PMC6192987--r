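# Counting: tagged transcriptome alignments -> unique-gene filtering ->
# UMI-deduplicated wells x genes count matrix, with MatrixMarket I/O.

#' Parse a tagged SAM file into alignment records
#'
#' Reads a SAM (converted internally to BAM via Rsamtools), parses the demux
#' tag out of each query name and collapses transcript-level references to
#' gene ids through the annotation.
#'
#' @param sam_path SAM (or BAM) file whose query names carry the
#'   `<id>_<barcode>_<umi>` demux tag.
#' @param annotation Annotation data.frame from [read_gene_annotation()] (or
#'   a `transcriptome`'s `genes` table).
#' @param lenient If TRUE, records with unparseable tags are counted and
#'   skipped; if FALSE they raise an error.
#' @return A data.table of records: qname, read_id, barcode, umi, gene,
#'   species, mapped, secondary, mapq; attribute `n_malformed`.
#' @export
parse_tagged_sam <- function(sam_path, annotation, lenient = TRUE) {
  if (inherits(annotation, "transcriptome")) annotation <- annotation$genes
  bam <- sam_path
  if (grepl("\\.sam$", sam_path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(sam_path, dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "mapq"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  tag <- parse_read_tag(x$qname)
  malformed <- is.na(tag$read_id)
  if (any(malformed) && !lenient)
    stop("malformed demux tag in ", sum(malformed), " SAM records")
  gene <- annotation$gene_id[match(as.character(x$rname),
                                   annotation$transcript_id)]
  species <- annotation$species[match(gene, annotation$gene_id)]
  rec <- data.table::data.table(
    qname = x$qname, read_id = tag$read_id, barcode = tag$barcode,
    umi = tag$umi, gene = gene, species = species,
    mapped = bitwAnd(x$flag, 4L) == 0L,
    secondary = bitwAnd(x$flag, 256L) > 0L | bitwAnd(x$flag, 2048L) > 0L,
    mapq = x$mapq)
  rec <- rec[!malformed]
  attr(rec, "n_malformed") <- sum(malformed)
  rec
}

#' Keep reads that map uniquely at gene level
#'
#' A read is retained when its mapped alignments, after transcript-to-gene
#' collapse, touch exactly one gene and include a primary record. Alignments
#' to several transcripts of the same gene therefore still count as unique.
#'
#' @param records Alignment records from [parse_tagged_sam()].
#' @param min_mapq Optional primary-record MAPQ floor (for real aligner
#'   output where e.g. 255 marks unique hits); NULL disables it.
#' @return One primary record per retained read (data.table).
#' @export
filter_unique <- function(records, min_mapq = NULL) {
  gene <- secondary <- mapped <- qname <- n_genes <- has_primary <- NULL
  rec <- records[mapped == TRUE & !is.na(gene)]
  # reads with a single record are unique iff that record is primary;
  # only reads with several records need per-read grouping
  multi <- unique(rec$qname[duplicated(rec$qname)])
  single <- rec[!(qname %in% multi) & secondary == FALSE]
  rest <- rec[qname %in% multi]
  if (nrow(rest)) {
    info <- rest[, list(n_genes = data.table::uniqueN(gene),
                        has_primary = any(!secondary)), by = qname]
    keep <- info[n_genes == 1L & has_primary == TRUE, qname]
    rest <- rest[secondary == FALSE][qname %in% keep]
    rest <- rest[!duplicated(qname)]
  }
  out <- rbind(single, rest)
  if (!is.null(min_mapq)) out <- out[out$mapq >= min_mapq]
  out
}

# directional UMI collapse within one (well, gene) group: merge a
# lower-count UMI into a Hamming-1 neighbour when count(parent) >=
# 2 * count(child) - 1. Returns the number of distinct molecules.
collapse_directional <- function(umis, reads_per_umi) {
  o <- order(-reads_per_umi, umis)
  umis <- umis[o]
  cnt <- reads_per_umi[o]
  n <- length(umis)
  if (n <= 1L) return(n)
  enc <- encode_barcodes(umis)
  parent <- rep(NA_integer_, n)
  for (i in seq_len(n)[-1L]) {
    for (j in seq_len(i - 1L)) {
      if (!is.na(parent[j])) next
      if (sum(enc[i, ] != enc[j, ]) == 1L && cnt[j] >= 2L * cnt[i] - 1L) {
        parent[i] <- j
        break
      }
    }
  }
  sum(is.na(parent))
}

#' Count UMIs per well and gene
#'
#' The deduplication stage: in `exact` mode (the default) the count for a
#' (well, gene) cell is the number of distinct UMIs observed there — reads
#' sharing (well, gene, UMI) are counted once. `directional` mode
#' additionally merges UMIs within Hamming distance 1 of a more abundant
#' UMI when `count(parent) >= 2 * count(child) - 1`, absorbing UMIs created
#' by sequencing errors. UMIs containing `N` are discarded first.
#'
#' @param records Unique-filtered records from [filter_unique()].
#' @param plate A `plate_map`; rows of the matrix follow its well order.
#' @param barcode_set The `barcode_set` used for tagging (maps the tag's
#'   barcode back to a well).
#' @param annotation Annotation data.frame or `transcriptome` (gene universe
#'   and species/ERCC metadata for the columns).
#' @param collapse `"exact"` or `"directional"`.
#' @param unknown_wells `"error"` (default) to fail on reads whose barcode
#'   maps to a well absent from the plate, `"skip"` to drop and count them.
#' @return A `count_matrix`: list with `counts` (sparse dgCMatrix wells x
#'   genes), `wells` (plate-map rows) and `genes` (gene metadata).
#' @export
count_umis <- function(records, plate, barcode_set, annotation,
                       collapse = c("exact", "directional"),
                       unknown_wells = c("error", "skip")) {
  collapse <- match.arg(collapse)
  unknown_wells <- match.arg(unknown_wells)
  if (inherits(annotation, "transcriptome")) annotation <- annotation$genes
  genes <- unique(annotation[, c("gene_id", "species")])
  genes$is_ercc <- genes$species == "ERCC"
  barcode <- umi <- gene <- well <- NULL
  rec <- data.table::as.data.table(records)[!grepl("N", umi, fixed = TRUE)]
  rec[, well := barcode_set$well[match(barcode, barcode_set$barcode)]]
  unk <- !(rec$well %in% plate$well) | is.na(rec$well)
  if (any(unk)) {
    if (unknown_wells == "error")
      stop(sum(unk), " reads map to wells absent from the plate map")
    rec <- rec[!unk]
  }
  n_skipped <- sum(unk)
  if (collapse == "exact") {
    cells <- unique(rec[, list(well, gene, umi)])[, list(n = .N),
                                                  by = list(well, gene)]
  } else {
    cells <- rec[, list(n_reads = .N), by = list(well, gene, umi)][
      , list(n = collapse_directional(umi, n_reads)), by = list(well, gene)]
  }
  i <- match(cells$well, plate$well)
  j <- match(cells$gene, genes$gene_id)
  if (anyNA(j)) stop("records reference genes absent from the annotation")
  counts <- Matrix::sparseMatrix(i = i, j = j, x = cells$n,
                                 dims = c(nrow(plate), nrow(genes)),
                                 dimnames = list(plate$well, genes$gene_id))
  cm <- structure(list(counts = counts,
                       wells = as.data.frame(plate),
                       genes = genes),
                  class = "count_matrix")
  attr(cm, "n_skipped") <- n_skipped
  cm
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d wells x %d genes, %d nonzero, %.0f UMIs\n",
              nrow(x$counts), ncol(x$counts),
              Matrix::nnzero(x$counts), sum(x$counts)))
  invisible(x)
}

#' Write / read a count matrix as MatrixMarket plus metadata TSVs
#'
#' Writes `matrix.mtx` (sparse, wells x genes), `wells.tsv`, `genes.tsv` and
#' an `ercc.tsv` per-well spike-in summary. Reading the directory back
#' reproduces the `count_matrix`.
#'
#' @param cm A `count_matrix`.
#' @param outdir Output directory (created if needed).
#' @export
write_count_matrix <- function(cm, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(cm$counts, file.path(outdir, "matrix.mtx"))
  write.table(cm$wells, file.path(outdir, "wells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cm$genes, file.path(outdir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ercc <- data.frame(well = rownames(cm$counts),
                     ercc_umis = Matrix::rowSums(cm$counts[, cm$genes$is_ercc,
                                                           drop = FALSE]),
                     total_umis = Matrix::rowSums(cm$counts))
  write.table(ercc, file.path(outdir, "ercc.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(outdir) {
  counts <- methods::as(Matrix::readMM(file.path(outdir, "matrix.mtx")),
                        "CsparseMatrix")
  wells <- read.delim(file.path(outdir, "wells.tsv"),
                      colClasses = c(well = "character"))
  genes <- read.delim(file.path(outdir, "genes.tsv"),
                      colClasses = c(gene_id = "character"))
  if (nrow(wells) != nrow(counts) || nrow(genes) != ncol(counts))
    stop("count matrix dimensions do not match metadata tables")
  dimnames(counts) <- list(wells$well, genes$gene_id)
  structure(list(counts = counts, wells = wells, genes = genes),
            class = "count_matrix")
}

#' Brute-force UMI counts from a simulation truth table
#'
#' Independent oracle for [count_umis()]: counts distinct (well, gene, UMI)
#' triples directly from the ground truth, attributing each molecule to the
#' well of the barcode it was written under.
#'
#' @param truth Truth data.frame from [simulate_reads()].
#' @param by `"barcode"` (default; what counting can see) or `"source"`
#'   (true origin well, differing only for contaminants).
#' @return data.frame well, gene, n.
#' @export
truth_umi_counts <- function(truth, by = c("barcode", "source")) {
  by <- match.arg(by)
  w <- if (by == "barcode") truth$barcode_well else truth$well
  key <- unique(data.frame(well = w, gene = truth$gene, umi = truth$umi,
                           stringsAsFactors = FALSE))
  agg <- stats::aggregate(umi ~ well + gene, data = key, FUN = length)
  names(agg)[3] <- "n"
  agg
}
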