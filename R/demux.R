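# Demultiplexing: pull the well barcode and UMI out of read 1, correct the
# barcode against the whitelist, and carry both into the read-2 identifier.

#' Extract the well barcode and UMI from read-1 sequences
#'
#' Substrings at the offsets configured in the [read_structure()]; sequences
#' are uppercased, nothing else is normalised. Reads shorter than the layout
#' requires are flagged rather than erroring, so callers can route them to
#' the unassigned pool with a distinct reason.
#'
#' @param seq Character vector of read-1 sequences.
#' @param structure A [read_structure()].
#' @return List with `barcode`, `umi` (NA where truncated) and `truncated`
#'   (logical).
#' @examples
#' extract_barcode_umi("acgtacgtacTTTTTTTTTTTTTTTTTTTTTT")
#' @export
extract_barcode_umi <- function(seq, structure = read_structure()) {
  seq <- toupper(seq)
  trunc <- nchar(seq) < min_read1_length(structure)
  bc <- substr(seq, structure$barcode_offset + 1L,
               structure$barcode_offset + structure$barcode_length)
  um <- substr(seq, structure$umi_offset + 1L,
               structure$umi_offset + structure$umi_length)
  bc[trunc] <- NA_character_
  um[trunc] <- NA_character_
  list(barcode = bc, umi = um, truncated = trunc)
}

#' Match observed barcodes against a whitelist with mismatch tolerance
#'
#' An exact hit wins. Otherwise, if exactly one whitelist barcode lies within
#' `max_mismatch`, the read is assigned there and flagged as corrected; zero
#' or several candidates leave it unassigned (several = ambiguous). With the
#' whitelist at pairwise distance >= 2 * max_mismatch + 1, ambiguity cannot
#' arise from errors on a true barcode. `N` bases mismatch every base.
#'
#' @param observed Character vector of observed barcodes (whitelist length).
#' @param barcode_set A `barcode_set`.
#' @param max_mismatch Maximum Hamming distance for correction (0 = exact
#'   only).
#' @return data.frame with columns `well` (NA if unassigned), `corrected`,
#'   `ambiguous`.
#' @export
match_barcode <- function(observed, barcode_set, max_mismatch = 1L) {
  L <- attr(barcode_set, "barcode_length")
  observed <- toupper(observed)
  if (any(nchar(observed) != L, na.rm = TRUE))
    stop("observed barcode length differs from the whitelist length")
  n <- length(observed)
  well <- barcode_set$well[match(observed, barcode_set$barcode)]
  corrected <- logical(n)
  ambiguous <- logical(n)
  todo <- which(is.na(well) & !is.na(observed))
  if (length(todo) && max_mismatch > 0L) {
    wl <- encode_barcodes(barcode_set$barcode)
    uo <- unique(observed[todo])
    om <- encode_barcodes(uo)
    uw <- character(length(uo))
    ua <- logical(length(uo))
    for (i in seq_along(uo)) {
      d <- rowSums(wl != matrix(om[i, ], nrow(wl), L, byrow = TRUE))
      hit <- which(d <= max_mismatch)
      if (length(hit) == 1L) uw[i] <- barcode_set$well[hit]
      else {
        uw[i] <- NA_character_
        ua[i] <- length(hit) > 1L
      }
    }
    m <- match(observed[todo], uo)
    well[todo] <- uw[m]
    corrected[todo] <- !is.na(uw[m])
    ambiguous[todo] <- ua[m]
  }
  data.frame(well = well, corrected = corrected, ambiguous = ambiguous,
             stringsAsFactors = FALSE)
}

# split "<id>_<barcode>_<umi>" from the right
parse_read_tag <- function(qname) {
  pat <- "^(.*)_([ACGTN]+)_([ACGTN]+)$"
  ok <- grepl(pat, qname)
  out <- data.frame(read_id = rep(NA_character_, length(qname)),
                    barcode = NA_character_, umi = NA_character_,
                    stringsAsFactors = FALSE)
  if (any(ok)) {
    q <- qname[ok]
    out$read_id[ok] <- sub(pat, "\\1", q)
    out$barcode[ok] <- sub(pat, "\\2", q)
    out$umi[ok] <- sub(pat, "\\3", q)
  }
  out
}

#' Tag read 2 with the corrected well barcode and UMI
#'
#' The demultiplexing stage: for each read pair, the barcode and UMI are
#' extracted from read 1, the barcode is matched against the whitelist, and
#' each retained read 2 is re-identified as
#' `<original_id>_<corrected_barcode>_<umi>`. Unassigned reads (no barcode
#' within tolerance, ambiguous, or truncated read 1) are dropped from the
#' tagged output but counted. Record order is preserved.
#'
#' @param r1,r2 Paired inputs: FASTQ file paths or `list(id, seq)` as found
#'   in a `sim_reads` object. Record counts must match.
#' @param barcode_set A `barcode_set`.
#' @param structure A [read_structure()].
#' @param max_mismatch Barcode correction tolerance (0 = exact only).
#' @param out Optional path for the tagged read-2 FASTQ.
#' @param stats_json Optional path for the [demux_stats] JSON report.
#' @return List with `tagged` (data.frame: qname, read_id, well, barcode,
#'   umi, seq) and `stats` (a `demux_stats` object).
#' @export
tag_reads <- function(r1, r2, barcode_set, structure = read_structure(),
                      max_mismatch = 1L, out = NULL, stats_json = NULL) {
  if (is.character(r1)) r1 <- read_fastq(r1)
  if (is.character(r2)) r2 <- read_fastq(r2)
  if (length(r1$seq) != length(r2$seq))
    stop("unpaired inputs: read1 has ", length(r1$seq),
         " records, read2 has ", length(r2$seq))
  ext <- extract_barcode_umi(r1$seq, structure)
  n <- length(r1$seq)
  well <- rep(NA_character_, n)
  corrected <- logical(n)
  ambiguous <- logical(n)
  ok <- !ext$truncated
  if (any(ok)) {
    mb <- match_barcode(ext$barcode[ok], barcode_set, max_mismatch)
    well[ok] <- mb$well
    corrected[ok] <- mb$corrected
    ambiguous[ok] <- mb$ambiguous
  }
  keep <- !is.na(well)
  bc_corr <- barcode_set$barcode[match(well, barcode_set$well)]
  tagged <- data.frame(
    qname = paste(r1$id[keep], bc_corr[keep], ext$umi[keep], sep = "_"),
    read_id = r1$id[keep], well = well[keep], barcode = bc_corr[keep],
    umi = ext$umi[keep], seq = r2$seq[keep], stringsAsFactors = FALSE)
  per_well <- table(factor(well[keep], levels = barcode_set$well))
  stats <- structure(list(
    total = n,
    assigned = sum(keep),
    unassigned = sum(!keep & !ambiguous),
    ambiguous = sum(ambiguous & !keep),
    corrected = sum(corrected & keep),
    truncated = sum(ext$truncated),
    per_well = as.integer(per_well),
    wells = names(per_well)), class = "demux_stats")
  if (!is.null(out)) write_fastq(tagged$qname, tagged$seq, out)
  if (!is.null(stats_json)) write_demux_stats(stats, stats_json)
  list(tagged = tagged, stats = stats)
}

#' Demultiplexing statistics
#'
#' `assigned + unassigned + ambiguous == total` always holds; `corrected`
#' counts reads assigned through mismatch tolerance and is <= assigned;
#' `truncated` reads are part of `unassigned`.
#'
#' @param stats A `demux_stats` object.
#' @param path Output path.
#' @name demux_stats
#' @export
write_demux_stats <- function(stats, path) {
  jsonlite::write_json(
    list(total = stats$total, assigned = stats$assigned,
         unassigned = stats$unassigned, ambiguous = stats$ambiguous,
         corrected = stats$corrected, truncated = stats$truncated,
         per_well = as.list(setNames(stats$per_well, stats$wells))),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @export
print.demux_stats <- function(x, ...) {
  cat(sprintf(
    "demux: %d reads; %d assigned (%d corrected), %d unassigned (%d truncated), %d ambiguous\n",
    x$total, x$assigned, x$corrected, x$unassigned, x$truncated, x$ambiguous))
  invisible(x)
}
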