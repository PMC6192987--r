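# Convenience orchestration of the full desk-scale pipeline:
# simulated reads -> demultiplex -> stand-in alignment -> unique filter ->
# UMI counting.

#' Run simulated reads through demultiplexing, alignment and counting
#'
#' Tags the read pairs ([tag_reads()]), emits stand-in transcriptome
#' alignments as SAM ([simulate_alignments()]), parses and unique-filters
#' them, and counts UMIs into a wells x genes matrix. When `dir` is given
#' the intermediate tagged FASTQ and SAM (and demux stats JSON) are written
#' there; otherwise they live in a temporary directory.
#'
#' @param sim A `sim_reads` object (e.g. from [simulate_reads()] or
#'   `simulate_barnyard_plate()$reads`).
#' @param barcode_set,tx,plate The barcode set, transcriptome and plate map
#'   the reads were simulated from.
#' @param structure The [read_structure()].
#' @param max_mismatch Barcode correction tolerance.
#' @param multimap_rate Fraction of reads reported multi-mapped by the
#'   stand-in aligner.
#' @param collapse UMI collapse mode for [count_umis()].
#' @param seed RNG seed (stand-in aligner).
#' @param dir Optional output directory for intermediates.
#' @return List: `cm` (`count_matrix`), `demux_stats`, `tagged`, `records`
#'   (unique-filtered alignment records).
#' @export
pipeline_count <- function(sim, barcode_set, tx, plate,
                           structure = read_structure(), max_mismatch = 1L,
                           multimap_rate = 0, collapse = "exact",
                           seed = 1L, dir = NULL) {
  tmp <- if (is.null(dir)) tempfile("welldge_run") else dir
  dir.create(tmp, showWarnings = FALSE, recursive = TRUE)
  tg <- tag_reads(sim$r1, sim$r2, barcode_set, structure,
                  max_mismatch = max_mismatch,
                  out = file.path(tmp, "tagged.fastq"),
                  stats_json = file.path(tmp, "demux_stats.json"))
  sam <- file.path(tmp, "aligned.sam")
  simulate_alignments(tg$tagged, sim$truth, tx,
                      multimap_rate = multimap_rate, seed = seed,
                      sam_path = sam)
  rec <- parse_tagged_sam(sam, tx)
  uniq <- filter_unique(rec)
  cm <- count_umis(uniq, plate, barcode_set, tx, collapse = collapse)
  if (is.null(dir)) unlink(tmp, recursive = TRUE)
  list(cm = cm, demux_stats = tg$stats, tagged = tg$tagged, records = uniq)
}
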