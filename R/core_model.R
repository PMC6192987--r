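#' welldge: plate-based 3' digital gene expression screening pipeline
#'
#' Simulation, demultiplexing, UMI counting, QC and compound-profiling
#' analytics for well-barcoded 3' counting RNA-seq screens run in 384- or
#' 1536-well plates.
#'
#' @import methods
#' @importFrom data.table data.table as.data.table uniqueN := .N
#' @importFrom stats rnorm runif rbinom rgeom rnbinom rpois cor sd pt p.adjust
#'   dist hclust as.dendrogram as.hclust cutree setNames median qnorm quantile
#'   var aggregate
#' @importFrom utils read.csv write.csv read.delim write.table head tail
#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

#' Read-structure description of read 1
#'
#' Read 1 of a well-barcoded 3' counting library carries the well barcode and
#' the unique molecular index (UMI) written into the RT primer; read 2 carries
#' the cDNA fragment. The default layout is a 10-base well barcode at the
#' start of read 1 followed immediately by a 10-base UMI.
#'
#' @param barcode_length Well-barcode length in bases (> 0).
#' @param umi_length UMI length in bases (> 0).
#' @param barcode_offset 0-based offset of the barcode in read 1.
#' @param umi_offset 0-based offset of the UMI in read 1. The barcode and UMI
#'   intervals must not overlap.
#' @return An object of class `read_structure`.
#' @examples
#' read_structure()
#' @export
read_structure <- function(barcode_length = 10L, umi_length = 10L,
                           barcode_offset = 0L, umi_offset = barcode_length) {
  barcode_length <- as.integer(barcode_length)
  umi_length <- as.integer(umi_length)
  barcode_offset <- as.integer(barcode_offset)
  umi_offset <- as.integer(umi_offset)
  if (barcode_length <= 0L || umi_length <= 0L)
    stop("barcode_length and umi_length must be positive")
  b <- c(barcode_offset, barcode_offset + barcode_length)
  u <- c(umi_offset, umi_offset + umi_length)
  if (max(b[1], u[1]) < min(b[2], u[2]))
    stop("barcode and UMI intervals overlap")
  structure(list(barcode_length = barcode_length, umi_length = umi_length,
                 barcode_offset = barcode_offset, umi_offset = umi_offset),
            class = "read_structure")
}

#' @export
print.read_structure <- function(x, ...) {
  cat(sprintf("read_structure: barcode %dbp @%d, UMI %dbp @%d\n",
              x$barcode_length, x$barcode_offset, x$umi_length, x$umi_offset))
  invisible(x)
}

# minimum read-1 length required to extract both elements
min_read1_length <- function(structure) {
  max(structure$barcode_offset + structure$barcode_length,
      structure$umi_offset + structure$umi_length)
}

#' Plate geometry
#'
#' @param wells Total number of wells: 96, 384 (default) or 1536.
#' @return Named integer vector `c(rows, cols)`.
#' @export
plate_geometry <- function(wells = 384) {
  geo <- switch(as.character(wells),
                "96" = c(8L, 12L), "384" = c(16L, 24L), "1536" = c(32L, 48L),
                stop("unsupported plate size: ", wells))
  c(rows = geo[1], cols = geo[2])
}

# row labels A..Z then AA, AB, ... for tall plates
plate_row_labels <- function(n_rows) {
  if (n_rows <= 26L) return(LETTERS[seq_len(n_rows)])
  extra <- n_rows - 26L
  c(LETTERS, paste0("A", LETTERS[seq_len(extra)]))
}

#' Well addresses of a plate, in row-major order
#'
#' String form is row letter(s) plus a zero-padded column number ("A01").
#'
#' @param geometry Integer vector `c(rows, cols)`, e.g. [plate_geometry()].
#' @return Character vector of well names, length `rows * cols`.
#' @examples
#' head(well_addresses(plate_geometry(384)))
#' @export
well_addresses <- function(geometry = plate_geometry(384)) {
  rows <- plate_row_labels(geometry[1])
  pad <- max(2L, nchar(as.character(geometry[2])))
  cols <- formatC(seq_len(geometry[2]), width = pad, flag = "0")
  as.vector(t(outer(rows, cols, paste0)))
}

#' Hamming distance between DNA strings
#'
#' Number of mismatching positions between equal-length strings. Vectorised
#' over pairs; `a` and `b` are recycled to a common length.
#'
#' @param a,b Character vectors of equal-length strings.
#' @return Integer vector of distances.
#' @examples
#' hamming_distance("ACGT", "TGCA")
#' @export
hamming_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  if (any(nchar(a) != nchar(b)))
    stop("hamming_distance: strings must have equal length")
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b,
         USE.NAMES = FALSE)
}

# Encode barcodes as an integer matrix (A=1..T=4, anything else 0 so that N
# mismatches every base). Rows = barcodes, columns = positions.
encode_barcodes <- function(x) {
  if (length(x) == 0L) return(matrix(integer(0), 0, 0))
  L <- nchar(x[1])
  m <- matrix(match(unlist(strsplit(toupper(x), "", fixed = TRUE)), DNA_BASES,
                    nomatch = 0L),
              nrow = length(x), ncol = L, byrow = TRUE)
  rownames(m) <- NULL
  m
}

#' Generate a whitelist of well barcodes with a pairwise-distance guarantee
#'
#' Draws random barcodes and keeps those at Hamming distance at least
#' `min_hamming` from every previously accepted one, then assigns them to
#' wells in row-major plate order. Distance >= 3 (the default) makes
#' single-mismatch correction unambiguous.
#'
#' @param n_wells Number of barcodes (one per well).
#' @param length Barcode length in bases.
#' @param min_hamming Minimum pairwise Hamming distance.
#' @param seed Integer RNG seed; the result is deterministic given the seed.
#' @param geometry Plate geometry used to name wells.
#' @param max_tries Attempt budget before declaring the request infeasible.
#' @return A `barcode_set`: data.frame with columns `barcode`, `well` and
#'   attributes `barcode_length`, `min_hamming`.
#' @examples
#' bs <- generate_barcode_set(4, length = 6, min_hamming = 3, seed = 1)
#' @export
generate_barcode_set <- function(n_wells, length = 10L, min_hamming = 3L,
                                 seed = 1L,
                                 geometry = plate_geometry(384),
                                 max_tries = 200L * n_wells + 2000L) {
  if (4^length < n_wells)
    stop("infeasible: 4^length < n_wells")
  if (min_hamming > length)
    stop("infeasible: min_hamming exceeds barcode length")
  if (n_wells > prod(geometry))
    stop("more barcodes requested than wells in the geometry")
  set.seed(seed)
  accepted <- matrix(0L, nrow = 0L, ncol = length)
  tries <- 0L
  while (nrow(accepted) < n_wells) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop(sprintf(
        "infeasible: could not place %d barcodes of length %d at Hamming >= %d within %d tries",
        n_wells, length, min_hamming, max_tries))
    cand <- sample.int(4L, length, replace = TRUE)
    if (nrow(accepted) > 0L) {
      d <- rowSums(accepted != matrix(cand, nrow(accepted), length,
                                      byrow = TRUE))
      if (min(d) < min_hamming) next
    }
    accepted <- rbind(accepted, cand)
  }
  codes <- apply(accepted, 1L, function(r) paste(DNA_BASES[r], collapse = ""))
  bs <- data.frame(barcode = codes,
                   well = well_addresses(geometry)[seq_len(n_wells)],
                   stringsAsFactors = FALSE)
  attr(bs, "barcode_length") <- as.integer(length)
  attr(bs, "min_hamming") <- as.integer(min_hamming)
  class(bs) <- c("barcode_set", "data.frame")
  validate_barcode_set(bs)
  bs
}

#' Validate a barcode set exhaustively
#'
#' Checks equal lengths, bijectivity of barcode <-> well, and that every
#' pairwise Hamming distance meets the set's `min_hamming` attribute.
#'
#' @param bs A `barcode_set`.
#' @return `bs`, invisibly; errors on violation.
#' @export
validate_barcode_set <- function(bs) {
  L <- attr(bs, "barcode_length")
  if (any(nchar(bs$barcode) != L))
    stop("barcode set invalid: unequal barcode lengths")
  if (anyDuplicated(bs$barcode) || anyDuplicated(bs$well))
    stop("barcode set invalid: barcode -> well mapping is not bijective")
  k <- nrow(bs)
  if (k > 1L) {
    m <- encode_barcodes(bs$barcode)
    sim <- matrix(0L, k, k)
    for (j in seq_len(ncol(m)))
      sim <- sim + outer(m[, j], m[, j], "==")
    d <- L - sim
    diag(d) <- L
    if (min(d) < attr(bs, "min_hamming"))
      stop(sprintf("barcode set invalid: pairwise Hamming distance %d < %d",
                   min(d), attr(bs, "min_hamming")))
  }
  invisible(bs)
}

#' Read and write barcode whitelists
#'
#' Whitelist format: two tab-separated columns `barcode`, `well`, no header.
#'
#' @param path File path.
#' @param min_hamming Distance attribute to attach on read (validated).
#' @return `read_barcode_whitelist` returns a `barcode_set`.
#' @export
read_barcode_whitelist <- function(path, min_hamming = 1L) {
  df <- read.delim(path, header = FALSE, col.names = c("barcode", "well"),
                   colClasses = "character")
  attr(df, "barcode_length") <- nchar(df$barcode[1])
  attr(df, "min_hamming") <- as.integer(min_hamming)
  class(df) <- c("barcode_set", "data.frame")
  validate_barcode_set(df)
  df
}

#' @rdname read_barcode_whitelist
#' @param bs A `barcode_set` to write.
#' @export
write_barcode_whitelist <- function(bs, path) {
  write.table(bs[, c("barcode", "well")], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

PLATE_MAP_COLS <- c("well", "treatment", "dose_um", "replicate", "species",
                    "cell_line")

#' Construct and validate a plate map
#'
#' A plate map assigns every well a treatment label (compound id, guide id or
#' "DMSO"), a dose in micromolar (NA for controls), a replicate index, a
#' species and a cell line.
#'
#' @param df data.frame with columns `well`, `treatment`, `dose_um`,
#'   `replicate`, `species`, `cell_line`.
#' @param geometry Plate geometry; every well must lie inside it and appear
#'   at most once, and replicate indices must be distinct within each
#'   (treatment, dose) group.
#' @return A `plate_map` (data.frame subclass) with a `geometry` attribute.
#' @export
plate_map <- function(df, geometry = plate_geometry(384)) {
  miss <- setdiff(PLATE_MAP_COLS, names(df))
  if (length(miss))
    stop("plate map missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, PLATE_MAP_COLS]
  df$dose_um <- suppressWarnings(as.numeric(df$dose_um))
  df$replicate <- as.integer(df$replicate)
  valid <- well_addresses(geometry)
  bad <- setdiff(df$well, valid)
  if (length(bad))
    stop("plate map wells outside the plate geometry: ",
         paste(head(bad, 5), collapse = ", "))
  if (anyDuplicated(df$well))
    stop("plate map has duplicate wells: ",
         paste(head(df$well[duplicated(df$well)], 5), collapse = ", "))
  grp <- paste(df$treatment, df$dose_um, sep = "@")
  dup <- vapply(split(df$replicate, grp), anyDuplicated, 0L)
  if (any(dup > 0L))
    stop("duplicate replicate index within (treatment, dose) group: ",
         names(dup)[dup > 0L][1])
  attr(df, "geometry") <- geometry
  class(df) <- c("plate_map", "data.frame")
  df
}

#' Read and write plate maps
#'
#' CSV with header `well,treatment,dose_um,replicate,species,cell_line`;
#' the dose field is empty for controls. Writing then reading reproduces the
#' plate map.
#'
#' @param path CSV path.
#' @param geometry Plate geometry for validation.
#' @return `read_plate_map` returns a `plate_map`.
#' @export
read_plate_map <- function(path, geometry = plate_geometry(384)) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(well = "character", treatment = "character",
                                species = "character",
                                cell_line = "character"))
  plate_map(df, geometry)
}

#' @rdname read_plate_map
#' @param plate A `plate_map` to write.
#' @export
write_plate_map <- function(plate, path) {
  write.csv(as.data.frame(plate), path, row.names = FALSE, quote = FALSE,
            na = "")
  invisible(path)
}

#' Checkerboard two-species plate map for a barnyard experiment
#'
#' Alternates two species across the plate so adjacent wells differ, giving
#' `rows * cols / 2` wells per species on an even geometry.
#'
#' @param geometry Plate geometry.
#' @param species Length-2 character vector of species labels.
#' @param cell_lines Length-2 character vector of cell-line labels.
#' @return A `plate_map` with treatment "cells" everywhere and no dose.
#' @export
checkerboard_plate_map <- function(geometry = plate_geometry(384),
                                   species = c("human", "mouse"),
                                   cell_lines = c("HEK293T", "C2C12")) {
  stopifnot(length(species) == 2L)
  rows <- rep(seq_len(geometry[1]), each = geometry[2])
  cols <- rep(seq_len(geometry[2]), times = geometry[1])
  pick <- ((rows + cols) %% 2L) + 1L
  df <- data.frame(well = well_addresses(geometry),
                   treatment = "cells", dose_um = NA_real_,
                   replicate = seq_len(prod(geometry)),
                   species = species[pick],
                   cell_line = cell_lines[pick],
                   stringsAsFactors = FALSE)
  plate_map(df, geometry)
}
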