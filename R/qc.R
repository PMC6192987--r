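# Quality control: barnyard species purity, well correlation, downsampling /
# gene-detection saturation, ROC benchmarking against a reference truth set,
# and CRISPR indel frame binning.

#' Species purity of a barnyard plate
#'
#' For each well, purity is the UMI count of the dominant species divided by
#' the well's total endogenous UMIs (ERCC excluded). The global pass fraction
#' is the share of nonempty wells with purity strictly above the threshold;
#' empty wells have undefined purity and are excluded from the denominator.
#'
#' @param cm A `count_matrix` whose gene metadata carries >= 2 species.
#' @param purity_threshold Strict purity threshold (default 0.96).
#' @return A `purity_report`: list with `per_well` (data.frame: well,
#'   per-species UMIs, total, purity), `pass_fraction`, `threshold`.
#' @export
species_purity <- function(cm, purity_threshold = 0.96) {
  endog <- !cm$genes$is_ercc
  sp <- sort(unique(cm$genes$species[endog]))
  if (length(sp) < 2L)
    stop("species purity needs gene metadata for at least two species")
  ind <- sapply(sp, function(s) as.numeric(cm$genes$species == s & endog))
  by_sp <- as.matrix(cm$counts %*% ind)
  colnames(by_sp) <- sp
  total <- rowSums(by_sp)
  purity <- ifelse(total > 0, apply(by_sp, 1L, max) / total, NA_real_)
  per_well <- data.frame(well = rownames(cm$counts), by_sp, total = total,
                         purity = purity, check.names = FALSE)
  rownames(per_well) <- NULL
  structure(list(per_well = per_well,
                 pass_fraction = mean(purity > purity_threshold, na.rm = TRUE),
                 threshold = purity_threshold),
            class = "purity_report")
}

#' @export
print.purity_report <- function(x, ...) {
  cat(sprintf("purity: %.1f%% of %d nonempty wells > %.2f\n",
              100 * x$pass_fraction, sum(!is.na(x$per_well$purity)),
              x$threshold))
  invisible(x)
}

#' Pearson correlation between wells
#'
#' Expression is taken over endogenous genes, by default as counts-per-million
#' then log(1 + x). Wells with zero variance after the transform get NA
#' correlations.
#'
#' @param cm A `count_matrix` with >= 2 wells.
#' @param transform `"log1p_cpm"` (default) or `"none"` (raw counts).
#' @return Symmetric wells x wells correlation matrix with unit diagonal.
#' @export
well_correlation <- function(cm, transform = c("log1p_cpm", "none")) {
  transform <- match.arg(transform)
  if (nrow(cm$counts) < 2L) stop("well correlation needs at least two wells")
  m <- as.matrix(cm$counts[, !cm$genes$is_ercc, drop = FALSE])
  if (transform == "log1p_cpm") {
    lib <- rowSums(m)
    lib[lib == 0] <- 1
    m <- log1p(m / lib * 1e6)
  }
  r <- suppressWarnings(cor(t(m)))
  diag(r) <- 1
  r
}

#' Binomial downsampling of a count matrix
#'
#' Thins every UMI independently with probability `fraction`, emulating a
#' shallower sequencing run. Deterministic given the seed.
#'
#' @param cm A `count_matrix`.
#' @param fraction Retention probability in [0, 1].
#' @param seed RNG seed.
#' @return A `count_matrix` with thinned counts.
#' @export
downsample <- function(cm, fraction, seed = 1L) {
  if (fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]")
  set.seed(seed)
  x <- cm$counts
  x@x <- as.numeric(rbinom(length(x@x), size = as.integer(x@x),
                           prob = fraction))
  cm$counts <- Matrix::drop0(x)
  cm
}

#' Genes detected per well above expression thresholds
#'
#' @param cm A `count_matrix`.
#' @param thresholds Ascending numeric thresholds; a gene is detected in a
#'   well when its count is strictly above the threshold.
#' @param include_ercc Count spike-ins too? Default FALSE.
#' @return Matrix wells x thresholds of detected-gene numbers.
#' @export
genes_detected <- function(cm, thresholds = 0, include_ercc = FALSE) {
  if (is.unsorted(thresholds)) stop("thresholds must be sorted ascending")
  m <- cm$counts
  if (!include_ercc) m <- m[, !cm$genes$is_ercc, drop = FALSE]
  out <- sapply(thresholds, function(t) Matrix::rowSums(m > t))
  out <- matrix(out, nrow = nrow(m),
                dimnames = list(rownames(m), paste0(">", thresholds)))
  out
}

#' Gene-detection saturation under downsampling
#'
#' Downsamples the matrix to each fraction and reports mean and SD of genes
#' detected per well at each threshold.
#'
#' @param cm A `count_matrix`.
#' @param fractions Retention fractions to evaluate.
#' @param thresholds Detection thresholds (see [genes_detected()]).
#' @param seed RNG seed.
#' @return A `saturation_curve` data.frame: fraction, threshold,
#'   mean_genes, sd_genes.
#' @export
saturation_curve <- function(cm, fractions = seq(0.1, 1, by = 0.1),
                             thresholds = 0, seed = 1L) {
  rows <- list()
  for (i in seq_along(fractions)) {
    d <- downsample(cm, fractions[i], seed = seed + i)
    g <- genes_detected(d, thresholds)
    rows[[i]] <- data.frame(fraction = fractions[i], threshold = thresholds,
                            mean_genes = colMeans(g),
                            sd_genes = apply(g, 2L, sd))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("saturation_curve", "data.frame")
  out
}

#' ROC of a score against a reference fold-change truth set
#'
#' Positives are genes whose reference |log2FC| exceeds `truth_lfc_cutoff`
#' (set `direction = "signed"` to require log2FC > cutoff instead). The curve
#' sweeps the score from high to low, grouping ties; AUC is the trapezoid
#' area and equals the Mann-Whitney U statistic normalised by
#' `n_pos * n_neg`.
#'
#' @param scores Named numeric vector: per-gene score from the platform under
#'   test (higher = more confidently differential).
#' @param reference_lfc Named numeric vector of reference log2 fold changes
#'   on the same gene universe.
#' @param truth_lfc_cutoff Reference cutoff defining positives (default 2).
#' @param direction `"absolute"` (default) or `"signed"`.
#' @return A `roc_result`: list with `points` (data.frame fpr, tpr), `auc`,
#'   `n_pos`, `n_neg`.
#' @export
roc_vs_reference <- function(scores, reference_lfc, truth_lfc_cutoff = 2,
                             direction = c("absolute", "signed")) {
  direction <- match.arg(direction)
  shared <- intersect(names(scores), names(reference_lfc))
  if (!length(shared)) stop("no shared genes between scores and reference")
  s <- scores[shared]
  ref <- reference_lfc[shared]
  pos <- if (direction == "absolute") abs(ref) > truth_lfc_cutoff
         else ref > truth_lfc_cutoff
  if (!any(pos) || all(pos))
    stop("degenerate labels: need at least one positive and one negative")
  o <- order(s, decreasing = TRUE)
  s <- s[o]; pos <- pos[o]
  # group tied scores into single sweep points
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(pos)[last]
  fp <- cumsum(!pos)[last]
  tpr <- c(0, tp / sum(pos))
  fpr <- c(0, fp / sum(!pos))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc,
                 n_pos = sum(pos), n_neg = sum(!pos)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Bin CRISPR indel genotypes into frame categories
#'
#' Tallied genotypes are binned by net indel length: 0 is wild type, a
#' nonzero multiple of 3 is in-frame, anything else is frameshift. Fractions
#' are read-count weighted and sum to 1.
#'
#' @param net_indel_bp Integer vector of net indel lengths (bases; signed).
#' @param read_count Non-negative read counts per genotype.
#' @return An `indel_summary`: named numeric vector
#'   (wild_type, in_frame, frameshift).
#' @examples
#' bin_indels(c(0, -3, -2), c(50, 25, 25))
#' @export
bin_indels <- function(net_indel_bp, read_count) {
  if (length(net_indel_bp) != length(read_count))
    stop("net_indel_bp and read_count must have equal length")
  if (any(read_count < 0)) stop("read counts must be >= 0")
  total <- sum(read_count)
  if (!length(read_count) || total == 0)
    stop("empty input: no reads to bin")
  cat3 <- ifelse(net_indel_bp == 0, "wild_type",
                 ifelse(net_indel_bp %% 3 == 0, "in_frame", "frameshift"))
  out <- c(wild_type = sum(read_count[cat3 == "wild_type"]),
           in_frame = sum(read_count[cat3 == "in_frame"]),
           frameshift = sum(read_count[cat3 == "frameshift"])) / total
  class(out) <- "indel_summary"
  out
}

#' @export
print.indel_summary <- function(x, ...) {
  cat(sprintf("indels: %.1f%% wild type, %.1f%% in-frame, %.1f%% frameshift\n",
              100 * x[["wild_type"]], 100 * x[["in_frame"]],
              100 * x[["frameshift"]]))
  invisible(x)
}

#' Read an indel tally table
#'
#' Tab-separated columns `net_indel_bp`, `read_count` (with header).
#' @param path File path.
#' @return data.frame with those two columns.
#' @export
read_indel_table <- function(path) {
  df <- read.delim(path)
  if (!all(c("net_indel_bp", "read_count") %in% names(df)))
    stop("indel table needs columns net_indel_bp, read_count")
  df
}
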