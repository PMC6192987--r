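# Compound profiling: a light internal differential-expression routine (real
# DESeq2 tables can be imported instead), potent-compound selection,
# candidate-gene ranking, quantile-normalised log2FC feature matrices, and
# hierarchical / tSNE clustering of compound signatures.

#' Internal differential expression between well groups
#'
#' A deliberately simple stand-in for a full count-model fit, sufficient for
#' truth-controlled simulations: size factors by median-of-ratios over genes
#' with a positive geometric mean; log2FC of pseudocounted group means of
#' normalised counts; two-sided Welch t-test on log(1 + normalised) values;
#' Benjamini-Hochberg adjustment over tested genes. Genes with zero counts
#' everywhere are excluded from testing (padj NA). For published-figure
#' fidelity, import DESeq2 result tables via [read_de_table()] instead.
#'
#' @param cm A `count_matrix` (or plain wells x genes matrix).
#' @param treatment_wells,control_wells Well names, >= 2 each.
#' @param pseudocount Added to group means before the log ratio (default 1).
#' @param treatment,dose_um Optional labels stored on the result.
#' @return A `de_table` data.frame: gene, log2fc, pvalue, padj, base_mean.
#' @export
internal_de <- function(cm, treatment_wells, control_wells, pseudocount = 1,
                        treatment = NA_character_, dose_um = NA_real_) {
  m <- if (inherits(cm, "count_matrix")) cm$counts else cm
  if (length(treatment_wells) < 2L || length(control_wells) < 2L)
    stop("each group needs at least 2 wells")
  wells <- c(treatment_wells, control_wells)
  miss <- setdiff(wells, rownames(m))
  if (length(miss)) stop("wells not in matrix: ", paste(miss, collapse = ", "))
  x <- t(as.matrix(m[wells, , drop = FALSE]))   # genes x wells
  grp <- rep(c("T", "C"), c(length(treatment_wells), length(control_wells)))
  # median-of-ratios size factors (genes observed in every well)
  pos <- rowSums(x == 0) == 0L
  if (any(pos)) {
    logg <- rowMeans(log(x[pos, , drop = FALSE]))
    sf <- apply(x[pos, , drop = FALSE], 2L,
                function(col) median(exp(log(col) - logg)))
  } else {
    ls <- colSums(x)
    sf <- ls / exp(mean(log(ls)))
  }
  norm <- sweep(x, 2L, sf, "/")
  tested <- rowSums(x) > 0L
  mt <- rowMeans(norm[, grp == "T", drop = FALSE])
  mc <- rowMeans(norm[, grp == "C", drop = FALSE])
  log2fc <- log2((mt + pseudocount) / (mc + pseudocount))
  lt <- log1p(norm[, grp == "T", drop = FALSE])
  lc <- log1p(norm[, grp == "C", drop = FALSE])
  n1 <- ncol(lt); n2 <- ncol(lc)
  m1 <- rowMeans(lt); m2 <- rowMeans(lc)
  v1 <- apply(lt, 1L, var); v2 <- apply(lc, 1L, var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  pval <- 2 * pt(-abs(tstat), df)
  pval[se2 == 0 & m1 == m2] <- 1
  pval[!tested] <- NA_real_
  padj <- rep(NA_real_, length(pval))
  padj[tested] <- p.adjust(pval[tested], method = "BH")
  out <- data.frame(gene = rownames(x), log2fc = log2fc, pvalue = pval,
                    padj = padj, base_mean = rowMeans(norm),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "treatment") <- treatment
  attr(out, "dose_um") <- dose_um
  class(out) <- c("de_table", "data.frame")
  out
}

#' @importFrom stats var
NULL

#' Read and write differential-expression tables
#'
#' Tab-separated with header columns `gene`, `log2fc`, `padj` (required;
#' `base_mean` and any extra columns are preserved).
#'
#' @param path File path.
#' @return `read_de_table` returns a `de_table`.
#' @export
read_de_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "log2fc", "padj")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("DE table missing columns: ", paste(miss, collapse = ", "))
  if (!is.numeric(df$log2fc) || !is.numeric(df$padj))
    stop("DE table columns log2fc and padj must be numeric")
  if (anyDuplicated(df$gene)) stop("DE table has duplicate gene ids")
  if (any(df$padj < 0 | df$padj > 1, na.rm = TRUE))
    stop("padj values outside [0, 1]")
  class(df) <- c("de_table", "data.frame")
  df
}

#' @rdname read_de_table
#' @param de A `de_table` to write.
#' @export
write_de_table <- function(de, path) {
  write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Significantly changed genes of a DE table
#'
#' Strict cutoffs on both criteria: `padj < padj_cutoff` and
#' `|log2FC| > lfc_cutoff`. Genes with missing padj never qualify.
#'
#' @param de A `de_table`.
#' @param padj_cutoff,lfc_cutoff Cutoffs (defaults 0.05 and 1).
#' @return Character vector of gene ids.
#' @export
significant_genes <- function(de, padj_cutoff = 0.05, lfc_cutoff = 1) {
  sel <- !is.na(de$padj) & de$padj < padj_cutoff & abs(de$log2fc) > lfc_cutoff
  de$gene[sel]
}

#' Select potent compounds
#'
#' A compound is potent when strictly more than `min_genes` genes pass the
#' significance cutoffs in its top-dose DE table.
#'
#' @param tables Named list of `de_table`s, one per compound at a common
#'   dose.
#' @param min_genes Strict threshold (default 50).
#' @param padj_cutoff,lfc_cutoff Passed to [significant_genes()].
#' @return Character vector of potent compound names.
#' @export
select_potent <- function(tables, min_genes = 50, padj_cutoff = 0.05,
                          lfc_cutoff = 1) {
  n_sig <- vapply(tables, function(t)
    length(significant_genes(t, padj_cutoff, lfc_cutoff)), 0L)
  names(tables)[n_sig > min_genes]
}

#' Quantile normalisation across columns
#'
#' Classic quantile normalisation: within each column values are ranked and
#' replaced by the across-column mean of the sorted values at that rank;
#' ties receive the mean over their rank range. Afterwards all column
#' empirical distributions are identical.
#'
#' @param values Numeric matrix (e.g. genes x compounds of log2FC), >= 2
#'   columns.
#' @return Matrix of the same shape and dimnames.
#' @examples
#' quantile_normalize(cbind(a = c(5, 1), b = c(2, 4)))
#' @export
quantile_normalize <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) < 2L) stop("quantile normalisation needs >= 2 columns")
  all_na <- colSums(!is.na(values)) == 0L
  if (any(all_na))
    stop("column(s) with all-missing values: ",
         paste(colnames(values)[all_na], collapse = ", "))
  if (nrow(values) == 1L) {
    # rank-1 case: every entry is the across-column mean
    out <- values
    out[] <- mean(values, na.rm = TRUE)
    return(out)
  }
  out <- limma::normalizeQuantiles(values, ties = TRUE)
  dimnames(out) <- dimnames(values)
  out
}

#' Rank and truncate candidate genes for one compound
#'
#' Significant genes ranked by ascending padj, ties broken by descending
#' |log2FC|, then lexicographic gene id, truncated at `max_genes`. The cap
#' (200 by default; 1000 for focused pairwise comparisons) prevents potent
#' compounds from dominating the combined feature space.
#'
#' @param de A `de_table`.
#' @param max_genes Cap on the list length (default 200).
#' @param padj_cutoff,lfc_cutoff Significance cutoffs.
#' @return Ordered character vector of gene ids (possibly shorter than the
#'   cap).
#' @export
select_candidates <- function(de, max_genes = 200, padj_cutoff = 0.05,
                              lfc_cutoff = 1) {
  sig <- significant_genes(de, padj_cutoff, lfc_cutoff)
  sub <- de[de$gene %in% sig, ]
  sub <- sub[order(sub$padj, -abs(sub$log2fc), sub$gene), ]
  head(sub$gene, max_genes)
}

#' Build the quantile-normalised log2FC feature matrix
#'
#' Rows are the union of per-compound candidate-gene lists; columns are
#' compounds; values are log2 fold changes, quantile-normalised across
#' compounds after assembly. Genes missing from a compound's table (untested
#' there) enter as log2FC 0 before normalisation.
#'
#' @param tables Named list of `de_table`s (>= 2 compounds).
#' @param max_genes,padj_cutoff,lfc_cutoff Passed to [select_candidates()].
#' @return A `feature_matrix`: numeric matrix genes x compounds with
#'   attribute `candidates` (the per-compound selected lists).
#' @export
build_feature_matrix <- function(tables, max_genes = 200, padj_cutoff = 0.05,
                                 lfc_cutoff = 1) {
  if (length(tables) < 2L) stop("need >= 2 compounds")
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop("tables must be a named list (one name per compound)")
  cand <- lapply(tables, select_candidates, max_genes = max_genes,
                 padj_cutoff = padj_cutoff, lfc_cutoff = lfc_cutoff)
  genes <- sort(unique(unlist(cand, use.names = FALSE)))
  if (!length(genes)) stop("empty candidate-gene union: nothing significant")
  lfc <- vapply(tables, function(t) {
    v <- t$log2fc[match(genes, t$gene)]
    v[is.na(v)] <- 0
    v
  }, numeric(length(genes)))
  lfc <- matrix(lfc, nrow = length(genes),
                dimnames = list(genes, names(tables)))
  fm <- quantile_normalize(lfc)
  attr(fm, "candidates") <- cand
  class(fm) <- c("feature_matrix", class(fm))
  fm
}

#' Hierarchical clustering of compound signatures
#'
#' Agglomerates compounds (columns) on the Euclidean distance between their
#' quantile-normalised log2FC profiles.
#'
#' @param features A `feature_matrix` (or plain genes x compounds matrix).
#' @param linkage `"complete"` (default), `"average"` or `"ward"`.
#' @return An `hclust` object over compounds.
#' @export
hierarchical_cluster <- function(features,
                                 linkage = c("complete", "average", "ward")) {
  linkage <- match.arg(linkage)
  m <- unclass(features)
  if (any(!is.finite(m))) stop("non-finite feature values")
  if (ncol(m) < 2L) stop("need >= 2 compounds to cluster")
  method <- c(complete = "complete", average = "average",
              ward = "ward.D2")[[linkage]]
  hclust(dist(t(m)), method = method)
}

#' Export a dendrogram as Newick text
#'
#' @param hc An `hclust` object.
#' @param path Optional file path; when NULL the Newick string is returned.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' 2-D tSNE embedding of compound signatures
#'
#' Thin wrapper around Rtsne over compounds (columns of the feature matrix);
#' the algorithm itself is out of scope here. Deterministic for a fixed seed.
#'
#' @param features A `feature_matrix`.
#' @param perplexity tSNE perplexity; requires > 3 * perplexity compounds.
#' @param max_iterations Gradient-descent iterations (default 3000).
#' @param seed RNG seed.
#' @return Matrix n_compounds x 2 with compound rownames; attribute
#'   `parameters` records the call.
#' @export
embed_tsne <- function(features, perplexity = 5, max_iterations = 3000,
                       seed = 1L) {
  if (!requireNamespace("Rtsne", quietly = TRUE))
    stop("embed_tsne requires the Rtsne package")
  m <- t(unclass(features))
  if (nrow(m) <= 3 * perplexity)
    stop("too few compounds for perplexity ", perplexity,
         ": need > ", 3 * perplexity)
  set.seed(seed)
  fit <- Rtsne::Rtsne(m, dims = 2L, perplexity = perplexity,
                      max_iter = max_iterations, check_duplicates = FALSE,
                      pca = nrow(m) > 30L)
  coords <- fit$Y
  rownames(coords) <- rownames(m)
  colnames(coords) <- c("tsne1", "tsne2")
  attr(coords, "parameters") <- list(perplexity = perplexity,
                                     max_iterations = max_iterations,
                                     seed = seed)
  coords
}

#' Write a feature matrix as TSV
#'
#' @param fm A `feature_matrix`.
#' @param path Output path (genes in the first column `gene`).
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(gene = rownames(fm), unclass(fm), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
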