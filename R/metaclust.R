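# Meta-hierarchical clustering across datasets: Fisher-Z similarity,
# DerSimonian-Laird random-effects combination, similarity-maximising
# average linkage, and dendrogram heights back on the correlation scale.

#' Fisher Z-transformation of a correlation and its inverse
#'
#' `fisher_z(r) = atanh(r)`, the variance-stabilising transform of the
#' Pearson correlation (sampling variance ~ 1/(n - 3)); correlations within
#' `eps` of +-1 are clamped to +-(1 - eps) before transforming so z stays
#' finite. `fisher_z_inverse` is `tanh`.
#'
#' @param r Correlation(s), |r| <= 1.
#' @param z Fisher-Z value(s).
#' @param eps Clamping margin (default 1e-6).
#' @return Transformed numeric vector.
#' @examples
#' fisher_z(0.8)
#' fisher_z_inverse(fisher_z(0.3))
#' @export
fisher_z <- function(r, eps = 1e-6) {
  if (any(abs(r) > 1, na.rm = TRUE)) stop("|r| > 1 is outside the domain")
  atanh(pmin(pmax(r, -1 + eps), 1 - eps))
}

#' @rdname fisher_z
#' @export
fisher_z_inverse <- function(z) tanh(z)

#' Fisher-Z similarity matrix of a dataset's samples
#'
#' Pearson correlations between sample columns, Fisher-Z transformed; the
#' diagonal carries an `Inf` sentinel (self-similarity) that is excluded
#' from all downstream combination and averaging.
#'
#' @param expr Numeric matrix features x samples.
#' @param n Effective sample size for the variance 1/(n - 3); defaults to
#'   the number of features.
#' @return A `similarity_matrix`: list with `z` (symmetric matrix), `n`,
#'   `labels`.
#' @export
similarity_matrix <- function(expr, n = nrow(expr)) {
  if (is.null(colnames(expr)))
    colnames(expr) <- paste0("S", seq_len(ncol(expr)))
  z <- fisher_z(cor(expr))
  diag(z) <- Inf
  structure(list(z = z, n = n, labels = colnames(expr)),
            class = "similarity_matrix")
}

#' Combine per-dataset similarities by random-effects meta-analysis
#'
#' For every sample pair, the per-dataset Fisher-Z values (variances
#' 1/(n - 3)) are combined with the DerSimonian-Laird estimator: the
#' between-dataset variance is
#' `tau2 = max(0, (Q - (k - 1)) / (sum(w) - sum(w^2)/sum(w)))` with fixed
#' weights `w = n - 3` and Q the weighted squared deviation from the
#' fixed-effect mean; the summary is the inverse-variance weighted mean with
#' weights `1 / (1/(n - 3) + tau2)`. A single dataset passes through
#' unchanged; when the per-dataset values agree the result reduces to the
#' fixed-effect mean.
#'
#' @param sims List of `similarity_matrix` objects sharing sample labels;
#'   each must have n >= 4.
#' @return A combined `similarity_matrix` (its `n` is the per-dataset n
#'   vector).
#' @export
combine_similarities <- function(sims) {
  if (inherits(sims, "similarity_matrix")) sims <- list(sims)
  k <- length(sims)
  labels <- sims[[1]]$labels
  for (s in sims) {
    if (!identical(s$labels, labels))
      stop("sample labels differ between datasets")
    if (s$n < 4) stop("each dataset needs n >= 4 features")
  }
  if (k == 1L) return(sims[[1]])
  p <- length(labels)
  zs <- lapply(sims, `[[`, "z")
  w <- vapply(sims, function(s) s$n - 3, 0)
  sw <- sum(w)
  zbar_fe <- Reduce(`+`, Map(`*`, zs, w)) / sw
  Q <- Reduce(`+`, Map(function(z, wi) wi * (z - zbar_fe)^2, zs, w))
  cc <- sw - sum(w^2) / sw
  tau2 <- pmax(0, (Q - (k - 1)) / cc)
  wstar <- lapply(w, function(wi) 1 / (1 / wi + tau2))
  comb <- Reduce(`+`, Map(`*`, zs, wstar)) / Reduce(`+`, wstar)
  diag(comb) <- Inf
  dimnames(comb) <- list(labels, labels)
  structure(list(z = comb, n = vapply(sims, `[[`, 0, "n"), labels = labels),
            class = "similarity_matrix")
}

#' Average-linkage clustering on combined Fisher-Z similarities
#'
#' Agglomerates samples by repeatedly merging the cluster pair with the
#' highest combined z, where cluster-cluster similarity is the unweighted
#' mean of member-pair z values (maintained by the Lance-Williams UPGMA
#' update). The display height of each merge is `tanh` of its linkage score,
#' i.e. a correlation. Ties break deterministically on the lowest index
#' pair.
#'
#' @param sim A combined `similarity_matrix`.
#' @return A `meta_dendrogram`: list with hclust-style `merge`, `linkage_z`,
#'   `height_r = tanh(linkage_z)`, `labels`, `order`.
#' @export
meta_average_linkage <- function(sim) {
  z <- sim$z
  p <- length(sim$labels)
  if (p < 2L) stop("need >= 2 samples")
  off <- z[upper.tri(z)]
  if (any(!is.finite(off))) stop("non-finite off-diagonal similarity")
  S <- z
  diag(S) <- -Inf
  size <- rep(1L, p)
  id <- -(1:p)                      # hclust convention: leaves negative
  active <- rep(TRUE, p)
  merge <- matrix(0L, p - 1L, 2L)
  linkage_z <- numeric(p - 1L)
  for (step in seq_len(p - 1L)) {
    act <- which(active)
    sub <- S[act, act, drop = FALSE]
    best <- which(sub == max(sub), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- act[best[1]]; j <- act[best[2]]
    linkage_z[step] <- S[i, j]
    merge[step, ] <- sort(c(id[i], id[j]))
    # UPGMA update: i absorbs j
    others <- setdiff(act, c(i, j))
    if (length(others)) {
      newv <- (size[i] * S[i, others] + size[j] * S[j, others]) /
        (size[i] + size[j])
      S[i, others] <- newv
      S[others, i] <- newv
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    id[i] <- step
  }
  ord <- dendro_leaf_order(merge)
  structure(list(merge = merge, linkage_z = linkage_z,
                 height_r = tanh(linkage_z), labels = sim$labels,
                 order = ord),
            class = "meta_dendrogram")
}

# leaf order by walking the merge table from the last merge down
dendro_leaf_order <- function(merge) {
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

#' @export
print.meta_dendrogram <- function(x, ...) {
  cat(sprintf("meta_dendrogram: %d samples, top merge r = %.3f\n",
              length(x$labels), x$height_r[length(x$height_r)]))
  invisible(x)
}

#' Convert a meta-dendrogram to hclust
#'
#' Heights are `1 - r` (distance-like, non-decreasing along merges), so the
#' tree can be plotted and cut with standard tools.
#'
#' @param x A `meta_dendrogram`.
#' @param ... Unused.
#' @return An `hclust` object.
#' @export
as.hclust.meta_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = 1 - x$height_r,
                 order = x$order, labels = x$labels,
                 method = "meta_average", call = match.call(),
                 dist.method = "fisher_z"),
            class = "hclust")
}

#' Write a meta-dendrogram merge table / Newick tree
#'
#' The merge table is tab-separated with columns `left,right,linkage_z,
#' height_r` (negative entries are leaves, positive entries earlier merges,
#' as in `hclust`). The Newick tree uses heights `1 - r` for viewer
#' compatibility.
#'
#' @param md A `meta_dendrogram`.
#' @param path Output path.
#' @export
write_merge_table <- function(md, path) {
  df <- data.frame(left = md$merge[, 1], right = md$merge[, 2],
                   linkage_z = md$linkage_z, height_r = md$height_r)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_merge_table
#' @export
metaclust_newick <- function(md, path = NULL) {
  dendrogram_newick(as.hclust(md), path)
}

#' Row ordering from clustering the pooled data matrix
#'
#' Rows (shared across datasets) are clustered once on the column-wise
#' concatenation of all datasets with average-linkage Euclidean clustering;
#' the resulting leaf order is what each per-dataset display matrix should
#' use, so stratified heatmaps stay comparable. Rows are sorted
#' lexicographically before clustering so the result does not depend on
#' input row order (ties break deterministically).
#'
#' @param mats List of numeric matrices with identical row-name sets.
#' @return Character vector: row names in pooled leaf order.
#' @export
pooled_row_order <- function(mats) {
  if (is.matrix(mats)) mats <- list(mats)
  rows <- sort(rownames(mats[[1]]))
  for (m in mats) {
    if (!identical(sort(rownames(m)), rows))
      stop("datasets do not share the same row universe")
  }
  pooled <- do.call(cbind, lapply(mats, function(m) m[rows, , drop = FALSE]))
  if (length(rows) < 2L) return(rows)
  hc <- hclust(dist(pooled), method = "average")
  rows[hc$order]
}
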