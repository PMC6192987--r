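# simulate a treated plate and run the internal DE routine
de_sim <- function(n_genes = 500, n_targets = 50, lfc = 2, mu = 200,
                   size = 100, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  mu_g <- rep(mu, n_genes)
  fold <- rep(1, n_genes)
  targets <- genes[seq_len(n_targets)]
  fold[seq_len(n_targets)] <- 2^lfc
  wells <- c("A01", "A02", "A03", "B01", "B02", "B03")
  counts <- rbind(
    t(replicate(3, rnbinom(n_genes, mu = mu_g * fold, size = size))),
    t(replicate(3, rnbinom(n_genes, mu = mu_g, size = size))))
  dimnames(counts) <- list(wells, genes)
  list(counts = counts, targets = targets,
       trt = wells[1:3], ctl = wells[4:6])
}

test_that("internal DE recovers planted fold changes", {
  sim <- de_sim(seed = 101)
  de <- internal_de(sim$counts, sim$trt, sim$ctl)
  est <- de$log2fc[match(sim$targets, de$gene)]
  expect_true(all(abs(est - 2) < 0.5))
  sens <- mean(sim$targets %in% significant_genes(de))
  expect_gte(sens, 0.8)
  expect_error(internal_de(sim$counts, sim$trt[1], sim$ctl), "at least 2")
})

test_that("internal DE excludes untestable genes and is null-calibrated", {
  sim <- de_sim(n_targets = 0, seed = 103)
  counts <- sim$counts
  counts[, "g0001"] <- 0L
  de <- internal_de(counts, sim$trt, sim$ctl)
  expect_true(is.na(de$padj[de$gene == "g0001"]))
  # null data: BH keeps the discovery fraction at or below the nominal level
  expect_lte(mean(de$padj < 0.05, na.rm = TRUE), 0.05)
})

test_that("DE tables round-trip and are validated on read", {
  de <- make_de(paste0("g", 1:3), c(1.5, -2, 0.1), c(0.01, 0.2, 0.9))
  f <- tempfile(fileext = ".tsv")
  write_de_table(de, f)
  back <- read_de_table(f)
  expect_equal(back$gene, de$gene)
  expect_equal(back$log2fc, de$log2fc)

  writeLines(c("gene\tlog2fc", "g1\t2"), f)
  expect_error(read_de_table(f), "missing columns")
  writeLines(c("gene\tlog2fc\tpadj", "g1\ttwo\t0.1"), f)
  expect_error(read_de_table(f), "numeric")
})

test_that("significance cutoffs are strict on both criteria", {
  de <- make_de(paste0("g", 1:4),
                log2fc = c(1.01, 3, -1.2, 0.5),
                padj = c(0.049, 0.05, 0.001, 0.001))
  sig <- significant_genes(de)
  expect_true("g1" %in% sig)    # both just inside
  expect_false("g2" %in% sig)   # padj == 0.05 excluded
  expect_true("g3" %in% sig)    # |log2FC| handles down-regulation
  expect_false("g4" %in% sig)   # |lfc| too small
})

test_that("potent compounds need strictly more than the gene threshold", {
  mk <- function(n_sig) make_de(paste0("g", 1:100),
                                log2fc = c(rep(2, n_sig), rep(0, 100 - n_sig)),
                                padj = c(rep(0.001, n_sig), rep(0.9, 100 - n_sig)))
  tables <- list(a = mk(51), b = mk(50), c = mk(80))
  expect_equal(select_potent(tables, min_genes = 50), c("a", "c"))
})

test_that("potency selection recovers exactly the active compounds", {
  set.seed(107)
  tables <- list()
  active <- sprintf("cmp%02d", 1:10)
  for (i in 1:40) {
    nm <- sprintf("cmp%02d", i)
    sim <- de_sim(n_genes = 300, n_targets = if (i <= 10) 80 else 0,
                  lfc = 2, seed = 200 + i)
    tables[[nm]] <- internal_de(sim$counts, sim$trt, sim$ctl)
  }
  expect_equal(sort(select_potent(tables)), sort(active))
})

test_that("quantile normalisation matches the hand example and property", {
  m <- cbind(c1 = c(5, 1), c2 = c(2, 4))
  q <- quantile_normalize(m)
  expect_equal(unname(q), cbind(c(4.5, 1.5), c(1.5, 4.5)))
  # identical columns are a fixed point
  m2 <- cbind(a = c(3, 1, 2), b = c(3, 1, 2))
  expect_equal(unname(quantile_normalize(m2)), unname(m2))
  # single row: every entry becomes the row mean
  expect_equal(as.numeric(quantile_normalize(cbind(a = 1, b = 5))),
               c(3, 3))
  # after normalisation all sorted columns agree
  set.seed(109)
  for (i in 1:10) {
    r <- matrix(rnorm(40 * 5), 40, 5)
    qn <- quantile_normalize(r)
    srt <- apply(qn, 2, sort)
    expect_equal(srt, srt[, c(1, 1:4)], tolerance = 1e-12)
  }
  expect_error(quantile_normalize(matrix(1:4, 4, 1)), ">= 2 columns")
})

test_that("candidate selection ranks by padj, then |lfc|, then id", {
  de <- make_de(paste0("g", 1:10),
                log2fc = c(2, -3, 2, 2, 2, 2, 2, 2, 2, 0.1),
                padj = c(0.01, 0.01, 0.02, rep(0.03, 6), 0.001))
  out <- select_candidates(de, max_genes = 200)
  expect_equal(length(out), 9)          # g10 fails |lfc|
  expect_equal(out[1:2], c("g2", "g1")) # padj tie: larger |lfc| first
  expect_equal(out[3], "g3")
  expect_true(all(out %in% significant_genes(de)))

  # cap at max_genes keeps the smallest padj values (brute-force check)
  set.seed(111)
  n <- 300
  de2 <- make_de(sprintf("g%03d", 1:n), log2fc = rep(2, n),
                 padj = runif(n, 0, 0.049))
  out2 <- select_candidates(de2, max_genes = 200)
  expect_equal(length(out2), 200)
  brute <- de2$gene[order(de2$padj)][1:200]
  expect_setequal(out2, brute)
})

test_that("feature matrices union candidates and impute missing as 0", {
  deA <- make_de(paste0("a", 1:5), rep(2, 5), rep(0.01, 5))
  deB <- make_de(paste0("b", 1:5), rep(-2, 5), rep(0.01, 5))
  fm <- build_feature_matrix(list(A = deA, B = deB))
  expect_equal(nrow(fm), 10)
  expect_equal(colnames(fm), c("A", "B"))
  expect_equal(sort(names(attr(fm, "candidates"))), c("A", "B"))

  fm2 <- build_feature_matrix(list(A = deA, B = deA))
  expect_equal(nrow(fm2), 5)
})

test_that("within-MoA-group signatures correlate more than between", {
  set.seed(113)
  genes <- sprintf("g%03d", 1:150)
  group_targets <- split(genes[1:90], rep(1:3, each = 30))
  tables <- list()
  for (g in 1:3) for (r in 1:3) {
    base_lfc <- rnorm(30, mean = c(2.5, -2.5, 2.5)[g], sd = 0.2)
    lfc <- rep(0, 150)
    lfc[match(group_targets[[g]], genes)] <- base_lfc + rnorm(30, 0, 0.3)
    padj <- rep(0.9, 150)
    padj[match(group_targets[[g]], genes)] <- 1e-4
    tables[[sprintf("grp%d_c%d", g, r)]] <- make_de(genes, lfc, padj)
  }
  fm <- build_feature_matrix(tables)
  rc <- cor(unclass(fm))
  grp <- rep(1:3, each = 3)
  same <- rc[outer(grp, grp, "==") & upper.tri(rc)]
  diff <- rc[outer(grp, grp, "!=") & upper.tri(rc)]
  expect_gt(mean(same), mean(diff))

  # and the dendrogram merges same-group compounds first
  hc <- hierarchical_cluster(fm, linkage = "average")
  k3 <- cutree(hc, 3)
  expect_equal(length(unique(tapply(grp, k3, function(x)
    paste(sort(unique(x)), collapse = "")))), 3)
})

test_that("hierarchical clustering matches a brute-force agglomeration", {
  m <- cbind(a = c(0, 0), b = c(3, 4), c = c(0, 0.1), d = c(10, 0))
  hc <- hierarchical_cluster(m, linkage = "complete")
  # identical-ish pair (a, c) merges first at their Euclidean distance
  expect_equal(hc$height[1], 0.1)
  expect_equal(sort(hc$merge[1, ]), c(-3, -1))

  # brute-force complete linkage on 4 hand-set points
  pts <- list(a = c(0, 0), b = c(3, 4), c = c(0, 0.1), d = c(10, 0))
  clusters <- as.list(1:4)
  heights <- c()
  dmat <- as.matrix(dist(t(m)))
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestv <- Inf
    for (i in 1:(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      v <- max(dmat[clusters[[i]], clusters[[j]]])
      if (v < bestv) { bestv <- v; best <- c(i, j) }
    }
    heights <- c(heights, bestv)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best[2]]
  }
  expect_equal(hc$height, heights)

  # two columns: a single merge at their Euclidean distance
  m2 <- cbind(x = c(0, 0), y = c(3, 4))
  expect_equal(hierarchical_cluster(m2)$height, 5)
  expect_error(hierarchical_cluster(cbind(a = c(1, NA), b = c(1, 2))),
               "non-finite")

  nw <- dendrogram_newick(hc)
  expect_match(nw, "^\\(.*\\);$")
})

test_that("tSNE embedding is seeded, shaped, and groups planted structure", {
  skip_if_not_installed("Rtsne")
  set.seed(115)
  fm <- matrix(rnorm(50 * 9), 50, 9,
               dimnames = list(NULL, paste0("c", 1:9)))
  fm[1:20, 1:3] <- fm[1:20, 1:3] + 6
  fm[21:40, 4:6] <- fm[21:40, 4:6] - 6
  e1 <- embed_tsne(fm, perplexity = 2, max_iterations = 300, seed = 7)
  e2 <- embed_tsne(fm, perplexity = 2, max_iterations = 300, seed = 7)
  expect_identical(e1[, 1:2], e2[, 1:2])
  expect_equal(dim(e1), c(9L, 2L))
  grp <- rep(1:3, each = 3)
  d <- as.matrix(dist(e1))
  within <- mean(d[outer(grp, grp, "==") & upper.tri(d)])
  between <- mean(d[outer(grp, grp, "!=") & upper.tri(d)])
  expect_lt(within, between)
  expect_error(embed_tsne(fm[, 1:4], perplexity = 2), "too few")
})
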