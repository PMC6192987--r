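# Independent from-scratch oracles used by the clustering tests.

# average linkage on similarities, recomputing cluster-cluster similarity as
# the raw mean over member pairs at every step (no Lance-Williams update);
# first (lowest-index) pair wins ties
brute_similarity_linkage <- function(z) {
  p <- nrow(z)
  clusters <- as.list(seq_len(p))
  sets <- list(); scores <- numeric(0)
  while (length(clusters) > 1) {
    best <- NULL; bestv <- -Inf
    for (a in seq_len(length(clusters) - 1)) {
      for (b in (a + 1):length(clusters)) {
        v <- mean(z[clusters[[a]], clusters[[b]]])
        if (v > bestv) { bestv <- v; best <- c(a, b) }
      }
    }
    sets[[length(sets) + 1L]] <- sort(c(clusters[[best[1]]],
                                        clusters[[best[2]]]))
    scores <- c(scores, bestv)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best[2]]
  }
  list(sets = sets, scores = scores)
}

# member sets per merge from an hclust-style merge table
merge_sets <- function(merge) {
  out <- vector("list", nrow(merge))
  members <- function(node) {
    if (node < 0) return(-node)
    out[[node]]
  }
  for (s in seq_len(nrow(merge)))
    out[[s]] <- sort(c(members(merge[s, 1]), members(merge[s, 2])))
  out
}

# random symmetric Fisher-Z similarity with the Inf diagonal sentinel
rand_simmat <- function(p, seed) {
  set.seed(seed)
  z <- matrix(0, p, p)
  z[upper.tri(z)] <- rnorm(p * (p - 1) / 2, 0.3, 0.5)
  z <- z + t(z)
  diag(z) <- Inf
  dimnames(z) <- list(paste0("s", 1:p), paste0("s", 1:p))
  structure(list(z = z, n = 50, labels = rownames(z)),
            class = "similarity_matrix")
}
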