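# Independent oracles and fixture builders shared across test files.

# Random band matrix with optional missing cells.
random_band_matrix <- function(n_iso = 10, n_loci = 8, n_pop = 3,
                               p_missing = 0) {
  vals <- matrix(rbinom(n_iso * n_loci, 1, runif(n_loci, 0.2, 0.8)),
                 n_iso, n_loci, byrow = TRUE)
  if (p_missing > 0)
    vals[runif(length(vals)) < p_missing] <- NA
  pops <- sort(rep_len(paste0("P", seq_len(n_pop)), n_iso))
  band_matrix(vals, populations = pops,
              isolate_ids = sprintf("iso%02d", seq_len(n_iso)),
              locus_ids = paste0("L", seq_len(n_loci)))
}

# Brute-force average linkage: at every step recompute each between-cluster
# distance as the plain mean over all leaf pairs from the ORIGINAL matrix
# (no Lance-Williams update), with the same lexicographic tie-break.
# Returns merge heights and the leaf sets merged at each step.
average_linkage_oracle <- function(d) {
  labels <- rownames(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1L) {
    k <- length(clusters)
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      dij <- mean(d[clusters[[i]], clusters[[j]]])
      lab <- sort(c(min(labels[clusters[[i]]]), min(labels[clusters[[j]]])))
      better <- dij < best_d - 1e-15 ||
        (abs(dij - best_d) <= 1e-15 && (is.null(best_key) ||
          lab[1] < best_key[1] ||
          (lab[1] == best_key[1] && lab[2] < best_key[2])))
      if (better) { best <- c(i, j); best_d <- dij; best_key <- lab }
    }
    heights <- c(heights, best_d / 2)
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges <- c(merges, list(merged))
    clusters <- c(clusters[-best], list(merged))
  }
  list(heights = heights, merges = merges)
}

# Leaf sets merged at each step of an upgma_tree, for comparison with the
# oracle above.
tree_merges <- function(tr) {
  n <- length(tr$labels)
  sets <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    grab <- function(i) if (i < 0) -i else sets[[i]]
    sets[[s]] <- sort(c(grab(tr$merge[s, 1]), grab(tr$merge[s, 2])))
  }
  sets
}

# Leaf depths (root to tip path lengths) of an ultrametric tree via ape.
leaf_depths <- function(tr) {
  ph <- ape::as.phylo(as.hclust(tr))
  dd <- ape::dist.nodes(ph)
  root <- ape::Ntip(ph) + 1L
  dd[root, seq_len(ape::Ntip(ph))]
}

# Empirical survival function: proportion of the cohort still alive after
# day t, from raw death days (no censoring).
empirical_survival <- function(death_days, t) {
  vapply(t, function(x) mean(death_days > x), numeric(1))
}

# Build a 2-isolate band matrix whose per-primer polymorphic band counts are
# exactly the given table (a polymorphic band differs between the isolates).
matrix_from_primer_counts <- function(counts) {
  cols <- list(); ids <- character(0)
  for (r in seq_len(nrow(counts))) {
    nb <- counts$bands[r]; np <- counts$polymorphic[r]
    poly <- c(rep(TRUE, np), rep(FALSE, nb - np))
    for (k in seq_len(nb)) {
      cols[[length(cols) + 1L]] <- if (poly[k]) c(1, 0) else c(1, 1)
      ids <- c(ids, paste0(counts$primer[r], "_", k))
    }
  }
  band_matrix(do.call(cbind, cols), populations = c("A", "A"),
              isolate_ids = c("i1", "i2"), locus_ids = ids)
}
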