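#' Nei's genetic identity between two populations
#'
#' I = Jxy / sqrt(Jx Jy), where for biallelic dominant loci
#' Jxy = mean over loci of (p_x p_y + q_x q_y), Jx = mean of (p_x^2 + q_x^2)
#' and Jy likewise. Identity is 1 for identical frequency vectors and 0 when
#' the populations share no alleles at any locus.
#'
#' @param fx,fy numeric vectors of band-allele frequencies over the same loci.
#' @return identity in `[0, 1]`.
#' @export
nei_identity <- function(fx, fy) {
  stopifnot(length(fx) == length(fy), all(fx >= 0 & fx <= 1),
            all(fy >= 0 & fy <= 1))
  jxy <- mean(fx * fy + (1 - fx) * (1 - fy))
  jx <- mean(fx^2 + (1 - fx)^2)
  jy <- mean(fy^2 + (1 - fy)^2)
  if (jx == 0 || jy == 0)
    stop("Nei identity undefined: zero within-population homozygosity",
         call. = FALSE)
  min(jxy / sqrt(jx * jy), 1)
}

#' Nei's genetic distance from identity
#'
#' D = -ln I; zero identity gives infinite distance (flagged as `Inf`).
#'
#' @param I genetic identity in `[0, 1]`.
#' @return distance D >= 0 (possibly `Inf`).
#' @export
nei_distance <- function(I) {
  if (any(I < 0 | I > 1)) stop("identity must lie in [0, 1]", call. = FALSE)
  ifelse(I == 0, Inf, -log(I))
}

#' Pairwise Nei identity and distance between populations
#'
#' Estimates per-population band-allele frequencies and returns the full
#' pairwise identity and distance matrices over analyzable populations.
#'
#' @param m a [band_matrix].
#' @param mode allele-frequency mode.
#' @param min_n minimum isolates per population.
#' @return list of class `identity_distance`: `identity` and `distance`
#'   (symmetric matrices with population dimnames), `populations`.
#' @export
identity_distance_matrix <- function(m, mode = c("haploid", "dominant-diploid"),
                                     min_n = 2L) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "band_matrix"))
  part <- partition_populations(m, min_n)
  keep <- part$population[part$analyzable]
  if (length(keep) < 2L)
    stop("need at least 2 analyzable populations", call. = FALSE)
  idx <- attr(part, "indices")
  freqs <- lapply(keep, function(g)
    locus_frequencies(m$values[idx[[g]], , drop = FALSE], mode))
  names(freqs) <- keep
  K <- length(keep)
  I <- diag(1, K)
  dimnames(I) <- list(keep, keep)
  for (i in seq_len(K - 1L)) for (j in (i + 1L):K)
    I[i, j] <- I[j, i] <- nei_identity(freqs[[i]], freqs[[j]])
  D <- nei_distance(I)
  diag(D) <- 0
  structure(list(identity = I, distance = D, populations = keep),
            class = "identity_distance")
}

#' Pairwise similarity between individual banding profiles
#'
#' Counts, per isolate pair over co-scored loci, a = shared band presences,
#' b + c = mismatches, d = shared absences, and returns the chosen
#' coefficient: Dice (Nei-Li) 2a/(2a+b+c), Jaccard a/(a+b+c), or simple
#' matching (a+d)/(a+b+c+d). Dice is the default, the usual choice for
#' dominant-marker fingerprints.
#'
#' @param m a [band_matrix].
#' @param coefficient `"dice"`, `"jaccard"` or `"simple-matching"`.
#' @return symmetric isolate x isolate similarity matrix with unit diagonal;
#'   `NA` where a pair shares no co-scored loci.
#' @export
individual_similarity <- function(m, coefficient = c("dice", "jaccard",
                                                     "simple-matching")) {
  coefficient <- match.arg(coefficient)
  stopifnot(inherits(m, "band_matrix"))
  X <- m$values
  n <- nrow(X)
  S <- diag(1, n)
  dimnames(S) <- list(rownames(X), rownames(X))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !is.na(X[i, ]) & !is.na(X[j, ])
    if (!any(ok)) { S[i, j] <- S[j, i] <- NA_real_; next }
    a <- sum(X[i, ok] == 1 & X[j, ok] == 1)
    d <- sum(X[i, ok] == 0 & X[j, ok] == 0)
    mis <- sum(ok) - a - d
    s <- switch(coefficient,
      "dice" = if (2 * a + mis == 0) 1 else 2 * a / (2 * a + mis),
      "jaccard" = if (a + mis == 0) 1 else a / (a + mis),
      "simple-matching" = (a + d) / sum(ok))
    S[i, j] <- S[j, i] <- s
  }
  S
}

cluster_label <- function(members, labels) min(labels[members])

#' UPGMA clustering of a distance matrix
#'
#' Unweighted pair-group method with arithmetic means: repeatedly merges the
#' closest pair of clusters; the distance from a merged cluster to any other
#' is the size-weighted mean of its parts' distances, i.e. the average of all
#' between-cluster leaf pair distances. Node height is half the merge
#' distance, so the tree is ultrametric. Ties are broken by the
#' lexicographically smallest pair of cluster labels (a cluster is labelled
#' by its smallest member leaf), making the tree deterministic.
#'
#' @param d symmetric numeric matrix with zero diagonal and finite
#'   non-negative entries, or a [stats::dist] object.
#' @return object of class `upgma_tree` with hclust-compatible components
#'   `merge`, `height`, `order`, `labels` (heights are merge distance / 2).
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 2L)
  if (any(!is.finite(d))) stop("distances must be finite", call. = FALSE)
  if (any(d < 0)) stop("distances must be non-negative", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-12 || any(abs(diag(d)) > 1e-12))
    stop("distance matrix must be symmetric with zero diagonal", call. = FALSE)
  n <- nrow(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # active clusters: list of member leaf indices; id: row in merge (>0) or -leaf
  members <- as.list(seq_len(n))
  ids <- -seq_len(n)
  D <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(members)
    # find min off-diagonal; tie-break by lexicographic (label_i, label_j)
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      lab <- sort(c(cluster_label(members[[i]], labels),
                    cluster_label(members[[j]], labels)))
      if (D[i, j] < best_d - 1e-15 ||
          (abs(D[i, j] - best_d) <= 1e-15 &&
           (is.null(best_key) ||
            lab[1L] < best_key[1L] ||
            (lab[1L] == best_key[1L] && lab[2L] < best_key[2L])))) {
        best <- c(i, j); best_d <- D[i, j]; best_key <- lab
      }
    }
    i <- best[1L]; j <- best[2L]
    # hclust row convention: leaves (by index) before clusters (by step)
    pair <- c(ids[[i]], ids[[j]])
    merge[step, ] <- pair[order(pair >= 0, abs(pair))]
    height[step] <- best_d / 2
    ni <- length(members[[i]]); nj <- length(members[[j]])
    newrow <- (ni * D[i, ] + nj * D[j, ]) / (ni + nj)
    keep <- setdiff(seq_len(k), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newrow[keep]),
               c(newrow[keep], 0))
    members <- c(members[keep], list(c(members[[i]], members[[j]])))
    ids <- c(ids[keep], step)
  }
  tr <- list(merge = merge, height = height, labels = labels,
             method = "average", dist.method = "user")
  tr$order <- order_from_merge(merge, n)
  class(tr) <- c("upgma_tree", "hclust")
  tr
}

order_from_merge <- function(merge, n) {
  leaves <- function(i) {
    if (i < 0) return(-i)
    c(leaves(merge[i, 1L]), leaves(merge[i, 2L]))
  }
  leaves(n - 1L)
}

#' Serialize an ultrametric tree to Newick text
#'
#' Converts the clustering to a rooted phylogram (branch lengths are height
#' differences) and writes standard Newick, parseable by any phylogenetics
#' reader.
#'
#' @param t an `upgma_tree` (or any hclust-like object).
#' @param digits significant digits for branch lengths.
#' @return Newick string ending in `;`.
#' @export
to_newick <- function(t, digits = 6L) {
  hc <- stats::as.hclust(t)
  # tree heights are already ultrametric node heights (merge distance / 2);
  # ape::as.phylo.hclust halves hclust heights, so compensate
  hc$height <- 2 * hc$height
  ph <- ape::as.phylo(hc)
  ape::write.tree(ph, digits = digits)
}

#' @export
as.hclust.upgma_tree <- function(x, ...) {
  x$call <- match.call()
  class(x) <- "hclust"
  x
}
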