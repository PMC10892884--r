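test_that("Nei identity behaves at its anchor points", {
  f <- runif(10)
  expect_equal(nei_identity(f, f), 1)
  # populations fixed for opposite states at every locus share no alleles
  expect_equal(nei_identity(c(1, 0), c(0, 1)), 0)
  # invariant to locus order
  set.seed(71)
  fx <- runif(20); fy <- runif(20)
  perm <- sample(20)
  expect_equal(nei_identity(fx, fy), nei_identity(fx[perm], fy[perm]),
               tolerance = 1e-14)
})

test_that("distance is the negative log of identity", {
  expect_equal(nei_distance(1), 0)
  expect_lt(abs(nei_distance(0.7821) - 0.2458), 5e-4)
  expect_lt(abs(nei_distance(0.9245) - 0.0785), 5e-4)
  expect_lt(abs(nei_distance(0.9242) - 0.0788), 5e-4)
  expect_lt(abs(nei_distance(0.8023) - 0.2203), 5e-4)
  expect_identical(nei_distance(0), Inf)
  expect_error(nei_distance(1.2), "\\[0, 1\\]")
  expect_error(nei_distance(-0.1), "\\[0, 1\\]")
})

test_that("published identity and distance tables are mutually consistent", {
  ref <- reference_table("population_identity_distance")
  expect_equal(nrow(ref), 28L)  # all pairs of the 8 analyzable groups
  expect_true(all(abs(nei_distance(ref$identity) - ref$distance) <= 5e-4))
})

test_that("population identity/distance matrices are symmetric and log-linked", {
  m <- simulate_marker_matrix(study_marker_config(seed = 13))
  idm <- identity_distance_matrix(m)
  part <- partition_populations(m)
  expect_setequal(idm$populations, part$population[part$analyzable])
  expect_equal(length(idm$populations), 8L)
  expect_equal(idm$identity, t(idm$identity))
  expect_equal(unname(diag(idm$identity)), rep(1, 8))
  expect_equal(unname(diag(idm$distance)), rep(0, 8))
  off <- upper.tri(idm$identity)
  expect_equal(idm$distance[off], -log(idm$identity[off]), tolerance = 1e-10)
})

test_that("individual similarity coefficients match hand counts", {
  m <- band_matrix(rbind(c(1, 0, 1), c(1, 0, 0)), populations = c("A", "A"),
                   isolate_ids = c("x", "y"))
  expect_equal(individual_similarity(m, "dice")["x", "y"], 2 / 3)
  expect_equal(individual_similarity(m, "jaccard")["x", "y"], 1 / 2)
  expect_equal(individual_similarity(m, "simple-matching")["x", "y"], 2 / 3)
  # identical profiles
  m_id <- band_matrix(rbind(c(1, 0, 1), c(1, 0, 1)), populations = c("A", "A"))
  for (coef in c("dice", "jaccard", "simple-matching"))
    expect_equal(individual_similarity(m_id, coef)[1, 2], 1)
  # disjoint presence profiles
  m_dis <- band_matrix(rbind(c(1, 1, 0, 0), c(0, 0, 1, 1)),
                       populations = c("A", "A"))
  expect_equal(individual_similarity(m_dis, "dice")[1, 2], 0)
  expect_equal(individual_similarity(m_dis, "jaccard")[1, 2], 0)
  # no co-scored loci -> NA
  m_na <- band_matrix(rbind(c(1, NA), c(NA, 0)), populations = c("A", "A"))
  expect_true(is.na(individual_similarity(m_na)[1, 2]))
})

test_that("similarity matrices are symmetric with unit diagonal", {
  set.seed(81)
  m <- random_band_matrix(n_iso = 8, n_loci = 12, p_missing = 0.1)
  for (coef in c("dice", "jaccard", "simple-matching")) {
    S <- individual_similarity(m, coef)
    expect_equal(S, t(S))
    expect_equal(unname(diag(S)), rep(1, 8))
    expect_true(all(S[!is.na(S)] >= 0 & S[!is.na(S)] <= 1))
  }
})

test_that("UPGMA reproduces hand-executed merges and Newick output", {
  d2 <- matrix(c(0, 0.2, 0.2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- upgma(d2)
  expect_equal(t2$height, 0.1)
  expect_equal(to_newick(t2), "(A:0.1,B:0.1);")
  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgma(d3)
  expect_equal(t3$height, c(1, 2))
  got <- ape::read.tree(text = to_newick(t3))
  want <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_true(ape::all.equal.phylo(got, want, use.edge.length = TRUE))
})

test_that("UPGMA agrees with a brute-force average-linkage oracle", {
  set.seed(91)
  for (rep in 1:30) {
    x <- matrix(rnorm(6 * 4), 6)
    rownames(x) <- paste0("s", 1:6)
    d <- as.matrix(dist(x))
    tr <- upgma(d)
    oracle <- average_linkage_oracle(d)
    expect_equal(tr$height, oracle$heights, tolerance = 1e-10)
    expect_identical(tree_merges(tr), oracle$merges)
    # ultrametric: all leaves equidistant from the root
    dep <- leaf_depths(tr)
    expect_lt(max(dep) - min(dep), 1e-9)
  }
})

test_that("UPGMA ties break on the lexicographically smallest label pair", {
  # equilateral triangle: every pair distance 1
  d <- matrix(1, 3, 3) - diag(3)
  dimnames(d) <- list(c("C", "A", "B"), c("C", "A", "B"))
  tr <- upgma(d)
  expect_identical(sort(tr$labels[-tr$merge[1, ]]), c("A", "B"))
})

test_that("UPGMA rejects malformed distance input", {
  d <- matrix(c(0, 1, 2, 0), 2)
  expect_error(upgma(d), "symmetric")
  dn <- matrix(c(0, -1, -1, 0), 2)
  expect_error(upgma(dn), "non-negative")
  di <- matrix(c(0, Inf, Inf, 0), 2)
  expect_error(upgma(di), "finite")
})

test_that("Newick output of a study-sized tree parses back with all leaves", {
  m <- simulate_marker_matrix(study_marker_config(seed = 17))
  S <- individual_similarity(m, "dice")
  tr <- upgma(1 - S)
  nwk <- to_newick(tr)
  ph <- ape::read.tree(text = nwk)
  expect_equal(ape::Ntip(ph), 31L)
  expect_setequal(ph$tip.label, rownames(m$values))
  # parse-reserialize stability
  expect_equal(ape::write.tree(ph), nwk)
})
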