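# Clustering, scaffolds, splits, property profiling.

test_that("dbscan matches the density-reachability oracle on random instances", {
  set.seed(31)
  for (rep in 1:12) {
    n <- sample(10:50, 1)
    # random distances with planted structure
    pts <- matrix(runif(n * 2), ncol = 2) * sample(1:3, 1)
    D <- as.matrix(dist(pts))
    eps <- runif(1, 0.1, 0.5)
    minc <- sample(2:5, 1)
    labels <- dockbench:::dbscan_from_dist(D, eps, minc)
    oracle <- dbscan_oracle(D, eps, minc)

    core <- oracle$core
    # 1) core points are never noise and share labels iff same component
    expect_true(all(labels[core] >= 0L))
    expect_identical(outer(labels[core], labels[core], "=="),
                     outer(oracle$comp[core], oracle$comp[core], "=="))
    # 2) noise iff not within eps of any core point; border points belong
    #    to an adjacent core's cluster
    border_ok <- vapply(setdiff(seq_len(n), core), function(i) {
      adj_cores <- core[D[i, core] <= eps]
      if (labels[i] == -1L) length(adj_cores) == 0L
      else labels[i] %in% labels[adj_cores]
    }, logical(1))
    expect_true(all(border_ok))
    # 3) cluster ids contiguous from 0
    ids <- sort(unique(labels[labels >= 0L]))
    if (length(ids)) expect_identical(ids, seq_along(ids) - 1L)
  }
})

test_that("dbscan edge cases: isolation and the everything-neighbor limit", {
  fps <- random_fp_set(8L, density = 0.03, seed = 9L)
  # eps = 1: every pair is a neighbor, one cluster, no noise
  labels <- dbscan_jaccard(fps, eps = 1, min_core_neighbors = 2L)
  expect_true(all(labels == 0L))

  # an isolated point beyond eps from all others is noise
  base <- lapply(1:6, function(i) random_fp(c(1:20 + i), nbits = 1024L))
  lone <- random_fp(900:940, nbits = 1024L)
  labels <- dbscan_jaccard(c(base, list(lone)), eps = 0.6,
                           min_core_neighbors = 2L)
  expect_identical(labels[7], -1L)
  expect_true(all(labels[1:6] == 0L))
})

test_that("generic scaffolds carbonize, prune side chains and unify analogs", {
  # acyclic molecules have the empty scaffold
  expect_identical(generic_murcko_scaffold("CCO")$generic_scaffold, "")
  expect_identical(generic_murcko_scaffold("CC(N)C(=O)O")$generic_scaffold, "")

  # frozen reference values (generic scaffold decomposition oracle)
  key <- function(s) generic_murcko_scaffold(s)$generic_scaffold
  benzene <- key("c1ccccc1")
  expect_identical(key("Cc1ccccc1"), benzene)                     # side chain
  expect_identical(key("CC(C)Cc1ccc(cc1)C(C)C(=O)O"), benzene)    # ibuprofen
  # heteroatom substitution: biphenyl and its pyridyl analog share a key
  expect_identical(key("c1ccc(-c2ccccc2)cc1"), key("c1ccc(-c2ccncc2)cc1"))
  # aromatic and saturated analogs unify (bond orders reduced)
  expect_identical(key("C1CCCCC1"), benzene)
  # fused systems stay fused
  expect_false(key("c1ccc2ccccc2c1") == benzene)
  expect_identical(key("c1ccc2ccccc2c1"), key("C1CCC2CCCCC2C1"))
})

test_that("scaffold keys are invariant under random decoration", {
  set.seed(77)
  scaffolds <- c("c1ccccc1", "c1ccncc1", "C1CCNCC1", "c1ccc2ccccc2c1")
  for (rep in 1:25) {
    base <- sample(scaffolds, 1)
    decorated <- dockbench:::.decorate(
      base, sample(dockbench:::.fixture_substituents, sample(1:3, 1),
                   replace = TRUE))
    if (is.na(decorated)) next
    expect_identical(
      generic_murcko_scaffold(decorated)$generic_scaffold,
      generic_murcko_scaffold(base)$generic_scaffold,
      label = decorated
    )
  }
})

test_that("cluster splits are leak-free partitions, deterministic per seed", {
  # 10 clusters of size 10, fraction 0.3: exactly 3 whole clusters in test
  labels <- rep(0:9, each = 10)
  sp <- cluster_split(labels, 0.3, seed = 4L)
  expect_length(sp$test, 30L)
  expect_identical(sort(c(sp$train, sp$test)), 1:100)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_length(intersect(unique(labels[sp$train]),
                          unique(labels[sp$test])), 0L)

  sp2 <- cluster_split(labels, 0.3, seed = 4L)
  expect_identical(sp, sp2)
  sp3 <- cluster_split(labels, 0.3, seed = 5L)
  expect_false(identical(sp, sp3))

  expect_error(cluster_split(rep(0L, 10), 0.3), "single cluster")
})

test_that("no identical fingerprints leak across a cluster split", {
  lib <- fixture_library(40L)
  fps <- fixture_fps(lib, "PATH6")
  labels <- dbscan_jaccard(fps, eps = 0.25, min_core_neighbors = 2L)
  sp <- cluster_split(labels, 0.3, seed = 1L)
  M <- dockbench:::fp_matrix(fps)
  S <- dockbench:::tanimoto_cross(M[sp$train, , drop = FALSE],
                                  M[sp$test, , drop = FALSE])
  expect_true(all(S < 1))
})

test_that("property profile matches counting definitions on ethanol", {
  p <- property_profile("CCO")
  expect_equal(p$MW, 46.07, tolerance = 0.01)
  expect_identical(as.integer(p$HBD), 1L)
  expect_identical(as.integer(p$HBA), 1L)
  expect_identical(as.integer(p$RB), 0L)
  expect_true(p$lipinski_pass)
})

test_that("QED lies in [0, 1] and ranks druglike above extreme molecules", {
  lib <- fixture_library(30L)
  q <- qed_score(lib)
  expect_true(all(q >= 0 & q <= 1))
  # a gross lipophilic chain scores worse than a balanced drug
  q2 <- qed_score(c("CC(C)Cc1ccc(cc1)C(C)C(=O)O",
                    "CCCCCCCCCCCCCCCCCCCCCCCCCC"))
  expect_gt(q2[[1]], q2[[2]])
  # memoized path returns the same values
  expect_equal(qed_cached(lib[1:5]), q[1:5])
})

test_that("a majority of the synthetic library is Lipinski-compliant", {
  pr <- property_profile(fixture_library(100L, seed = 19L))
  expect_gte(mean(pr$lipinski_pass), 0.7)
})

test_that("graph-based alert matchers agree with the SMARTS patterns", {
  lib <- fixture_library(80L, seed = 57L)
  sdf <- ChemmineR::smiles2sdf(
    stats::setNames(canonical_smiles(lib), paste0("m", seq_along(lib))))
  want <- dockbench:::.alert_counts_smarts(sdf)
  got <- vapply(lib, function(s)
    dockbench:::.alert_count_graph(dockbench:::parse_molgraph(s)), numeric(1))
  expect_equal(unname(got), unname(want))
  # spot checks on canonical alert carriers
  carriers <- c(nitro = "C[N+](=O)[O-]", peroxide = "CCOOC",
                aldehyde = "CCC=O", disulfide = "CSSC",
                michael = "C=CC(=O)C", epoxide = "CC1CO1")
  for (s in carriers) {
    expect_gte(dockbench:::.alert_count_graph(dockbench:::parse_molgraph(s)),
               1, label = s)
  }
  expect_identical(
    dockbench:::.alert_count_graph(dockbench:::parse_molgraph("CCO")), 0L)
})

test_that("aromatic ring counting follows the cycle rank of the aromatic subgraph", {
  expect_identical(aromatic_ring_count("c1ccccc1"), 1L)
  expect_identical(aromatic_ring_count("c1ccc2ccccc2c1"), 2L)    # fused
  expect_identical(aromatic_ring_count("c1ccc(-c2ccccc2)cc1"), 2L)
  expect_identical(aromatic_ring_count("C1CCCCC1"), 0L)
  expect_identical(aromatic_ring_count("CCO"), 0L)
  expect_identical(aromatic_ring_count("c1ccc2[nH]ccc2c1"), 2L)  # indole
})
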