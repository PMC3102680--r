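chain_ontology <- function() {
  # root <- A <- B and a parallel branch root <- C <- D
  ontology_graph(child = c("A", "B", "C", "D"),
                 parent = c("root", "A", "root", "C"))
}

test_that("annotation propagation closes term sets under is_a", {
  og <- chain_ontology()
  ann <- propagate_annotations(list(P1 = "B"), og)
  expect_setequal(ann$P1, c("B", "A"))   # root excluded
  # idempotence
  expect_setequal(propagate_annotations(ann, og)$P1, ann$P1)
  expect_error(propagate_annotations(list(P1 = "Z"), og), "not in ontology")
})

test_that("pathway similarity is the namespace-averaged term Jaccard", {
  # flat single-root ontology so term sets are used as-is
  og <- ontology_graph(child = c("A", "B", "C", "D"),
                       parent = rep("root", 4))
  ann <- list(P1 = "A", P2 = "B", P3 = "C", P4 = "D",
              P5 = c("A", "B", "C"), P6 = c("B", "C", "D"))
  prop <- propagate_annotations(ann, og)
  expect_equal(pathway_similarity("P5", "P6", prop, og), 0.5)  # 2 / 4
  expect_equal(pathway_similarity(c("P1", "P2"), c("P1", "P2"), prop, og), 1)
  expect_equal(pathway_similarity("P1", "P2", prop, og), 0)
  expect_error(pathway_similarity("P1", "ZZ", prop, og), "no annotated")
  # best-match-average variant is also bounded and symmetric
  b1 <- pathway_similarity(c("P1", "P2"), c("P2", "P3"), prop, og, "bma")
  b2 <- pathway_similarity(c("P2", "P3"), c("P1", "P2"), prop, og, "bma")
  expect_equal(b1, b2)
  expect_true(b1 >= 0 && b1 <= 1)
})

test_that("similarity matrices are symmetric with unit diagonal", {
  og <- ontology_graph(child = c("A", "B", "C", "D"),
                       parent = rep("root", 4))
  ann <- list(X = c("A", "B"), Y = c("B", "C"), Z = "D")
  pc <- pathway_collection(list(PW1 = "X", PW2 = "Y", PW3 = "Z",
                                PW4 = "X"))   # PW4 duplicates PW1's member
  m <- similarity_matrix(pc, ann, og)
  expect_equal(dim(m), c(4L, 4L))
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 4))
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(m["PW1", "PW4"], 1)   # identical annotation unions

  # random synthetic instances keep the invariant
  for (seed in 1:5) {
    sim <- simulate_dataset(sim_config(seed = seed, n_proteins = 40,
                                       n_pathways = 6L,
                                       members_per_pathway = 4L))
    ms <- similarity_matrix(sim$pathways, sim$annotations, sim$ontology)
    expect_equal(ms, t(ms))
    expect_equal(unname(diag(ms)), rep(1, 6))
    expect_true(all(ms >= 0 & ms <= 1))
  }
})

test_that("block-structured similarity yields two clusters at 0.5", {
  ids <- paste0("PW", 1:6)
  m <- matrix(0.1, 6, 6, dimnames = list(ids, ids))
  m[1:3, 1:3] <- 0.9; m[4:6, 4:6] <- 0.9
  diag(m) <- 1
  cl <- cluster_pathways(m, threshold = 0.5)
  expect_equal(length(unique(cl$clusters)), 2L)
  expect_equal(unname(cl$clusters[1:3]), rep(cl$clusters[["PW1"]], 3))
  expect_equal(unname(cl$clusters[4:6]), rep(cl$clusters[["PW4"]], 3))
  # direct-distance mode agrees on this matrix
  cld <- cluster_pathways(m, threshold = 0.5, mode = "direct")
  expect_equal(length(unique(cld$clusters)), 2L)

  # two identical rows merge at distance 0
  expect_equal(cl$hclust$height[1], 0, tolerance = 1e-12)

  # a threshold above every pairwise profile correlation -> all singletons
  set.seed(73)
  r <- matrix(runif(36, 0, 0.2), 6, 6, dimnames = list(ids, ids))
  r <- (r + t(r)) / 2; diag(r) <- 1
  clr <- cluster_pathways(r, threshold = 0.999)
  expect_equal(length(unique(clr$clusters)), 6L)
})

test_that("cluster partitions refine monotonically and ignore input order", {
  set.seed(79)
  ids <- paste0("PW", 1:8)
  m <- matrix(runif(64, 0, 1), 8, 8, dimnames = list(ids, ids))
  m <- (m + t(m)) / 2; diag(m) <- 1
  prev <- NULL
  for (thr in seq(0, 1, by = 0.1)) {
    cur <- cluster_pathways(m, threshold = thr)$clusters
    if (!is.null(prev)) {
      # raising the threshold never merges: each new block sits inside one
      # previous block
      for (g in unique(cur))
        expect_length(unique(prev[names(cur)[cur == g]]), 1L)
    }
    prev <- cur
  }
  # permuting the input order leaves the partition unchanged
  perm <- sample(8)
  cl1 <- cluster_pathways(m, 0.5)$clusters
  cl2 <- cluster_pathways(m[perm, perm], 0.5)$clusters
  expect_equal(cl2[names(cl1)], cl1)
})

test_that("associated pathways are thresholded and ranked", {
  ids <- c("Q", "A", "B", "C", "D")
  m <- diag(1, 5); dimnames(m) <- list(ids, ids)
  m["Q", c("A", "B", "C", "D")] <- c(0.548, 0.52, 0.505, 0.49)
  m[, "Q"] <- m["Q", ]
  out <- associated_pathways("Q", m, threshold = 0.5)
  expect_equal(out$pathway_id, c("A", "B", "C"))
  expect_equal(out$similarity, c(0.548, 0.52, 0.505))
  expect_false("Q" %in% out$pathway_id)
  expect_equal(nrow(associated_pathways("Q", m, threshold = 1.1)), 0L)
  expect_error(associated_pathways("ZZ", m), "unknown query")
})

test_that("planted annotation communities are recovered by clustering", {
  skip_if_not_installed("mclust")
  hits <- 0L
  for (seed in 1:20) {
    sim <- simulate_dataset(sim_config(seed = seed, n_proteins = 300,
                                       peptides_per_protein = c(1L, 1L),
                                       n_pathways = 10L,
                                       members_per_pathway = 8L,
                                       n_communities = 2L,
                                       annotation_noise = 0.05))
    m <- similarity_matrix(sim$pathways, sim$annotations, sim$ontology)
    # within-community similarity exceeds between-community similarity
    comm <- sim$truth$pathway_communities[rownames(m)]
    same <- outer(comm, comm, "==") & upper.tri(m)
    diff <- outer(comm, comm, "!=") & upper.tri(m)
    if (mean(m[same]) > mean(m[diff])) hits <- hits + 1L
  }
  expect_gte(hits, 19L)

  # cluster recovery on one instance
  sim <- simulate_dataset(sim_config(seed = 101, n_proteins = 300,
                                     peptides_per_protein = c(1L, 1L),
                                     n_pathways = 10L,
                                     members_per_pathway = 8L,
                                     n_communities = 2L,
                                     annotation_noise = 0.05))
  m <- similarity_matrix(sim$pathways, sim$annotations, sim$ontology)
  cl <- cluster_pathways(m, threshold = 0.5)
  ari <- mclust::adjustedRandIndex(
    cl$clusters, sim$truth$pathway_communities[names(cl$clusters)])
  expect_gte(ari, 0.9)
})
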