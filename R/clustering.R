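## GO-based pathway functional similarity and average-linkage clustering of
## similarity profiles.

#' Propagate annotations to is_a ancestors
#'
#' Closes each protein's term set under the ontology's is_a ancestors,
#' excluding root terms (every protein trivially reaches the root, which
#' would inflate similarity).
#'
#' @param annotations named list protein -> term ids.
#' @param ontology an [ontology_graph].
#' @return Named list protein -> propagated term ids.
#' @export
propagate_annotations <- function(annotations, ontology) {
  missing <- setdiff(unique(unlist(annotations)), ontology$terms)
  if (length(missing))
    stop("annotated term(s) not in ontology: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  anc_cache <- new.env(parent = emptyenv())
  anc_of <- function(term) {
    if (!is.null(anc_cache[[term]])) return(anc_cache[[term]])
    a <- term_ancestors(ontology, term, include_self = TRUE)
    anc_cache[[term]] <- a
    a
  }
  lapply(annotations, function(terms) {
    setdiff(unique(unlist(lapply(terms, anc_of))), ontology$roots)
  })
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Functional similarity between two pathways
#'
#' The default rule forms each pathway's term set as the union of its
#' members' propagated annotations and scores the pair by the Jaccard index
#' of the two sets, computed per ontology namespace (root) and averaged over
#' the namespaces present in either pathway — which prevents root-level
#' inflation when several namespaces coexist. The `"bma"` alternative is a
#' best-match-average over member-protein pairs, where protein-protein
#' similarity is the Jaccard index of propagated term sets.
#'
#' @param members1,members2 character vectors of member proteins.
#' @param annotations propagated annotations from [propagate_annotations].
#' @param ontology the [ontology_graph] (for namespace assignment).
#' @param method `"jaccard"` (default) or `"bma"`.
#' @return Similarity in [0, 1].
#' @export
pathway_similarity <- function(members1, members2, annotations, ontology,
                               method = c("jaccard", "bma")) {
  method <- match.arg(method)
  t1 <- annotations[intersect(members1, names(annotations))]
  t2 <- annotations[intersect(members2, names(annotations))]
  if (length(t1) == 0L || length(t2) == 0L)
    stop("pathway with no annotated member")
  if (method == "bma") {
    sim_mat <- outer(seq_along(t1), seq_along(t2),
                     Vectorize(function(i, j) jaccard(t1[[i]], t2[[j]])))
    return((mean(apply(sim_mat, 1L, max)) +
              mean(apply(sim_mat, 2L, max))) / 2)
  }
  u1 <- unique(unlist(t1)); u2 <- unique(unlist(t2))
  ns <- term_namespace(ontology)
  spaces <- unique(ns[c(u1, u2)])
  if (length(spaces) == 0L) return(0)
  mean(vapply(spaces, function(s)
    jaccard(u1[ns[u1] == s], u2[ns[u2] == s]), 0))
}

#' Pathway functional-similarity matrix
#'
#' @param pathways a `pathway_collection`.
#' @param annotations raw annotations (propagated internally).
#' @param ontology an [ontology_graph].
#' @param method passed to [pathway_similarity].
#' @return Symmetric matrix with unit diagonal, values in [0, 1], rows and
#'   columns named by pathway id.
#' @export
similarity_matrix <- function(pathways, annotations, ontology,
                              method = c("jaccard", "bma")) {
  method <- match.arg(method)
  if (length(pathways) < 2L) stop("need >= 2 pathways")
  prop <- propagate_annotations(annotations, ontology)
  ids <- names(pathways)
  n <- length(ids)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    s <- pathway_similarity(pathways[[i]], pathways[[j]], prop, ontology,
                            method)
    m[i, j] <- s; m[j, i] <- s
  }
  m
}

profile_correlation_dist <- function(sim) {
  ids <- rownames(sim)
  n <- nrow(sim)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    keep <- setdiff(seq_len(n), c(i, j))   # self-columns excluded pairwise
    r <- if (length(keep) >= 2L &&
             stats::sd(sim[i, keep]) > 0 && stats::sd(sim[j, keep]) > 0)
      stats::cor(sim[i, keep], sim[j, keep]) else 0
    d[i, j] <- 1 - r; d[j, i] <- 1 - r
  }
  stats::as.dist(d)
}

#' Cluster pathways from a similarity matrix
#'
#' Hierarchical agglomerative average-linkage clustering. In the default
#' `"profile"` mode the distance between two pathways is one minus the
#' Pearson correlation of their similarity-matrix rows (their own two
#' columns excluded pairwise); `"direct"` mode uses `1 - similarity`.
#' Clusters are the dendrogram cut at distance `1 - threshold`; singletons
#' are allowed. Pathways are ordered lexicographically by id before
#' agglomeration so tied merges resolve deterministically and the partition
#' does not depend on input order.
#'
#' @param sim similarity matrix from [similarity_matrix].
#' @param threshold correlation (or similarity) threshold defining the cut;
#'   default 0.5.
#' @param mode `"profile"` or `"direct"`.
#' @return List with `clusters` (named integer partition), `hclust` (the
#'   dendrogram), `threshold`, `mode`.
#' @export
cluster_pathways <- function(sim, threshold = 0.5,
                             mode = c("profile", "direct")) {
  mode <- match.arg(mode)
  if (nrow(sim) < 2L) stop("need >= 2 pathways to cluster")
  ord <- order(rownames(sim))
  sim <- sim[ord, ord, drop = FALSE]
  d <- if (mode == "profile") profile_correlation_dist(sim) else
    stats::as.dist(1 - sim)
  hc <- stats::hclust(d, method = "average")
  clusters <- stats::cutree(hc, h = 1 - threshold)
  list(clusters = clusters, hclust = hc, threshold = threshold, mode = mode)
}

#' Pathways associated with a query pathway
#'
#' @param query pathway id present in the matrix.
#' @param sim similarity matrix.
#' @param threshold minimum similarity (default 0.5, the half-maximum
#'   score).
#' @return Data frame `pathway_id`, `similarity`, descending; the query
#'   itself is excluded.
#' @export
associated_pathways <- function(query, sim, threshold = 0.5) {
  if (!query %in% rownames(sim)) stop("unknown query pathway: ", query)
  s <- sim[query, setdiff(colnames(sim), query)]
  s <- s[s >= threshold]
  s <- sort(s, decreasing = TRUE)
  data.frame(pathway_id = names(s), similarity = unname(s),
             stringsAsFactors = FALSE)
}

#' Write a similarity matrix as TSV (with header row and column)
#' @param sim similarity matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(sim, path) {
  df <- data.frame(pathway_id = rownames(sim),
                   as.data.frame(sim, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity_matrix
#' @export
read_similarity_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Export a clustering dendrogram in Newick format
#' @param clustering result of [cluster_pathways].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(clustering, path) {
  ape::write.tree(ape::as.phylo(clustering$hclust), file = path)
  invisible(path)
}
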