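## Readers/writers for the external formats the pipeline touches:
## GMT pathway sets, two-column protein->GO annotations, ontology graphs
## (edge-list or minimal OBO), FASTA, and the ratio-table TSV dialect.

#' Read pathway membership sets from a GMT file
#'
#' Standard GMT: one pathway per line, tab-separated fields
#' `id`, `description`, then member protein identifiers.
#'
#' @param path file path.
#' @return A `pathway_collection`: named list of character member vectors,
#'   with a `description` attribute (named character).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(pathway_collection(list()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, 1L) < 3L
  if (any(short))
    stop("GMT line ", which(short)[1], " has fewer than 3 fields")
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicated pathway id: ", ids[duplicated(ids)][1])
  members <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(members) <- ids
  desc <- vapply(parts, `[[`, "", 2L)
  names(desc) <- ids
  pathway_collection(members, desc)
}

#' @rdname read_gmt
#' @param members named list of character vectors (pathway id -> members).
#' @param description optional named character of pathway descriptions.
#' @export
pathway_collection <- function(members, description = NULL) {
  if (anyDuplicated(names(members))) stop("pathway ids must be unique")
  if (any(vapply(members, length, 1L) == 0L))
    stop("pathway member sets must be non-empty")
  if (is.null(description)) {
    description <- rep("", length(members))
    names(description) <- names(members)
  }
  structure(members, description = description, class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat("pathway_collection:", length(x), "pathways,",
      length(unique(unlist(x))), "distinct members\n")
  invisible(x)
}

#' Write a pathway collection to GMT
#' @param x a `pathway_collection`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  desc <- attr(x, "description")
  lines <- vapply(seq_along(x), function(i) {
    paste(c(names(x)[i], desc[[names(x)[i]]], x[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read protein-to-term annotations
#'
#' GAF-like two-column TSV: `protein<TAB>term`, one association per line.
#' Lines starting with `!` are treated as comments.
#'
#' @param path file path.
#' @return Named list: protein -> character vector of term ids.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "!")]
  if (length(lines) == 0L) return(structure(list(), names = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(parts, length, 1L) < 2L))
    stop("annotation line must have 2 tab-separated fields")
  prot <- vapply(parts, `[[`, "", 1L)
  term <- vapply(parts, `[[`, "", 2L)
  split(term, prot) |> lapply(unique)
}

#' Write protein-to-term annotations
#' @param annotations named list protein -> term ids.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  prot <- rep(names(annotations), lengths(annotations))
  writeLines(paste(prot, unlist(annotations), sep = "\t"), path)
  invisible(path)
}

#' Construct an ontology graph from is_a edges
#'
#' The ontology is a rooted directed acyclic graph of terms linked by `is_a`
#' edges (child -> parent). Terms with no parent are roots; each root defines
#' a namespace used when functional similarity is averaged per namespace.
#'
#' @param child,parent character vectors of equal length; each pair is one
#'   `is_a` edge.
#' @param names optional named character of term names.
#' @return An `ontology_graph`.
#' @export
ontology_graph <- function(child, parent, names = NULL) {
  stopifnot(length(child) == length(parent))
  terms <- unique(c(child, parent))
  g <- igraph::graph_from_data_frame(
    data.frame(from = child, to = parent, stringsAsFactors = FALSE),
    directed = TRUE, vertices = terms)
  if (!igraph::is_dag(g)) stop("ontology contains a cycle")
  roots <- terms[igraph::degree(g, mode = "out") == 0L]
  structure(list(graph = g, terms = terms, roots = roots, names = names),
            class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("ontology_graph:", length(x$terms), "terms,",
      igraph::ecount(x$graph), "is_a edges,",
      length(x$roots), "root(s)\n")
  invisible(x)
}

#' Read an ontology graph
#'
#' Two dialects are supported. `edge-list` is a two-column TSV
#' `child<TAB>parent`. `obo` is a minimal OBO parser consuming only
#' `[Term]` stanzas and their `id:`, `name:` and `is_a:` tags; every other
#' tag and relationship type is ignored, which is sufficient for is_a
#' ancestor propagation and similarity computation.
#'
#' @param path file path.
#' @param format `"edge-list"` or `"obo"`.
#' @return An [ontology_graph].
#' @export
read_ontology <- function(path, format = c("edge-list", "obo")) {
  format <- match.arg(format)
  if (format == "edge-list") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(vapply(parts, length, 1L) < 2L))
      stop("edge-list line must have 2 tab-separated fields")
    return(ontology_graph(vapply(parts, `[[`, "", 1L),
                          vapply(parts, `[[`, "", 2L)))
  }
  lines <- readLines(path, warn = FALSE)
  stanza_starts <- which(lines == "[Term]")
  if (length(stanza_starts) == 0L) stop("no [Term] stanzas found")
  bounds <- c(stanza_starts, length(lines) + 1L)
  ids <- character(); nms <- character()
  child <- character(); parent <- character()
  for (i in seq_along(stanza_starts)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    block <- block[!startsWith(block, "[")]
    id <- sub("^id: *", "", grep("^id:", block, value = TRUE)[1])
    nm <- sub("^name: *", "", grep("^name:", block, value = TRUE)[1])
    isa <- grep("^is_a:", block, value = TRUE)
    isa <- sub(" *!.*$", "", sub("^is_a: *", "", isa))
    ids <- c(ids, id); nms <- c(nms, nm)
    if (length(isa)) {
      child <- c(child, rep(id, length(isa)))
      parent <- c(parent, isa)
    }
  }
  names(nms) <- ids
  og <- ontology_graph(child, parent, names = nms)
  # isolated terms (no is_a in either direction) still belong to the graph
  missing <- setdiff(ids, og$terms)
  if (length(missing)) {
    og$graph <- igraph::add_vertices(og$graph, length(missing),
                                     name = missing)
    og$terms <- c(og$terms, missing)
    og$roots <- unique(c(og$roots, missing))
  }
  og
}

#' Write an ontology graph as an is_a edge list
#' @param ontology an [ontology_graph].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(ontology, path) {
  e <- igraph::as_data_frame(ontology$graph, what = "edges")
  writeLines(paste(e$from, e$to, sep = "\t"), path)
  invisible(path)
}

#' Ancestors of a term under is_a
#'
#' @param ontology an [ontology_graph].
#' @param term term id.
#' @param include_self include the term itself (default `FALSE`).
#' @return Character vector of ancestor term ids (unordered).
#' @export
term_ancestors <- function(ontology, term, include_self = FALSE) {
  if (!term %in% ontology$terms) stop("term not in ontology: ", term)
  anc <- names(igraph::subcomponent(ontology$graph, term, mode = "out"))
  if (!include_self) anc <- setdiff(anc, term)
  anc
}

#' Namespace (root) of each ontology term
#'
#' @param ontology an [ontology_graph].
#' @return Named character: term -> id of the root it descends from. Terms
#'   reachable from several roots are assigned the lexicographically first.
#' @export
term_namespace <- function(ontology) {
  ns <- rep(NA_character_, length(ontology$terms))
  names(ns) <- ontology$terms
  for (root in sort(ontology$roots)) {
    below <- names(igraph::subcomponent(ontology$graph, root, mode = "in"))
    ns[below[is.na(ns[below])]] <- root
  }
  ns
}

#' Read protein sequences from FASTA
#' @param path file path.
#' @return Named character vector of amino-acid sequences (uppercase).
#' @export
read_protein_fasta <- function(path) {
  x <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                          set.attributes = FALSE)
  toupper(unlist(x))
}

#' Write protein sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(seqs, path) {
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = path, as.string = TRUE)
  invisible(path)
}
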