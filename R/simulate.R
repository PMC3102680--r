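## Seeded generator of complete synthetic inputs: a five-cell-line,
## triplicate-run phosphopeptide panel with an internal standard, protein
## sequences embedding controlled phosphosite motif contexts, pathway
## memberships with planted active pathways, a small GO-like DAG with
## community-structured annotations, and the ground truth behind it all.

#' Simulation configuration
#'
#' Defaults emulate the experimental design the pipeline targets: five cell
#' lines (an immortalized parent line `3KT`, its Ras-transformed derivative
#' `3KTR`, and three NSCLC lines) each measured in three LC-MS/MS runs, with
#' a spiked beta-casein internal standard, log-normal abundances, per-run
#' multiplicative scale biases, planted log2 effects, and class-exclusive
#' detections.
#'
#' @param cell_lines cell-line labels; first is the reference class.
#' @param replicates runs per cell line (default 3).
#' @param n_proteins number of simulated phosphoproteins.
#' @param peptides_per_protein integer range (min, max) of phosphopeptides
#'   per protein, sampled uniformly.
#' @param baseline_log2_mean,baseline_log2_sd per-peptide baseline log2
#'   abundance distribution.
#' @param run_scale_log2_sd sd (log2) of the per-run multiplicative scale
#'   bias; `run_scale_factors` may instead give explicit per-run factors.
#' @param run_scale_factors optional numeric vector of per-run scales
#'   (length `length(cell_lines) * replicates`).
#' @param replicate_noise_sd replicate measurement noise sd in log2 units;
#'   the default 0.2 gives triplicate CVs around 14\%, inside the 20\% QC
#'   bound typical of label-free runs.
#' @param n_regulated number of peptides with a planted regulation effect.
#' @param effect_size absolute planted log2 shift for regulated peptides
#'   (sign drawn at random per peptide).
#' @param regulated_lines cell lines receiving the planted peptide effects.
#' @param planted_effects optional explicit data.frame
#'   (`peptide_id`, `cell_line`, `log2_shift`) overriding
#'   `n_regulated`/`effect_size`; peptide ids follow the generator's
#'   `<protein>_<site>` scheme.
#' @param class_exclusive_fraction fraction of peptides rendered fully
#'   undetected in one non-reference cell line (sentinel-coded downstream).
#' @param motif_mix probabilities of proline-directed / basophilic /
#'   acidophilic / other site contexts; must sum to 1.
#' @param n_pathways,members_per_pathway pathway collection shape.
#' @param n_active_pathways pathways with a planted activity effect.
#' @param activity_effect log2 shift added to every peptide of an active
#'   pathway's member proteins in `active_lines`.
#' @param active_lines cell lines in which active pathways are shifted.
#' @param ontology_depth,ontology_branching shape of the generated rooted
#'   ontology tree.
#' @param n_communities annotation communities; pathways are assigned
#'   round-robin to distinct root branches so co-community pathways share
#'   annotation subtrees (clusterable structure).
#' @param terms_per_protein annotation terms drawn per (protein, pathway).
#' @param annotation_noise probability that an annotation term is drawn
#'   from the whole ontology instead of the community subtree.
#' @param seed integer seed; fully determines the output.
#' @return A `sim_config`.
#' @export
sim_config <- function(cell_lines = c("3KT", "3KTR", "A549", "H322", "H1299"),
                       replicates = 3L,
                       n_proteins = 200L,
                       peptides_per_protein = c(1L, 3L),
                       baseline_log2_mean = 20,
                       baseline_log2_sd = 1.5,
                       run_scale_log2_sd = 0.5,
                       run_scale_factors = NULL,
                       replicate_noise_sd = 0.2,
                       n_regulated = 50L,
                       effect_size = 2,
                       regulated_lines = "3KTR",
                       planted_effects = NULL,
                       class_exclusive_fraction = 0.02,
                       motif_mix = c(proline_directed = 0.40,
                                     basophilic = 0.20,
                                     acidophilic = 0.15,
                                     other = 0.25),
                       n_pathways = 20L,
                       members_per_pathway = 10L,
                       n_active_pathways = 1L,
                       activity_effect = 1,
                       active_lines = "3KTR",
                       ontology_depth = 3L,
                       ontology_branching = 3L,
                       n_communities = 2L,
                       terms_per_protein = 3L,
                       annotation_noise = 0.1,
                       seed = 1L) {
  if (abs(sum(motif_mix) - 1) > 1e-8) stop("motif_mix must sum to 1")
  if (length(motif_mix) != 4L ||
      !identical(names(motif_mix), MOTIF_CLASSES))
    stop("motif_mix must be named ", paste(MOTIF_CLASSES, collapse = ", "))
  if (replicate_noise_sd < 0) stop("replicate_noise_sd must be >= 0")
  if (n_active_pathways > n_pathways)
    stop("more active pathways than pathways")
  if (members_per_pathway > n_proteins)
    stop("members_per_pathway exceeds n_proteins")
  if (n_communities > ontology_branching)
    stop("n_communities cannot exceed ontology_branching")
  if (!all(regulated_lines %in% cell_lines) ||
      !all(active_lines %in% cell_lines))
    stop("regulated/active lines must be among cell_lines")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

sample_aa <- function(n, exclude = character()) {
  pool <- setdiff(AA20, exclude)
  sample(pool, n, replace = TRUE)
}

## one 13-mer window with the residue constraints of a motif class;
## constraints are chosen so the ground-truth class survives the
## classification precedence (proline-directed > basophilic > acidophilic)
make_window <- function(class) {
  center <- sample(c("S", "T", "Y"), 1L, prob = c(0.80, 0.15, 0.05))
  w <- sample_aa(13L)
  w[7] <- center
  set <- function(off, res) w[7 + off] <<- res
  avoid <- function(off, res) if (w[7 + off] %in% res)
    w[7 + off] <<- sample_aa(1L, exclude = res)
  switch(class,
    proline_directed = set(1L, "P"),
    basophilic = { set(-3L, "R"); avoid(1L, "P") },
    acidophilic = { set(1L, sample(c("D", "E"), 1L)); avoid(-3L, "R") },
    other = { avoid(1L, c("P", "D", "E")); avoid(-3L, "R")
              avoid(3L, "E") })
  paste(w, collapse = "")
}

#' Simulate a complete synthetic dataset
#'
#' Generates run-level abundances
#' `2^(baseline + planted effect + noise) * run_scale`, an internal-standard
#' row whose abundance is exactly `run_scale * 2^baseline_log2_mean` in
#' every run (so normalization cancels the run scales exactly), protein
#' sequences embedding the configured motif context at each phosphosite,
#' pathway memberships with planted active pathways, a rooted ontology tree
#' with community-structured annotations, and the ground truth.
#'
#' @param config a [sim_config].
#' @return List with elements `quant` ([quant_table]), `proteome` (named
#'   character of protein sequences), `pathways` (`pathway_collection`),
#'   `annotations` (named list), `ontology` ([ontology_graph]), and `truth`
#'   (list: `regulated` data.frame, `active_pathways`, `site_class`,
#'   `exclusive` data.frame, `run_scale`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cl <- config$cell_lines
  n_runs <- length(cl) * config$replicates
  runs <- data.frame(
    run_id = paste0(rep(cl, each = config$replicates), "_r",
                    rep(seq_len(config$replicates), length(cl))),
    cell_line = rep(cl, each = config$replicates),
    replicate = rep(seq_len(config$replicates), length(cl)),
    stringsAsFactors = FALSE)

  ## proteins, peptides, motif contexts
  prot_ids <- sprintf("PROT%04d", seq_len(config$n_proteins))
  pep_range <- seq(config$peptides_per_protein[1],
                   config$peptides_per_protein[2])
  npep <- if (length(pep_range) == 1L)
    rep(pep_range, config$n_proteins)
  else sample(pep_range, config$n_proteins, replace = TRUE)
  pep_protein <- rep(prot_ids, npep)
  n_pep <- length(pep_protein)
  pep_class <- sample(MOTIF_CLASSES, n_pep, replace = TRUE,
                      prob = config$motif_mix)
  windows <- vapply(pep_class, make_window, "")
  ## protein sequence = concatenated 13-mer windows; site k sits at 13(k-1)+7
  seq_by_prot <- split(windows, factor(pep_protein, levels = prot_ids))
  proteome <- vapply(seq_by_prot, paste, "", collapse = "")
  pep_index <- unlist(lapply(npep, seq_len))
  site_pos <- 13L * (pep_index - 1L) + 7L
  center <- substr(windows, 7L, 7L)
  site_label <- paste0(center, site_pos)
  pep_id <- paste0(pep_protein, "_", site_label)
  pep_seq <- windows
  substr(pep_seq, 7L, 7L) <- tolower(center)
  names(windows) <- pep_id

  ## pathways and planted activity effects
  path_ids <- sprintf("PW%03d", seq_len(config$n_pathways))
  members <- lapply(path_ids, function(p)
    sample(prot_ids, config$members_per_pathway))
  names(members) <- path_ids
  pathways <- pathway_collection(
    members, stats::setNames(paste("synthetic pathway", path_ids), path_ids))
  active <- if (config$n_active_pathways > 0L)
    sample(path_ids, config$n_active_pathways) else character()

  ## planted per-peptide regulation effects
  effect <- matrix(0, n_pep, length(cl), dimnames = list(pep_id, cl))
  if (!is.null(config$planted_effects)) {
    pe <- config$planted_effects
    for (i in seq_len(nrow(pe)))
      effect[pe$peptide_id[i], pe$cell_line[i]] <- pe$log2_shift[i]
    regulated <- data.frame(peptide_id = pe$peptide_id,
                            cell_line = pe$cell_line,
                            log2_shift = pe$log2_shift,
                            stringsAsFactors = FALSE)
  } else if (config$n_regulated > 0L) {
    idx <- sample(n_pep, min(config$n_regulated, n_pep))
    sign <- sample(c(1, -1), length(idx), replace = TRUE)
    regulated <- do.call(rbind, lapply(config$regulated_lines, function(l)
      data.frame(peptide_id = pep_id[idx], cell_line = l,
                 log2_shift = sign * config$effect_size,
                 stringsAsFactors = FALSE)))
    for (i in seq_len(nrow(regulated)))
      effect[regulated$peptide_id[i], regulated$cell_line[i]] <-
        effect[regulated$peptide_id[i], regulated$cell_line[i]] +
        regulated$log2_shift[i]
  } else {
    regulated <- data.frame(peptide_id = character(),
                            cell_line = character(), log2_shift = numeric())
  }
  ## pathway activity: shift every peptide of active members
  for (p in active) {
    memb_pep <- pep_id[pep_protein %in% pathways[[p]]]
    for (l in config$active_lines)
      effect[memb_pep, l] <- effect[memb_pep, l] + config$activity_effect
  }

  ## abundances
  run_scale <- if (!is.null(config$run_scale_factors)) {
    stopifnot(length(config$run_scale_factors) == n_runs)
    config$run_scale_factors
  } else 2^stats::rnorm(n_runs, 0, config$run_scale_log2_sd)
  names(run_scale) <- runs$run_id
  baseline <- stats::rnorm(n_pep, config$baseline_log2_mean,
                           config$baseline_log2_sd)
  noise <- matrix(stats::rnorm(n_pep * n_runs, 0, config$replicate_noise_sd),
                  n_pep, n_runs)
  log2_ab <- baseline + effect[, runs$cell_line] + noise
  ab <- sweep(2^log2_ab, 2L, run_scale, "*")
  dimnames(ab) <- list(pep_id, runs$run_id)

  ## class-exclusive detections: fully missing in one non-reference line
  n_excl <- round(config$class_exclusive_fraction * n_pep)
  exclusive <- data.frame(peptide_id = character(), missing_line = character())
  if (n_excl > 0L && length(cl) > 1L) {
    excl_idx <- sample(n_pep, n_excl)
    excl_line <- sample(cl[-1], n_excl, replace = TRUE)
    for (i in seq_len(n_excl))
      ab[excl_idx[i], runs$cell_line == excl_line[i]] <- NA
    exclusive <- data.frame(peptide_id = pep_id[excl_idx],
                            missing_line = excl_line,
                            stringsAsFactors = FALSE)
  }

  ## internal standard: exactly run_scale * constant in every run
  std_ab <- run_scale * 2^config$baseline_log2_mean
  ab <- rbind(ab, IS_BCASEIN = std_ab)
  peptides <- data.frame(
    peptide_id = c(pep_id, "IS_BCASEIN"),
    protein = c(pep_protein, "P02666"),
    gene = c(sub("PROT", "G", pep_protein), "CSN2"),
    sequence = c(pep_seq, "FQsEEQQQTEDELQDK"),
    sites = c(site_label, "S50"),
    stringsAsFactors = FALSE)
  quant <- quant_table(ab, peptides, runs, standard_id = "IS_BCASEIN")

  ## ontology tree + community-structured annotations
  onto <- make_tree_ontology(config$ontology_depth, config$ontology_branching)
  root_children <- onto$children_of_root
  comm_of_path <- rep(seq_len(config$n_communities),
                      length.out = config$n_pathways)
  names(comm_of_path) <- path_ids
  subtree_terms <- lapply(seq_len(config$n_communities), function(k)
    setdiff(names(igraph::subcomponent(onto$graph$graph,
                                       root_children[k], mode = "in")),
            onto$graph$roots))
  all_terms <- setdiff(onto$graph$terms, onto$graph$roots)
  annotations <- stats::setNames(vector("list", config$n_proteins), prot_ids)
  for (p in path_ids) {
    pool <- subtree_terms[[comm_of_path[[p]]]]
    for (prot in pathways[[p]]) {
      pick <- vapply(seq_len(config$terms_per_protein), function(.)
        if (stats::runif(1) < config$annotation_noise)
          sample(all_terms, 1L) else sample(pool, 1L), "")
      annotations[[prot]] <- unique(c(annotations[[prot]], pick))
    }
  }
  ## proteins in no pathway get background annotations
  empty <- vapply(annotations, is.null, TRUE)
  for (prot in prot_ids[empty])
    annotations[[prot]] <- unique(sample(all_terms,
                                         config$terms_per_protein,
                                         replace = TRUE))

  truth <- list(
    regulated = regulated,
    active_pathways = active,
    pathway_communities = comm_of_path,
    site_class = stats::setNames(factor(pep_class, levels = MOTIF_CLASSES),
                                 pep_id),
    windows = windows,
    exclusive = exclusive,
    run_scale = run_scale)
  list(quant = quant, proteome = proteome, pathways = pathways,
       annotations = annotations, ontology = onto$graph, truth = truth)
}

make_tree_ontology <- function(depth, branching) {
  child <- character(); parent <- character()
  level <- "T:root"
  for (d in seq_len(depth)) {
    nxt <- character()
    for (p in level) {
      kids <- paste0(sub("^T:", "T:", p), ".", seq_len(branching))
      child <- c(child, kids)
      parent <- c(parent, rep(p, branching))
      nxt <- c(nxt, kids)
    }
    level <- nxt
  }
  g <- ontology_graph(child, parent)
  list(graph = g,
       children_of_root = paste0("T:root.", seq_len(branching)))
}

#' Simulate a null dataset
#'
#' Same generator with all planted effects and class-exclusive detections
#' removed: the cell lines are isogenic-like classes differing only by
#' replicate noise and run scales.
#'
#' @param config a [sim_config]; its effect fields are overridden to zero.
#' @return Same structure as [simulate_dataset].
#' @export
simulate_null_dataset <- function(config = sim_config()) {
  config$n_regulated <- 0L
  config$n_active_pathways <- 0L
  config$class_exclusive_fraction <- 0
  config$planted_effects <- NULL
  simulate_dataset(config)
}

#' Write all artifacts of a simulated dataset
#'
#' Emits every component in the pipeline's on-disk dialects: quant TSV,
#' protein FASTA, GMT, annotation TSV, ontology edge-list TSV, and the
#' ground truth as JSON.
#'
#' @param sim result of [simulate_dataset].
#' @param dir output directory (created if absent).
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    quant = file.path(dir, "quant.tsv"),
    proteome = file.path(dir, "proteome.fasta"),
    pathways = file.path(dir, "pathways.gmt"),
    annotations = file.path(dir, "annotations.tsv"),
    ontology = file.path(dir, "ontology_edges.tsv"),
    truth = file.path(dir, "truth.json"))
  write_quant_table(sim$quant, paths["quant"])
  write_protein_fasta(sim$proteome, paths["proteome"])
  write_gmt(sim$pathways, paths["pathways"])
  write_annotations(sim$annotations, paths["annotations"])
  write_ontology(sim$ontology, paths["ontology"])
  truth <- sim$truth
  truth$site_class <- as.list(stats::setNames(as.character(truth$site_class),
                                              names(truth$site_class)))
  truth$windows <- as.list(truth$windows)
  truth$run_scale <- as.list(truth$run_scale)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
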