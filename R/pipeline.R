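## End-to-end orchestration: simulate or load inputs, quantify, call
## regulation and concurrence, enrich motifs, score pathway activity,
## cluster pathways, and write every stage artifact plus a run manifest.

#' Pipeline configuration
#'
#' Exactly one of `simulation` (a [sim_config]) or `inputs` (named paths)
#' must be supplied.
#'
#' @param simulation a [sim_config], or `NULL` when reading real inputs.
#' @param inputs named list of file paths: `quant` (TSV), `proteome`
#'   (FASTA), `pathways` (GMT), `annotations` (TSV), `ontology` (edge-list
#'   TSV); or `NULL` when simulating.
#' @param comparisons list of [comparison_spec] (or 2-character vectors
#'   `c(test, reference)` completed with `regulation_threshold`).
#' @param regulation_threshold log2 regulation threshold (two-fold rule:
#'   1.0).
#' @param concurrence optional list with `require` and `exclude` comparison
#'   labels for the multi-line concurrence filter.
#' @param qc a [qc_config].
#' @param enrichment an [enrichment_config].
#' @param activity an [activity_config].
#' @param cluster_threshold,cluster_mode,similarity_method clustering stage
#'   settings (see [cluster_pathways], [pathway_similarity]).
#' @param center ratio centering statistic (`"mean"` or `"median"`).
#' @param stages stages to run, in order, among `"quant"`, `"motifs"`,
#'   `"pathways"`, `"cluster"`.
#' @param seed integer seed for any stochastic stage.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, inputs = NULL,
                            comparisons = list(c("3KTR", "3KT")),
                            regulation_threshold = 1.0,
                            concurrence = NULL,
                            qc = qc_config(),
                            enrichment = enrichment_config(),
                            activity = activity_config(),
                            cluster_threshold = 0.5,
                            cluster_mode = "profile",
                            similarity_method = "jaccard",
                            center = "mean",
                            stages = c("quant", "motifs", "pathways",
                                       "cluster"),
                            seed = 1L) {
  comparisons <- lapply(comparisons, function(cmp) {
    if (inherits(cmp, "comparison_spec")) return(cmp)
    if (regulation_threshold > 0)
      comparison_spec(cmp[1], cmp[2], regulation_threshold)
    else list(test = cmp[1], reference = cmp[2],
              threshold = regulation_threshold,
              label = paste0(cmp[1], "/", cmp[2]))
  })
  structure(list(simulation = simulation, inputs = inputs,
                 comparisons = comparisons,
                 regulation_threshold = regulation_threshold,
                 concurrence = concurrence, qc = qc,
                 enrichment = enrichment, activity = activity,
                 cluster_threshold = cluster_threshold,
                 cluster_mode = cluster_mode,
                 similarity_method = similarity_method,
                 center = center, stages = stages,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' @param config a [pipeline_config].
#' @return Character vector of findings; empty when the config is runnable.
#' @export
validate_config <- function(config) {
  findings <- character()
  has_sim <- !is.null(config$simulation)
  has_in <- !is.null(config$inputs)
  if (has_sim == has_in)
    findings <- c(findings,
                  "exactly one of simulation or inputs must be supplied")
  if (!is.numeric(config$regulation_threshold) ||
      config$regulation_threshold <= 0)
    findings <- c(findings, "regulation_threshold must be > 0")
  if (length(config$comparisons) == 0L)
    findings <- c(findings, "at least one comparison is required")
  if (has_in) {
    need <- c(quant = "quant")
    if ("motifs" %in% config$stages) need <- c(need, proteome = "proteome")
    if ("pathways" %in% config$stages) need <- c(need, pathways = "pathways")
    if ("cluster" %in% config$stages)
      need <- c(need, pathways = "pathways", annotations = "annotations",
                ontology = "ontology")
    for (nm in unique(need))
      if (is.null(config$inputs[[nm]]))
        findings <- c(findings, paste0(
          "stage needing input '", nm, "' is enabled but no path given"))
  }
  if (!is.null(config$concurrence)) {
    labels <- vapply(config$comparisons, `[[`, "", "label")
    bad <- setdiff(c(config$concurrence$require, config$concurrence$exclude),
                   labels)
    if (length(bad))
      findings <- c(findings, paste0("concurrence names unknown comparison: ",
                                     paste(bad, collapse = ", ")))
  }
  findings
}

#' Extract phosphosite windows for ratio-table rows
#'
#' Looks up each row's protein in the proteome and extracts one window per
#' `;`-separated site label (residue + 1-based protein position).
#'
#' @param meta data.frame with `protein` and `sites` columns.
#' @param proteome named character vector of protein sequences.
#' @param flank flank width (default 6).
#' @return Character vector of windows; names give the originating row
#'   index and site label.
#' @export
table_windows <- function(meta, proteome, flank = 6L) {
  out <- character(); nm <- character()
  for (i in seq_len(nrow(meta))) {
    prot <- meta$protein[i]
    if (!prot %in% names(proteome))
      stop("protein not in proteome: ", prot)
    for (site in strsplit(meta$sites[i], ";", fixed = TRUE)[[1]]) {
      pos <- as.integer(sub("^[STY]", "", site))
      out <- c(out, extract_window(proteome[[prot]], pos, flank))
      nm <- c(nm, paste0(i, ":", site))
    }
  }
  stats::setNames(out, nm)
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) inputs, then run the enabled stages in order:
#' normalization + ratio + regulation (`quant`), motif classification,
#' enrichment and kinase-subset homogeneity (`motifs`), pathway activity
#' scoring (`pathways`), and functional-similarity clustering (`cluster`).
#' All stage outputs are written under `out_dir` as TSV (inspectable and
#' resumable), plus a JSON run manifest with the seed and a config hash.
#' One log line per stage reports row counts so the per-comparison
#' quantified/up/down accounting is auditable.
#'
#' @param config a [pipeline_config].
#' @param out_dir output directory.
#' @param quiet suppress stage log lines.
#' @return A report bundle (list): `ratios`, `calls`, `concurrence`,
#'   `motif_enrichments`, `subset_freqs`, `homogeneity`, `activity`,
#'   `similarity`, `clusters`, `manifest`.
#' @export
run_full_pipeline <- function(config, out_dir, quiet = FALSE) {
  findings <- validate_config(config)
  if (length(findings))
    stop("invalid pipeline config:\n  ", paste(findings, collapse = "\n  "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(stage, ...) if (!quiet)
    message("[", stage, "] ", paste0(...))
  report <- list()

  ## inputs
  if (!is.null(config$simulation)) {
    sim <- tryCatch(simulate_dataset(config$simulation),
                    error = function(e) stop("stage simulate: ",
                                             conditionMessage(e)))
    write_simulated_dataset(sim, file.path(out_dir, "inputs"))
    quant <- sim$quant; proteome <- sim$proteome
    pathways <- sim$pathways; annotations <- sim$annotations
    ontology <- sim$ontology
    report$truth <- sim$truth
    log_line("simulate", nrow(quant$abundance), " peptides x ",
             ncol(quant$abundance), " runs")
  } else {
    ip <- config$inputs
    quant <- read_quant_table(ip$quant)
    proteome <- if (!is.null(ip$proteome)) read_protein_fasta(ip$proteome)
    pathways <- if (!is.null(ip$pathways)) read_gmt(ip$pathways)
    annotations <- if (!is.null(ip$annotations))
      read_annotations(ip$annotations)
    ontology <- if (!is.null(ip$ontology)) read_ontology(ip$ontology)
    log_line("load", nrow(quant$abundance), " peptides")
  }

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE))
  }

  ## quant stage
  ratios <- NULL
  if ("quant" %in% config$stages) {
    ratios <- run_stage("quant", {
      norm <- normalize_to_standard(quant)
      summ <- summarize_replicates(norm, config$qc)
      rt <- log2_ratio_table(summ, config$comparisons)
      center_ratios(rt, config$center)
    })
    write_ratio_table(ratios, file.path(out_dir, "ratios.tsv"))
    calls <- call_regulation_table(ratios, config$regulation_threshold)
    utils::write.table(calls, file.path(out_dir, "regulation_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$ratios <- ratios
    report$calls <- calls
    for (lbl in comparisons(ratios)) {
      v <- ratio_matrix(ratios)[, lbl]
      cc <- call_regulation(v, config$regulation_threshold)
      log_line("quant", lbl, ": quantified=",
               sum(!is_sentinel(v) & !is.na(v)),
               " up=", sum(cc == "up"), " down=", sum(cc == "down"))
    }
    if (!is.null(config$concurrence)) {
      conc <- run_stage("quant", concurrent_regulation(
        ratios, config$concurrence$require, config$concurrence$exclude,
        config$regulation_threshold))
      utils::write.table(conc, file.path(out_dir, "concurrence.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$concurrence <- conc
      log_line("quant", "concurrent proteins: ",
               length(unique(conc$protein)))
    }
  }

  ## motifs stage
  if ("motifs" %in% config$stages && !is.null(ratios)) {
    res <- run_stage("motifs", {
      meta <- as.data.frame(ratios)[setdiff(names(ratios),
                                            comparisons(ratios))]
      win_all <- table_windows(meta, proteome)
      row_of <- as.integer(sub(":.*$", "", names(win_all)))
      m <- ratio_matrix(ratios)
      enr <- list(); freqs <- list()
      for (lbl in comparisons(ratios)) {
        v <- m[row_of, lbl]
        quantified <- !is.na(v) & !is_sentinel(v)
        cc <- call_regulation(v, config$regulation_threshold)
        fg <- win_all[cc %in% c("up", "down")]
        bg <- win_all[quantified]
        enr[[lbl]] <- if (length(fg))
          motifx_enrich(fg, bg, config$enrichment) else NULL
        freqs[[lbl]] <- if (length(fg))
          subset_frequencies(classify_window(fg))
        else data.frame(class = MOTIF_CLASSES, count = 0L,
                        proportion = NA_real_, stringsAsFactors = FALSE)
      }
      labels <- comparisons(ratios)
      homog <- list()
      if (length(labels) >= 2L)
        for (i in seq_len(length(labels) - 1L))
          for (j in (i + 1L):length(labels)) {
            ca <- freqs[[labels[i]]]$count; cb <- freqs[[labels[j]]]$count
            if (sum(ca) == 0L || sum(cb) == 0L) next
            key <- paste(labels[i], "vs", labels[j])
            homog[[key]] <- homogeneity_test(ca, cb)
          }
      list(enr = enr, freqs = freqs, homog = homog)
    })
    report$motif_enrichments <- res$enr
    report$subset_freqs <- res$freqs
    report$homogeneity <- res$homog
    freq_df <- do.call(rbind, lapply(names(res$freqs), function(l)
      cbind(comparison = l, res$freqs[[l]])))
    utils::write.table(freq_df, file.path(out_dir, "subset_frequencies.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    enr_df <- do.call(rbind, lapply(names(res$enr), function(l)
      if (!is.null(res$enr[[l]]) && nrow(res$enr[[l]]))
        cbind(comparison = l,
              res$enr[[l]][setdiff(names(res$enr[[l]]), "constraints")])))
    if (!is.null(enr_df))
      utils::write.table(enr_df, file.path(out_dir, "motif_enrichments.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    log_line("motifs", length(res$enr), " comparisons enriched, ",
             length(res$homog), " homogeneity tests")
  }

  ## pathway activity stage
  if ("pathways" %in% config$stages) {
    act <- run_stage("pathways", {
      norm <- normalize_to_standard(quant)
      score_all_pathways(norm, pathways, config$comparisons,
                         config$activity, config$qc)
    })
    utils::write.table(act, file.path(out_dir, "pathway_activity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$activity <- act
    log_line("pathways", nrow(act), " (pathway, comparison) scores; ",
             nrow(attr(act, "filtered")), " filtered by min_members")
  }

  ## clustering stage
  if ("cluster" %in% config$stages) {
    clu <- run_stage("cluster", {
      sim_m <- similarity_matrix(pathways, annotations, ontology,
                                 config$similarity_method)
      list(sim = sim_m,
           clustering = cluster_pathways(sim_m, config$cluster_threshold,
                                         config$cluster_mode))
    })
    write_similarity_matrix(clu$sim, file.path(out_dir, "similarity.tsv"))
    cl_df <- data.frame(pathway_id = names(clu$clustering$clusters),
                        cluster = unname(clu$clustering$clusters))
    utils::write.table(cl_df, file.path(out_dir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_dendrogram_newick(clu$clustering,
                            file.path(out_dir, "dendrogram.nwk"))
    report$similarity <- clu$sim
    report$clusters <- clu$clustering
    log_line("cluster", max(clu$clustering$clusters), " clusters at ",
             "threshold ", config$cluster_threshold)
  }

  ## manifest
  cfg_path <- file.path(out_dir, "config.yml")
  yaml::write_yaml(serialize_config(config), cfg_path)
  manifest <- list(
    package = "phosflow",
    version = as.character(utils::packageVersion("phosflow")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    stages = config$stages,
    outputs = list.files(out_dir, recursive = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  report$manifest <- manifest
  invisible(report)
}

## flatten config into plain lists for YAML
serialize_config <- function(config) {
  x <- unclass(config)
  x$comparisons <- lapply(x$comparisons, function(cmp)
    list(test = cmp$test, reference = cmp$reference,
         threshold = cmp$threshold))
  x$simulation <- if (!is.null(x$simulation)) unclass(x$simulation)
  x$qc <- unclass(x$qc)
  x$enrichment <- unclass(x$enrichment)
  x$activity <- unclass(x$activity)
  x
}
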