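## Pathway activity inference: per-pathway signed t-type score comparing
## summed phosphoprotein signature levels between two replicated classes.

#' Activity-analysis configuration
#'
#' @param min_members minimum number of detected member phosphoproteins for
#'   a pathway to be scored (default 5).
#' @param aggregate rule collapsing a protein's phosphopeptides to one
#'   representative value per run: `"mean"` (default) or `"max_abs"`
#'   (peptide with the largest absolute level).
#' @param epsilon variance floor added inside the score's denominator;
#'   default 0 (guards degenerate zero-variance inputs when set > 0).
#' @return An `activity_config`.
#' @export
activity_config <- function(min_members = 5L,
                            aggregate = c("mean", "max_abs"),
                            epsilon = 0) {
  if (min_members < 1L) stop("min_members must be >= 1")
  if (epsilon < 0) stop("epsilon must be >= 0")
  structure(list(min_members = as.integer(min_members),
                 aggregate = match.arg(aggregate),
                 epsilon = epsilon),
            class = "activity_config")
}

#' Protein representative values per run
#'
#' Collapses phosphopeptide levels to one value per protein per run. The
#' default rule is the mean over the protein's detected phosphopeptides,
#' keeping pathway sums comparable across proteins with different peptide
#' counts; `"max_abs"` takes the peptide with the largest absolute level.
#'
#' @param levels numeric matrix of normalized log2 levels, peptides x runs.
#' @param proteins character vector mapping each peptide row to its protein.
#' @param aggregate `"mean"` or `"max_abs"`.
#' @return Numeric matrix, proteins x runs; `NA` where no peptide of the
#'   protein was detected in a run.
#' @export
protein_representative_values <- function(levels, proteins,
                                          aggregate = c("mean", "max_abs")) {
  aggregate <- match.arg(aggregate)
  stopifnot(nrow(levels) == length(proteins))
  groups <- split(seq_len(nrow(levels)), proteins)
  out <- matrix(NA_real_, length(groups), ncol(levels),
                dimnames = list(names(groups), colnames(levels)))
  for (i in seq_along(groups)) {
    sub <- levels[groups[[i]], , drop = FALSE]
    out[i, ] <- if (aggregate == "mean") {
      v <- colMeans(sub, na.rm = TRUE)
      v[is.nan(v)] <- NA_real_
      v
    } else {
      apply(sub, 2L, function(col) {
        col <- col[!is.na(col)]
        if (!length(col)) NA_real_ else col[which.max(abs(col))]
      })
    }
  }
  out
}

#' Per-replicate pathway signature sums
#'
#' For one pathway, sums the representative values of its detected member
#' phosphoproteins in every run of the two classes. Members are the
#' intersection of the pathway's protein set with proteins fully observed
#' across the runs involved; `k` is the size of that intersection. Pathways
#' with `k < min_members` are filtered (returned as `NULL` sums).
#'
#' @param protein_matrix proteins x runs matrix from
#'   [protein_representative_values].
#' @param members character vector of the pathway's member proteins.
#' @param runs_c1,runs_c2 column names of the replicate runs in the test and
#'   reference class.
#' @param cfg an [activity_config].
#' @return List with `k`, `members` (detected), and `P_c1`, `P_c2`
#'   (per-replicate sums; `NULL` when filtered).
#' @export
pathway_replicate_level <- function(protein_matrix, members,
                                    runs_c1, runs_c2,
                                    cfg = activity_config()) {
  runs <- c(runs_c1, runs_c2)
  present <- intersect(members, rownames(protein_matrix))
  if (length(present)) {
    sub <- protein_matrix[present, runs, drop = FALSE]
    complete <- rowSums(is.na(sub)) == 0L
    present <- present[complete]
  }
  k <- length(present)
  if (k < cfg$min_members)
    return(list(k = k, members = present, P_c1 = NULL, P_c2 = NULL))
  sums <- colSums(protein_matrix[present, runs, drop = FALSE])
  list(k = k, members = present,
       P_c1 = sums[runs_c1], P_c2 = sums[runs_c2])
}

#' Pathway activity score
#'
#' Signed t-type statistic discriminating the pathway's summed signature
#' levels between two classes (Welch form, sample standard deviations):
#' \deqn{a_p = \frac{\bar P_{c_1} - \bar P_{c_2}}
#'   {\sqrt{\rho_{c_1}^2 / n_{c_1} + \rho_{c_2}^2 / n_{c_2} + \epsilon}}}
#' Positive scores mean higher pathway-signature phosphorylation in the
#' test class.
#'
#' @param P_c1,P_c2 per-replicate pathway sums for the test and reference
#'   class (length >= 2 each).
#' @param epsilon variance floor (default 0).
#' @return The scalar activity score.
#' @export
activity_score <- function(P_c1, P_c2, epsilon = 0) {
  if (length(P_c1) < 2L || length(P_c2) < 2L)
    stop("activity score needs >= 2 replicates per class")
  denom2 <- stats::var(P_c1) / length(P_c1) +
    stats::var(P_c2) / length(P_c2) + epsilon
  if (denom2 == 0) stop("zero pooled variance; set epsilon > 0")
  (mean(P_c1) - mean(P_c2)) / sqrt(denom2)
}

#' Score every pathway across comparisons
#'
#' Runs the full activity analysis: protein representative values from
#' normalized log2 phosphopeptide levels, per-replicate pathway sums,
#' member filtering (`k >= min_members`), and the signed activity score for
#' each comparison. The number of regulated members (any phosphopeptide of
#' the protein beyond the two-fold rule in that comparison) is reported
#' alongside.
#'
#' @param x a normalized [quant_table]; levels are log2-transformed
#'   internally.
#' @param pathways a `pathway_collection`.
#' @param comparison_list list of [comparison_spec].
#' @param cfg an [activity_config].
#' @param qc a [qc_config] used for the regulated-member count.
#' @return Data frame, one row per (pathway, comparison) for pathways
#'   passing the member filter, ranked by descending score within each
#'   comparison: `pathway_id`, `name`, `comparison`, `k`,
#'   `n_regulated_members`, `a_p`. Filtered pathways are listed in the
#'   `"filtered"` attribute with their `k`.
#' @export
score_all_pathways <- function(x, pathways, comparison_list,
                               cfg = activity_config(), qc = qc_config()) {
  stopifnot(inherits(x, "quant_table"))
  if (inherits(comparison_list, "comparison_spec"))
    comparison_list <- list(comparison_list)
  ab <- x$abundance
  keep <- if (!is.na(x$standard_id))
    x$peptides$peptide_id != x$standard_id else rep(TRUE, nrow(ab))
  levels_log2 <- log2(ab[keep, , drop = FALSE])
  proteins <- x$peptides$protein[keep]
  # regulated-member counts reuse the ratio/call machinery
  summ <- summarize_replicates(x, qc)
  desc <- attr(pathways, "description")
  rows <- list(); filtered <- list()
  for (cmp in comparison_list) {
    runs_c1 <- x$runs$run_id[x$runs$cell_line == cmp$test]
    runs_c2 <- x$runs$run_id[x$runs$cell_line == cmp$reference]
    if (!length(runs_c1) || !length(runs_c2))
      stop("no runs for comparison ", cmp$label)
    pm <- protein_representative_values(levels_log2, proteins,
                                        aggregate = cfg$aggregate)
    rt <- log2_ratio_table(summ, list(cmp))
    calls <- call_regulation(ratio_matrix(rt)[, 1L], cmp$threshold)
    reg_prot <- unique(rt$protein[calls %in% c("up", "down")])
    for (pid in names(pathways)) {
      lev <- pathway_replicate_level(pm, pathways[[pid]],
                                     runs_c1, runs_c2, cfg)
      if (is.null(lev$P_c1)) {
        filtered[[length(filtered) + 1L]] <-
          data.frame(pathway_id = pid, comparison = cmp$label, k = lev$k,
                     stringsAsFactors = FALSE)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        pathway_id = pid,
        name = unname(desc[pid]),
        comparison = cmp$label,
        k = lev$k,
        n_regulated_members = length(intersect(lev$members, reg_prot)),
        a_p = activity_score(lev$P_c1, lev$P_c2, cfg$epsilon),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pathway_id = character(), name = character(),
               comparison = character(), k = integer(),
               n_regulated_members = integer(), a_p = numeric())
  res <- res[order(res$comparison, -res$a_p), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "filtered") <- if (length(filtered)) do.call(rbind, filtered) else
    data.frame(pathway_id = character(), comparison = character(),
               k = integer())
  res
}
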