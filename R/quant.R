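#' Specify a pairwise cell-line comparison
#'
#' @param test test-class cell line label (e.g. `"3KTR"`).
#' @param reference reference-class cell line label (e.g. `"3KT"`).
#' @param threshold regulation threshold in log2 units; the default 1.0
#'   corresponds to the two-fold rule (|log2 ratio| >= 1 is regulated).
#' @return A `comparison_spec`.
#' @export
comparison_spec <- function(test, reference, threshold = 1.0) {
  stopifnot(is.character(test), is.character(reference),
            test != reference)
  if (!is.numeric(threshold) || threshold <= 0)
    stop("regulation threshold must be > 0")
  structure(list(test = test, reference = reference, threshold = threshold,
                 label = paste0(test, "/", reference)),
            class = "comparison_spec")
}

#' QC configuration for replicate summarization
#'
#' @param cv_threshold coefficient-of-variation cutoff flagging noisy
#'   triplicates; default 0.20 (20\% CV).
#' @param min_detected_replicates minimum detected replicates for a
#'   (peptide, cell line) mean to be reported; default 2 (of 3 runs).
#' @return A `qc_config`.
#' @export
qc_config <- function(cv_threshold = 0.20, min_detected_replicates = 2L) {
  if (!(cv_threshold > 0 && cv_threshold < 1))
    stop("cv_threshold must be in (0, 1)")
  if (min_detected_replicates < 1L)
    stop("min_detected_replicates must be >= 1")
  structure(list(cv_threshold = cv_threshold,
                 min_detected_replicates = as.integer(min_detected_replicates)),
            class = "qc_config")
}

#' Normalize abundances against the internal-standard peptide
#'
#' Each run's abundances are divided by the abundance of the spiked
#' internal-standard peptide (beta-casein) in that same run, cancelling
#' run-to-run multiplicative intensity differences. The standard row itself
#' becomes all-1.
#'
#' @param x a [quant_table] with a designated standard row.
#' @return A [quant_table] of normalized abundances.
#' @export
normalize_to_standard <- function(x) {
  stopifnot(inherits(x, "quant_table"))
  if (is.na(x$standard_id))
    stop("quant table has no internal-standard row")
  std <- x$abundance[x$peptides$peptide_id == x$standard_id, ]
  bad <- is.na(std) | std <= 0
  if (any(bad))
    stop("internal standard missing or non-positive in run(s): ",
         paste(x$runs$run_id[bad], collapse = ", "))
  x$abundance <- sweep(x$abundance, 2L, std, "/")
  x
}

#' Coefficient of variation across replicate runs
#'
#' Sample standard deviation divided by the mean of the detected values.
#'
#' @param values numeric vector of per-replicate abundances; `NA` = not
#'   detected.
#' @return CV as a fraction (0.10 = 10\%).
#' @export
replicate_cv <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2L) stop("CV requires >= 2 detected values")
  m <- mean(v)
  if (m == 0) stop("CV undefined for zero mean")
  stats::sd(v) / m
}

#' Summarize replicate runs per cell line
#'
#' For each (peptide, cell line), the mean over detected replicates is
#' reported when at least `min_detected_replicates` runs detected the
#' peptide; otherwise the cell is missing. A per-cell CV and a QC flag
#' (`cv <= cv_threshold`) accompany the means.
#'
#' @param x a normalized [quant_table].
#' @param qc a [qc_config].
#' @return A `quant_summary`: list with `mean`, `cv`, `n_detected`,
#'   `cv_ok` matrices (peptides x cell lines), `peptides`, `standard_id`,
#'   `qc`.
#' @export
summarize_replicates <- function(x, qc = qc_config()) {
  stopifnot(inherits(x, "quant_table"), inherits(qc, "qc_config"))
  lines <- unique(x$runs$cell_line)
  np <- nrow(x$abundance)
  mk <- function() matrix(NA_real_, np, length(lines),
                          dimnames = list(rownames(x$abundance), lines))
  mean_m <- mk(); cv_m <- mk()
  n_det <- matrix(0L, np, length(lines),
                  dimnames = list(rownames(x$abundance), lines))
  for (cl in lines) {
    cols <- x$runs$run_id[x$runs$cell_line == cl]
    sub <- x$abundance[, cols, drop = FALSE]
    n <- rowSums(!is.na(sub))
    n_det[, cl] <- n
    keep <- n >= qc$min_detected_replicates
    mean_m[keep, cl] <- rowMeans(sub[keep, , drop = FALSE], na.rm = TRUE)
    has_cv <- n >= 2L & keep
    if (any(has_cv)) {
      sd_v <- apply(sub[has_cv, , drop = FALSE], 1L, stats::sd, na.rm = TRUE)
      cv_m[has_cv, cl] <- sd_v / mean_m[has_cv, cl]
    }
  }
  structure(list(mean = mean_m, cv = cv_m, n_detected = n_det,
                 cv_ok = cv_m <= qc$cv_threshold,
                 peptides = x$peptides, standard_id = x$standard_id,
                 qc = qc),
            class = "quant_summary")
}

#' Log2-ratio table across comparisons
#'
#' For each comparison `test/reference`, `log2(mean_test / mean_reference)`
#' where both cell-line means are present; `+9999` when detected in the test
#' class only, `-9999` in the reference class only, `NaN` in neither.
#'
#' @param summary a [summarize_replicates] result.
#' @param comparisons list of [comparison_spec].
#' @param drop_standard drop the internal-standard row (default `TRUE`).
#' @return A [ratio_table].
#' @export
log2_ratio_table <- function(summary, comparisons, drop_standard = TRUE) {
  stopifnot(inherits(summary, "quant_summary"))
  if (inherits(comparisons, "comparison_spec"))
    comparisons <- list(comparisons)
  m <- summary$mean
  cols <- lapply(comparisons, function(cmp) {
    for (cl in c(cmp$test, cmp$reference))
      if (!cl %in% colnames(m)) stop("unknown cell line in comparison: ", cl)
    te <- m[, cmp$test]; re <- m[, cmp$reference]
    out <- rep(NaN, nrow(m))
    both <- !is.na(te) & !is.na(re)
    out[both] <- log2(te[both] / re[both])
    out[!is.na(te) & is.na(re)] <- SENTINEL_TEST_ONLY
    out[is.na(te) & !is.na(re)] <- SENTINEL_REF_ONLY
    out
  })
  rm_ <- do.call(cbind, cols)
  colnames(rm_) <- vapply(comparisons, `[[`, "", "label")
  meta <- summary$peptides
  if (drop_standard && !is.na(summary$standard_id)) {
    keep <- meta$peptide_id != summary$standard_id
    meta <- meta[keep, , drop = FALSE]
    rm_ <- rm_[keep, , drop = FALSE]
  }
  ratio_table(meta, rm_)
}

#' Log-center ratios per comparison
#'
#' Shifts the non-sentinel log2 ratios of each comparison so that their
#' center (mean by default, optionally median) is zero, removing any residual
#' global offset between the classes. Sentinels are untouched.
#'
#' @param x a [ratio_table].
#' @param center `"mean"` or `"median"`.
#' @return A centered [ratio_table].
#' @export
center_ratios <- function(x, center = c("mean", "median")) {
  center <- match.arg(center)
  fun <- if (center == "mean") mean else stats::median
  m <- ratio_matrix(x)
  for (j in seq_len(ncol(m))) {
    ok <- !is_sentinel(m[, j]) & !is.na(m[, j])
    if (!any(ok))
      stop("comparison ", colnames(m)[j], " has no quantifiable ratios")
    m[ok, j] <- m[ok, j] - fun(m[ok, j])
  }
  meta_cols <- setdiff(names(x), comparisons(x))
  ratio_table(as.data.frame(x)[meta_cols], m)
}

#' Regulation call levels
#' @export
REGULATION_LEVELS <- c("up", "down", "unchanged",
                       "test_only", "reference_only", "not_quantified")

#' Call regulation from log2 ratios
#'
#' The two-fold rule: `up` when ratio >= threshold, `down` when
#' ratio <= -threshold, `unchanged` otherwise (threshold 1.0 log2 unit by
#' default). Sentinels map to `test_only` / `reference_only` /
#' `not_quantified`; a sentinel never supports a directional call.
#'
#' @param ratio numeric vector of ratio-table entries.
#' @param threshold regulation threshold in log2 units (> 0).
#' @return Factor with levels [REGULATION_LEVELS].
#' @export
call_regulation <- function(ratio, threshold = 1.0) {
  if (threshold <= 0) stop("threshold must be > 0")
  out <- rep("unchanged", length(ratio))
  out[is.nan(ratio) | is.na(ratio)] <- "not_quantified"
  sent_hi <- !is.na(ratio) & ratio == SENTINEL_TEST_ONLY
  sent_lo <- !is.na(ratio) & ratio == SENTINEL_REF_ONLY
  out[sent_hi] <- "test_only"
  out[sent_lo] <- "reference_only"
  reg <- !is.na(ratio) & !sent_hi & !sent_lo & !is.nan(ratio)
  out[reg & ratio >= threshold] <- "up"
  out[reg & ratio <= -threshold] <- "down"
  factor(out, levels = REGULATION_LEVELS)
}

#' Regulation calls for every entry of a ratio table
#'
#' @param x a [ratio_table].
#' @param threshold regulation threshold in log2 units.
#' @return Data frame shaped like `x` with call factors in the comparison
#'   columns.
#' @export
call_regulation_table <- function(x, threshold = 1.0) {
  m <- ratio_matrix(x)
  calls <- as.data.frame(lapply(as.data.frame(m, check.names = FALSE),
                                call_regulation, threshold = threshold),
                         check.names = FALSE)
  meta_cols <- setdiff(names(x), comparisons(x))
  cbind(as.data.frame(x)[meta_cols], calls)
}

#' Direction-aware concurrence filter across cell lines
#'
#' Identifies proteins regulated in the same direction across a required set
#' of comparisons while *not* concurrently regulated in an excluded set. A
#' protein qualifies when at least one of its phosphosites is called `up`
#' (or `down`) in every `require` comparison with one common direction, and
#' in every `exclude` comparison that site is unchanged, regulated in the
#' opposite direction, or sentinel-coded (a sentinel counts as
#' non-concurrent, never as support for a direction).
#'
#' @param x a [ratio_table].
#' @param require comparison labels that must agree in direction.
#' @param exclude comparison labels that must not share that direction.
#' @param threshold regulation threshold in log2 units.
#' @param by metadata column identifying the protein (default `"gene"`).
#' @return Data frame with one row per qualifying protein: `protein` (the
#'   `by` value), `direction` (`"up"`/`"down"`), `n_sites` (qualifying site
#'   rows). The per-site qualification table is attached as attribute
#'   `"sites"`.
#' @export
concurrent_regulation <- function(x, require, exclude = character(),
                                  threshold = 1.0, by = "gene") {
  comp <- comparisons(x)
  unknown <- setdiff(c(require, exclude), comp)
  if (length(unknown))
    stop("unknown comparison label(s): ", paste(unknown, collapse = ", "))
  if (length(require) == 0L) stop("at least one 'require' comparison needed")
  calls <- call_regulation_table(x, threshold = threshold)
  req <- as.matrix(as.data.frame(lapply(calls[require], as.character),
                                 check.names = FALSE))
  exc <- if (length(exclude))
    as.matrix(as.data.frame(lapply(calls[exclude], as.character),
                            check.names = FALSE))
  else matrix(character(), nrow(calls), 0L)
  qualifies <- function(dir) {
    all_req <- apply(req == dir, 1L, all)
    none_exc <- if (ncol(exc)) apply(exc != dir, 1L, all) else TRUE
    all_req & none_exc
  }
  up <- qualifies("up"); down <- qualifies("down")
  sites <- data.frame(
    protein = calls[[by]],
    sites = calls$sites,
    direction = ifelse(up, "up", ifelse(down, "down", NA_character_)),
    stringsAsFactors = FALSE)
  hit <- sites[!is.na(sites$direction), , drop = FALSE]
  agg <- if (nrow(hit)) {
    sp <- split(hit, paste(hit$protein, hit$direction, sep = "\r"))
    do.call(rbind, lapply(sp, function(d) data.frame(
      protein = d$protein[1], direction = d$direction[1],
      n_sites = nrow(d), stringsAsFactors = FALSE)))
  } else data.frame(protein = character(), direction = character(),
                    n_sites = integer())
  agg <- agg[order(agg$direction, agg$protein), , drop = FALSE]
  rownames(agg) <- NULL
  structure(agg, sites = hit)
}
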