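## Log2-ratio tables with sentinel codes for class-exclusive detection.
##
## Coding scheme, matching label-free practice when a peptide is quantifiable
## in only one member of a pair:
##   finite value  log2(test / reference)
##   +9999         detected in the test class only
##   -9999         detected in the reference class only
##   NaN           detected in neither class

#' Sentinel codes used in ratio tables
#'
#' `SENTINEL_TEST_ONLY` (+9999) marks peptides detected only in the test
#' class of a comparison; `SENTINEL_REF_ONLY` (-9999) only in the reference
#' class. Peptides detected in neither class carry `NaN`.
#' @export
SENTINEL_TEST_ONLY <- 9999

#' @rdname SENTINEL_TEST_ONLY
#' @export
SENTINEL_REF_ONLY <- -9999

#' Is a ratio entry a sentinel code?
#' @param x numeric vector of ratio entries.
#' @return Logical vector; `TRUE` for +9999, -9999 and NaN entries.
#' @export
is_sentinel <- function(x) {
  is.nan(x) | (!is.na(x) & (x == SENTINEL_TEST_ONLY | x == SENTINEL_REF_ONLY))
}

#' Construct a log2-ratio table
#'
#' @param meta data.frame of peptide metadata with at least `peptide_id`,
#'   `protein`, `gene`, `sequence`, `sites`.
#' @param ratios numeric matrix, peptides x comparisons; columns named
#'   `"<test>/<reference>"`; entries are finite log2 ratios or sentinels.
#' @return A `ratio_table` (data.frame subclass with a `comparisons`
#'   attribute naming the ratio columns).
#' @export
ratio_table <- function(meta, ratios) {
  ratios <- as.matrix(ratios)
  stopifnot(nrow(meta) == nrow(ratios), !is.null(colnames(ratios)))
  bad <- !is.na(ratios) & !is_sentinel(ratios) & !is.finite(ratios)
  if (any(bad)) stop("non-sentinel ratio entries must be finite")
  out <- cbind(meta, as.data.frame(ratios, check.names = FALSE))
  rownames(out) <- NULL
  structure(out, comparisons = colnames(ratios),
            class = c("ratio_table", "data.frame"))
}

#' Comparison columns of a ratio table
#' @param x a `ratio_table`.
#' @return Character vector of comparison labels (`"<test>/<reference>"`).
#' @export
comparisons <- function(x) attr(x, "comparisons")

ratio_matrix <- function(x) {
  as.matrix(as.data.frame(x)[, comparisons(x), drop = FALSE])
}

#' Write / read a ratio table as TSV
#'
#' Sentinels are written literally as `9999`, `-9999` and `NaN`; comparison
#' column names keep their `test/reference` labels.
#'
#' @param x a [ratio_table].
#' @param path file path.
#' @return `write_ratio_table`: `path`, invisibly. `read_ratio_table`: a
#'   [ratio_table].
#' @export
write_ratio_table <- function(x, path) {
  df <- as.data.frame(x)
  # 17 significant digits so write -> read round-trips doubles exactly
  for (cmp in comparisons(x))
    df[[cmp]] <- ifelse(is.nan(df[[cmp]]), "NaN",
                        sprintf("%.17g", df[[cmp]]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "NaN",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_ratio_table
#' @param meta_cols column names treated as metadata; all other columns are
#'   comparisons.
#' @export
read_ratio_table <- function(path,
                             meta_cols = c("peptide_id", "protein", "gene",
                                           "sequence", "sites")) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(meta_cols, names(df))
  if (length(miss)) stop("missing metadata columns: ",
                         paste(miss, collapse = ", "))
  comp <- setdiff(names(df), meta_cols)
  m <- as.matrix(df[comp])
  m[is.na(m)] <- NaN
  ratio_table(df[meta_cols], m)
}

#' Bundled fixture: concurrently Ras-regulated phosphorylation events
#'
#' A curated set of 19 phosphopeptide log2 ratios from a published label-free
#' phosphoproteomics comparison of KRAS(V12)-transformed immortalized human
#' bronchial epithelial cells (3KTR) and three NSCLC lines (A549, H322,
#' H1299), each against the untransformed 3KT parent line. These are the
#' phosphorylation events found regulated two-fold upon Ras transformation
#' and concurrently regulated in the two adenocarcinoma lines but not in the
#' large-cell carcinoma line; `-9999` marks peptides detected in 3KT but not
#' in H1299. Phosphorylated residues are lowercase in the peptide sequence.
#'
#' @return A [ratio_table] with comparisons `3KTR/3KT`, `A549/3KT`,
#'   `H322/3KT`, `H1299/3KT`.
#' @export
load_ras_phospho_fixture <- function() {
  path <- system.file("extdata", "ras_phospho_ratios.tsv",
                      package = "phosflow", mustWork = TRUE)
  read_ratio_table(path)
}
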