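#' Construct a phosphopeptide quantitation table
#'
#' A `quant_table` holds run-level phosphopeptide abundances across a panel of
#' cell lines measured in replicate LC-MS/MS runs, together with peptide
#' metadata and the identity of the spiked internal-standard peptide used for
#' run-to-run normalization.
#'
#' Phosphorylated residues are marked by lowercase `s`/`t`/`y` inside
#' `peptides$sequence`; all other residues are uppercase. Site labels
#' (e.g. `"S392"`) give the phosphorylated residue and its 1-based position on
#' the parent protein. Multiply phosphorylated peptides are carried as single
#' rows with `;`-separated site labels.
#'
#' @param abundance numeric matrix, peptides x runs; `NA` marks a peptide not
#'   detected in that run. Values must be nonnegative.
#' @param peptides data.frame with columns `peptide_id`, `protein`, `gene`,
#'   `sequence`, `sites`; one row per abundance-matrix row.
#' @param runs data.frame with columns `run_id`, `cell_line`, `replicate`;
#'   one row per abundance-matrix column. Run ids must be unique.
#' @param standard_id peptide_id of the internal-standard row, or `NA` if the
#'   table carries no standard (normalization then unavailable).
#' @return An object of class `quant_table`.
#' @export
quant_table <- function(abundance, peptides, runs, standard_id = NA_character_) {
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  stopifnot(is.data.frame(peptides), is.data.frame(runs))
  req_pep <- c("peptide_id", "protein", "gene", "sequence", "sites")
  if (!all(req_pep %in% names(peptides)))
    stop("peptides must have columns: ", paste(req_pep, collapse = ", "))
  req_run <- c("run_id", "cell_line", "replicate")
  if (!all(req_run %in% names(runs)))
    stop("runs must have columns: ", paste(req_run, collapse = ", "))
  if (nrow(peptides) != nrow(abundance))
    stop("peptides rows must match abundance rows")
  if (nrow(runs) != ncol(abundance))
    stop("runs rows must match abundance columns")
  if (anyDuplicated(runs$run_id))
    stop("duplicate run ids: ",
         paste(unique(runs$run_id[duplicated(runs$run_id)]), collapse = ", "))
  if (anyDuplicated(peptides$peptide_id))
    stop("duplicate peptide ids")
  if (any(abundance < 0, na.rm = TRUE))
    stop("negative abundance values are not allowed")
  if (!is.na(standard_id) && sum(peptides$peptide_id == standard_id) != 1L)
    stop("standard_id '", standard_id, "' must match exactly one peptide row")
  rownames(abundance) <- peptides$peptide_id
  colnames(abundance) <- runs$run_id
  structure(
    list(abundance = abundance, peptides = peptides, runs = runs,
         standard_id = standard_id),
    class = "quant_table")
}

#' @export
print.quant_table <- function(x, ...) {
  cat("quant_table: ", nrow(x$abundance), " phosphopeptides x ",
      ncol(x$abundance), " runs (",
      length(unique(x$runs$cell_line)), " cell lines)\n", sep = "")
  if (!is.na(x$standard_id))
    cat("internal standard: ", x$standard_id, "\n", sep = "")
  invisible(x)
}

#' @export
dim.quant_table <- function(x) dim(x$abundance)

#' Read a phosphopeptide quantitation table from TSV
#'
#' The on-disk dialect is tab-delimited UTF-8 with a header row. Metadata
#' columns `peptide_id`, `protein`, `gene`, `sequence`, `sites`,
#' `is_standard` come first; every remaining column is one LC-MS/MS run named
#' `<cell_line>_r<replicate>`. Missing abundances are empty cells, never 0
#' (a zero would silently corrupt CVs and ratios downstream).
#'
#' @param path file path.
#' @param require_standard error when no row is flagged as internal standard
#'   (default `TRUE`; set `FALSE` for tables analyzed without normalization).
#' @return A [quant_table].
#' @export
read_quant_table <- function(path, require_standard = TRUE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "", colClasses = "character")
  meta_cols <- c("peptide_id", "protein", "gene", "sequence", "sites",
                 "is_standard")
  if (!all(meta_cols %in% names(df)))
    stop("quant table must have columns: ", paste(meta_cols, collapse = ", "))
  run_cols <- setdiff(names(df), meta_cols)
  if (length(run_cols) == 0L) stop("no run columns found")
  ab <- sapply(df[run_cols], function(v) suppressWarnings(as.numeric(v)))
  ab <- matrix(ab, nrow = nrow(df), dimnames = list(NULL, run_cols))
  bad <- !is.na(ab) & ab < 0
  if (any(bad)) stop("negative abundance in run ",
                     colnames(ab)[which(bad, arr.ind = TRUE)[1, 2]])
  is_std <- df$is_standard %in% c("1", "TRUE", "true", "yes")
  if (sum(is_std) > 1L) stop("more than one internal-standard row")
  if (require_standard && sum(is_std) == 0L)
    stop("no internal-standard row flagged (is_standard column)")
  std_id <- if (any(is_std)) df$peptide_id[is_std] else NA_character_
  runs <- parse_run_ids(run_cols)
  peptides <- df[c("peptide_id", "protein", "gene", "sequence", "sites")]
  quant_table(ab, peptides, runs, standard_id = std_id)
}

parse_run_ids <- function(run_cols) {
  m <- regmatches(run_cols, regexec("^(.*)_r([0-9]+)$", run_cols))
  cl <- vapply(m, function(x) if (length(x) == 3L) x[2] else NA_character_, "")
  rep <- vapply(m, function(x) if (length(x) == 3L) x[3] else NA_character_, "")
  if (anyNA(cl)) {
    # run ids without the <line>_r<k> shape: treat each run as its own line
    cl[is.na(cl)] <- run_cols[is.na(cl)]
    rep[is.na(rep)] <- "1"
  }
  data.frame(run_id = run_cols, cell_line = cl,
             replicate = as.integer(rep), stringsAsFactors = FALSE)
}

#' Write a quantitation table to TSV
#'
#' Inverse of [read_quant_table]; missing cells are written as empty strings.
#'
#' @param x a [quant_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(x, path) {
  stopifnot(inherits(x, "quant_table"))
  # 17 significant digits so write -> read round-trips doubles exactly
  ab <- apply(x$abundance, 2L, function(v)
    ifelse(is.na(v), NA_character_, sprintf("%.17g", v)))
  ab <- matrix(ab, nrow = nrow(x$abundance),
               dimnames = dimnames(x$abundance))
  out <- cbind(
    x$peptides[c("peptide_id", "protein", "gene", "sequence", "sites")],
    is_standard = as.integer(!is.na(x$standard_id) &
                               x$peptides$peptide_id == x$standard_id),
    as.data.frame(ab, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
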