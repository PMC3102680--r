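## Phosphosite sequence windows, kinase-motif classification, iterative
## binomial (motif-x style) enrichment, and kinase-subset frequency tests.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Extract a phosphosite sequence window
#'
#' Returns the 13-residue window (positions -6..+6) centered on a
#' phosphorylated S/T/Y, padded with `_` where the window runs past a
#' protein terminus.
#'
#' @param sequence protein amino-acid sequence.
#' @param position 1-based position of the phosphosite on the protein.
#' @param flank residues on each side of the site (default 6).
#' @return Character window of length `2 * flank + 1`.
#' @export
extract_window <- function(sequence, position, flank = 6L) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (position < 1L || position > n)
    stop("site position ", position, " outside sequence of length ", n)
  center <- substr(sequence, position, position)
  if (!center %in% c("S", "T", "Y"))
    stop("site residue must be S, T or Y; got '", center, "'")
  padded <- paste0(strrep("_", flank), sequence, strrep("_", flank))
  substr(padded, position, position + 2L * flank)
}

#' Windows from phospho-marked peptide sequences
#'
#' Peptide sequences carry lowercase `s`/`t`/`y` at phosphorylated residues.
#' One window is extracted per marked residue, centered on it and padded
#' with `_` beyond the peptide termini. Useful when full protein sequences
#' are not at hand and the peptide provides the local context.
#'
#' @param sequences character vector of phospho-marked peptide sequences.
#' @param flank residues on each side of the site (default 6).
#' @return Character vector of windows (possibly longer than `sequences`
#'   when peptides carry several sites), named by peptide index and site
#'   offset.
#' @export
peptide_windows <- function(sequences, flank = 6L) {
  out <- character(); nm <- character()
  for (i in seq_along(sequences)) {
    s <- sequences[[i]]
    chars <- strsplit(s, "")[[1]]
    pos <- which(chars %in% c("s", "t", "y"))
    for (p in pos) {
      out <- c(out, extract_window(toupper(s), p, flank))
      nm <- c(nm, paste0(i, ":", p))
    }
  }
  names(out) <- nm
  out
}

#' Kinase-motif classes
#' @export
MOTIF_CLASSES <- c("proline_directed", "basophilic", "acidophilic", "other")

#' Default motif-class rules
#'
#' Each class is a set of alternative patterns; a pattern is a set of
#' (offset, allowed residues) constraints relative to the phosphosite, all
#' of which must hold. Defaults encode the canonical kinase consensus
#' signatures: proline-directed `[pS/T]-P` (P at +1; MAPK/CDK/GSK-type),
#' basophilic `R-X-X-[pS]` (R at -3; PKA/PKC-type), and acidophilic
#' (acidic D/E at +1, or E at +3; CK2-type). The list order is the
#' precedence used to resolve windows matching several classes
#' (proline-directed > basophilic > acidophilic).
#'
#' @return Named list of classes, each a list of patterns; a pattern is a
#'   list of `list(offset =, residues =)` constraints.
#' @export
motif_rules <- function() {
  list(
    proline_directed = list(list(list(offset = 1L, residues = "P"))),
    basophilic = list(list(list(offset = -3L, residues = "R"))),
    acidophilic = list(list(list(offset = 1L, residues = c("D", "E"))),
                       list(list(offset = 3L, residues = "E")))
  )
}

window_residue <- function(windows, offset, flank = 6L) {
  substr(windows, flank + 1L + offset, flank + 1L + offset)
}

pattern_matches <- function(windows, pattern, flank = 6L) {
  ok <- rep(TRUE, length(windows))
  for (con in pattern)
    ok <- ok & window_residue(windows, con$offset, flank) %in% con$residues
  ok
}

#' Which motif classes does each window match?
#'
#' @param windows character vector of fixed-width windows.
#' @param rules class rules as from [motif_rules].
#' @param flank flank width of the windows.
#' @return Logical matrix, windows x classes (excluding `other`).
#' @export
motif_matches <- function(windows, rules = motif_rules(), flank = 6L) {
  m <- vapply(rules, function(patterns) {
    Reduce(`|`, lapply(patterns, pattern_matches,
                       windows = windows, flank = flank))
  }, logical(length(windows)))
  matrix(m, nrow = length(windows), ncol = length(rules),
         dimnames = list(NULL, names(rules)))
}

#' Assign a kinase-motif class to phosphosite windows
#'
#' Deterministic rule-based assignment by the precedence order of `rules`
#' (default proline-directed > basophilic > acidophilic > other); windows
#' matching no class are `other`.
#'
#' @inheritParams motif_matches
#' @return Factor with levels [MOTIF_CLASSES].
#' @export
classify_window <- function(windows, rules = motif_rules(), flank = 6L) {
  m <- motif_matches(windows, rules, flank)
  cls <- rep("other", length(windows))
  for (nm in rev(names(rules))) cls[m[, nm]] <- nm
  factor(cls, levels = c(names(rules), "other"))
}

#' Upper tail of the binomial distribution
#'
#' `P(X >= k)` for `X ~ Binomial(n, p)` — the significance of observing at
#' least `k` foreground matches given the background match frequency.
#'
#' @param k observed count.
#' @param n number of trials.
#' @param p success probability.
#' @return Tail probability.
#' @export
binom_tail <- function(k, n, p) {
  stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Configuration for iterative motif enrichment
#'
#' @param p_threshold binomial-tail significance required to fix a
#'   position/residue pair (default `1e-10`).
#' @param min_occurrences minimum foreground count for a candidate pair
#'   (default 20).
#' @param max_depth maximum constraints per motif (default 6).
#' @return An `enrichment_config`.
#' @export
enrichment_config <- function(p_threshold = 1e-10, min_occurrences = 20L,
                              max_depth = 6L) {
  if (!(p_threshold > 0 && p_threshold < 1))
    stop("p_threshold must be in (0, 1)")
  structure(list(p_threshold = p_threshold,
                 min_occurrences = as.integer(min_occurrences),
                 max_depth = as.integer(max_depth)),
            class = "enrichment_config")
}

motif_string <- function(constraints, flank = 6L) {
  chars <- rep(".", 2L * flank + 1L)
  chars[flank + 1L] <- "*"
  for (i in seq_len(nrow(constraints))) {
    res <- constraints$residues[[i]]
    chars[flank + 1L + constraints$offset[i]] <-
      if (length(res) > 1L) paste0("[", paste(res, collapse = ""), "]") else res
  }
  paste(chars, collapse = "")
}

grow_motif <- function(fg, bg, cfg, flank) {
  fixed <- data.frame(offset = integer(), residue = character(),
                      p = numeric(), fold = numeric(),
                      stringsAsFactors = FALSE)
  offsets <- setdiff(seq(-flank, flank), 0L)
  cur_fg <- fg; cur_bg <- bg
  while (nrow(fixed) < cfg$max_depth) {
    free <- setdiff(offsets, fixed$offset)
    best <- NULL
    for (off in free) {
      fg_res <- window_residue(cur_fg, off, flank)
      bg_res <- window_residue(cur_bg, off, flank)
      fg_tab <- table(factor(fg_res, levels = AA20))
      bg_tab <- table(factor(bg_res, levels = AA20))
      for (aa in AA20) {
        k <- fg_tab[[aa]]
        if (k < cfg$min_occurrences) next
        kb <- bg_tab[[aa]]
        if (kb == 0L) next   # background frequency not estimable
        p0 <- kb / length(cur_bg)
        if (p0 >= 1) next
        p <- binom_tail(k, length(cur_fg), p0)
        if (is.null(best) || p < best$p)
          best <- list(offset = off, residue = aa, p = p,
                       fold = (k / length(cur_fg)) / p0)
      }
    }
    if (is.null(best) || best$p >= cfg$p_threshold) break
    fixed <- rbind(fixed, data.frame(offset = best$offset,
                                     residue = best$residue,
                                     p = best$p, fold = best$fold,
                                     stringsAsFactors = FALSE))
    keep_fg <- window_residue(cur_fg, best$offset, flank) == best$residue
    keep_bg <- window_residue(cur_bg, best$offset, flank) == best$residue
    cur_fg <- cur_fg[keep_fg]; cur_bg <- cur_bg[keep_bg]
  }
  if (nrow(fixed) == 0L) return(NULL)
  list(constraints = fixed, fg = cur_fg, bg = cur_bg)
}

#' Iterative binomial motif enrichment
#'
#' Motif-x style extraction. A motif is grown by repeatedly scoring every
#' (position offset, residue) pair by the binomial tail probability of its
#' foreground count given the background frequency, fixing the most
#' significant pair while `p < p_threshold` and the count is at least
#' `min_occurrences`, and restricting both sets to matching windows. When a
#' motif can grow no further it is emitted, all windows matching it are
#' removed from the foreground and background, and extraction restarts, so
#' several disjoint motifs can be recovered. The background should contain
#' the plausible proteome context — by convention all quantified (not only
#' regulated) windows.
#'
#' @param foreground character vector of regulated-site windows.
#' @param background character vector of background windows.
#' @param cfg an [enrichment_config].
#' @param flank flank width of the windows (default 6).
#' @return Data frame of motifs, most significant first: `motif` (text form,
#'   `*` = phosphosite center), `p` (binomial tail at the motif's final
#'   fixation), `score` (sum of -log10 p over fixation steps), `fold`
#'   (foreground/background frequency ratio at final fixation),
#'   `fg_count`, `fg_size`; the per-step constraint tables are attached as
#'   list-column `constraints`.
#' @export
motifx_enrich <- function(foreground, background,
                          cfg = enrichment_config(), flank = 6L) {
  if (length(foreground) == 0L) stop("empty foreground")
  out <- list()
  fg <- foreground; bg <- background
  while (length(fg) > 0L) {
    m <- grow_motif(fg, bg, cfg, flank)
    if (is.null(m)) break
    cons <- m$constraints
    cons$residues <- as.list(cons$residue)
    out[[length(out) + 1L]] <- data.frame(
      motif = motif_string(cons, flank),
      p = cons$p[nrow(cons)],
      score = sum(-log10(pmax(cons$p, .Machine$double.xmin))),
      fold = cons$fold[nrow(cons)],
      fg_count = length(m$fg),
      fg_size = length(fg),
      stringsAsFactors = FALSE)
    attr(out[[length(out)]], "constraints") <- m$constraints
    pat <- lapply(seq_len(nrow(cons)), function(i)
      list(offset = cons$offset[i], residues = cons$residue[i]))
    drop_fg <- pattern_matches(fg, pat, flank)
    drop_bg <- pattern_matches(bg, pat, flank)
    fg <- fg[!drop_fg]; bg <- bg[!drop_bg]
  }
  if (length(out) == 0L)
    return(data.frame(motif = character(), p = numeric(), score = numeric(),
                      fold = numeric(), fg_count = integer(),
                      fg_size = integer()))
  cons_list <- lapply(out, attr, "constraints")
  res <- do.call(rbind, out)
  res$constraints <- cons_list
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Kinase-subset frequencies
#'
#' Counts and proportions of phosphosites per kinase-motif subset
#' (proline-directed, basophilic, acidophilic, other).
#'
#' @param classes factor/character vector of motif classes.
#' @return Data frame with `class`, `count`, `proportion`; proportions sum
#'   to 1.
#' @export
subset_frequencies <- function(classes) {
  if (length(classes) == 0L) stop("empty class list")
  f <- factor(as.character(classes), levels = MOTIF_CLASSES)
  if (anyNA(f)) stop("unknown motif class label")
  counts <- table(f)
  data.frame(class = MOTIF_CLASSES, count = as.integer(counts),
             proportion = as.numeric(counts) / length(classes),
             stringsAsFactors = FALSE)
}

#' Chi-square homogeneity test of two frequency vectors
#'
#' Pearson chi-square test (no continuity correction) that two cell lines
#' share the same distribution over kinase subsets, computed on the 2 x k
#' count table. Categories with zero pooled total are dropped before
#' testing.
#'
#' @param freq_a,freq_b count vectors of equal length.
#' @return List with `statistic`, `df`, `p.value`.
#' @export
homogeneity_test <- function(freq_a, freq_b) {
  if (length(freq_a) != length(freq_b))
    stop("count vectors must have equal length")
  if (sum(freq_a) == 0 || sum(freq_b) == 0)
    stop("all-zero count vector")
  keep <- (freq_a + freq_b) > 0
  tab <- rbind(freq_a[keep], freq_b[keep])
  if (ncol(tab) < 2L)
    return(list(statistic = 0, df = 0L, p.value = 1))
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}

#' Illustrative kinase families per motif subset
#'
#' A static lookup from motif class to the kinase families whose consensus
#' matches it. Illustrative only — no site-specific kinase prediction is
#' performed.
#'
#' @return Named list of character vectors.
#' @export
kinase_families <- function() {
  list(proline_directed = c("MAPK", "CDK", "GSK"),
       basophilic = c("PAK", "PKC", "PKA", "PKB/AKT", "DMPK", "CLK", "Pim"),
       acidophilic = c("CK2"),
       other = character())
}
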