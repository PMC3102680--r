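# Tiny in-code fixtures shared across tests.

# A minimal 5-line x 3-replicate quant table with a standard row and
# hand-set abundances; two peptides on the same protein.
tiny_quant <- function(lines = c("3KT", "3KTR"), replicates = 3L,
                       abundance = NULL) {
  runs <- data.frame(
    run_id = paste0(rep(lines, each = replicates), "_r",
                    rep(seq_len(replicates), length(lines))),
    cell_line = rep(lines, each = replicates),
    replicate = rep(seq_len(replicates), length(lines)),
    stringsAsFactors = FALSE)
  peptides <- data.frame(
    peptide_id = c("PEP1", "PEP2", "STD"),
    protein = c("PROT1", "PROT1", "P02666"),
    gene = c("G1", "G1", "CSN2"),
    sequence = c("AAAAAAsAAAAAA", "CCCCCCtPCCCCC", "FQsEEQQQTEDELQDK"),
    sites = c("S7", "T7", "S50"),
    stringsAsFactors = FALSE)
  if (is.null(abundance))
    abundance <- matrix(100, 3L, nrow(runs),
                        dimnames = list(peptides$peptide_id, runs$run_id))
  quant_table(abundance, peptides, runs, standard_id = "STD")
}

# build a window with given residues at offsets (default random-free "A")
make_test_window <- function(center = "S", ...) {
  spec <- list(...)
  chars <- rep("A", 13)
  chars[7] <- center
  for (nm in names(spec)) chars[7 + as.integer(nm)] <- spec[[nm]]
  paste(chars, collapse = "")
}

# exact-summation binomial upper tail, independent of stats::pbinom
binom_tail_oracle <- function(k, n, p) {
  if (k > n) return(0)
  i <- k:n
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}

# first-principles Pearson chi-square for a 2 x k table
chisq_oracle <- function(a, b) {
  tab <- rbind(a, b)
  keep <- colSums(tab) > 0
  tab <- tab[, keep, drop = FALSE]
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - exp_tab)^2 / exp_tab)
  df <- ncol(tab) - 1L
  list(statistic = stat, df = df, p.value = stats::pchisq(stat, df,
                                                          lower.tail = FALSE))
}
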