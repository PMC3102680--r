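test_that("window extraction pads termini and validates the site", {
  expect_equal(extract_window("MKSPR", 3), "____MKSPR____")
  seq20 <- "ABCDEFSHIJKLMNOPQRST"
  substr(seq20, 7, 7) <- "S"
  expect_equal(extract_window(seq20, 7), substr(seq20, 1, 13))
  expect_equal(nchar(extract_window(seq20, 7)), 13L)
  expect_error(extract_window("MKAPR", 3), "must be S, T or Y")
  expect_error(extract_window("MKSPR", 9), "outside sequence")
})

test_that("peptide windows center on lowercase phospho marks", {
  w <- peptide_windows("LSPsPTSQR")   # phospho-S at position 4
  expect_equal(unname(w), "___LSPSPTSQR_")
  expect_equal(classify_window(w), factor("proline_directed",
                                          levels = MOTIF_CLASSES))
  # two sites on one peptide give two windows
  expect_length(peptide_windows("AsAAAAtPAA"), 2L)
})

test_that("motif classification follows the precedence rule", {
  pro <- make_test_window("T", `1` = "P")
  baso <- make_test_window("S", `-3` = "R")
  acid1 <- make_test_window("S", `1` = "D")
  acid2 <- make_test_window("S", `3` = "E")
  both <- make_test_window("S", `-3` = "R", `1` = "P")
  other <- make_test_window("S")
  got <- classify_window(c(pro, baso, acid1, acid2, both, other))
  expect_equal(as.character(got),
               c("proline_directed", "basophilic", "acidophilic",
                 "acidophilic", "proline_directed", "other"))
  # secondary matches are still visible
  m <- motif_matches(both)
  expect_true(m[, "proline_directed"] && m[, "basophilic"])
})

test_that("binomial tails agree with an exact-summation oracle", {
  set.seed(23)
  cases <- data.frame(k = c(200, 150, 20, 1, 5),
                      n = c(200, 200, 100, 10, 5),
                      p = c(0.1, 0.5, 0.2, 0.01, 0.9))
  for (i in sample(1:50)) {
    n <- sample(5:300, 1); k <- sample(seq_len(n), 1)
    cases <- rbind(cases, data.frame(k = k, n = n, p = runif(1, 0.01, 0.99)))
  }
  for (i in seq_len(nrow(cases))) {
    got <- binom_tail(cases$k[i], cases$n[i], cases$p[i])
    want <- binom_tail_oracle(cases$k[i], cases$n[i], cases$p[i])
    expect_equal(got, want, tolerance = 1e-9)
  }
  # the k = n = 200, p = 0.1 corner is astronomically significant
  expect_equal(binom_tail(200, 200, 0.1), 0.1^200, tolerance = 1e-9)
})

test_that("iterative enrichment recovers planted motifs and only them", {
  set.seed(31)
  bg_pool <- replicate(2000, make_test_window("S"))
  # ~10% background P at +1 and a disjoint ~10% R at -3
  idx_p <- 1:200; idx_r <- 201:400
  bg_pool[idx_p] <- vapply(bg_pool[idx_p], function(w) {
    substr(w, 8, 8) <- "P"; w
  }, "")
  bg_pool[idx_r] <- vapply(bg_pool[idx_r], function(w) {
    substr(w, 4, 4) <- "R"; w
  }, "")

  # all-P foreground against the 10% background
  fg <- replicate(200, make_test_window("S", `1` = "P"))
  res <- motifx_enrich(fg, bg_pool)
  expect_equal(nrow(res), 1L)
  expect_equal(res$constraints[[1]]$offset, 1L)
  expect_equal(res$constraints[[1]]$residue, "P")
  expect_equal(res$p[1], 0.1^200, tolerance = 1e-6)

  # foreground drawn from the background itself finds nothing
  res0 <- motifx_enrich(sample(bg_pool, 300), bg_pool)
  expect_equal(nrow(res0), 0L)

  # two disjoint planted blocks are both extracted, most significant first
  fg2 <- c(replicate(100, make_test_window("S", `1` = "P")),
           replicate(100, make_test_window("S", `-3` = "R")))
  res2 <- motifx_enrich(fg2, bg_pool)
  expect_equal(nrow(res2), 2L)
  keys <- vapply(res2$constraints, function(d)
    paste0(d$offset[1], d$residue[1]), "")
  expect_setequal(keys, c("1P", "-3R"))
  expect_true(all(diff(res2$p) >= 0))

  expect_error(motifx_enrich(character(), bg_pool), "empty foreground")
})

test_that("enrichment on synthetic sites recovers the generator's motifs", {
  set.seed(43)
  sim <- simulate_dataset(sim_config(seed = 19, n_proteins = 400,
                                     peptides_per_protein = c(1L, 1L),
                                     motif_mix = c(proline_directed = 0.25,
                                                   basophilic = 0.25,
                                                   acidophilic = 0.10,
                                                   other = 0.40)))
  w <- sim$truth$windows
  cls <- sim$truth$site_class
  # 5x frequency advantage: foreground enriched for proline-directed sites
  fg <- c(w[cls == "proline_directed"], sample(w[cls == "other"], 20))
  res <- motifx_enrich(unname(fg), unname(w))
  expect_gt(nrow(res), 0L)
  expect_equal(res$constraints[[1]]$offset[1], 1L)
  expect_equal(res$constraints[[1]]$residue[1], "P")
  expect_true(all(res$p < 1e-10))
  # a null foreground sampled from all windows reports nothing
  res0 <- motifx_enrich(unname(sample(w, 200)), unname(w))
  expect_equal(nrow(res0), 0L)
})

test_that("subset frequencies count the four kinase classes", {
  f <- subset_frequencies(c("proline_directed", "proline_directed",
                            "basophilic", "other"))
  expect_equal(f$count, c(2L, 1L, 0L, 1L))
  expect_equal(sum(f$proportion), 1)
  f2 <- subset_frequencies(rep("proline_directed", 7))
  expect_equal(f2$proportion, c(1, 0, 0, 0))
  expect_error(subset_frequencies(character()), "empty")

  # the bundled Ras-regulated events are predominantly proline-directed
  rt <- load_ras_phospho_fixture()
  freq <- subset_frequencies(classify_window(peptide_windows(rt$sequence)))
  expect_equal(freq$class[which.max(freq$count)], "proline_directed")
  expect_gt(freq$proportion[freq$class == "proline_directed"], 0.5)
})

test_that("homogeneity test matches a first-principles chi-square", {
  same <- homogeneity_test(c(30, 10, 5, 5), c(30, 10, 5, 5))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  sep <- homogeneity_test(c(50, 0), c(0, 50))
  expect_equal(sep$statistic, 100)
  expect_equal(sep$df, 1L, ignore_attr = TRUE)
  expect_lt(sep$p.value, 1e-4)

  close <- homogeneity_test(c(30, 10), c(28, 12))
  expect_gt(close$p.value, 0.05)
  expect_equal(close$statistic, chisq_oracle(c(30, 10), c(28, 12))$statistic,
               tolerance = 1e-12)

  set.seed(37)
  for (i in 1:25) {
    a <- rpois(4, 20); b <- rpois(4, 15)
    if (sum(a) == 0 || sum(b) == 0) next
    got <- homogeneity_test(a, b)
    want <- chisq_oracle(a, b)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-12)
    expect_equal(got$p.value, want$p.value, tolerance = 1e-12)
  }

  # zero-total categories are dropped before testing
  z <- homogeneity_test(c(10, 0, 5), c(12, 0, 6))
  expect_equal(z$df, 1L, ignore_attr = TRUE)
  expect_error(homogeneity_test(c(0, 0), c(1, 2)), "all-zero")
})
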