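test_that("consensus reproduces every printed consensus row of the study tables", {
  # autosomal panel
  atab <- astr_table()
  expected_astr <- list(
    MN0104 = c(D13S317 = "9/11", D7S820 = "10/12", D2S1338 = "17/20",
               D21S11 = "29/29", D16S359 = "9/12", D18S51 = "12/13",
               CSF1PO = "11/12", FGA = "21/27"),
    MN0105 = c(D13S317 = "8/11", D7S820 = "11/12", D2S1338 = "23/23",
               D21S11 = "29/32.2", D16S359 = "9/12", D18S51 = "14/19",
               CSF1PO = "11/12", FGA = "24/26"),
    MN0125 = c(D13S317 = "8/9", D7S820 = "10/12", D2S1338 = "17/20",
               D21S11 = "29/33.2", D16S359 = "9/12", D18S51 = "12/13",
               CSF1PO = "11/12", FGA = "19/27"),
    MN0124 = c(D13S317 = "11/12", D7S820 = "8/8", D2S1338 = "17/23",
               D21S11 = "29/30", D16S359 = "9/12", D18S51 = "13/16",
               CSF1PO = "12/13", FGA = "23/24"),
    MN0376 = c(D13S317 = "12/12", D7S820 = "10/10", D2S1338 = "23/27",
               D21S11 = "31/32.2", D16S359 = "9/9", D18S51 = "13/24",
               CSF1PO = "9/12", FGA = "21/23"))
  for (s in names(expected_astr)) {
    cp <- call_consensus(atab, s, astr_loci())
    got <- stats::setNames(cp$consensus, cp$locus)
    expect_equal(got[names(expected_astr[[s]])], expected_astr[[s]], label = s)
  }
  # the single ambiguous cell: a one-one tie between genotypes sharing an allele
  cp126 <- call_consensus(atab, "MN0126", astr_loci())
  d21 <- which(cp126$locus == "D21S11")
  expect_true(is.na(cp126$consensus[d21]))
  expect_setequal(cp126$candidates[[d21]], c("30/30", "30/33.2"))
  expect_true(cp126$discordant[d21])
  rest <- stats::setNames(cp126$consensus, cp126$locus)[
    c("D13S317", "D7S820", "D2S1338", "D16S359", "D18S51", "CSF1PO", "FGA")]
  expect_equal(unname(rest), c("8/9", "12/12", "20/24", "9/11", "12/16",
                               "11/12", "19/22"))
  # Y-STR consensus rows, including the 8/13-vs-13 majority at YGATAH4
  ytab <- ystr_table()
  cp376 <- call_consensus(ytab, "MN0376")
  got <- stats::setNames(cp376$consensus, cp376$locus)
  expect_equal(unname(got["YGATAH4"]), "13")
  expect_true(cp376$discordant[cp376$locus == "YGATAH4"])
  cp104 <- call_consensus(ytab, "MN0104")
  expect_false(any(cp104$discordant))
  expect_equal(unname(stats::setNames(cp104$consensus, cp104$locus)["DYS385"]),
               "13/17")
})

test_that("a majority over a dissenting replicate is kept but flagged discordant", {
  atab <- astr_table()
  cp <- call_consensus(atab, "MN0104", astr_loci())
  i <- which(cp$locus == "CSF1PO")
  expect_equal(cp$consensus[i], "11/12")
  expect_true(cp$discordant[i])
  expect_equal(cp$n_support[i], 2L)
  expect_equal(cp$n_success[i], 3L)
})

test_that("discordance accounting over the full table gives 5 of 48 cells", {
  disc <- count_discordances(astr_table(), astr_loci())
  expect_equal(disc$total_cells, 48)
  expect_equal(disc$discordant_cells, 5)
  flagged <- which(disc$flags, arr.ind = TRUE)
  got <- paste(rownames(disc$flags)[flagged[, 1]],
               colnames(disc$flags)[flagged[, 2]])
  expect_setequal(got, c("MN0104 CSF1PO", "MN0105 D21S11", "MN0126 D21S11",
                         "MN0124 D16S359", "MN0124 D18S51"))
})

test_that("replicate order never changes the consensus", {
  atab <- astr_table()
  set.seed(99)
  perm <- atab[sample(nrow(atab)), , drop = FALSE]
  attr(perm, "loci") <- attr(atab, "loci")
  class(perm) <- class(atab)
  for (s in unique(atab$sample)) {
    a <- call_consensus(atab, s, astr_loci())
    b <- call_consensus(perm, s, astr_loci())
    expect_equal(a$consensus, b$consensus, label = s)
    expect_equal(a$discordant, b$discordant, label = s)
  }
})

test_that("planted conflicts are recounted exactly (brute-force oracle)", {
  set.seed(7)
  loci <- paste0("L", 1:6)
  for (rep_i in 1:20) {
    n_samp <- sample(2:4, 1)
    rows <- list()
    for (s in seq_len(n_samp)) {
      base <- vapply(loci, function(l)
        format_genotype(sort(sample(8:15, 2, replace = TRUE))), character(1))
      for (r in 1:3) {
        call <- base
        miss <- stats::runif(length(loci)) < 0.15
        call[miss] <- "-"
        rows[[length(rows) + 1L]] <- c(sample = paste0("S", s), replicate = r, call)
      }
    }
    tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    # plant conflicts: flip one replicate call in a few random cells
    n_plant <- sample(0:5, 1)
    for (k in seq_len(n_plant)) {
      i <- sample(nrow(tab), 1); l <- sample(loci, 1)
      tab[i, l] <- "6/7"   # allele values outside the generating range
    }
    attr(tab, "loci") <- loci
    class(tab) <- c("replicate_table", class(tab))
    got <- count_discordances(tab, loci)
    # independent recount: a cell is discordant iff its successful calls
    # (allele-sorted) are not all equal
    oracle <- 0L
    for (s in unique(tab$sample)) for (l in loci) {
      calls <- tab[[l]][tab$sample == s]
      calls <- calls[calls != "-"]
      norm <- vapply(parse_genotype(calls), function(g)
        paste(g, collapse = "/"), character(1))
      if (length(norm) > 0 && length(unique(norm)) > 1) oracle <- oracle + 1L
    }
    expect_equal(got$discordant_cells, oracle, label = paste("table", rep_i))
  }
})

test_that("consensus alleles never leave the union of replicate alleles", {
  set.seed(17)
  for (i in 1:200) {
    calls <- replicate(3, format_genotype(sort(sample(8:12, 2, replace = TRUE))))
    if (stats::runif(1) < 0.3) calls[sample(3, 1)] <- "-"
    tab <- data.frame(sample = "s", replicate = 1:3, L1 = calls,
                      stringsAsFactors = FALSE)
    attr(tab, "loci") <- "L1"
    class(tab) <- c("replicate_table", class(tab))
    cp <- call_consensus(tab, "s")
    pool <- unlist(parse_genotype(calls))
    cons <- unlist(parse_genotype(c(cp$consensus[!is.na(cp$consensus)],
                                    unlist(cp$candidates))))
    expect_true(all(cons %in% pool))
  }
})

test_that("consensus recovery under allelic dropout matches the binomial enumeration", {
  # truth: heterozygote; 3 replicates; dropout d turns a replicate into an
  # apparent homozygote. Consensus (strict majority of successful calls,
  # min_count 2) recovers the truth iff >= 2 replicates stay intact.
  d <- 0.3
  n_sim <- 2000
  truth <- c(10, 12)
  nm <- noise_model(allelic_dropout = d)
  hits <- 0L
  set.seed(31)
  seeds <- sample.int(1e6, n_sim)
  for (i in seq_len(n_sim)) {
    tab <- simulate_replicates(list(L1 = truth), nm, 3, seed = seeds[i])
    cp <- call_consensus(tab, "sim")
    if (!is.na(cp$consensus[1]) && cp$consensus[1] == "10/12") hits <- hits + 1L
  }
  p_analytic <- sum(stats::dbinom(2:3, 3, 1 - d))
  se <- sqrt(p_analytic * (1 - p_analytic) / n_sim)
  expect_lt(abs(hits / n_sim - p_analytic), 3 * se)
})

test_that("amelogenin sex calls use a strict majority and fail to ND", {
  atab <- astr_table()
  expect_equal(sex_from_amelogenin(atab, "MN0104"), "XY")
  expect_equal(sex_from_amelogenin(atab, "MN0126"), "XY")  # one failed replicate
  expect_equal(sex_from_amelogenin(atab, "MN0105"), "XX")
  none <- data.frame(sample = "x", replicate = 1:2, Amel = c("-", "-"),
                     stringsAsFactors = FALSE)
  expect_equal(sex_from_amelogenin(none, "x"), "ND")
  tie <- data.frame(sample = "x", replicate = 1:2, Amel = c("XX", "XY"),
                    stringsAsFactors = FALSE)
  expect_equal(sex_from_amelogenin(tie, "x"), "ND")
})

test_that("zero successful replicates at a locus yields a missing consensus", {
  tab <- data.frame(sample = "s", replicate = 1:3,
                    L1 = c("-", "-", "-"), L2 = c("9/9", "9/9", "9/9"),
                    stringsAsFactors = FALSE)
  attr(tab, "loci") <- c("L1", "L2")
  class(tab) <- c("replicate_table", class(tab))
  cp <- call_consensus(tab, "s")
  expect_true(is.na(cp$consensus[cp$locus == "L1"]))
  expect_equal(cp$n_success[cp$locus == "L1"], 0L)
  expect_false(cp$discordant[cp$locus == "L1"])
  expect_equal(cp$consensus[cp$locus == "L2"], "9/9")
  expect_false(cp$discordant[cp$locus == "L2"])
})
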