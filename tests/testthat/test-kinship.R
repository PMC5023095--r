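test_that("shared allele counts follow the largest multiset matching", {
  expect_equal(shared_allele_count(c(29, 29), c(30, 33.2)), 0L)
  expect_equal(shared_allele_count(c(10, 10), c(10, 10)), 2L)
  expect_equal(shared_allele_count(c(13, 17), c(13, 13)), 1L)
  expect_equal(shared_allele_count(c(13, 13), c(13, 17)), 1L)
  expect_equal(shared_allele_count("21/27", "19/22"), 0L)
  expect_equal(shared_allele_count(c(10, 12), c(10, 12)), 2L)
})

test_that("locus LR is 1 under unrelatedness and 0 under exclusion", {
  f <- three_allele_freqs()
  set.seed(5)
  for (i in 1:20) {
    g1 <- sort(sample(as.numeric(names(f)), 2, replace = TRUE))
    g2 <- sort(sample(as.numeric(names(f)), 2, replace = TRUE))
    expect_equal(locus_lr(g1, g2, "unrelated", f), 1)
  }
  # Mendelian exclusion zeroes the parent-offspring LR exactly
  f2 <- c("19" = 0.25, "21" = 0.25, "22" = 0.25, "27" = 0.25)
  expect_identical(locus_lr(c(21, 27), c(19, 22), "parent_offspring", f2), 0)
  expect_identical(locus_lr(c(19, 22), c(21, 27), "parent_offspring", f2), 0)
})

test_that("the parent-offspring transmission term matches the closed form", {
  # g1 = a/b, g2 = a/c with distinct alleles: LR = 1/(4 p_a)
  f <- c("1" = 0.1, "2" = 0.4, "3" = 0.5)
  expect_equal(locus_lr(c(1, 2), c(1, 3), "parent_offspring", f), 2.5)
  # shared homozygote: g1 = a/a, g2 = a/a: LR = 1/p_a
  expect_equal(locus_lr(c(1, 1), c(1, 1), "parent_offspring", f), 10)
  # full sibling identical heterozygote a/b: 1/4 + (p_a+p_b)/(8 p_a p_b) + 1/(8 p_a p_b)
  pa <- 0.1; pb <- 0.4
  expect_equal(locus_lr(c(1, 2), c(1, 2), "full_sibling", f),
               0.25 + (pa + pb) / (8 * pa * pb) + 1 / (8 * pa * pb))
})

test_that("implied conditional genotype distributions sum to one (enumeration)", {
  f <- three_allele_freqs()
  al <- as.numeric(names(f))
  gts <- list()
  for (a in al) for (b in al) if (a <= b) gts[[length(gts) + 1]] <- c(a, b)
  hw <- vapply(gts, function(g)
    if (g[1] == g[2]) f[[as.character(g[1])]]^2 else
      2 * f[[as.character(g[1])]] * f[[as.character(g[2])]], numeric(1))
  expect_equal(sum(hw), 1)
  # for every g1, the one-IBD transmission distribution over g2 sums to 1:
  # recover P(g2 | g1, 1 IBD) as T1 * P_HW(g2) from the PO LR (k1 = 1)
  for (g1 in gts) {
    p_cond <- vapply(seq_along(gts), function(j) {
      lr <- locus_lr(g1, gts[[j]], "parent_offspring", f)
      lr * hw[j]
    }, numeric(1))
    expect_equal(sum(p_cond), 1, tolerance = 1e-12,
                 label = paste("g1 =", paste(g1, collapse = "/")))
  }
})

test_that("locus LRs agree with a Monte-Carlo pedigree oracle", {
  # moderate-size version of the simulation cross-check: joint genotype-pair
  # frequencies under each hypothesis vs unrelatedness on a 3-allele locus
  f <- three_allele_freqs()
  al <- names(f)
  n <- 2e5
  set.seed(12)
  draw <- function(n) matrix(sample(al, 2 * n, TRUE, prob = f), n)
  key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  g1u <- draw(n); g2u <- draw(n)
  # parent-offspring: child = one parental allele + one population allele
  g1p <- draw(n)
  pass <- ifelse(stats::runif(n) < 0.5, g1p[, 1], g1p[, 2])
  g2p <- cbind(pass, sample(al, n, TRUE, prob = f))
  ku <- paste(key(g1u), key(g2u)); kp <- paste(key(g1p), key(g2p))
  tu <- table(ku); tp <- table(kp)
  configs <- names(tu)[tu > 500]
  for (cfg in configs) {
    parts <- strsplit(cfg, " ")[[1]]
    g1 <- as.numeric(parts[1:2]); g2 <- as.numeric(parts[3:4])
    lr <- locus_lr(g1, g2, "parent_offspring", f)
    cu <- as.numeric(tu[cfg])
    cp <- if (cfg %in% names(tp)) as.numeric(tp[cfg]) else 0
    est <- cp / cu
    if (cp == 0) {
      expect_identical(lr, 0, label = cfg)
    } else {
      se <- est * sqrt(1 / cp + 1 / cu)
      expect_lt(abs(lr - est), 3 * se + 1e-12, label = cfg)
    }
  }
})

test_that("combined LR is the locus product and is order-invariant", {
  f <- list(L1 = c("1" = 0.1, "2" = 0.4, "3" = 0.5),
            L2 = c("7" = 0.3, "8" = 0.7))
  g1 <- c(L1 = "1/2", L2 = "7/7")
  g2 <- c(L1 = "1/3", L2 = "7/8")
  cl <- combined_lr(g1, g2, "parent_offspring", f)
  expect_equal(cl$lr, prod(cl$per_locus))
  expect_equal(unname(cl$per_locus["L1"]),
               locus_lr("1/2", "1/3", "parent_offspring", f$L1))
  rev_cl <- combined_lr(g1[c("L2", "L1")], g2[c("L2", "L1")],
                        "parent_offspring", f)
  expect_equal(rev_cl$lr, cl$lr)
  # missing loci are skipped and listed
  g2m <- c(L1 = "1/3", L2 = "-")
  clm <- combined_lr(g1, g2m, "parent_offspring", f)
  expect_equal(clm$skipped, "L2")
  expect_equal(clm$lr, unname(cl$per_locus["L1"]))
})

test_that("posteriors follow Bayes' rule and sum to one", {
  lrs <- c(parent_offspring = 4, full_sibling = 1, unrelated = 1)
  post <- posterior_probs(lrs)
  expect_equal(sum(post), 1)
  expect_equal(unname(post["parent_offspring"]), 2 / 3)
  # zero LR forces a zero posterior
  post0 <- posterior_probs(c(parent_offspring = 0, unrelated = 1))
  expect_identical(unname(post0["parent_offspring"]), 0)
  # equal LRs return the prior
  pr <- c(a = 0.2, b = 0.8)
  expect_equal(posterior_probs(c(a = 3, b = 3), pr), pr)
  expect_error(posterior_probs(c(a = 1), priors = c(a = 0.5)), "sum to 1")
})

test_that("missing frequencies error without a floor and are floored with one", {
  f <- c("10" = 0.5, "11" = 0.5)
  expect_error(locus_lr(c(10, 11), c(10, 12), "parent_offspring", f),
               "no frequency")
  expect_message(
    lr <- locus_lr(c(10, 11), c(10, 12), "parent_offspring", f, floor = 0.01),
    "floor")
  expect_equal(lr, 1 / (4 * 0.5))
})

test_that("the study pair MN0104-MN0126 is excluded as parent-offspring in every scenario", {
  atab <- astr_table()
  p104 <- call_consensus(atab, "MN0104", astr_loci())
  p126 <- call_consensus(atab, "MN0126", astr_loci())
  freqs <- read_allele_freqs()
  res <- classify_pair(p104, p126, freqs)
  expect_length(res$scenarios, 2)   # the two D21S11 candidates
  for (sc in res$scenarios) {
    expect_setequal(sc$exclusion_loci, c("D21S11", "FGA"))
    expect_identical(unname(sc$lrs["parent_offspring"]), 0)
    expect_identical(unname(sc$posteriors["parent_offspring"]), 0)
    expect_gt(sc$posteriors[["full_sibling"]], 0)
  }
  # frequency independence of the exclusion: a different strictly positive
  # table gives the same zero
  f2 <- lapply(freqs, function(x) {
    y <- x + seq_along(x) * 1e-3
    y / sum(y)
  })
  res2 <- classify_pair(p104, p126, f2)
  for (sc in res2$scenarios) {
    expect_identical(unname(sc$posteriors["parent_offspring"]), 0)
  }
})

test_that("the putative mother is compatible with both sons at all eight loci", {
  atab <- astr_table()
  freqs <- read_allele_freqs()
  p125 <- call_consensus(atab, "MN0125", astr_loci())
  p104 <- call_consensus(atab, "MN0104", astr_loci())
  p126 <- call_consensus(atab, "MN0126", astr_loci())
  trio <- trio_mendelian_check(p125, list(p104, p126))
  smry <- attr(trio, "summary")
  expect_equal(smry$compatible_loci, c(8, 8))
  expect_equal(smry$tested_loci, c(8, 8))
  # the MN0126 D21S11 compatibility runs through the 33.2-bearing candidate
  row <- trio[trio$child == "MN0126" & trio$locus == "D21S11", ]
  expect_true(row$compatible)
  expect_match(row$note, "30/33.2")
  # both mother-son pairs have positive PO and sibling posteriors; for the
  # ambiguous son this holds in the 33.2-bearing scenario, while the 30/30
  # candidate would exclude the maternal link at D21S11
  res104 <- classify_pair(p125, p104, freqs)
  expect_length(res104$scenarios, 1)
  for (res in list(res104, classify_pair(p125, p126, freqs))) {
    for (sc in res$scenarios) {
      if (grepl("30/30", sc$scenario)) {
        expect_equal(sc$exclusion_loci, "D21S11")
        expect_identical(unname(sc$posteriors["parent_offspring"]), 0)
      } else {
        expect_length(sc$exclusion_loci, 0)
        expect_gt(sc$posteriors[["parent_offspring"]], 0)
        expect_gt(sc$posteriors[["full_sibling"]], 0)
      }
    }
  }
})

test_that("a child sharing nothing at one locus is flagged by the trio check", {
  mother <- c(L1 = "10/11", L2 = "8/9")
  child <- c(L1 = "10/12", L2 = "6/7")
  out <- trio_mendelian_check(mother, list(child))
  expect_true(out$compatible[out$locus == "L1"])
  expect_false(out$compatible[out$locus == "L2"])
})

test_that("identical profiles favour full siblings over unrelatedness at every locus", {
  f <- read_allele_freqs()
  set.seed(3)
  for (l in names(f)) {
    g <- format_genotype(sort(as.numeric(sample(names(f[[l]]), 2, TRUE))))
    expect_gte(locus_lr(g, g, "full_sibling", f[[l]]), 1)
  }
})
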