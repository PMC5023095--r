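#' Pairwise relationship hypotheses and their IBD sharing coefficients
#'
#' Cotterman coefficients \code{(k0, k1, k2)} give the probabilities that a
#' pair of non-inbred individuals shares 0, 1 or 2 alleles identical by
#' descent at an autosomal locus: unrelated \code{(1,0,0)}, parent-offspring
#' \code{(0,1,0)}, full siblings \code{(1/4,1/2,1/4)}.
#'
#' @param labels Which hypotheses to return.
#' @return Data frame with columns \code{label}, \code{k0}, \code{k1},
#'   \code{k2}.
#' @export
kinship_hypotheses <- function(labels = c("unrelated", "parent_offspring",
                                          "full_sibling")) {
  all <- data.frame(
    label = c("unrelated", "parent_offspring", "full_sibling"),
    k0 = c(1, 0, 0.25),
    k1 = c(0, 1, 0.5),
    k2 = c(0, 0, 0.25),
    stringsAsFactors = FALSE
  )
  out <- all[all$label %in% labels, , drop = FALSE]
  if (nrow(out) == 0) stop("no known hypothesis among: ",
                           paste(labels, collapse = ", "), call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Read an allele-frequency table
#'
#' TSV with columns \code{locus}, \code{allele}, \code{frequency}. All
#' frequencies must be strictly positive and sum to 1 (within 1e-6) within
#' each locus.
#'
#' @param path Path to the table; defaults to the bundled synthetic table for
#'   the 8-locus autosomal panel.
#' @return Named list (by locus) of named numeric frequency vectors.
#' @export
read_allele_freqs <- function(path = palaeokin_file("allele_freqs_synthetic.tsv")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "numeric"))
  if (any(tab$frequency <= 0)) stop("allele frequencies must be > 0", call. = FALSE)
  out <- lapply(split(tab, tab$locus), function(d) {
    f <- stats::setNames(d$frequency, d$allele)
    if (abs(sum(f) - 1) > 1e-6) {
      stop("frequencies at locus ", d$locus[1], " sum to ", sum(f), call. = FALSE)
    }
    f
  })
  out
}

# frequency lookup with optional floor for alleles absent from the table
allele_freq <- function(freqs_locus, allele, locus = "?", floor = NULL) {
  key <- format(allele, trim = TRUE, scientific = FALSE)
  if (key %in% names(freqs_locus)) return(unname(freqs_locus[key]))
  if (!is.null(floor)) {
    message("allele ", key, " at locus ", locus,
            " absent from frequency table; floor frequency ", floor, " used")
    return(floor)
  }
  stop("no frequency for allele ", key, " at locus ", locus,
       " and no floor configured", call. = FALSE)
}

hw_prob <- function(g, freqs_locus, locus = "?", floor = NULL) {
  p <- vapply(g, allele_freq, numeric(1), freqs_locus = freqs_locus,
              locus = locus, floor = floor)
  if (length(g) == 1 || g[1] == g[2]) p[1]^2 else 2 * p[1] * p[2]
}

# P(g2 | one allele of g1 transmitted IBD, other allele from the population)
transmit_prob <- function(g1, g2, freqs_locus, locus = "?", floor = NULL) {
  pr <- function(a) allele_freq(freqs_locus, a, locus, floor)
  mean(vapply(g1, function(x) {
    if (g2[1] == g2[2]) {
      if (x == g2[1]) pr(g2[1]) else 0
    } else {
      if (x == g2[1]) pr(g2[2]) else if (x == g2[2]) pr(g2[1]) else 0
    }
  }, numeric(1)))
}

#' Single-locus kinship likelihood ratio
#'
#' Evaluates \eqn{LR = k_0 + k_1 T_1 + k_2 T_2}, the likelihood of the
#' observed genotype pair under the relationship hypothesis relative to
#' unrelatedness. \eqn{T_1} is the transmission term (one allele of
#' \code{g1} passed identical-by-descent, the partner allele drawn from the
#' population, against the Hardy-Weinberg probability of \code{g2});
#' \eqn{T_2 = 1/P(g2)} when the two genotypes are identical as multisets and
#' 0 otherwise. When the pair shares no allele, the \eqn{k_1}/\eqn{k_2}
#' terms are structurally zero, so a Mendelian exclusion gives a
#' parent-offspring LR of exactly 0 under the no-mutation model.
#'
#' @param g1,g2 Genotypes (numeric allele vectors of length 2, or strings).
#' @param hyp One row of [kinship_hypotheses()], or a hypothesis label.
#' @param freqs_locus Named frequency vector for the locus.
#' @param locus Locus name, for messages.
#' @param floor Optional floor frequency substituted (and logged) for alleles
#'   missing from the table.
#' @return Non-negative numeric LR.
#' @examples
#' f <- c("1" = 0.1, "2" = 0.4, "3" = 0.5)
#' locus_lr(c(1, 2), c(1, 3), "parent_offspring", f)  # 1/(4*0.1) = 2.5
#' @export
locus_lr <- function(g1, g2, hyp, freqs_locus, locus = "?", floor = NULL) {
  if (is.character(g1) && length(g1) == 1) g1 <- parse_genotype(g1)[[1]]
  if (is.character(g2) && length(g2) == 1) g2 <- parse_genotype(g2)[[1]]
  if (is.null(g1) || is.null(g2)) stop("both genotypes must be non-missing", call. = FALSE)
  if (length(g1) == 1) g1 <- rep(g1, 2)   # apparent homozygote
  if (length(g2) == 1) g2 <- rep(g2, 2)
  if (is.character(hyp)) hyp <- kinship_hypotheses(hyp)
  k0 <- hyp$k0; k1 <- hyp$k1; k2 <- hyp$k2
  t1 <- 0; t2 <- 0
  if (k1 > 0 || k2 > 0) {
    p2 <- hw_prob(g2, freqs_locus, locus, floor)
    if (k1 > 0) t1 <- transmit_prob(g1, g2, freqs_locus, locus, floor) / p2
    if (k2 > 0 && identical(sort(g1), sort(g2))) t2 <- 1 / p2
  }
  k0 + k1 * t1 + k2 * t2
}

#' Combined likelihood ratio over a locus panel
#'
#' Product of [locus_lr()] over loci typed unambiguously in both profiles;
#' loci missing (or unresolved) in either profile are skipped and listed.
#'
#' @param geno1,geno2 Named genotype-string vectors per locus (one scenario
#'   of a consensus profile; see [profile_scenarios()]).
#' @param hyp Hypothesis row or label.
#' @param freqs Frequency table from [read_allele_freqs()].
#' @param floor Optional floor frequency.
#' @return List with \code{lr}, \code{per_locus} (named numeric) and
#'   \code{skipped} (loci left out).
#' @export
combined_lr <- function(geno1, geno2, hyp, freqs, floor = NULL) {
  loci <- intersect(names(geno1), names(geno2))
  ok <- !is.na(geno1[loci]) & !is.na(geno2[loci]) &
    geno1[loci] != "-" & geno2[loci] != "-"
  usable <- loci[ok]
  if (length(usable) == 0) stop("no locus definable in both profiles", call. = FALSE)
  per <- vapply(usable, function(l) {
    locus_lr(geno1[[l]], geno2[[l]], hyp, freqs[[l]], locus = l, floor = floor)
  }, numeric(1))
  list(lr = prod(per), per_locus = per, skipped = loci[!ok])
}

#' Posterior probabilities over relationship hypotheses
#'
#' Bayes' rule over the evaluated hypothesis set:
#' \eqn{P(h | data) = \pi_h LR_h / \sum_{h'} \pi_{h'} LR_{h'}}. The default
#' prior is uniform over the supplied hypotheses; reports always state the
#' prior used.
#'
#' @param lrs Named numeric vector of combined LRs per hypothesis.
#' @param priors Named numeric prior vector summing to 1; default uniform.
#' @return Named numeric posterior vector summing to 1.
#' @export
posterior_probs <- function(lrs, priors = NULL) {
  if (is.null(priors)) {
    priors <- stats::setNames(rep(1 / length(lrs), length(lrs)), names(lrs))
  }
  priors <- priors[names(lrs)]
  if (anyNA(priors) || abs(sum(priors) - 1) > 1e-9) {
    stop("priors must cover every hypothesis and sum to 1", call. = FALSE)
  }
  w <- priors * lrs
  if (sum(w) == 0) stop("all hypotheses have zero likelihood", call. = FALSE)
  w / sum(w)
}

#' Pairwise kinship classification
#'
#' Computes, for a pair of consensus profiles, the Mendelian exclusion loci
#' (no allele shared), the combined likelihood ratio for every hypothesis
#' and the posterior over the hypothesis set. An ambiguous locus in either
#' profile is expanded combinatorially into scenarios, each evaluated and
#' reported separately (never averaged).
#'
#' @param p1,p2 \code{consensus_profile} objects (or named genotype-string
#'   vectors).
#' @param freqs Frequency table from [read_allele_freqs()].
#' @param hypotheses Data frame from [kinship_hypotheses()].
#' @param priors Optional named prior vector (default uniform).
#' @param floor Optional floor frequency for alleles absent from the table.
#' @return Object of class \code{kinship_result}: a list with \code{pair}
#'   and one entry per scenario carrying \code{scenario},
#'   \code{exclusion_loci}, \code{lrs}, \code{posteriors}, \code{per_locus},
#'   \code{skipped}.
#' @examples
#' reps <- read_replicate_table(palaeokin_file("astr_replicates.tsv"))
#' loci <- setdiff(attr(reps, "loci"), "Amel")
#' a <- call_consensus(reps, "MN0104", loci)
#' b <- call_consensus(reps, "MN0126", loci)
#' classify_pair(a, b, read_allele_freqs())
#' @export
classify_pair <- function(p1, p2, freqs,
                          hypotheses = kinship_hypotheses(),
                          priors = NULL, floor = NULL) {
  sc1 <- if (inherits(p1, "consensus_profile")) profile_scenarios(p1) else
    list(structure(unlist(p1), scenario = ""))
  sc2 <- if (inherits(p2, "consensus_profile")) profile_scenarios(p2) else
    list(structure(unlist(p2), scenario = ""))
  id1 <- if (inherits(p1, "consensus_profile")) attr(p1, "sample_id") else "p1"
  id2 <- if (inherits(p2, "consensus_profile")) attr(p2, "sample_id") else "p2"
  scenarios <- list()
  for (g1 in sc1) for (g2 in sc2) {
    loci <- intersect(names(g1), names(g2))
    ok <- !is.na(g1[loci]) & !is.na(g2[loci]) & g1[loci] != "-" & g2[loci] != "-"
    usable <- loci[ok]
    excl <- usable[vapply(usable, function(l)
      shared_allele_count(g1[[l]], g2[[l]]) == 0L, logical(1))]
    lrs <- stats::setNames(numeric(nrow(hypotheses)), hypotheses$label)
    per <- list()
    for (i in seq_len(nrow(hypotheses))) {
      cl <- combined_lr(g1, g2, hypotheses[i, ], freqs, floor = floor)
      lrs[hypotheses$label[i]] <- cl$lr
      per[[hypotheses$label[i]]] <- cl$per_locus
      skipped <- cl$skipped
    }
    post <- posterior_probs(lrs, priors)
    lab <- paste(attr(g1, "scenario"), attr(g2, "scenario"), sep = ";")
    lab <- gsub("^;|;$", "", lab)
    scenarios[[length(scenarios) + 1L]] <- list(
      scenario = lab, exclusion_loci = excl, lrs = lrs,
      posteriors = post, per_locus = per, skipped = skipped)
  }
  structure(list(pair = c(id1, id2), scenarios = scenarios,
                 prior = if (is.null(priors)) "uniform over evaluated hypotheses"
                         else priors),
            class = "kinship_result")
}

#' @export
print.kinship_result <- function(x, ...) {
  cat("Kinship:", x$pair[1], "vs", x$pair[2], "\n")
  for (sc in x$scenarios) {
    if (nzchar(sc$scenario)) cat("  scenario", sc$scenario, "\n")
    if (length(sc$exclusion_loci)) {
      cat("  exclusion loci:", paste(sc$exclusion_loci, collapse = ", "), "\n")
    }
    for (h in names(sc$lrs)) {
      cat(sprintf("  %-17s LR = %-12.4g posterior = %.4f\n",
                  h, sc$lrs[[h]], sc$posteriors[[h]]))
    }
  }
  cat("  prior:", if (is.character(x$prior)) x$prior else
    paste(names(x$prior), x$prior, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Mendelian compatibility of a putative mother with children
#'
#' At each autosomal locus a child is compatible with the mother when they
#' share at least one allele. Ambiguous loci are scored compatible when any
#' candidate genotype combination shares an allele; the candidates that do
#' are reported.
#'
#' @param mother A \code{consensus_profile} (or named genotype vector).
#' @param children List of profiles.
#' @return Data frame with one row per child-locus: \code{child},
#'   \code{locus}, \code{compatible}, \code{note}; plus per-child summary in
#'   the \code{"summary"} attribute.
#' @export
trio_mendelian_check <- function(mother, children) {
  as_cand <- function(p) {
    if (inherits(p, "consensus_profile")) {
      cand <- p$candidates
      cand[!is.na(p$consensus)] <- as.list(p$consensus[!is.na(p$consensus)])
      stats::setNames(cand, p$locus)
    } else {
      lapply(stats::setNames(unlist(p), names(unlist(p))), identity)
    }
  }
  id_of <- function(p, default) {
    if (inherits(p, "consensus_profile")) attr(p, "sample_id") else default
  }
  m <- as_cand(mother)
  rows <- list()
  for (ci in seq_along(children)) {
    ch <- as_cand(children[[ci]])
    cid <- id_of(children[[ci]], paste0("child", ci))
    for (l in intersect(names(m), names(ch))) {
      mg <- m[[l]][!is.na(m[[l]]) & m[[l]] != "-"]
      cg <- ch[[l]][!is.na(ch[[l]]) & ch[[l]] != "-"]
      if (length(mg) == 0 || length(cg) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          child = cid, locus = l, compatible = NA, note = "untyped",
          stringsAsFactors = FALSE)
        next
      }
      hits <- expand.grid(mg = mg, cg = cg, stringsAsFactors = FALSE)
      sh <- mapply(function(a, b) shared_allele_count(a, b) >= 1L,
                   hits$mg, hits$cg)
      note <- ""
      if ((length(mg) > 1 || length(cg) > 1) && any(sh)) {
        note <- paste("compatible via", paste(unique(
          paste(hits$mg[sh], hits$cg[sh], sep = "~")), collapse = ", "))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        child = cid, locus = l, compatible = any(sh), note = note,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  smry <- do.call(rbind, lapply(split(out, out$child), function(d) {
    data.frame(child = d$child[1],
               compatible_loci = sum(d$compatible, na.rm = TRUE),
               tested_loci = sum(!is.na(d$compatible)),
               stringsAsFactors = FALSE)
  }))
  rownames(smry) <- NULL
  attr(out, "summary") <- smry
  out
}
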