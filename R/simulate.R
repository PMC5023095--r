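#' Specify a pedigree for simulation
#'
#' Individuals are listed with sex and 0, 1 or 2 known parents; the pedigree
#' must be acyclic and parents must precede use. Autosomal genotypes descend
#' by Mendelian inheritance from founder genotypes drawn under
#' Hardy-Weinberg from the frequency table; Y-STR haplotypes are copied
#' father to son; mtDNA haplotypes are copied mother to child.
#'
#' @param individuals Data frame with columns \code{id}, \code{sex}
#'   (\code{"M"}/\code{"F"}), \code{father}, \code{mother} (\code{NA} for
#'   unknown).
#' @param freqs Autosomal allele-frequency table ([read_allele_freqs()]).
#' @param ystr_founders Named list of founder Y haplotypes (named numeric
#'   vectors, locus -> allele); founder males draw from these round-robin.
#' @param mt_founders Character vector of founder mtDNA lineage labels;
#'   founders draw from these round-robin (females and males alike).
#' @param seed Mandatory integer seed.
#' @return Object of class \code{pedigree_spec}.
#' @export
pedigree_spec <- function(individuals, freqs = read_allele_freqs(),
                          ystr_founders = list(Y1 = c(DYS19 = 14, DYS390 = 22,
                                                      DYS391 = 11, DYS393 = 13)),
                          mt_founders = c("mtA", "mtB"), seed) {
  if (missing(seed)) stop("a seed is required for reproducibility", call. = FALSE)
  need <- c("id", "sex", "father", "mother")
  if (!all(need %in% names(individuals))) {
    stop("individuals need columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(individuals$id)) stop("duplicate individual ids", call. = FALSE)
  # acyclicity: every individual must be orderable after its parents
  order <- character()
  pending <- individuals$id
  repeat {
    ready <- vapply(pending, function(i) {
      r <- individuals[individuals$id == i, ]
      ok <- function(p) is.na(p) || p %in% order
      ok(r$father) && ok(r$mother)
    }, logical(1))
    if (!any(ready)) {
      if (length(pending)) stop("pedigree is cyclic or has unknown parents: ",
                                paste(pending, collapse = ", "), call. = FALSE)
      break
    }
    order <- c(order, pending[ready])
    pending <- pending[!ready]
    if (length(pending) == 0) break
  }
  structure(list(individuals = individuals, freqs = freqs,
                 ystr_founders = ystr_founders, mt_founders = mt_founders,
                 seed = as.integer(seed), order = order),
            class = "pedigree_spec")
}

sample_hw_genotype <- function(freqs_locus) {
  a <- sample(names(freqs_locus), 2L, replace = TRUE, prob = freqs_locus)
  sort(as.numeric(a))
}

#' Simulate true genotypes for a pedigree
#'
#' Founders draw autosomal genotypes under Hardy-Weinberg from the frequency
#' table, a founder Y haplotype (males) and a founder mtDNA lineage;
#' children receive one uniformly chosen allele from each parent per
#' autosomal locus, their father's Y (sons) and their mother's mtDNA.
#' Deterministic given the spec's seed.
#'
#' @param spec A [pedigree_spec()].
#' @return Named list (by individual) of \code{list(sex, astr, ystr, mt)};
#'   \code{astr} is a named list of numeric allele pairs.
#' @export
simulate_pedigree <- function(spec) {
  set.seed(spec$seed)
  loci <- names(spec$freqs)
  out <- list()
  yf_i <- 0L; mt_i <- 0L
  for (id in spec$order) {
    row <- spec$individuals[spec$individuals$id == id, ]
    founder_y <- function() {
      yf_i <<- yf_i %% length(spec$ystr_founders) + 1L
      spec$ystr_founders[[yf_i]]
    }
    founder_mt <- function() {
      mt_i <<- mt_i %% length(spec$mt_founders) + 1L
      spec$mt_founders[[mt_i]]
    }
    pick <- function(g) g[sample.int(2L, 1L)]
    astr <- lapply(stats::setNames(loci, loci), function(l) {
      pa <- if (!is.na(row$father)) pick(out[[row$father]]$astr[[l]]) else
        sample(names(spec$freqs[[l]]), 1L, prob = spec$freqs[[l]])
      ma <- if (!is.na(row$mother)) pick(out[[row$mother]]$astr[[l]]) else
        sample(names(spec$freqs[[l]]), 1L, prob = spec$freqs[[l]])
      sort(as.numeric(c(pa, ma)))
    })
    ystr <- if (row$sex == "M") {
      if (!is.na(row$father)) out[[row$father]]$ystr else founder_y()
    } else NULL
    mt <- if (!is.na(row$mother)) out[[row$mother]]$mt else founder_mt()
    out[[id]] <- list(sex = row$sex, astr = astr, ystr = ystr, mt = mt)
  }
  structure(out, class = "sim_pedigree")
}

#' Laboratory noise model for replicate simulation
#'
#' @param locus_dropout Probability a locus fails wholesale in a replicate.
#' @param allelic_dropout Probability one allele of a heterozygote is lost,
#'   producing an apparent homozygote.
#' @param misread Per-allele probability of a +/-1 full-repeat misread.
#' @param replicate_failure Probability a whole replicate fails (all loci
#'   missing).
#' @return List of class \code{noise_model}.
#' @export
noise_model <- function(locus_dropout = 0, allelic_dropout = 0,
                        misread = 0, replicate_failure = 0) {
  p <- c(locus_dropout, allelic_dropout, misread, replicate_failure)
  if (any(p < 0 | p > 1)) stop("noise probabilities must lie in [0,1]", call. = FALSE)
  structure(list(locus_dropout = locus_dropout,
                 allelic_dropout = allelic_dropout,
                 misread = misread,
                 replicate_failure = replicate_failure),
            class = "noise_model")
}

#' Simulate noisy replicate observations of a true profile
#'
#' Each replicate is an independent corruption of the true genotypes under
#' the noise model: whole-replicate failure, per-locus failure, allelic
#' dropout of heterozygotes, and +/-1-repeat misreads. Deterministic given
#' the seed. Output uses the same layout [read_replicate_table()] consumes,
#' so simulated data flow through the consensus caller unchanged.
#'
#' @param true_profile Named list of numeric allele pairs (autosomal) or
#'   single values (haploid), e.g. the \code{astr} slot of a simulated
#'   individual.
#' @param noise A [noise_model()].
#' @param n Number of replicates.
#' @param seed Integer seed.
#' @param sample_id Sample label for the table.
#' @return A \code{replicate_table} data frame.
#' @export
simulate_replicates <- function(true_profile, noise, n, seed,
                                sample_id = "sim") {
  set.seed(seed)
  loci <- names(true_profile)
  rows <- lapply(seq_len(n), function(r) {
    if (stats::runif(1) < noise$replicate_failure) {
      return(stats::setNames(as.list(rep("-", length(loci))), loci))
    }
    calls <- lapply(true_profile, function(g) {
      if (stats::runif(1) < noise$locus_dropout) return("-")
      g <- as.numeric(g)
      if (length(g) == 2 && g[1] != g[2] &&
          stats::runif(1) < noise$allelic_dropout) {
        g <- rep(g[sample.int(2L, 1L)], 2L)   # apparent homozygote
      }
      mis <- stats::runif(length(g)) < noise$misread
      g[mis] <- g[mis] + sample(c(-1, 1), sum(mis), replace = TRUE)
      format_genotype(g)
    })
    stats::setNames(calls, loci)
  })
  tab <- data.frame(sample = sample_id, replicate = seq_len(n),
                    stringsAsFactors = FALSE)
  for (l in loci) tab[[l]] <- vapply(rows, function(x) x[[l]], character(1))
  attr(tab, "loci") <- loci
  class(tab) <- c("replicate_table", class(tab))
  tab
}

#' Simulate deamination-damaged and UDG-repaired clone sets
#'
#' Emulates post-mortem cytosine deamination in cloned PCR products: in the
#' inactive-UDG arm every eligible base (a C, or a G for the opposite
#' strand) of each clone is independently converted (C to T, G to A) with
#' probability \code{damage_rate}; the active-UDG arm carries no such
#' conversions. The positions actually damaged in each clone are recorded
#' for planted-truth validation.
#'
#' @param haplotype True \code{mt_haplotype} of the sample.
#' @param ref Region reference \code{list(seq, start, end)}.
#' @param region One-row region data frame.
#' @param damage_rate Per-base conversion probability in the inactive arm.
#' @param n_inactive,n_active Clone counts (study arms used at least 5 and
#'   4 clones respectively).
#' @param seed Integer seed.
#' @return List with \code{inactive} and \code{active} \code{clone_set}s and
#'   \code{planted} (data frame \code{clone}, \code{position},
#'   \code{change}).
#' @export
simulate_deamination <- function(haplotype, ref, region, damage_rate,
                                 n_inactive = 5L, n_active = 4L, seed) {
  set.seed(seed)
  refchars <- strsplit(toupper(ref$seq), "")[[1]]
  subs <- haplotype$variants[haplotype$variants$kind == "substitution", , drop = FALSE]
  base_map <- stats::setNames(refchars, seq(region$start, region$end))
  base_map[as.character(subs$position)] <- subs$base
  eligible <- as.integer(names(base_map)[base_map %in% c("C", "G")])
  planted <- data.frame(clone = integer(), position = integer(),
                        change = character(), stringsAsFactors = FALSE)
  damage_one <- function(clone_idx) {
    hit <- eligible[stats::runif(length(eligible)) < damage_rate]
    v <- haplotype$variants
    for (p in hit) {
      from <- base_map[[as.character(p)]]
      to <- if (from == "C") "T" else "A"
      planted <<- rbind(planted, data.frame(clone = clone_idx, position = p,
                                            change = paste0(from, ">", to),
                                            stringsAsFactors = FALSE))
      at <- which(v$kind == "substitution" & v$position == p)
      if (length(at)) {
        v$base[at] <- to
      } else {
        v <- rbind(v, data.frame(position = p, kind = "substitution",
                                 base = to, count = NA_integer_,
                                 stringsAsFactors = FALSE))
      }
    }
    v <- v[order(v$position), , drop = FALSE]
    h <- haplotype
    h$variants <- v
    h$sample_id <- paste0(haplotype$sample_id, "_clone", clone_idx)
    h
  }
  inactive_clones <- lapply(seq_len(n_inactive), damage_one)
  active_clones <- lapply(seq_len(n_active), function(i) {
    h <- haplotype
    h$sample_id <- paste0(haplotype$sample_id, "_udg_clone", i)
    h
  })
  list(inactive = clone_set(haplotype$sample_id, "inactive_udg", inactive_clones),
       active = clone_set(haplotype$sample_id, "active_udg", active_clones),
       planted = planted)
}

sim_pair <- function(relationship, freqs, loci) {
  pick <- function(g) g[sample.int(2L, 1L)]
  draw <- function(l) sample_hw_genotype(freqs[[l]])
  g <- lapply(stats::setNames(loci, loci), function(l) {
    f <- freqs[[l]]
    switch(relationship,
      unrelated = list(draw(l), draw(l)),
      parent_offspring = {
        p <- draw(l)
        child <- sort(c(pick(p), as.numeric(sample(names(f), 1L, prob = f))))
        list(p, child)
      },
      full_sibling = {
        pa <- draw(l); ma <- draw(l)
        s1 <- sort(c(pick(pa), pick(ma)))
        s2 <- sort(c(pick(pa), pick(ma)))
        list(s1, s2)
      },
      stop("unknown relationship: ", relationship, call. = FALSE))
  })
  list(p1 = stats::setNames(format_genotype(lapply(g, `[[`, 1)), loci),
       p2 = stats::setNames(format_genotype(lapply(g, `[[`, 2)), loci))
}

#' Relationship-recovery experiment on simulated pairs
#'
#' Simulates genotype pairs with known relationship, classifies each with
#' [classify_pair()] under the supplied hypothesis set, and tabulates the
#' maximum-posterior label against the truth. Also reports, per true
#' relationship, how often at least one Mendelian exclusion locus occurred.
#' Deterministic given the seed.
#'
#' @param freqs Allele-frequency table.
#' @param relationships True relationships to simulate.
#' @param n_pairs Pairs per relationship.
#' @param seed Integer seed.
#' @param loci Locus panel (defaults to every locus in \code{freqs}).
#' @param hypotheses Hypothesis set evaluated by the classifier.
#' @return List with \code{confusion} (truth x predicted matrix),
#'   \code{accuracy} (named vector), \code{exclusion_rate} (named vector).
#' @export
run_recovery_experiment <- function(freqs,
                                    relationships = c("unrelated",
                                                      "parent_offspring",
                                                      "full_sibling"),
                                    n_pairs, seed,
                                    loci = names(freqs),
                                    hypotheses = kinship_hypotheses()) {
  set.seed(seed)
  labels <- hypotheses$label
  confusion <- matrix(0L, length(relationships), length(labels),
                      dimnames = list(relationships, labels))
  exclusion <- stats::setNames(numeric(length(relationships)), relationships)
  if (n_pairs == 0) {
    return(list(confusion = confusion,
                accuracy = stats::setNames(rep(NA_real_, length(relationships)),
                                           relationships),
                exclusion_rate = exclusion))
  }
  for (rel in relationships) {
    for (i in seq_len(n_pairs)) {
      pr <- sim_pair(rel, freqs, loci)
      res <- classify_pair(pr$p1, pr$p2, freqs, hypotheses = hypotheses)
      sc <- res$scenarios[[1]]
      pred <- names(sc$posteriors)[which.max(sc$posteriors)]
      confusion[rel, pred] <- confusion[rel, pred] + 1L
      if (length(sc$exclusion_loci) > 0) exclusion[rel] <- exclusion[rel] + 1
    }
  }
  acc <- vapply(relationships, function(r) {
    if (r %in% labels) confusion[r, r] / n_pairs else NA_real_
  }, numeric(1))
  list(confusion = confusion, accuracy = acc,
       exclusion_rate = exclusion / n_pairs)
}
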