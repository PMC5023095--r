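#' Read an STR replicate table
#'
#' Tab-separated layout mirroring laboratory report tables: one row per
#' replicate with columns \code{sample}, \code{replicate}, optionally
#' \code{lab}, then one column per locus (genotypes as \code{"a/b"} strings,
#' \code{"-"} for a failed amplification). An amelogenin column (\code{Amel},
#' values \code{XX}/\code{XY}) is carried through unchanged.
#'
#' @param path Path to the TSV file.
#' @return Data frame of class \code{replicate_table}; the locus columns are
#'   recorded in the \code{"loci"} attribute.
#' @export
read_replicate_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (!all(c("sample", "replicate") %in% names(tab))) {
    stop("replicate table needs 'sample' and 'replicate' columns", call. = FALSE)
  }
  loci <- setdiff(names(tab), c("sample", "replicate", "lab"))
  attr(tab, "loci") <- loci
  class(tab) <- c("replicate_table", class(tab))
  tab
}

replicate_loci <- function(tab, loci = NULL) {
  if (!is.null(loci)) return(loci)
  l <- attr(tab, "loci")
  if (is.null(l)) l <- setdiff(names(tab), c("sample", "replicate", "lab"))
  l
}

# per-locus genotype vote: returns list(consensus, candidates, n_support,
# n_success, discordant)
vote_locus <- function(calls, min_fraction, min_count) {
  gl <- parse_genotype(calls)
  ok <- !vapply(gl, is.null, logical(1))
  n <- sum(ok)
  if (n == 0) {
    return(list(consensus = NA_character_, candidates = character(),
                n_support = 0L, n_success = 0L, discordant = FALSE))
  }
  keys <- vapply(gl[ok], geno_key, character(1))
  counts <- sort(table(keys), decreasing = TRUE)
  top <- counts[1]
  discordant <- length(counts) > 1
  if (top / n > min_fraction && top >= min_count) {
    return(list(consensus = names(counts)[1],
                candidates = names(counts)[1],
                n_support = as.integer(top), n_success = n,
                discordant = discordant))
  }
  # no qualifying majority: report the tied (or under-supported) candidates
  cand <- names(counts)[counts == top]
  list(consensus = NA_character_, candidates = sort(cand),
       n_support = as.integer(top), n_success = n, discordant = discordant)
}

#' Consensus genotype calling over replicates
#'
#' Aggregates replicate STR calls for one sample into a consensus profile by
#' genotype-level voting: at each locus, a genotype held by a strict majority
#' of the successful (non-missing) replicate calls, and by at least
#' \code{min_count} of them, becomes the consensus. Any disagreement among
#' successful calls flags the locus \code{discordant} even when a majority
#' exists; a tie (or an under-supported majority) yields no consensus but an
#' explicit candidate set that downstream kinship analysis expands into
#' scenarios. Wholly failed replicates contribute no votes.
#'
#' @param reps A \code{replicate_table} (possibly covering several samples).
#' @param sample Sample id to call; may be omitted when the table holds a
#'   single sample.
#' @param loci Locus columns to use; defaults to all locus columns.
#' @param min_fraction Required majority as a fraction of successful calls;
#'   must exceed 0.5 is not required, but the vote only passes when
#'   \code{support/n > min_fraction} (default 0.5, i.e. strict majority).
#' @param min_count Minimum number of supporting replicates (default 2).
#' @return A data frame of class \code{consensus_profile} with one row per
#'   locus: \code{consensus} (genotype string or NA), \code{candidates}
#'   (list column), \code{n_support}, \code{n_success}, \code{discordant}.
#'   The sample id is kept in the \code{"sample_id"} attribute.
#' @examples
#' reps <- read_replicate_table(palaeokin_file("astr_replicates.tsv"))
#' call_consensus(reps, "MN0126")
#' @export
call_consensus <- function(reps, sample = NULL, loci = NULL,
                           min_fraction = 0.5, min_count = 2L) {
  loci <- replicate_loci(reps, loci)
  if (is.null(sample)) {
    ids <- unique(reps$sample)
    if (length(ids) != 1) stop("table holds several samples; pick one", call. = FALSE)
    sample <- ids
  }
  rows <- reps[reps$sample == sample, , drop = FALSE]
  if (nrow(rows) == 0) stop("no replicates for sample ", sample, call. = FALSE)
  votes <- lapply(loci, function(l) vote_locus(rows[[l]], min_fraction, min_count))
  out <- data.frame(locus = loci,
                    consensus = vapply(votes, `[[`, character(1), "consensus"),
                    n_support = vapply(votes, `[[`, integer(1), "n_support"),
                    n_success = vapply(votes, `[[`, integer(1), "n_success"),
                    discordant = vapply(votes, `[[`, logical(1), "discordant"),
                    stringsAsFactors = FALSE)
  out$candidates <- lapply(votes, `[[`, "candidates")
  attr(out, "sample_id") <- sample
  class(out) <- c("consensus_profile", class(out))
  out
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat("Consensus profile:", attr(x, "sample_id"), "\n")
  shown <- ifelse(is.na(x$consensus),
                  vapply(x$candidates, function(c)
                    if (length(c)) paste(c, collapse = " or ") else "-", character(1)),
                  x$consensus)
  flag <- ifelse(x$discordant, " *", "")
  cat(paste0("  ", format(x$locus), "  ", shown, flag, collapse = "\n"), "\n")
  if (any(x$discordant)) cat("  (* non-unanimous replicate calls)\n")
  invisible(x)
}

#' Genotypes of a consensus profile, one scenario at a time
#'
#' An ambiguous locus (no consensus, several candidates) makes a profile a
#' set of scenarios -- every combination of one candidate per ambiguous
#' locus. This helper enumerates them.
#'
#' @param profile A \code{consensus_profile}.
#' @return A list of named genotype-string vectors (one per scenario), each
#'   tagged with a \code{"scenario"} attribute describing the candidate
#'   choices made.
#' @export
profile_scenarios <- function(profile) {
  base <- stats::setNames(profile$consensus, profile$locus)
  amb <- which(is.na(profile$consensus) & lengths(profile$candidates) > 1)
  if (length(amb) == 0) {
    # single-candidate unresolved loci (under-supported) stay missing
    return(list(structure(base, scenario = "")))
  }
  choices <- expand.grid(lapply(profile$candidates[amb], identity),
                         stringsAsFactors = FALSE)
  lapply(seq_len(nrow(choices)), function(i) {
    g <- base
    g[amb] <- unlist(choices[i, ])
    structure(g, scenario = paste0(profile$locus[amb], "=",
                                   unlist(choices[i, ]), collapse = ","))
  })
}

#' Count discordant consensus cells across samples
#'
#' A cell is one sample-by-locus consensus; it is discordant when its
#' successful replicate calls are not unanimous (wholly failed replicates
#' cast no vote). Used to summarise reproducibility of a replicate typing
#' campaign.
#'
#' @param reps A \code{replicate_table} covering all samples.
#' @param loci Locus panel over which to count (defaults to all locus
#'   columns; pass the 8 autosomal loci to exclude amelogenin).
#' @param ... Passed to [call_consensus()].
#' @return List with \code{discordant_cells}, \code{total_cells} and a
#'   sample-by-locus logical matrix \code{flags}.
#' @export
count_discordances <- function(reps, loci = NULL, ...) {
  loci <- replicate_loci(reps, loci)
  samples <- unique(reps$sample)
  flags <- matrix(FALSE, length(samples), length(loci),
                  dimnames = list(samples, loci))
  for (s in samples) {
    cp <- call_consensus(reps, s, loci, ...)
    flags[s, ] <- cp$discordant
  }
  list(discordant_cells = sum(flags),
       total_cells = length(samples) * length(loci),
       flags = flags)
}

#' Molecular sex from replicate amelogenin calls
#'
#' Strict majority over the successful amelogenin calls; \code{"ND"} when no
#' replicate amplified or no strict majority exists.
#'
#' @param reps A \code{replicate_table}.
#' @param sample Sample id (optional for single-sample tables).
#' @param column Name of the amelogenin column (default \code{"Amel"}).
#' @return \code{"XX"}, \code{"XY"} or \code{"ND"}.
#' @export
sex_from_amelogenin <- function(reps, sample = NULL, column = "Amel") {
  if (is.null(sample)) {
    ids <- unique(reps$sample)
    if (length(ids) != 1) stop("table holds several samples; pick one", call. = FALSE)
    sample <- ids
  }
  calls <- reps[[column]][reps$sample == sample]
  calls <- calls[!is.na(calls) & calls %in% c("XX", "XY")]
  if (length(calls) == 0) return("ND")
  counts <- sort(table(calls), decreasing = TRUE)
  if (counts[1] * 2 > length(calls)) names(counts)[1] else "ND"
}

#' Write a consensus profile as TSV
#'
#' @param profile A \code{consensus_profile}.
#' @param path Output path.
#' @export
write_consensus_tsv <- function(profile, path) {
  out <- data.frame(sample = attr(profile, "sample_id"),
                    locus = profile$locus,
                    consensus = ifelse(is.na(profile$consensus),
                                       vapply(profile$candidates, paste,
                                              character(1), collapse = " or "),
                                       profile$consensus),
                    n_support = profile$n_support,
                    n_success = profile$n_success,
                    discordant = profile$discordant,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
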