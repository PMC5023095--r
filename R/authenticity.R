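#' Build a clone set
#'
#' A clone set groups the haplotypes read from independent clones of one PCR
#' product, under one treatment arm (direct amplification, active UDG, or
#' heat-inactivated UDG).
#'
#' @param sample_id Sample label.
#' @param treatment \code{"direct"}, \code{"active_udg"} or
#'   \code{"inactive_udg"}.
#' @param haplotypes List of \code{mt_haplotype} objects (one per distinct
#'   clone sequence).
#' @param counts Integer clone counts per haplotype (default 1 each).
#' @return Object of class \code{clone_set}.
#' @export
clone_set <- function(sample_id, treatment = c("direct", "active_udg", "inactive_udg"),
                      haplotypes, counts = NULL) {
  treatment <- match.arg(treatment)
  if (length(haplotypes) == 0) stop("a clone set needs at least one clone", call. = FALSE)
  if (is.null(counts)) counts <- rep(1L, length(haplotypes))
  if (length(counts) != length(haplotypes) || any(counts < 1)) {
    stop("counts must give a positive clone count per haplotype", call. = FALSE)
  }
  structure(list(sample_id = sample_id, treatment = treatment,
                 haplotypes = haplotypes, counts = as.integer(counts)),
            class = "clone_set")
}

#' Screen a sample haplotype against modern reference profiles
#'
#' Flags every reference (researchers who excavated or handled the samples)
#' whose haplotype is within \code{max_distance} differences of the sample
#' over the shared regions; an empty result is a pass. With the default
#' \code{max_distance = 0} a reference is flagged iff the profiles are
#' identical over the shared regions.
#'
#' @param sample An \code{mt_haplotype}.
#' @param references Named list of \code{mt_haplotype} reference profiles.
#' @param max_distance Maximum [haplotype_distance()] to flag (default 0).
#' @return Data frame with columns \code{reference}, \code{distance} for the
#'   flagged references (zero rows = pass).
#' @export
screen_contamination <- function(sample, references, max_distance = 0L) {
  if (length(references) == 0) stop("reference set is empty", call. = FALSE)
  d <- vapply(references, haplotype_distance, numeric(1), h1 = sample)
  nm <- if (!is.null(names(references))) names(references) else
    vapply(references, `[[`, character(1), "sample_id")
  hit <- d <= max_distance
  data.frame(reference = nm[hit], distance = as.integer(d[hit]),
             row.names = NULL, stringsAsFactors = FALSE)
}

# majority consensus base per position across clones in a set, at
# substitution level: returns named vector pos -> base for every position
# where a strict majority (> min_fraction) of clones carries a substitution
clone_substitution_consensus <- function(cs, min_fraction = 0.5) {
  n <- sum(cs$counts)
  tallies <- list()
  for (k in seq_along(cs$haplotypes)) {
    v <- cs$haplotypes[[k]]$variants
    subs <- v[v$kind == "substitution", , drop = FALSE]
    for (i in seq_len(nrow(subs))) {
      key <- paste0(subs$position[i], subs$base[i])
      tallies[[key]] <- (if (is.null(tallies[[key]])) 0L else tallies[[key]]) +
        cs$counts[k]
    }
  }
  keep <- names(tallies)[vapply(tallies, function(x) x / n > min_fraction, logical(1))]
  pos <- as.integer(sub("[ACGT]$", "", keep))
  base <- substr(keep, nchar(keep), nchar(keep))
  stats::setNames(base, pos)
}

#' Detect post-mortem deamination damage via UDG comparison
#'
#' Compares the clone-consensus sequence from the inactive-UDG arm with the
#' directly amplified haplotype. Post-mortem cytosine deamination shows up
#' as C-to-T (or, read on the other strand, G-to-A) transitions that appear
#' in the inactive-UDG clones but not in direct PCR; treatment with active
#' UDG excises the deaminated bases, so a genuine damage site reverts to the
#' direct base in the active arm. Discrepancies that are not
#' deamination-consistent are reported as anomalies, not damage calls.
#'
#' @param direct \code{mt_haplotype} from direct amplification.
#' @param active,inactive \code{clone_set} objects for the two UDG arms.
#' @param ref Region reference: \code{list(seq, start, end)} as returned by
#'   [read_region_fasta()] (needed to know the base at undamaged positions).
#' @param region One-row region data frame covering the compared span.
#' @param min_clone_fraction Clone-consensus majority threshold (default
#'   strict majority).
#' @return Data frame of class \code{damage_calls} with columns
#'   \code{position}, \code{change} (\code{"C>T"} or \code{"G>A"}),
#'   \code{reverted_by_udg}; anomalies (non-deamination discrepancies) are
#'   attached as the \code{"anomalies"} attribute, and the per-position
#'   damaged-clone fractions as \code{"clone_fractions"}.
#' @export
detect_damage <- function(direct, active, inactive, ref, region,
                          min_clone_fraction = 0.5) {
  refchars <- strsplit(toupper(ref$seq), "")[[1]]
  base_at <- function(pos, subs) {
    key <- as.character(pos)
    if (key %in% names(subs)) subs[[key]] else refchars[pos - region$start + 1L]
  }
  dsubs <- direct$variants[direct$variants$kind == "substitution", , drop = FALSE]
  direct_map <- stats::setNames(dsubs$base, dsubs$position)
  act <- clone_substitution_consensus(active, min_clone_fraction)
  inact <- clone_substitution_consensus(inactive, min_clone_fraction)
  positions <- sort(unique(as.integer(c(names(direct_map), names(act), names(inact)))))
  positions <- positions[positions >= region$start & positions <= region$end]
  calls <- data.frame(position = integer(), change = character(),
                      reverted_by_udg = logical(), stringsAsFactors = FALSE)
  anomalies <- data.frame(position = integer(), direct = character(),
                          inactive = character(), active = character(),
                          stringsAsFactors = FALSE)
  for (p in positions) {
    b_dir <- base_at(p, direct_map)
    b_in <- base_at(p, inact)
    b_act <- base_at(p, act)
    if (b_in == b_dir) next   # inactive arm agrees with direct: no event
    deam <- (b_dir == "C" && b_in == "T") || (b_dir == "G" && b_in == "A")
    if (deam) {
      calls <- rbind(calls, data.frame(
        position = p, change = paste0(b_dir, ">", b_in),
        reverted_by_udg = (b_act == b_dir), stringsAsFactors = FALSE))
    } else {
      anomalies <- rbind(anomalies, data.frame(
        position = p, direct = b_dir, inactive = b_in, active = b_act,
        stringsAsFactors = FALSE))
    }
  }
  # transparency: fraction of inactive clones carrying each called change
  n_in <- sum(inactive$counts)
  frac <- vapply(seq_len(nrow(calls)), function(i) {
    tgt <- sub(".*>", "", calls$change[i])
    hit <- vapply(seq_along(inactive$haplotypes), function(k) {
      v <- inactive$haplotypes[[k]]$variants
      any(v$kind == "substitution" & v$position == calls$position[i] & v$base == tgt) *
        inactive$counts[k]
    }, numeric(1))
    sum(hit) / n_in
  }, numeric(1))
  attr(calls, "clone_fractions") <- frac
  attr(calls, "anomalies") <- anomalies
  class(calls) <- c("damage_calls", class(calls))
  calls
}
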