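# Shared fixtures and small independent oracles used across test files.

hvr_ref <- function() {
  read_region_fasta(palaeokin_file("synthetic_hvr_reference.fa"))
}

hvr1_region <- function() region_spec("HVR1", 15977, 16399)
hvr2_region <- function() region_spec("HVR2", 29, 381)

# independent string-edit oracle for apply_variants: performs each edit by
# direct substring surgery, processing positions from the 3' end so earlier
# coordinates stay valid
oracle_apply <- function(ref_seq, variants, region) {
  s <- strsplit(ref_seq, "")[[1]]
  v <- variants[order(-variants$position), , drop = FALSE]
  for (i in seq_len(nrow(v))) {
    loc <- v$position[i] - region$start + 1L
    if (v$kind[i] == "substitution") {
      s[loc] <- v$base[i]
    } else if (v$kind[i] == "deletion") {
      s <- s[-loc]
    } else {
      s <- append(s, rep(v$base[i], v$count[i]), after = loc)
    }
  }
  paste(s, collapse = "")
}

# random canonical (3'-normalised, non-overlapping) variant set on a
# reference segment: substitutions anywhere, indels only at homopolymer run
# ends, all edits separated by at least 4 bp
random_canonical_variants <- function(ref_seq, region, n_sub = 3, n_indel = 1) {
  ref <- strsplit(ref_seq, "")[[1]]
  n <- length(ref)
  run_end <- which(ref[-n] != ref[-1])    # ref[p+1] != ref[p]
  used <- integer()
  free <- function(p) all(abs(p - used) > 4)
  rows <- list()
  for (k in seq_len(n_indel)) {
    cand <- run_end[run_end > 5 & run_end < n - 5]
    cand <- cand[vapply(cand, free, logical(1))]
    if (length(cand) == 0) break
    p <- sample(cand, 1)
    used <- c(used, p)
    if (stats::runif(1) < 0.5) {
      rows[[length(rows) + 1L]] <- data.frame(
        position = region$start + p - 1L, kind = "deletion",
        base = NA_character_, count = NA_integer_, stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        position = region$start + p - 1L, kind = "insertion",
        base = ref[p], count = sample(1:3, 1), stringsAsFactors = FALSE)
    }
  }
  for (k in seq_len(n_sub)) {
    cand <- which(vapply(seq_len(n), free, logical(1)))
    cand <- cand[cand > 2 & cand < n - 2]
    if (length(cand) == 0) break
    p <- sample(cand, 1)
    used <- c(used, p)
    b <- sample(setdiff(c("A", "C", "G", "T"), ref[p]), 1)
    rows[[length(rows) + 1L]] <- data.frame(
      position = region$start + p - 1L, kind = "substitution", base = b,
      count = NA_integer_, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(NULL)
  v <- do.call(rbind, rows)
  v <- v[order(v$position, match(v$kind, c("substitution", "deletion", "insertion"))), ,
         drop = FALSE]
  rownames(v) <- NULL
  v
}

# consensus study tables, read once per test run
astr_table <- function() read_replicate_table(palaeokin_file("astr_replicates.tsv"))
ystr_table <- function() read_replicate_table(palaeokin_file("ystr_replicates.tsv"))
astr_loci <- function() setdiff(attr(astr_table(), "loci"), "Amel")

# small 3-allele frequency system used by kinship oracles
three_allele_freqs <- function() c("10" = 0.2, "11" = 0.3, "12" = 0.5)

# enumeration oracle: probability that two unrelated Hardy-Weinberg
# genotypes at one locus share no allele identical-by-state
oracle_p_ibs0 <- function(f) {
  al <- names(f)
  gts <- expand.grid(a = al, b = al, stringsAsFactors = FALSE)
  gts <- gts[as.numeric(gts$a) <= as.numeric(gts$b), ]
  pg <- mapply(function(a, b) if (a == b) f[[a]]^2 else 2 * f[[a]] * f[[b]],
               gts$a, gts$b)
  tot <- 0
  for (i in seq_len(nrow(gts))) for (j in seq_len(nrow(gts))) {
    if (length(intersect(c(gts$a[i], gts$b[i]), c(gts$a[j], gts$b[j]))) == 0) {
      tot <- tot + pg[i] * pg[j]
    }
  }
  as.numeric(tot)
}
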