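#' Default mtDNA control-region spans
#'
#' The two hypervariable segments of the human mtDNA control region that are
#' conventionally sequenced for forensic haplotyping, in 1-based rCRS
#' coordinates: HVR1 spans 15,977-16,399 and HVR2 spans 29-381.
#'
#' @return A data frame with columns \code{name}, \code{start}, \code{end}.
#' @export
hvr_regions <- function() {
  data.frame(
    name  = c("HVR1", "HVR2"),
    start = c(15977L, 29L),
    end   = c(16399L, 381L),
    stringsAsFactors = FALSE
  )
}

#' Define an mtDNA region
#'
#' @param name Region label.
#' @param start,end 1-based inclusive rCRS coordinates, with
#'   \code{1 <= start <= end <= 16569}.
#' @return A one-row region data frame.
#' @export
region_spec <- function(name, start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end > 16569L || start > end) {
    stop("invalid region: need 1 <= start <= end <= 16569", call. = FALSE)
  }
  data.frame(name = name, start = start, end = end, stringsAsFactors = FALSE)
}

MT_GENOME_LENGTH <- 16569L

empty_variants <- function() {
  data.frame(position = integer(), kind = character(), base = character(),
             count = integer(), stringsAsFactors = FALSE)
}

#' Parse mtDNA variants in forensic rCRS-difference notation
#'
#' Variants are named by rCRS position followed by the event: a base letter
#' for a substitution (\code{"16093C"}), \code{del} for a deletion
#' (\code{"249del"}), and \code{+} with an optional copy count and the
#' inserted base for an insertion (\code{"309+C"}, \code{"310+3C"}). The
#' alternative "point" dialect (\code{"309.1C"}) is accepted via
#' \code{dialect = "point"}; consecutive point entries at one anchor are
#' merged into a single counted insertion.
#'
#' @param text Character vector of variant strings, or a single
#'   whitespace-separated string.
#' @param dialect \code{"plus"} (canonical, default) or \code{"point"}.
#' @return A variant data frame with columns \code{position}, \code{kind},
#'   \code{base}, \code{count}, sorted by position.
#' @examples
#' parse_mt_variants("16093C 16223T 16261T")
#' parse_mt_variants("309.1C 309.2C", dialect = "point")
#' @export
parse_mt_variants <- function(text, dialect = c("plus", "point")) {
  dialect <- match.arg(dialect)
  toks <- unlist(strsplit(text, "[[:space:]]+"))
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0) return(empty_variants())
  rows <- lapply(toks, parse_one_variant, dialect = dialect)
  v <- do.call(rbind, rows)
  if (dialect == "point") v <- merge_point_insertions(v)
  v <- v[order(v$position, match(v$kind, c("substitution", "deletion", "insertion"))), , drop = FALSE]
  rownames(v) <- NULL
  if (anyDuplicated(v$position[v$kind == "substitution"])) {
    stop("more than one substitution at a single position", call. = FALSE)
  }
  v
}

parse_one_variant <- function(tok, dialect = "plus") {
  chk_pos <- function(p) {
    p <- as.integer(p)
    if (is.na(p) || p < 1L || p > MT_GENOME_LENGTH) {
      stop("position out of range 1..16569 in variant '", tok, "'", call. = FALSE)
    }
    p
  }
  if (grepl("^[0-9]+[ACGT]$", tok)) {
    p <- chk_pos(sub("[ACGT]$", "", tok))
    return(data.frame(position = p, kind = "substitution",
                      base = substr(tok, nchar(tok), nchar(tok)),
                      count = NA_integer_, stringsAsFactors = FALSE))
  }
  if (grepl("^[0-9]+del$", tok)) {
    p <- chk_pos(sub("del$", "", tok))
    return(data.frame(position = p, kind = "deletion", base = NA_character_,
                      count = NA_integer_, stringsAsFactors = FALSE))
  }
  if (grepl("^[0-9]+\\+[0-9]*[ACGT]$", tok)) {
    m <- regmatches(tok, regexec("^([0-9]+)\\+([0-9]*)([ACGT])$", tok))[[1]]
    p <- chk_pos(m[2])
    n <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    if (n < 1L) stop("insertion count must be positive in '", tok, "'", call. = FALSE)
    return(data.frame(position = p, kind = "insertion", base = m[4],
                      count = n, stringsAsFactors = FALSE))
  }
  if (dialect == "point" && grepl("^[0-9]+\\.[0-9]+[ACGT]$", tok)) {
    m <- regmatches(tok, regexec("^([0-9]+)\\.([0-9]+)([ACGT])$", tok))[[1]]
    p <- chk_pos(m[2])
    return(data.frame(position = p, kind = "insertion", base = m[4],
                      count = 1L, stringsAsFactors = FALSE))
  }
  stop("malformed variant string: '", tok, "'", call. = FALSE)
}

merge_point_insertions <- function(v) {
  ins <- v$kind == "insertion"
  if (!any(ins)) return(v)
  merged <- do.call(rbind, lapply(split(v[ins, , drop = FALSE],
                                        paste(v$position[ins], v$base[ins])),
    function(d) {
      d$count[1] <- sum(d$count)
      d[1, , drop = FALSE]
    }))
  rbind(v[!ins, , drop = FALSE], merged)
}

#' Serialize variants to canonical notation
#'
#' Inverse of [parse_mt_variants()].
#'
#' @param variants A variant data frame.
#' @return Character vector of canonical variant strings.
#' @export
format_mt_variants <- function(variants) {
  if (nrow(variants) == 0) return(character())
  mapply(function(p, k, b, n) {
    switch(k,
      substitution = paste0(p, b),
      deletion     = paste0(p, "del"),
      insertion    = if (n == 1L) paste0(p, "+", b) else paste0(p, "+", n, b)
    )
  }, variants$position, variants$kind, variants$base, variants$count,
  USE.NAMES = FALSE)
}

#' Construct an mtDNA haplotype
#'
#' A haplotype is the set of differences from the rCRS over declared
#' control-region spans, plus any haplogroup-diagnostic coding-region SNP
#' calls typed separately (e.g. \code{"3010A,5178A"}).
#'
#' @param sample_id Sample label.
#' @param hvr1,hvr2 Variant strings for the two default regions (canonical
#'   notation, whitespace-separated), or \code{""}.
#' @param coding Comma-separated coding-region calls such as
#'   \code{"3010A,5178A"}, or \code{""}/\code{"-"} for none.
#' @param regions Region data frame; defaults to [hvr_regions()].
#' @return An object of class \code{mt_haplotype}.
#' @export
mt_haplotype <- function(sample_id, hvr1 = "", hvr2 = "", coding = "",
                         regions = hvr_regions()) {
  v1 <- parse_mt_variants(hvr1)
  v2 <- parse_mt_variants(hvr2)
  check_span <- function(v, nm) {
    rg <- regions[regions$name == nm, ]
    if (nrow(rg) == 0 || nrow(v) == 0) return(invisible())
    out <- v$position < rg$start | v$position > rg$end
    if (any(out)) {
      stop("variant outside the ", nm, " span: ",
           paste(format_mt_variants(v[out, , drop = FALSE]), collapse = " "),
           call. = FALSE)
    }
  }
  check_span(v1, "HVR1")
  check_span(v2, "HVR2")
  v <- rbind(v1, v2)
  v <- v[order(v$position), , drop = FALSE]
  rownames(v) <- NULL
  cc <- parse_coding_calls(coding)
  if (length(cc)) {
    pos <- as.integer(names(cc))
    inside <- vapply(pos, function(p)
      any(p >= regions$start & p <= regions$end), logical(1))
    if (any(inside)) {
      stop("coding call position inside a control-region span: ",
           paste(pos[inside], collapse = ", "), call. = FALSE)
    }
  }
  structure(list(sample_id = sample_id, regions = regions,
                 variants = v, coding = cc),
            class = "mt_haplotype")
}

parse_coding_calls <- function(coding) {
  if (is.null(coding) || is.na(coding) || !nzchar(coding) || coding == "-") {
    return(stats::setNames(character(), character()))
  }
  toks <- trimws(unlist(strsplit(coding, ",")))
  toks <- toks[nzchar(toks)]
  ok <- grepl("^[0-9]+[ACGT]$", toks)
  if (!all(ok)) stop("malformed coding call: '", toks[!ok][1], "'", call. = FALSE)
  pos <- sub("[ACGT]$", "", toks)
  base <- substr(toks, nchar(toks), nchar(toks))
  if (anyDuplicated(pos)) {
    d <- pos[duplicated(pos)][1]
    bases <- unique(base[pos == d])
    if (length(bases) > 1) {
      stop("conflicting coding calls at position ", d, ": ",
           paste(bases, collapse = " vs "), call. = FALSE)
    }
  }
  keep <- !duplicated(pos)
  stats::setNames(base[keep], pos[keep])
}

#' @export
print.mt_haplotype <- function(x, ...) {
  cat("mtDNA haplotype", x$sample_id, "\n")
  for (i in seq_len(nrow(x$regions))) {
    rg <- x$regions[i, ]
    vv <- x$variants[x$variants$position >= rg$start & x$variants$position <= rg$end, ]
    cat(sprintf("  %s (%d-%d): %s\n", rg$name, rg$start, rg$end,
                if (nrow(vv)) paste(format_mt_variants(vv), collapse = " ") else "(reference)"))
  }
  if (length(x$coding)) {
    cat("  coding:", paste0(names(x$coding), x$coding, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a haplotype table
#'
#' Reads a tab-separated table with columns \code{sample}, \code{hvr1},
#' \code{hvr2}, \code{coding} (and optionally \code{role}, \code{lab},
#' \code{sex_anth}, \code{sex_amel}, \code{haplogroup}); returns the parsed
#' haplotypes alongside the raw table. When a sample appears once per
#' laboratory, rows are de-duplicated by sample id for the haplotype list
#' (replication is retained in the table).
#'
#' @param path Path to the TSV file.
#' @return A list with \code{haplotypes} (named list of \code{mt_haplotype})
#'   and \code{table} (the raw data frame).
#' @export
read_mt_haplotypes <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample", "hvr1", "hvr2", "coding")
  if (!all(need %in% names(tab))) {
    stop("haplotype table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  first <- tab[!duplicated(tab$sample), , drop = FALSE]
  haps <- lapply(seq_len(nrow(first)), function(i) {
    mt_haplotype(first$sample[i], first$hvr1[i], first$hvr2[i], first$coding[i])
  })
  names(haps) <- first$sample
  list(haplotypes = haps, table = tab)
}

#' Write a haplotype table
#'
#' @param haplotypes Named list of \code{mt_haplotype} objects.
#' @param path Output TSV path.
#' @param haplogroups Optional named character vector of assigned labels.
#' @export
write_mt_haplotypes <- function(haplotypes, path, haplogroups = NULL) {
  rows <- lapply(haplotypes, function(h) {
    per_region <- vapply(seq_len(nrow(h$regions)), function(i) {
      rg <- h$regions[i, ]
      vv <- h$variants[h$variants$position >= rg$start & h$variants$position <= rg$end, ]
      paste(format_mt_variants(vv), collapse = " ")
    }, character(1))
    data.frame(sample = h$sample_id,
               hvr1 = per_region[match("HVR1", h$regions$name)],
               hvr2 = per_region[match("HVR2", h$regions$name)],
               coding = if (length(h$coding))
                 paste0(names(h$coding), h$coding, collapse = ",") else "-",
               haplogroup = if (!is.null(haplogroups))
                 haplogroups[[h$sample_id]] else NA_character_,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' Read region sequences from a FASTA file
#'
#' Record descriptions are expected to carry a \code{region=start-end} tag
#' giving the rCRS span of the segment.
#'
#' @param path FASTA path.
#' @return Named list of \code{list(seq, start, end)}; names are the record
#'   ids.
#' @export
read_region_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop("no FASTA records in ", path, call. = FALSE)
  ends <- c(hdr[-1] - 1L, length(lines))
  out <- list()
  for (k in seq_along(hdr)) {
    desc <- sub("^>", "", lines[hdr[k]])
    id <- strsplit(desc, "[[:space:]]+")[[1]][1]
    seq <- toupper(paste(lines[(hdr[k] + 1L):ends[k]], collapse = ""))
    m <- regmatches(desc, regexec("region=([0-9]+)-([0-9]+)", desc))[[1]]
    start <- if (length(m)) as.integer(m[2]) else NA_integer_
    end <- if (length(m)) as.integer(m[3]) else NA_integer_
    out[[id]] <- list(seq = seq, start = start, end = end)
  }
  out
}

#' Realize a variant set on a reference segment
#'
#' Applies substitutions, deletions and insertions (rCRS coordinates) to a
#' reference region sequence. This is the inverse of [call_variants()] and is
#' mainly used for round-trip validation and simulation.
#'
#' @param ref_seq Reference segment as a single character string.
#' @param variants Variant data frame (see [parse_mt_variants()]).
#' @param region One-row region data frame locating \code{ref_seq} on the
#'   rCRS.
#' @return The edited sequence as a character string.
#' @export
apply_variants <- function(ref_seq, variants, region) {
  ref <- strsplit(ref_seq, "")[[1]]
  n <- length(ref)
  if (n != region$end - region$start + 1L) {
    stop("reference length does not match region span", call. = FALSE)
  }
  if (nrow(variants) == 0) return(ref_seq)
  if (any(variants$position < region$start | variants$position > region$end)) {
    stop("variant outside the region", call. = FALSE)
  }
  loc <- variants$position - region$start + 1L
  sub_i <- which(variants$kind == "substitution")
  if (any(variants$base[sub_i] == ref[loc[sub_i]])) {
    bad <- sub_i[variants$base[sub_i] == ref[loc[sub_i]]][1]
    stop("invalid variant ", format_mt_variants(variants[bad, , drop = FALSE]),
         ": stated base equals the reference base", call. = FALSE)
  }
  out <- as.list(ref)
  for (i in sub_i) out[[loc[i]]] <- variants$base[i]
  for (i in which(variants$kind == "deletion")) out[[loc[i]]] <- character(0)
  for (i in which(variants$kind == "insertion")) {
    out[[loc[i]]] <- c(out[[loc[i]]], rep(variants$base[i], variants$count[i]))
  }
  paste(unlist(out), collapse = "")
}

# Global unit-cost alignment (Needleman-Wunsch), vectorised row scan.
# Characters outside ACGT are wildcards (match anything at zero cost).
nw_align <- function(ref, smp) {
  n <- length(ref)
  m <- length(smp)
  D <- matrix(0, n + 1L, m + 1L)
  D[1, ] <- 0:m
  D[, 1] <- 0:n
  acgt <- c("A", "C", "G", "T")
  smp_ok <- smp %in% acgt
  j_idx <- 0:m
  for (i in seq_len(n)) {
    prev <- D[i, ]
    subc <- as.numeric(ref[i] != smp & smp_ok & ref[i] %in% acgt)
    cand <- pmin(prev[1:m] + subc, prev[2:(m + 1)] + 1)
    vals <- c(prev[1] + 1, cand)
    D[i + 1L, ] <- j_idx + cummin(vals - j_idx)
  }
  # traceback: prefer diagonal, then up (delete ref), then left (insert)
  i <- n; j <- m
  ops <- character(0)   # reversed sequence of "D"(diag) "U"(up) "L"(left)
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0) {
      subc <- as.numeric(ref[i] != smp[j] && smp_ok[j] && ref[i] %in% acgt)
      if (D[i + 1L, j + 1L] == D[i, j] + subc) {
        ops <- c(ops, "D"); i <- i - 1L; j <- j - 1L; next
      }
    }
    if (i > 0 && D[i + 1L, j + 1L] == D[i, j + 1L] + 1) {
      ops <- c(ops, "U"); i <- i - 1L; next
    }
    ops <- c(ops, "L"); j <- j - 1L
  }
  rev(ops)
}

#' Call variants from a sample region sequence
#'
#' Globally aligns the sample sequence against the reference segment with
#' unit mismatch/gap costs (regions are short, so the dynamic program is
#' exact), then names the differences in canonical forensic notation.
#' Insertions and deletions falling in homopolymer runs are placed at the 3'
#' end of the run, the standard forensic mtDNA convention, which makes the
#' calls deterministic. Sample positions with ambiguous (non-ACGT) bases are
#' excluded from the variant set and recorded in the \code{"ambiguous"}
#' attribute with a warning.
#'
#' @param sample_seq Sample sequence for the full region (IUPAC ambiguity
#'   codes tolerated, see above).
#' @param ref_seq Reference segment for the same region.
#' @param region One-row region data frame.
#' @return Variant data frame (rCRS coordinates), with attribute
#'   \code{"ambiguous"} (data frame of flagged positions).
#' @export
call_variants <- function(sample_seq, ref_seq, region) {
  if (is.null(sample_seq) || !nzchar(sample_seq)) {
    stop("empty sample sequence", call. = FALSE)
  }
  ref <- strsplit(toupper(ref_seq), "")[[1]]
  smp <- strsplit(toupper(sample_seq), "")[[1]]
  smp <- smp[smp != "-"]   # alignment gaps in the input carry no information
  if (length(ref) != region$end - region$start + 1L) {
    stop("reference length does not match region span", call. = FALSE)
  }
  ops <- nw_align(ref, smp)
  acgt <- c("A", "C", "G", "T")
  vars <- empty_variants()
  amb <- data.frame(position = integer(), base = character(),
                    stringsAsFactors = FALSE)
  i <- 0L; j <- 0L
  k <- 1L
  nops <- length(ops)
  while (k <= nops) {
    op <- ops[k]
    if (op == "D") {
      i <- i + 1L; j <- j + 1L
      if (!(smp[j] %in% acgt)) {
        amb <- rbind(amb, data.frame(position = region$start + i - 1L,
                                     base = smp[j], stringsAsFactors = FALSE))
      } else if (ref[i] != smp[j]) {
        vars <- rbind(vars, data.frame(position = region$start + i - 1L,
                                       kind = "substitution", base = smp[j],
                                       count = NA_integer_,
                                       stringsAsFactors = FALSE))
      }
      k <- k + 1L
    } else if (op == "U") {
      i <- i + 1L
      vars <- rbind(vars, data.frame(position = region$start + i - 1L,
                                     kind = "deletion", base = NA_character_,
                                     count = NA_integer_,
                                     stringsAsFactors = FALSE))
      k <- k + 1L
    } else {
      # run of insertions anchored after ref position i
      run <- character(0)
      while (k <= nops && ops[k] == "L") {
        j <- j + 1L
        run <- c(run, smp[j])
        k <- k + 1L
      }
      anchor <- i
      for (b in unique(run)) {
        cnt <- sum(run == b)
        if (!(b %in% acgt)) {
          amb <- rbind(amb, data.frame(position = region$start + anchor - 1L,
                                       base = b, stringsAsFactors = FALSE))
          next
        }
        vars <- rbind(vars, data.frame(position = region$start + anchor - 1L,
                                       kind = "insertion", base = b,
                                       count = cnt, stringsAsFactors = FALSE))
      }
    }
  }
  vars <- normalize_indels_3prime(vars, ref, region)
  vars <- vars[order(vars$position,
                     match(vars$kind, c("substitution", "deletion", "insertion"))), ,
               drop = FALSE]
  rownames(vars) <- NULL
  if (nrow(amb)) {
    warning("ambiguous base(s) excluded at position(s): ",
            paste(amb$position, collapse = ", "), call. = FALSE)
  }
  attr(vars, "ambiguous") <- amb
  vars
}

# shift indels inside homopolymer runs to the 3' end of the run
normalize_indels_3prime <- function(vars, ref, region) {
  n <- length(ref)
  loc <- function(p) p - region$start + 1L
  # insertions: slide the anchor right while the next reference base equals
  # the inserted base
  ins <- which(vars$kind == "insertion")
  for (idx in ins) {
    p <- loc(vars$position[idx])
    b <- vars$base[idx]
    while (p + 1L <= n && ref[p + 1L] == b) p <- p + 1L
    vars$position[idx] <- region$start + p - 1L
  }
  # collapse insertions that land on the same anchor with the same base
  if (length(ins) > 1) {
    key <- paste(vars$position, vars$kind, vars$base)
    dup <- duplicated(key) & vars$kind == "insertion"
    if (any(dup)) {
      for (idx in which(dup)) {
        first <- which(key == key[idx])[1]
        vars$count[first] <- vars$count[first] + vars$count[idx]
      }
      vars <- vars[!dup, , drop = FALSE]
    }
  }
  # deletions: within each homopolymer run, deleted positions become the
  # 3'-most positions of the run
  del <- which(vars$kind == "deletion")
  if (length(del)) {
    runs <- cumsum(c(TRUE, ref[-1] != ref[-n]))   # run id per ref position
    dpos <- loc(vars$position[del])
    for (r in unique(runs[dpos])) {
      members <- which(runs == r)
      k <- sum(runs[dpos] == r)
      new_local <- utils::tail(members, k)
      vars$position[del[runs[dpos] == r]] <- region$start + new_local - 1L
    }
  }
  vars
}

#' Read an mtDNA haplogroup rule tree
#'
#' Plain TSV with columns \code{label}, \code{parent} (\code{-} for the
#' root), \code{snps} (comma-separated \code{<position><base>} motifs,
#' \code{-} for none). The rules must form a tree rooted at a single
#' reference node.
#'
#' @param path Path to the rules file; defaults to the bundled tree covering
#'   the diagnostic coding SNPs typed in this study.
#' @return A data frame of class \code{mt_rules} with parsed \code{snp_pos} /
#'   \code{snp_base} list columns.
#' @export
read_haplogroup_rules <- function(path = palaeokin_file("mt_haplogroup_rules.tsv")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (anyDuplicated(tab$label)) stop("duplicate haplogroup labels", call. = FALSE)
  root <- tab$label[tab$parent %in% c("-", "root", "", NA)]
  if (length(root) != 1) stop("rule tree must have exactly one root", call. = FALSE)
  known <- c(tab$label)
  bad <- !(tab$parent %in% c(known, "-", "root", "", NA))
  if (any(bad)) stop("unknown parent label: ", tab$parent[bad][1], call. = FALSE)
  snps <- lapply(tab$snps, function(s) {
    if (is.na(s) || !nzchar(s) || s == "-") return(list(pos = character(), base = character()))
    toks <- trimws(unlist(strsplit(s, ",")))
    ok <- grepl("^[0-9]+[ACGT]$", toks)
    if (!all(ok)) stop("malformed rule SNP: '", toks[!ok][1], "'", call. = FALSE)
    list(pos = sub("[ACGT]$", "", toks),
         base = substr(toks, nchar(toks), nchar(toks)))
  })
  tab$snp_pos <- lapply(snps, `[[`, "pos")
  tab$snp_base <- lapply(snps, `[[`, "base")
  # cycle check via depth computation
  depth <- function(lab, seen = character()) {
    if (lab %in% seen) stop("rule tree contains a cycle at ", lab, call. = FALSE)
    p <- tab$parent[tab$label == lab]
    if (p %in% c("-", "root", "", NA) || p == root) return(1L)
    1L + depth(p, c(seen, lab))
  }
  tab$depth <- vapply(tab$label, depth, integer(1))
  class(tab) <- c("mt_rules", class(tab))
  tab
}

rule_path <- function(rules, label) {
  path <- character()
  cur <- label
  repeat {
    path <- c(cur, path)
    p <- rules$parent[rules$label == cur]
    if (p %in% c("-", "root", "", NA)) break
    cur <- p
  }
  path
}

#' Assign an mtDNA haplogroup from diagnostic SNPs
#'
#' Walks the rule tree and returns the deepest node whose defining SNPs --
#' accumulated along the path from the root -- are all observed in the
#' haplotype. Coding-region calls are matched against the typed coding SNPs;
#' a rule SNP lying inside a declared control-region span is matched against
#' the haplotype's substitution variants. A haplotype matching no rule is
#' labelled with the root ("reference"/undetermined).
#'
#' @param h An \code{mt_haplotype}.
#' @param rules Rule tree from [read_haplogroup_rules()].
#' @return A list with \code{label}, \code{matched_snps} (canonical strings
#'   observed on the winning path) and \code{unmatched_expected} (defining
#'   SNPs of the winning node's children, i.e. what a deeper call would have
#'   needed).
#' @examples
#' h <- mt_haplotype("x", coding = "3010A,5178A")
#' classify_mt_haplogroup(h)$label  # "D4"
#' @export
classify_mt_haplogroup <- function(h, rules = read_haplogroup_rules()) {
  observed <- function(pos, base) {
    if (pos %in% names(h$coding)) return(h$coding[[pos]] == base)
    p <- as.integer(pos)
    if (any(p >= h$regions$start & p <= h$regions$end)) {
      vv <- h$variants
      return(any(vv$kind == "substitution" & vv$position == p & vv$base == base))
    }
    FALSE
  }
  root <- rules$label[rules$parent %in% c("-", "root", "", NA)]
  best <- root; best_depth <- 0L; best_matched <- character()
  for (i in seq_len(nrow(rules))) {
    lab <- rules$label[i]
    if (lab == root) next
    path <- rule_path(rules, lab)
    snp_pos <- unlist(rules$snp_pos[match(path, rules$label)])
    snp_base <- unlist(rules$snp_base[match(path, rules$label)])
    if (length(snp_pos) == 0) next
    hit <- mapply(observed, snp_pos, snp_base)
    if (all(hit)) {
      d <- rules$depth[i]
      matched <- paste0(snp_pos, snp_base)
      if (d > best_depth ||
          (d == best_depth && length(matched) > length(best_matched)) ||
          (d == best_depth && length(matched) == length(best_matched) && lab < best)) {
        best <- lab; best_depth <- d; best_matched <- matched
      }
    }
  }
  kids <- rules$label[rules$parent == best]
  unmatched <- unlist(lapply(kids, function(k) {
    i <- match(k, rules$label)
    paste0(rules$snp_pos[[i]], rules$snp_base[[i]])
  }))
  list(label = best, matched_snps = best_matched,
       unmatched_expected = if (is.null(unmatched)) character() else unmatched)
}

#' Count haplotype differences over shared regions
#'
#' The size of the symmetric difference between the two variant sets,
#' restricted to region spans declared by both haplotypes. Zero means the two
#' profiles are indistinguishable over the shared regions -- the criterion
#' used when screening ancient samples against modern researcher profiles.
#'
#' @param h1,h2 \code{mt_haplotype} objects.
#' @return Non-negative integer.
#' @export
haplotype_distance <- function(h1, h2) {
  shared <- intersect(h1$regions$name, h2$regions$name)
  if (length(shared) == 0) {
    stop("haplotypes declare no common region", call. = FALSE)
  }
  tot <- 0L
  for (nm in shared) {
    r1 <- h1$regions[h1$regions$name == nm, ]
    r2 <- h2$regions[h2$regions$name == nm, ]
    lo <- max(r1$start, r2$start); hi <- min(r1$end, r2$end)
    pick <- function(h) {
      v <- h$variants
      format_mt_variants(v[v$position >= lo & v$position <= hi, , drop = FALSE])
    }
    a <- pick(h1); b <- pick(h2)
    tot <- tot + length(setdiff(a, b)) + length(setdiff(b, a))
  }
  tot
}
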