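#' Read a Y-chromosome biallelic marker panel
#'
#' The panel lists, per marker, the haplogroup it defines, that haplogroup's
#' parent in the Y tree, and the ancestral/derived states as they appear in
#' sequencing read-outs (a base letter, a sequence motif whose loss is the
#' derived state, or \code{del}).
#'
#' @param path Panel TSV; defaults to the bundled 10-marker panel
#'   (M175, RPS4Y, M231, M174, M304, M242, M207, M173, M17, M343).
#' @return Data frame of class \code{y_panel}.
#' @export
read_y_panel <- function(path = palaeokin_file("y_marker_panel.tsv")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker", "haplogroup", "parent", "ancestral", "derived")
  if (!all(need %in% names(tab))) {
    stop("panel must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$marker) || anyDuplicated(tab$haplogroup)) {
    stop("panel markers and haplogroups must be unique", call. = FALSE)
  }
  bad <- !(tab$parent %in% c(tab$haplogroup, "root"))
  if (any(bad)) stop("unknown parent haplogroup: ", tab$parent[bad][1], call. = FALSE)
  class(tab) <- c("y_panel", class(tab))
  tab
}

#' Read Y-marker calls as printed states
#'
#' Reads a sample-by-marker table whose cells hold the observed state as
#' printed in sequencing summaries (\code{TTCTC}, a base letter, \code{del})
#' or a missing-data code (\code{-} for amplification failure, \code{ND} for
#' not done), and converts each cell to \code{ancestral} / \code{derived} /
#' \code{missing} against the panel.
#'
#' @param path Calls TSV with a \code{sample} column plus one column per
#'   marker.
#' @param panel Marker panel from [read_y_panel()].
#' @return Named list (by sample) of named state vectors.
#' @export
read_y_marker_calls <- function(path = palaeokin_file("y_marker_calls.tsv"),
                                panel = read_y_panel()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  markers <- setdiff(names(tab), "sample")
  unknown <- setdiff(markers, panel$marker)
  if (length(unknown)) stop("marker not in panel: ", unknown[1], call. = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    st <- vapply(markers, function(m) {
      raw <- as.character(tab[i, m])
      if (is.na(raw) || raw %in% c("-", "ND", "")) return("missing")
      p <- panel[panel$marker == m, ]
      if (raw == p$ancestral) return("ancestral")
      if (raw == p$derived) return("derived")
      stop("state '", raw, "' at marker ", m,
           " matches neither ancestral nor derived panel state", call. = FALSE)
    }, character(1))
    stats::setNames(st, markers)
  })
  names(out) <- tab$sample
  out
}

y_path <- function(panel, haplogroup) {
  path <- character()
  cur <- haplogroup
  while (cur != "root") {
    path <- c(cur, path)
    cur <- panel$parent[panel$haplogroup == cur]
  }
  path
}

#' Hierarchical Y-haplogroup assignment
#'
#' Returns the deepest haplogroup whose defining marker is observed in the
#' derived state and whose root-path contains no marker observed in the
#' ancestral state. Missing markers on the path do not block descent -- a
#' deeper derived call still wins -- but the result is flagged
#' \code{inferred}. Derived calls on incompatible branches (neither an
#' ancestor of the other) raise an inconsistency error. With no derived call
#' at all the sample stays at the root (\code{"undetermined"}).
#'
#' @param calls Named character vector of states (\code{ancestral} /
#'   \code{derived} / \code{missing}) per marker.
#' @param panel Marker panel from [read_y_panel()].
#' @return List with \code{label}, \code{support} (derived markers on the
#'   winning path) and \code{inferred} (TRUE when a path marker was missing).
#' @examples
#' panel <- read_y_panel()
#' calls <- read_y_marker_calls(panel = panel)
#' classify_y_haplogroup(calls$MN0104, panel)$label  # "R1b"
#' @export
classify_y_haplogroup <- function(calls, panel = read_y_panel()) {
  calls <- calls[names(calls) %in% panel$marker]
  if (length(calls) == 0 || all(calls == "missing")) {
    stop("at least one non-missing marker call is required", call. = FALSE)
  }
  derived <- names(calls)[calls == "derived"]
  if (length(derived) == 0) {
    return(list(label = "undetermined", support = character(), inferred = FALSE))
  }
  hg_of <- function(m) panel$haplogroup[panel$marker == m]
  marker_of <- function(hg) panel$marker[panel$haplogroup == hg]
  # candidates: derived markers whose root-path has no observed-ancestral call
  cand <- Filter(function(m) {
    path <- y_path(panel, hg_of(m))
    pmk <- vapply(path, marker_of, character(1))
    !any(calls[pmk] == "ancestral", na.rm = TRUE)
  }, derived)
  if (length(cand) == 0) {
    stop("derived call(s) at ", paste(derived, collapse = ", "),
         " contradicted by ancestral calls on their path", call. = FALSE)
  }
  # branch consistency: every pair of candidate haplogroups must be nested
  hgs <- vapply(cand, hg_of, character(1))
  paths <- lapply(hgs, y_path, panel = panel)
  for (a in seq_along(hgs)) for (b in seq_along(hgs)) {
    if (a < b && !(hgs[a] %in% paths[[b]]) && !(hgs[b] %in% paths[[a]])) {
      stop("inconsistent derived calls on incompatible branches: ",
           cand[a], " (", hgs[a], ") vs ", cand[b], " (", hgs[b], ")",
           call. = FALSE)
    }
  }
  deepest <- which.max(lengths(paths))
  path <- paths[[deepest]]
  pmk <- vapply(path, marker_of, character(1))
  list(label = unname(hgs[deepest]),
       support = unname(pmk[calls[pmk] == "derived" & !is.na(calls[pmk])]),
       inferred = any(calls[pmk] == "missing", na.rm = TRUE))
}

#' Compare two Y-STR haplotypes locus by locus
#'
#' Only loci typed in both profiles are counted. At each such locus the
#' allele multisets are compared: equal multisets are \code{identical},
#' overlapping-but-unequal are \code{partial}, disjoint are \code{mismatch}.
#' A single reported value at a duplicated locus (e.g. DYS385 "13") is
#' treated as one observed allele with the second possibly dropped out: it
#' scores \code{identical} against a partner carrying only that allele and
#' \code{partial} against a partner carrying it alongside a second, distinct
#' allele.
#'
#' @param p1,p2 Named character vectors (or one-row data frames) of genotype
#'   strings per locus; \code{"-"} marks a failed locus.
#' @return List of class \code{y_match_summary} with counts
#'   \code{definable_both}, \code{identical}, \code{partial},
#'   \code{mismatch}, and a per-locus category vector.
#' @export
compare_y_str <- function(p1, p2) {
  p1 <- unlist(p1); p2 <- unlist(p2)
  loci <- intersect(names(p1), names(p2))
  g1 <- parse_genotype(p1[loci]); g2 <- parse_genotype(p2[loci])
  both <- !vapply(g1, is.null, logical(1)) & !vapply(g2, is.null, logical(1))
  cat_of <- function(a, b) {
    if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
    if (length(a) == length(b)) {
      if (identical(sort(a), sort(b))) return("identical")
      if (shared_allele_count(a, b) > 0) return("partial")
      return("mismatch")
    }
    # one observed allele vs two: dropout-aware scoring
    if (!(a %in% b)) return("mismatch")
    if (length(unique(b)) == 1) "identical" else "partial"
  }
  cats <- stats::setNames(rep(NA_character_, length(loci)), loci)
  cats[both] <- mapply(function(a, b) cat_of(a, b), g1[both], g2[both])
  structure(list(definable_both = sum(both),
                 identical = sum(cats == "identical", na.rm = TRUE),
                 partial = sum(cats == "partial", na.rm = TRUE),
                 mismatch = sum(cats == "mismatch", na.rm = TRUE),
                 by_locus = cats),
            class = "y_match_summary")
}

#' @export
print.y_match_summary <- function(x, ...) {
  cat(sprintf("Y-STR comparison: %d loci definable in both; %d identical, %d partial, %d mismatch\n",
              x$definable_both, x$identical, x$partial, x$mismatch))
  invisible(x)
}

#' Serialize a Y-STR match summary to JSON
#'
#' @param x A \code{y_match_summary}.
#' @param path Optional output path; with \code{NULL} the JSON string is
#'   returned.
#' @export
write_y_match_json <- function(x, path = NULL) {
  payload <- list(definable_both = x$definable_both, identical = x$identical,
                  partial = x$partial, mismatch = x$mismatch,
                  by_locus = as.list(x$by_locus))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null", na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
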