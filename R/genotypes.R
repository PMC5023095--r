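#' Parse an STR genotype string
#'
#' STR genotypes are written in the forensic "a/b" convention: two alleles
#' separated by a slash for diploid (or duplicated-locus) calls, a single
#' value for haploid or single-allele observations, and "-" (or empty) for a
#' failed amplification. Microvariant alleles such as \code{33.2} are kept as
#' numeric values.
#'
#' @param text Character vector of genotype strings (e.g. \code{"11/12"},
#'   \code{"13"}, \code{"-"}).
#' @return A list of sorted numeric allele vectors; \code{NULL} elements mark
#'   missing calls.
#' @examples
#' parse_genotype(c("11/12", "30/33.2", "-"))
#' @export
parse_genotype <- function(text) {
  lapply(text, function(x) {
    if (is.na(x) || !nzchar(x) || x %in% c("-", "ND", "NA")) return(NULL)
    a <- suppressWarnings(as.numeric(strsplit(x, "/", fixed = TRUE)[[1]]))
    if (anyNA(a) || any(a <= 0)) {
      stop("malformed genotype string: '", x, "'", call. = FALSE)
    }
    if (length(a) > 2) {
      stop("genotype '", x, "' has more than two alleles", call. = FALSE)
    }
    sort(a)
  })
}

#' Format allele vectors back to genotype strings
#'
#' Inverse of [parse_genotype()]: alleles are sorted and joined with "/";
#' \code{NULL} (missing) becomes \code{"-"}.
#'
#' @param alleles A numeric allele vector or a list of them.
#' @return Character vector of genotype strings.
#' @export
format_genotype <- function(alleles) {
  if (is.numeric(alleles)) alleles <- list(alleles)
  vapply(alleles, function(a) {
    if (is.null(a) || length(a) == 0) "-" else
      paste(vapply(sort(a), format, character(1), trim = TRUE,
                   scientific = FALSE), collapse = "/")
  }, character(1))
}

# canonical vote key for consensus: sorted alleles joined by "/"
geno_key <- function(alleles) format_genotype(alleles)

#' Number of alleles shared identical-by-state between two genotypes
#'
#' The size of the largest one-to-one matching between the two allele
#' multisets: \code{29/29} vs \code{30/33.2} share 0, \code{13/17} vs
#' \code{13/13} share 1, identical heterozygotes share 2. A count of 0 at an
#' autosomal locus is a Mendelian exclusion for parent-offspring under a
#' no-mutation model.
#'
#' @param g1,g2 Numeric allele vectors (length 1 or 2), or genotype strings.
#' @return Integer 0, 1 or 2.
#' @examples
#' shared_allele_count(c(29, 29), c(30, 33.2))  # 0
#' shared_allele_count("13/17", "13/13")        # 1
#' @export
shared_allele_count <- function(g1, g2) {
  if (is.character(g1)) g1 <- parse_genotype(g1)[[1]]
  if (is.character(g2)) g2 <- parse_genotype(g2)[[1]]
  if (is.null(g1) || is.null(g2)) {
    stop("shared_allele_count requires two non-missing genotypes", call. = FALSE)
  }
  t1 <- table(g1)
  t2 <- table(g2)
  common <- intersect(names(t1), names(t2))
  if (length(common) == 0) return(0L)
  as.integer(sum(pmin(t1[common], t2[common])))
}
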