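#' Path to a bundled data file
#'
#' The package ships the printed study tables (mtDNA haplotypes, Y-marker
#' states, Y-STR and A-STR replicate profiles), the diagnostic haplogroup
#' rule files, and two explicitly synthetic stand-ins: an allele-frequency
#' table for the 8-locus autosomal panel (the study's population reference
#' table is unpublished) and a control-region reference segment used for
#' sequence-level demonstrations.
#'
#' @param file File name under \code{inst/extdata}; with no argument, lists
#'   the available files.
#' @return A file path, or a character vector of file names.
#' @examples
#' palaeokin_file()
#' palaeokin_file("astr_replicates.tsv")
#' @export
palaeokin_file <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "palaeokin")))
  }
  p <- system.file("extdata", file, package = "palaeokin")
  if (!nzchar(p)) stop("no bundled file named '", file, "'", call. = FALSE)
  p
}
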