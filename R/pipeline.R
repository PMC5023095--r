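#' Study configuration
#'
#' Bundles the input paths and analysis settings for [run_study()]. The
#' defaults point at the packaged study tables and the bundled synthetic
#' allele-frequency table.
#'
#' @param mt_haplotypes,mt_rules,y_panel,y_calls,ystr_replicates,astr_replicates,allele_freqs
#'   Input file paths.
#' @param min_fraction,min_count Consensus thresholds (see
#'   [call_consensus()]).
#' @param hypotheses Kinship hypothesis labels to evaluate.
#' @param priors Optional named prior vector (default uniform).
#' @param autosomal_loci Autosomal locus panel (amelogenin excluded).
#' @return List of class \code{study_config}.
#' @export
study_config <- function(mt_haplotypes = palaeokin_file("mt_haplotypes.tsv"),
                         mt_rules = palaeokin_file("mt_haplogroup_rules.tsv"),
                         y_panel = palaeokin_file("y_marker_panel.tsv"),
                         y_calls = palaeokin_file("y_marker_calls.tsv"),
                         ystr_replicates = palaeokin_file("ystr_replicates.tsv"),
                         astr_replicates = palaeokin_file("astr_replicates.tsv"),
                         allele_freqs = palaeokin_file("allele_freqs_synthetic.tsv"),
                         min_fraction = 0.5, min_count = 2L,
                         hypotheses = c("unrelated", "parent_offspring",
                                        "full_sibling"),
                         priors = NULL,
                         autosomal_loci = NULL) {
  paths <- c(mt_haplotypes = mt_haplotypes, mt_rules = mt_rules,
             y_panel = y_panel, y_calls = y_calls,
             ystr_replicates = ystr_replicates,
             astr_replicates = astr_replicates, allele_freqs = allele_freqs)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(paths = as.list(paths), min_fraction = min_fraction,
                 min_count = as.integer(min_count), hypotheses = hypotheses,
                 priors = priors, autosomal_loci = autosomal_loci),
            class = "study_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full molecular-genealogy study
#'
#' Executes consensus calling, mtDNA and Y haplogroup classification, Y-STR
#' haplotype matching, pairwise kinship inference, the trio Mendelian check
#' and the researcher contamination screen, in that order, on the configured
#' inputs. The report is deterministic on fixed inputs (stable ordering, no
#' timestamps).
#'
#' @param config A [study_config()].
#' @return List of class \code{study_report}.
#' @examples
#' rep <- run_study(study_config())
#' rep$astr$discordant_cells   # 5 of 48
#' @export
run_study <- function(config = study_config()) {
  mt <- stage("mt-haplotypes", read_mt_haplotypes(config$paths$mt_haplotypes))
  rules <- stage("mt-rules", read_haplogroup_rules(config$paths$mt_rules))
  body_ids <- unique(mt$table$sample[mt$table$role == "body"])
  researcher_ids <- unique(mt$table$sample[mt$table$role == "researcher"])
  if (length(body_ids) == 0) {
    return(structure(list(schema_version = 1L, samples = character(),
                          mt = NULL, y = NULL, ystr = NULL, astr = NULL,
                          kinship = NULL, authenticity = NULL),
                     class = "study_report"))
  }

  mt_calls <- stage("mt-classify", {
    out <- lapply(mt$haplotypes[body_ids], classify_mt_haplogroup, rules = rules)
    stats::setNames(out, body_ids)
  })

  panel <- stage("y-panel", read_y_panel(config$paths$y_panel))
  y_states <- stage("y-calls", read_y_marker_calls(config$paths$y_calls, panel))
  y_calls <- stage("y-classify",
    lapply(y_states, classify_y_haplogroup, panel = panel))

  ystr <- stage("ystr-consensus", {
    tab <- read_replicate_table(config$paths$ystr_replicates)
    profs <- lapply(unique(tab$sample), function(s)
      call_consensus(tab, s, min_fraction = config$min_fraction,
                     min_count = config$min_count))
    names(profs) <- unique(tab$sample)
    profs
  })
  ystr_geno <- lapply(ystr, function(p)
    stats::setNames(ifelse(is.na(p$consensus), "-", p$consensus), p$locus))
  ystr_pairs <- list()
  ids <- names(ystr)
  for (a in seq_along(ids)) for (b in seq_along(ids)) if (a < b) {
    ystr_pairs[[paste(ids[a], ids[b], sep = "-")]] <-
      compare_y_str(ystr_geno[[a]], ystr_geno[[b]])
  }

  astr_tab <- stage("astr-read", read_replicate_table(config$paths$astr_replicates))
  loci <- config$autosomal_loci
  if (is.null(loci)) loci <- setdiff(attr(astr_tab, "loci"), "Amel")
  astr <- stage("astr-consensus", {
    profs <- lapply(unique(astr_tab$sample), function(s)
      call_consensus(astr_tab, s, loci, config$min_fraction, config$min_count))
    names(profs) <- unique(astr_tab$sample)
    profs
  })
  disc <- count_discordances(astr_tab, loci,
                             min_fraction = config$min_fraction,
                             min_count = config$min_count)
  sex <- vapply(unique(astr_tab$sample), function(s)
    sex_from_amelogenin(astr_tab, s), character(1))

  freqs <- stage("frequencies", read_allele_freqs(config$paths$allele_freqs))
  hyps <- kinship_hypotheses(config$hypotheses)
  kin <- stage("kinship", {
    out <- list()
    aids <- names(astr)
    for (a in seq_along(aids)) for (b in seq_along(aids)) if (a < b) {
      key <- paste(aids[a], aids[b], sep = "-")
      res <- classify_pair(astr[[aids[a]]], astr[[aids[b]]], freqs,
                           hypotheses = hyps, priors = config$priors)
      for (sc in res$scenarios) {
        if (nzchar(sc$scenario)) {
          message("kinship ", key, ": ambiguous locus expanded, scenario ",
                  sc$scenario)
        }
      }
      out[[key]] <- res
    }
    out
  })

  trio <- NULL
  if (all(c("MN0125", "MN0104", "MN0126") %in% names(astr))) {
    trio <- stage("trio", trio_mendelian_check(
      astr[["MN0125"]], list(astr[["MN0104"]], astr[["MN0126"]])))
  }

  screen <- stage("contamination", {
    refs <- mt$haplotypes[researcher_ids]
    if (length(refs) == 0) NULL else {
      out <- lapply(mt$haplotypes[body_ids], screen_contamination,
                    references = refs)
      stats::setNames(out, body_ids)
    }
  })

  structure(list(
    schema_version = 1L,
    samples = body_ids,
    mt = list(haplogroups = vapply(mt_calls, `[[`, character(1), "label"),
              detail = mt_calls),
    y = list(haplogroups = vapply(y_calls, `[[`, character(1), "label"),
             inferred = vapply(y_calls, `[[`, logical(1), "inferred"),
             detail = y_calls),
    sex = sex,
    ystr = list(profiles = ystr, matches = ystr_pairs),
    astr = list(profiles = astr,
                discordant_cells = disc$discordant_cells,
                total_cells = disc$total_cells,
                discordance_flags = disc$flags),
    kinship = kin,
    trio = trio,
    authenticity = list(
      contamination = screen,
      pass = if (is.null(screen)) NA else
        vapply(screen, function(d) nrow(d) == 0, logical(1)))
  ), class = "study_report")
}

#' Serialize a study report to canonical JSON
#'
#' Writes a stable, timestamp-free JSON rendering of the report's summary
#' quantities (haplogroup labels, sex calls, discordance counts, Y-STR match
#' counts, kinship posteriors and exclusions, trio compatibility,
#' contamination screen outcome). Running the study twice on the same inputs
#' yields byte-identical files.
#'
#' @param report A \code{study_report}.
#' @param path Output path; with \code{NULL} the JSON string is returned.
#' @export
write_study_report <- function(report, path = NULL) {
  kin <- lapply(report$kinship, function(res) {
    lapply(res$scenarios, function(sc) {
      list(scenario = sc$scenario,
           exclusion_loci = as.list(sc$exclusion_loci),
           lrs = as.list(sc$lrs),
           posteriors = as.list(sc$posteriors))
    })
  })
  ystr <- lapply(report$ystr$matches, function(m)
    list(definable_both = m$definable_both, identical = m$identical,
         partial = m$partial, mismatch = m$mismatch))
  trio <- if (!is.null(report$trio)) {
    s <- attr(report$trio, "summary")
    stats::setNames(lapply(seq_len(nrow(s)), function(i)
      list(compatible_loci = s$compatible_loci[i],
           tested_loci = s$tested_loci[i])), s$child)
  }
  payload <- list(
    schema_version = report$schema_version,
    samples = as.list(report$samples),
    mt_haplogroups = as.list(report$mt$haplogroups),
    y_haplogroups = as.list(report$y$haplogroups),
    sex = as.list(report$sex),
    ystr_matches = ystr,
    astr_discordance = list(discordant_cells = report$astr$discordant_cells,
                            total_cells = report$astr$total_cells),
    kinship = kin,
    trio = trio,
    contamination_pass = as.list(report$authenticity$pass)
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
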