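#' Serialize a trait localization as a JSON report
#'
#' The report carries the flanking markers, recombinant counts, the
#' per-interval recombination estimates (r with its binomial standard
#' error) and any warnings.
#'
#' @param localization A [localize_trait()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_localization_json <- function(localization, path) {
  report <- list(
    trait = localization$trait_name,
    proximal_flank = localization$proximal_flank,
    distal_flank = localization$distal_flank,
    n_proximal_recombinants = localization$n_proximal_recombinants,
    n_distal_recombinants = localization$n_distal_recombinants,
    inside_markers = localization$inside_markers,
    interval_bp = localization$interval_bp,
    intervals = interval_estimates(localization$haplotypes),
    warnings = localization$warnings
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Serialize a consequence report (plus upstream results) as JSON
#'
#' Aggregates the deletion call, overlap annotation, triage outcome and
#' splice-consequence prediction into a single machine-readable report.
#'
#' @param consequence A [predict_consequence()] result.
#' @param path Output file path.
#' @param triage_result Optional [triage()] result to include.
#' @param localization Optional [localize_trait()] result to include.
#' @return `path`, invisibly.
#' @export
write_consequence_json <- function(consequence, path, triage_result = NULL,
                                   localization = NULL) {
  call <- consequence$annotation$call
  report <- list(
    gene = consequence$gene,
    deletion = list(chrom = call$chrom, start_bp = call$start_bp,
                    length_bp = call$length_bp,
                    ambiguity_span = call$ambiguity_span),
    overlap = list(genes = consequence$annotation$genes,
                   splice_sites_lost = consequence$annotation$splice_sites_lost),
    skipped_exons = consequence$skipped_exons,
    wt_amplicon_bp = consequence$wt_amplicon_bp,
    mut_amplicon_bp = consequence$mut_amplicon_bp,
    frameshift = consequence$frameshift,
    last_identical_residue = consequence$last_identical_residue,
    novel_residues = consequence$novel_residues,
    wt_protein_aa = consequence$wt_protein_aa,
    mut_protein_aa = consequence$mut_protein_aa,
    truncated_domains = consequence$truncated_domains
  )
  if (!is.null(triage_result)) {
    report$triage <- list(primary = triage_result$primary,
                          excluded = triage_result$excluded)
  }
  if (!is.null(localization)) {
    report$localization <- list(
      proximal_flank = localization$proximal_flank,
      distal_flank = localization$distal_flank,
      interval_bp = localization$interval_bp)
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
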