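# Standard nuclear codon table.
CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

#' Translate a CDS with the standard nuclear codon table
#'
#' Translation starts at `cds_start` (0-based transcript offset) and runs
#' codon by codon until the first stop codon or the end of the sequence;
#' the stop is not included in the product. If the end is reached without
#' an in-frame stop, the result carries the attribute
#' `no_in_frame_stop = TRUE`. Codons containing characters outside ACGT
#' translate to `X`. No alternative genetic codes are supported.
#'
#' @param transcript Nucleotide string (character or
#'   [Biostrings::DNAString]).
#' @param cds_start 0-based offset of the first codon.
#' @return Amino-acid string (single-letter codes).
#' @examples
#' translate_cds("ATGAAATAG", 0)  # "MK"
#' @export
translate_cds <- function(transcript, cds_start = 0) {
  transcript <- toupper(as.character(transcript))
  n <- nchar(transcript)
  if (n < cds_start + 3) abort("transcript too short to hold one codon")
  starts <- seq(cds_start + 1, n - 2, by = 3)
  codons <- substring(transcript, starts, starts + 2)
  aa <- unname(CODON_TABLE[codons])
  aa[is.na(aa)] <- "X"
  stop_at <- match("*", aa)
  if (is.na(stop_at)) {
    structure(paste0(aa, collapse = ""), no_in_frame_stop = TRUE)
  } else {
    paste0(aa[seq_len(stop_at - 1)], collapse = "")
  }
}

#' Compare wild-type and mutant protein sequences by common prefix
#'
#' Adequate for single-junction frameshifts: the proteins are identical up
#' to the divergence point, after which the mutant carries novel residues.
#' `last_identical_residue` is the common-prefix length, `novel_residues`
#' the number of mutant residues beyond it, and a frameshift is reported
#' (as `"after codon k"`) whenever the mutant diverges from the wild type
#' before its own end.
#'
#' @param wt,mut Amino-acid strings.
#' @return A list: `last_identical_residue`, `novel_residues`,
#'   `frameshift`, `wt_protein_aa`, `mut_protein_aa`.
#' @examples
#' compare_proteins("MKLV", "MKQ")  # last identical 2, novel 1
#' @export
compare_proteins <- function(wt, mut) {
  wt <- as.character(wt)
  mut <- as.character(mut)
  prefix <- Biostrings::lcprefix(Biostrings::BString(wt),
                                 Biostrings::BString(mut))
  prefix <- min(prefix, nchar(wt), nchar(mut))
  novel <- nchar(mut) - prefix
  list(
    last_identical_residue = as.integer(prefix),
    novel_residues = as.integer(novel),
    frameshift = if (novel > 0) paste0("after codon ", prefix) else "none",
    wt_protein_aa = nchar(wt),
    mut_protein_aa = nchar(mut)
  )
}

#' Fraction of each protein domain retained after truncation
#'
#' A mutant diverging at residue `d` retains a domain spanning residues
#' `[aa_start, aa_end]` (1-based inclusive) identically over
#' `max(0, min(d, aa_end) - aa_start + 1)` of its residues. Domains with
#' retention below 1 are flagged truncated.
#'
#' @param comparison A [compare_proteins()] result (or a list with
#'   `last_identical_residue`).
#' @param domains A data frame: `name`, `aa_start`, `aa_end`.
#' @return A tibble: `domain`, `aa_start`, `aa_end`, `fraction_retained`,
#'   `truncated`.
#' @export
domain_overlap <- function(comparison, domains) {
  if (is.null(domains) || nrow(domains) == 0) {
    return(tibble(domain = character(), aa_start = integer(),
                  aa_end = integer(), fraction_retained = numeric(),
                  truncated = logical()))
  }
  d <- comparison$last_identical_residue
  domains <- as_tibble(domains)
  span <- domains$aa_end - domains$aa_start + 1
  retained <- pmax(0, pmin(d, domains$aa_end) - domains$aa_start + 1) / span
  tibble(domain = domains$name, aa_start = domains$aa_start,
         aa_end = domains$aa_end, fraction_retained = retained,
         truncated = retained < 1)
}

# Lift a genomic position through a deletion [d0, d1): positions in the
# deleted block collapse onto d0.
lift_position <- function(pos, d0, d1) {
  ifelse(pos >= d1, pos - (d1 - d0), pmin(pos, d0))
}

#' Predict the mutant gene model produced by a genomic deletion
#'
#' Applies the structural exon-skipping rule: every exon whose splice
#' acceptor is lost (per [annotate_deletion()]) is skipped from the mutant
#' transcript — donor loss triggers skipping symmetrically — while exons
#' partially deleted but with intact splice sites keep their remaining
#' sequence, and deletions strictly internal to an intron leave the spliced
#' transcript unchanged. Exon coordinates are lifted onto the deleted
#' genome and transcription-order ordinals are preserved, so primer pairs
#' keep addressing the surviving exons. The rule is purely structural
#' (splice-site presence); splicing strength and branch points are not
#' modeled.
#'
#' @param model The wild-type [gene_model()].
#' @param call A [find_deletion()] result.
#' @param annotation Optional [annotate_deletion()] result computed against
#'   this model (recomputed when omitted).
#' @return A [gene_model()] on the deleted genome (frame check relaxed).
#' @export
predict_mutant_model <- function(model, call, annotation = NULL) {
  if (is.null(annotation)) annotation <- annotate_deletion(call, list(model))
  d0 <- call$start_bp
  d1 <- call$start_bp + call$length_bp

  sites <- annotation$splice_sites_lost
  lost_ords <- unique(sites$exon_ordinal[sites$gene == model$name])

  ex <- model$exons
  fully_deleted <- ex$start >= d0 & ex$end <= d1
  drop <- ex$ordinal %in% lost_ords | fully_deleted

  # transcript-coordinate bookkeeping of removed bases (exon drop or
  # direct exonic deletion), to relocate the CDS start on the mutant
  lens <- exon_lengths(model)
  before <- c(0, cumsum(lens)[-length(lens)])
  removed <- purrr::map_dfr(seq_len(nrow(ex)), function(i) {
    t0 <- before[i]
    t1 <- before[i] + lens[i]
    if (drop[i]) return(tibble(t0 = t0, t1 = t1))
    ov <- interval_overlap(ex$start[i], ex$end[i], d0, d1)
    if (ov == 0) return(NULL)
    if (model$strand == "+") {
      a <- max(ex$start[i], d0) - ex$start[i]
      tibble(t0 = t0 + a, t1 = t0 + a + ov)
    } else {
      b <- ex$end[i] - max(ex$start[i], d0)
      tibble(t0 = t0 + (ex$end[i] - min(ex$end[i], d1)), t1 = t0 + b)
    }
  })

  cds_start_genomic <- transcript_to_genomic(
    model, seq(model$cds_start, model$cds_start + 2))
  start_codon_deleted <- any(cds_start_genomic >= d0 & cds_start_genomic < d1)
  start_exon <- model$exons$ordinal[
    findInterval(model$cds_start, before)]
  if (start_codon_deleted || start_exon %in% ex$ordinal[drop]) {
    abort("start lost: the deletion removes the CDS start codon")
  }

  removed_before <- function(x) {
    if (nrow(removed) == 0) return(0)
    sum(pmax(0, pmin(removed$t1, x) - removed$t0))
  }
  new_cds_start <- model$cds_start - removed_before(model$cds_start)
  new_cds_end <- model$cds_end - removed_before(model$cds_end)

  # partially deleted exons clip to their surviving genomic footprint
  kept <- ex[!drop, ]
  new_exons <- tibble(
    ordinal = kept$ordinal,
    start = lift_position(ifelse(kept$start >= d0 & kept$start < d1,
                                 d1, kept$start), d0, d1),
    end = lift_position(ifelse(kept$end > d0 & kept$end <= d1,
                               d0, kept$end), d0, d1)
  )
  new_exons <- new_exons[new_exons$end > new_exons$start, ]

  new_tlen <- sum(new_exons$end - new_exons$start)
  out <- gene_model(model$name, model$strand, new_exons,
                    cds_start = new_cds_start,
                    cds_end = min(new_cds_end, new_tlen),
                    domains = model$domains, check_frame = FALSE)
  # wild-type transcript intervals removed by the deletion (exon drops plus
  # direct exonic deletion); used downstream for the frame rule
  attr(out, "removed_tx") <- removed
  out
}

#' Predict the full splice consequence of a deletion for one gene
#'
#' Convenience pipeline: annotates the deletion, derives the mutant model
#' by the exon-skipping rule, splices and translates both alleles,
#' predicts RT-PCR product lengths for a primer pair, compares the
#' proteins, and reports domain truncation.
#'
#' @param model Wild-type [gene_model()].
#' @param genome Wild-type genomic sequence.
#' @param call A [find_deletion()] result.
#' @param primers A [primer_pair()] on the wild-type exons.
#' @param annotation Optional precomputed [annotate_deletion()] result.
#' @return A list of class `consequence_report`: `gene`, `skipped_exons`,
#'   `wt_amplicon_bp`, `mut_amplicon_bp`, `frameshift`,
#'   `last_identical_residue`, `novel_residues`, `wt_protein_aa`,
#'   `mut_protein_aa`, `truncated_domains`, plus the underlying models and
#'   proteins.
#' @export
predict_consequence <- function(model, genome, call, primers,
                                annotation = NULL) {
  genome <- as.character(genome)
  if (is.null(annotation)) annotation <- annotate_deletion(call, list(model))
  mutant_model <- predict_mutant_model(model, call, annotation)
  mutant_genome <- apply_deletion(genome, call$start_bp, call$length_bp)

  wt_tx <- splice(model, genome)
  mut_tx <- splice(mutant_model, mutant_genome)
  wt_prot <- translate_cds(wt_tx, model$cds_start)
  mut_prot <- translate_cds(mut_tx, mutant_model$cds_start)
  cmp <- compare_proteins(wt_prot, mut_prot)
  # frame rule: a frameshift occurs iff the number of removed coding
  # nucleotides is not a multiple of 3; an in-frame skip diverges at the
  # junction without shifting the frame
  removed <- attr(mutant_model, "removed_tx")
  removed_coding <- if (is.null(removed) || nrow(removed) == 0) 0 else {
    sum(pmax(0, pmin(removed$t1, model$cds_end) -
               pmax(removed$t0, model$cds_start)))
  }
  cmp$frameshift <- if (removed_coding %% 3 == 0) "none" else cmp$frameshift
  domains <- domain_overlap(cmp, model$domains)

  structure(c(list(
    gene = model$name,
    skipped_exons = setdiff(model$exons$ordinal, mutant_model$exons$ordinal),
    wt_amplicon_bp = predict_amplicon(model, primers),
    mut_amplicon_bp = predict_amplicon(mutant_model, primers)),
    cmp,
    list(
      truncated_domains = domains[domains$truncated, ],
      domains = domains,
      wt_model = model, mutant_model = mutant_model,
      wt_protein = wt_prot, mutant_protein = mut_prot,
      annotation = annotation)
  ), class = "consequence_report")
}

#' @export
print.consequence_report <- function(x, ...) {
  cat(sprintf("<consequence_report> %s\n", x$gene))
  cat(sprintf("  skipped exon(s): %s\n",
              if (length(x$skipped_exons) == 0) "none"
              else paste(x$skipped_exons, collapse = ", ")))
  cat(sprintf("  RT-PCR product: %d bp wild type, %d bp mutant\n",
              x$wt_amplicon_bp, x$mut_amplicon_bp))
  cat(sprintf("  frameshift: %s; %d novel residue(s)\n",
              x$frameshift, x$novel_residues))
  cat(sprintf("  protein: %d aa wild type -> %d aa mutant\n",
              x$wt_protein_aa, x$mut_protein_aa))
  if (nrow(x$truncated_domains) > 0) {
    d <- x$truncated_domains
    cat("  truncated domains:",
        paste(sprintf("%s (%.0f%% retained)", d$domain,
                      100 * d$fraction_retained), collapse = "; "), "\n")
  }
  invisible(x)
}

#' @rdname predict_consequence
#' @param x A `consequence_report`.
#' @param ... Unused.
#' @export
glance.consequence_report <- function(x, ...) {
  tibble(gene = x$gene,
         skipped_exons = paste(x$skipped_exons, collapse = ","),
         wt_amplicon_bp = x$wt_amplicon_bp,
         mut_amplicon_bp = x$mut_amplicon_bp,
         frameshift = x$frameshift,
         last_identical_residue = x$last_identical_residue,
         novel_residues = x$novel_residues,
         wt_protein_aa = x$wt_protein_aa,
         mut_protein_aa = x$mut_protein_aa,
         n_truncated_domains = nrow(x$truncated_domains))
}

#' @rdname predict_consequence
#' @export
tidy.consequence_report <- function(x, ...) x$domains
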