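#' Detect a single contiguous deletion between coisogenic sequences
#'
#' Coisogenic strains differ at a single mutated locus, so the mutant
#' sequence must equal the wild-type sequence with one contiguous block
#' removed; anything else is an error by contract. The comparator is
#' alignment-free: it takes the longest common prefix `P` and suffix `S`
#' of the two sequences, requires `P + S >= length(mutant)` (every base of
#' the mutant explained), and reports the left-aligned placement. Within a
#' repetitive context several placements are equivalent; the number of
#' equivalent left shifts absorbed is reported as `ambiguity_span`.
#'
#' @param wild,mutant Nucleotide sequences (character or
#'   [Biostrings::DNAString]); `mutant` must be shorter than `wild`.
#' @param chrom Chromosome/sequence label recorded on the call.
#' @return A list of class `deletion_call`: `chrom`, `start_bp` (0-based,
#'   left-aligned), `length_bp`, `ambiguity_span`.
#' @examples
#' find_deletion("AACGTTT", "AATTT")  # start 2, length 2
#' @export
find_deletion <- function(wild, mutant, chrom = "chr") {
  wild <- as.character(wild)
  mutant <- as.character(mutant)
  lw <- nchar(wild)
  lm <- nchar(mutant)
  if (lw == 0 || lm == 0) abort("sequences must be non-empty")
  if (lm >= lw) {
    if (lm == lw && wild != mutant) {
      p <- Biostrings::lcprefix(Biostrings::BString(wild),
                                Biostrings::BString(mutant))
      abort(paste0("not a simple deletion: equal-length sequences mismatch ",
                   "at position ", p + 1))
    }
    abort("`mutant` must be shorter than `wild`")
  }
  bw <- Biostrings::BString(wild)
  bm <- Biostrings::BString(mutant)
  p <- Biostrings::lcprefix(bw, bm)
  s <- Biostrings::lcsuffix(bw, bm)
  if (p + s < lm) {
    abort(paste0("not a simple deletion: sequences conflict at position ",
                 p + 1, " beyond any single contiguous deletion"))
  }
  len <- lw - lm
  start <- max(0L, lm - s)
  structure(list(chrom = chrom, start_bp = as.integer(start),
                 length_bp = as.integer(len),
                 ambiguity_span = as.integer(min(p, lm) - start)),
            class = "deletion_call")
}

#' @export
print.deletion_call <- function(x, ...) {
  cat(sprintf("<deletion_call> %s:%d-%d (0-based), %d bp deleted, ambiguity %d\n",
              x$chrom, x$start_bp, x$start_bp + x$length_bp,
              x$length_bp, x$ambiguity_span))
  invisible(x)
}

interval_overlap <- function(a0, a1, b0, b1) pmax(0, pmin(a1, b1) - pmax(a0, b0))

#' Annotate a deletion's overlap with gene models
#'
#' For each gene the deletion is classified as `intronic_only` or
#' `removes_exonic_sequence`; features hit are listed with the fraction of
#' each removed, and canonical splice sites lost are reported. A splice
#' acceptor is the last 2 intronic nt plus the first exonic nt of an exon
#' (in transcription orientation); a donor is the last exonic nt plus the
#' first 2 intronic nt. Losing any part of a site counts as loss. Ordinals
#' are transcription-order, so the classification is strand-aware.
#'
#' @param call A [find_deletion()] result (or a list with `start_bp`,
#'   `length_bp`).
#' @param models A list of [gene_model()] objects.
#' @return A list of class `overlap_annotation`: `genes` (tibble: `gene`,
#'   `classification`), `features_hit` (tibble: `gene`, `feature`,
#'   `ordinal`, `fraction_removed`), `splice_sites_lost` (tibble: `gene`,
#'   `exon_ordinal`, `site`).
#' @export
annotate_deletion <- function(call, models) {
  if (inherits(models, "gene_model")) models <- list(models)
  d0 <- call$start_bp
  d1 <- call$start_bp + call$length_bp

  genes <- NULL
  feats <- NULL
  sites <- NULL
  for (model in models) {
    ex <- model$exons
    ex_ov <- interval_overlap(ex$start, ex$end, d0, d1)
    intr <- intron_table(model)
    in_ov <- if (nrow(intr) > 0) {
      interval_overlap(intr$start, intr$end, d0, d1)
    } else numeric(0)
    if (all(ex_ov == 0) && all(in_ov == 0)) next

    cls <- if (any(ex_ov > 0)) "removes_exonic_sequence" else "intronic_only"
    genes <- dplyr::bind_rows(genes, tibble(gene = model$name,
                                            classification = cls))
    if (any(ex_ov > 0)) {
      hit <- ex_ov > 0
      feats <- dplyr::bind_rows(feats, tibble(
        gene = model$name, feature = "exon", ordinal = ex$ordinal[hit],
        fraction_removed = ex_ov[hit] / (ex$end[hit] - ex$start[hit])))
    }
    if (any(in_ov > 0)) {
      hit <- in_ov > 0
      feats <- dplyr::bind_rows(feats, tibble(
        gene = model$name, feature = "intron", ordinal = intr$ordinal[hit],
        fraction_removed = in_ov[hit] / (intr$end[hit] - intr$start[hit])))
    }
    ss <- splice_site_table(model)
    if (nrow(ss) > 0) {
      lost <- interval_overlap(ss$start, ss$end, d0, d1) > 0
      if (any(lost)) {
        sites <- dplyr::bind_rows(sites, tibble(
          gene = model$name, exon_ordinal = ss$exon_ordinal[lost],
          site = ss$site[lost]))
      }
    }
  }
  if (is.null(genes)) {
    warn("deletion overlaps no gene model")
    genes <- tibble(gene = character(), classification = character())
  }
  structure(list(
    genes = genes,
    features_hit = feats %||% tibble(gene = character(), feature = character(),
                                     ordinal = integer(),
                                     fraction_removed = numeric()),
    splice_sites_lost = sites %||% tibble(gene = character(),
                                          exon_ordinal = integer(),
                                          site = character()),
    call = call
  ), class = "overlap_annotation")
}

#' @export
print.overlap_annotation <- function(x, ...) {
  cat(sprintf("<overlap_annotation> %d bp deletion at %s:%d\n",
              x$call$length_bp, x$call$chrom, x$call$start_bp))
  for (i in seq_len(nrow(x$genes))) {
    cat(sprintf("  %s: %s\n", x$genes$gene[i], x$genes$classification[i]))
  }
  if (nrow(x$splice_sites_lost) > 0) {
    s <- x$splice_sites_lost
    cat("  splice sites lost:",
        paste(sprintf("%s exon %d %s", s$gene, s$exon_ordinal, s$site),
              collapse = "; "), "\n")
  }
  invisible(x)
}

#' @rdname annotate_deletion
#' @param x An `overlap_annotation`.
#' @param ... Unused.
#' @export
tidy.overlap_annotation <- function(x, ...) x$features_hit

#' Write a deletion call as a minimal VCF 4.2 record
#'
#' Uses the 1-based anchor-base convention: `POS` is the base preceding the
#' deleted block, `REF` is the anchor base plus the deleted sequence, `ALT`
#' the anchor base alone.
#'
#' @param call A [find_deletion()] result.
#' @param wild The wild-type sequence the call was made against.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_deletion_vcf <- function(call, wild, path) {
  wild <- as.character(wild)
  s <- call$start_bp
  if (s == 0) abort("cannot anchor a deletion at position 0 in VCF notation")
  ref <- substring(wild, s, s + call$length_bp)   # anchor + deleted block
  alt <- substring(wild, s, s)
  lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", call$chrom, nchar(wild)),
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Length difference between REF and ALT">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tSVTYPE=DEL;SVLEN=-%d",
            call$chrom, s, ref, alt, call$length_bp)
  )
  writeLines(lines, path)
  invisible(path)
}
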