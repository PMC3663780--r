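#' Construct a gene model
#'
#' A gene model holds the exon structure and CDS of one gene on a genomic
#' sequence. Exons are given in transcription order as 0-based half-open
#' genomic intervals (so for a minus-strand gene they run from high to low
#' coordinates); overlapping genes are supported by keeping each model
#' independent. The CDS is expressed in spliced-transcript coordinates
#' (0-based half-open) and must have a length divisible by 3 for wild-type
#' models; models derived by deletion lifting relax that check.
#'
#' @param name Gene identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons A data frame with columns `start`, `end` (0-based half-open
#'   genomic) and optionally `ordinal` (transcription-order exon numbers,
#'   default `1..n`; preserved through exon skipping).
#' @param cds_start,cds_end CDS bounds in transcript coordinates, 0-based
#'   half-open (the stop codon is the last 3 nt of the CDS).
#' @param domains Optional data frame (`name`, `aa_start`, `aa_end`),
#'   1-based inclusive residue spans on the wild-type protein.
#' @param check_frame Enforce CDS length divisible by 3 (wild-type models).
#'
#' @return A list of class `gene_model`.
#' @export
gene_model <- function(name, strand, exons, cds_start, cds_end,
                       domains = NULL, check_frame = TRUE) {
  strand <- match.arg(strand, c("+", "-"))
  exons <- as_tibble(exons)
  if (!all(c("start", "end") %in% names(exons))) {
    abort("`exons` needs `start` and `end` columns")
  }
  if (!"ordinal" %in% names(exons)) exons$ordinal <- seq_len(nrow(exons))
  exons <- exons[c("ordinal", "start", "end")]
  exons$ordinal <- as.integer(exons$ordinal)
  exons$start <- as.numeric(exons$start)
  exons$end <- as.numeric(exons$end)
  if (nrow(exons) < 1) abort("a gene model needs at least one exon")
  if (any(exons$end <= exons$start)) abort("exons must have positive length")
  ascending <- if (strand == "+") exons$start else rev(exons$start)
  if (is.unsorted(ascending, strictly = TRUE)) {
    abort("exons must be ordered in transcription order for the strand")
  }
  asc <- exons[order(exons$start), ]
  if (nrow(asc) > 1 && any(asc$start[-1] < asc$end[-nrow(asc)])) {
    abort("exons must not overlap")
  }
  tlen <- sum(exons$end - exons$start)
  if (cds_start < 0 || cds_end > tlen || cds_end <= cds_start) {
    abort("CDS must lie within the spliced transcript")
  }
  if (check_frame && (cds_end - cds_start) %% 3 != 0) {
    abort("wild-type CDS length must be divisible by 3")
  }
  if (!is.null(domains)) {
    domains <- as_tibble(domains)
    stopifnot(all(c("name", "aa_start", "aa_end") %in% names(domains)))
  }
  structure(list(name = name, strand = strand, exons = exons,
                 cds_start = cds_start, cds_end = cds_end,
                 domains = domains),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s strand): %d exons, transcript %d nt, CDS %d nt\n",
              x$name, x$strand, nrow(x$exons), transcript_length(x),
              x$cds_end - x$cds_start))
  invisible(x)
}

#' Exon lengths and spliced-transcript length
#'
#' @param model A [gene_model()].
#' @return `exon_lengths()`: integer vector in transcription order, named by
#'   exon ordinal; `transcript_length()`: total spliced length in nt.
#' @export
exon_lengths <- function(model) {
  setNames(as.integer(model$exons$end - model$exons$start),
           model$exons$ordinal)
}

#' @rdname exon_lengths
#' @export
transcript_length <- function(model) sum(exon_lengths(model))

#' Splice a gene model out of its genomic sequence
#'
#' Concatenates the exon sequences in transcription order, reverse
#' complementing for minus-strand genes.
#'
#' @param model A [gene_model()].
#' @param genome Genomic sequence (character string or
#'   [Biostrings::DNAString]).
#' @return The spliced transcript as a character string; its length equals
#'   the sum of the exon lengths.
#' @export
splice <- function(model, genome) {
  genome <- as.character(genome)
  glen <- nchar(genome)
  if (any(model$exons$start < 0) || any(model$exons$end > glen)) {
    abort("exon coordinates exceed the genomic sequence")
  }
  asc <- model$exons[order(model$exons$start), ]
  pieces <- substring(genome, asc$start + 1, asc$end)
  joined <- paste0(pieces, collapse = "")
  if (model$strand == "-") {
    joined <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(joined)))
  }
  joined
}

# Genomic coordinate (0-based) of a transcript position (0-based).
transcript_to_genomic <- function(model, tpos) {
  lens <- exon_lengths(model)
  cum <- cumsum(lens)
  before <- c(0, cum[-length(cum)])
  i <- findInterval(tpos, before)
  off <- tpos - before[i]
  ex <- model$exons[i, ]
  if (model$strand == "+") ex$start + off else ex$end - 1 - off
}

# Genomic intervals (ascending, 0-based half-open) covered by a transcript
# interval [t0, t1), one row per exon touched, with transcription ordinals.
transcript_interval_to_genomic <- function(model, t0, t1) {
  lens <- exon_lengths(model)
  cum <- cumsum(lens)
  before <- c(0, cum[-length(cum)])
  out <- purrr::map_dfr(seq_len(nrow(model$exons)), function(i) {
    a <- max(t0, before[i])
    b <- min(t1, cum[i])
    if (b <= a) return(NULL)
    ex <- model$exons[i, ]
    if (model$strand == "+") {
      tibble(ordinal = ex$ordinal,
             start = ex$start + (a - before[i]),
             end = ex$start + (b - before[i]))
    } else {
      tibble(ordinal = ex$ordinal,
             start = ex$end - (b - before[i]),
             end = ex$end - (a - before[i]))
    }
  })
  out[order(out$start), ]
}

# Intron intervals in ascending genomic order with transcription-order
# ordinals: intron `k` separates transcription exons k and k+1.
intron_table <- function(model) {
  if (nrow(model$exons) < 2) {
    return(tibble(ordinal = integer(), start = numeric(), end = numeric()))
  }
  asc <- model$exons[order(model$exons$start), ]
  n <- nrow(asc)
  gaps <- tibble(start = asc$end[-n], end = asc$start[-1],
                 up = asc$ordinal[-n], down = asc$ordinal[-1])
  gaps$ordinal <- pmin(gaps$up, gaps$down)
  gaps[c("ordinal", "start", "end")]
}

# Genomic intervals of canonical splice sites. Acceptor: last 2 intronic nt
# plus first exonic nt of an exon (3' splice site in transcription
# orientation); donor: last exonic nt plus first 2 intronic nt. First exon
# has no acceptor, last exon no donor.
splice_site_table <- function(model) {
  n <- nrow(model$exons)
  purrr::map_dfr(seq_len(n), function(i) {
    ex <- model$exons[i, ]
    out <- NULL
    if (model$strand == "+") {
      if (i > 1) {
        out <- dplyr::bind_rows(out, tibble(
          exon_ordinal = ex$ordinal, site = "acceptor",
          start = ex$start - 2, end = ex$start + 1))
      }
      if (i < n) {
        out <- dplyr::bind_rows(out, tibble(
          exon_ordinal = ex$ordinal, site = "donor",
          start = ex$end - 1, end = ex$end + 2))
      }
    } else {
      if (i > 1) {
        out <- dplyr::bind_rows(out, tibble(
          exon_ordinal = ex$ordinal, site = "acceptor",
          start = ex$end - 1, end = ex$end + 2))
      }
      if (i < n) {
        out <- dplyr::bind_rows(out, tibble(
          exon_ordinal = ex$ordinal, site = "donor",
          start = ex$start - 2, end = ex$start + 1))
      }
    }
    out
  })
}

#' Define an RT-PCR primer pair on a spliced transcript
#'
#' Primer sites are addressed by transcription-order exon ordinal, 0-based
#' offset within the exon, and site length; the forward site must lie
#' upstream of the reverse site on the spliced transcript. Predicted
#' product lengths are inclusive of both primer 3' ends, matching how gel
#' product sizes are reported.
#'
#' @param forward,reverse Length-3 numeric vectors
#'   `c(exon_ordinal, offset, length)`.
#' @return A list of class `primer_pair`.
#' @export
primer_pair <- function(forward, reverse) {
  stopifnot(length(forward) == 3, length(reverse) == 3)
  structure(list(
    forward = list(exon = forward[1], offset = forward[2], length = forward[3]),
    reverse = list(exon = reverse[1], offset = reverse[2], length = reverse[3])
  ), class = "primer_pair")
}

#' Predict the RT-PCR amplicon length on a (possibly mutant) spliced model
#'
#' The product length is the spliced-transcript distance from the first
#' base of the forward primer site to the last base of the reverse site,
#' inclusive. Exon ordinals are looked up in the model, so on an
#' exon-skipped mutant model the same primer pair yields the shortened
#' product; a primer whose exon has been skipped raises a "primer site
#' lost" error.
#'
#' @param model A [gene_model()].
#' @param primers A [primer_pair()].
#' @return Integer product length in bp.
#' @examples
#' fx <- replica_locus_fixture()
#' predict_amplicon(fx$genes$Fam83g_like, fx$primers$fam_nested$pair)  # 484
#' @export
predict_amplicon <- function(model, primers) {
  lens <- exon_lengths(model)
  ords <- model$exons$ordinal
  before <- setNames(c(0, cumsum(lens)[-length(lens)]), ords)
  for (side in c("forward", "reverse")) {
    p <- primers[[side]]
    if (!p$exon %in% ords) {
      abort(sprintf("primer site lost: %s primer exon %d absent from model '%s'",
                    side, p$exon, model$name))
    }
    if (p$offset < 0 || p$offset + p$length > lens[as.character(p$exon)]) {
      abort(sprintf("%s primer site exceeds its exon", side))
    }
  }
  f <- primers$forward
  r <- primers$reverse
  t_f <- before[as.character(f$exon)] + f$offset
  t_r_end <- before[as.character(r$exon)] + r$offset + r$length
  if (t_f + f$length > t_r_end - r$length) {
    abort("reverse primer site lies upstream of the forward site")
  }
  as.integer(t_r_end - t_f)
}
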