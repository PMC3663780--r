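#' Remove a contiguous block from a nucleotide sequence
#'
#' @param sequence Nucleotide string (character or
#'   [Biostrings::DNAString]).
#' @param start 0-based start of the block to remove.
#' @param length Block length in bp (`0` returns the input unchanged).
#' @return The sequence with `[start, start + length)` removed.
#' @examples
#' apply_deletion("ACGTACGT", 2, 3)  # "ACACGT"
#' @export
apply_deletion <- function(sequence, start, length) {
  sequence <- as.character(sequence)
  n <- nchar(sequence)
  if (start < 0 || length < 0 || start + length > n) {
    abort("deletion must lie within the sequence")
  }
  if (length == 0) return(sequence)
  paste0(substring(sequence, 1, start),
         substring(sequence, start + length + 1, n))
}

#' Describe one gene for the locus fixture generator
#'
#' Exon and intron lengths are given in transcription order; for a
#' minus-strand gene the generator lays the exons out from high to low
#' genomic coordinates starting from the right edge of the gene's span.
#'
#' @param name Gene identifier.
#' @param strand `"+"` or `"-"`.
#' @param genomic_start Leftmost genomic coordinate of the gene (0-based).
#' @param exon_lengths Positive integers, transcription order.
#' @param intron_lengths Positive integers, transcription order (one fewer
#'   than the exons).
#' @param cds_start,cds_end CDS bounds in transcript coordinates (0-based
#'   half-open).
#' @param transcript_seq Optional designed transcript sequence (character,
#'   length = sum of exon lengths); when absent, exonic sequence is taken
#'   from the random background.
#' @param domains Optional domain table (`name`, `aa_start`, `aa_end`).
#' @return A list of class `gene_spec`.
#' @export
gene_spec <- function(name, strand, genomic_start, exon_lengths,
                      intron_lengths, cds_start, cds_end,
                      transcript_seq = NULL, domains = NULL) {
  if (length(intron_lengths) != length(exon_lengths) - 1) {
    abort("need exactly one intron length between each pair of exons")
  }
  if (any(exon_lengths <= 0) || any(intron_lengths <= 0)) {
    abort("exon and intron lengths must be positive")
  }
  if (!is.null(transcript_seq) &&
      nchar(transcript_seq) != sum(exon_lengths)) {
    abort("`transcript_seq` length must equal the summed exon lengths")
  }
  structure(list(name = name, strand = strand,
                 genomic_start = genomic_start,
                 exon_lengths = as.integer(exon_lengths),
                 intron_lengths = as.integer(intron_lengths),
                 cds_start = cds_start, cds_end = cds_end,
                 transcript_seq = transcript_seq, domains = domains),
            class = "gene_spec")
}

# Genomic exon coordinates (transcription order) implied by a gene_spec.
gene_spec_exons <- function(spec) {
  n <- length(spec$exon_lengths)
  span <- sum(spec$exon_lengths) + sum(spec$intron_lengths)
  steps <- c(0, cumsum(spec$exon_lengths[-n] + spec$intron_lengths))
  if (spec$strand == "+") {
    start <- spec$genomic_start + steps
    tibble(ordinal = seq_len(n), start = start,
           end = start + spec$exon_lengths)
  } else {
    end <- spec$genomic_start + span - steps
    tibble(ordinal = seq_len(n), start = end - spec$exon_lengths, end = end)
  }
}

#' Specify a complete synthetic locus fixture
#'
#' @param genes A list of [gene_spec()] objects (genes may overlap, e.g. a
#'   gene nested in another gene's intron).
#' @param seq_length Total genomic sequence length in bp.
#' @param deletion `c(start, length)`, 0-based; must overlap at least one
#'   declared gene.
#' @param primers Named list, each element `list(gene = , pair = )` with a
#'   [primer_pair()].
#' @param chrom Sequence name used in FASTA/GFF3/VCF output.
#' @param seed Seed for the random background fill.
#' @return A list of class `locus_fixture_spec`.
#' @export
locus_fixture_spec <- function(genes, seq_length, deletion,
                               primers = list(), chrom = "fixture_locus",
                               seed = 1) {
  if (inherits(genes, "gene_spec")) genes <- list(genes)
  structure(list(genes = genes, seq_length = as.integer(seq_length),
                 deletion = list(start = as.integer(deletion[1]),
                                 length = as.integer(deletion[2])),
                 primers = primers, chrom = chrom, seed = seed),
            class = "locus_fixture_spec")
}

#' Build a synthetic locus fixture (genome, gene models, deletion, primers)
#'
#' Generates a seeded random genomic background, writes each gene's exonic
#' sequence into it (designed transcript sequences take precedence over the
#' background), patches canonical GT/AG dinucleotides onto every intron
#' boundary (strand-aware), and validates the declared deletion against the
#' resulting models. A fixture whose deletion removes no splice site is
#' flagged `no_splice_site_removed` in its descriptor.
#'
#' @param spec A [locus_fixture_spec()].
#' @return A list of class `locus_fixture`: `genome` (wild-type, character),
#'   `mutant_genome`, `genes` (named list of [gene_model()]), `deletion`,
#'   `primers`, `chrom`, `descriptor` (flags plus provenance, serialized to
#'   JSON by [write_locus_fixture()]).
#' @export
make_locus_fixture <- function(spec) {
  stopifnot(inherits(spec, "locus_fixture_spec"))
  L <- spec$seq_length
  d0 <- spec$deletion$start
  d1 <- d0 + spec$deletion$length
  if (d0 < 0 || d1 > L) abort("deletion must lie within the sequence")

  base <- withr::with_seed(spec$seed,
    sample(c("A", "C", "G", "T"), L, replace = TRUE))

  models <- list()
  for (gs in spec$genes) {
    exons <- gene_spec_exons(gs)
    if (min(exons$start) < 0 || max(exons$end) > L) {
      abort(sprintf("gene '%s' exceeds the sequence", gs$name))
    }
    model <- gene_model(gs$name, gs$strand, exons,
                        cds_start = gs$cds_start, cds_end = gs$cds_end,
                        domains = gs$domains)
    # write designed exonic sequence into the background
    if (!is.null(gs$transcript_seq)) {
      plus_image <- if (gs$strand == "+") gs$transcript_seq else {
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(gs$transcript_seq)))
      }
      asc <- exons[order(exons$start), ]
      off <- 0
      img <- strsplit(plus_image, "")[[1]]
      for (i in seq_len(nrow(asc))) {
        len <- asc$end[i] - asc$start[i]
        base[(asc$start[i] + 1):asc$end[i]] <- img[(off + 1):(off + len)]
        off <- off + len
      }
    }
    models[[gs$name]] <- model
  }
  # canonical splice dinucleotides on every intron boundary
  for (model in models) {
    intr <- intron_table(model)
    for (i in seq_len(nrow(intr))) {
      s <- intr$start[i]
      e <- intr$end[i]
      if (model$strand == "+") {
        base[(s + 1):(s + 2)] <- c("G", "T")
        base[(e - 1):e] <- c("A", "G")
      } else {
        base[(s + 1):(s + 2)] <- c("C", "T")   # AG on the minus strand
        base[(e - 1):e] <- c("A", "C")         # GT on the minus strand
      }
    }
  }
  genome <- paste0(base, collapse = "")

  spans <- purrr::map_dfr(models, function(m) {
    tibble(start = min(m$exons$start), end = max(m$exons$end))
  })
  if (all(interval_overlap(spans$start, spans$end, d0, d1) == 0)) {
    abort("deletion does not overlap the declared gene features")
  }
  call <- structure(list(chrom = spec$chrom, start_bp = d0,
                         length_bp = d1 - d0, ambiguity_span = 0L),
                    class = "deletion_call")
  ann <- annotate_deletion(call, models)
  descriptor <- list(
    chrom = spec$chrom,
    seq_length = L,
    deletion = spec$deletion,
    flags = list(
      no_splice_site_removed = nrow(ann$splice_sites_lost) == 0),
    primers = purrr::map(spec$primers, function(p) list(
      gene = p$gene,
      forward = unlist(p$pair$forward),
      reverse = unlist(p$pair$reverse)))
  )
  structure(list(genome = genome,
                 mutant_genome = apply_deletion(genome, d0, d1 - d0),
                 genes = models, deletion = spec$deletion,
                 primers = spec$primers, chrom = spec$chrom,
                 annotation = ann, descriptor = descriptor),
            class = "locus_fixture")
}

#' @export
print.locus_fixture <- function(x, ...) {
  cat(sprintf("<locus_fixture> %s: %d bp, %d gene(s), %d bp deletion at %d\n",
              x$chrom, nchar(x$genome), length(x$genes),
              x$deletion$length, x$deletion$start))
  invisible(x)
}

# Random non-stop codons (uniform over the 61 sense codons).
random_sense_codons <- function(n) {
  sense <- names(CODON_TABLE)[CODON_TABLE != "*"]
  sample(sense, n, replace = TRUE)
}

#' The replica two-gene locus fixture
#'
#' A structural replica of an overlapping two-gene locus: gene B
#' (`Fam83g_like`, plus strand) has five exons with a 125-nt exon 3 and a
#' 2,439-nt CDS (812 codons plus stop); gene A (`Slc5a10_like`, minus
#' strand) has thirteen 150-bp exons arranged so that its intron 10-11
#' (transcription order) fully contains a 955-bp deletion which removes
#' the final 830 bp of gene B's intron 2-3 together with the whole of
#' exon 3 — taking out exon 3's splice acceptor while staying strictly
#' intronic for gene A. The nested primer pair `fam_nested` (exons 1 and 4
#' of gene B) yields a 484-bp spliced wild-type product, hence a 359-bp
#' product once exon 3 is skipped. The exon 2/3 junction falls inside
#' codon 272, and the shifted reading frame in exon 4 meets an out-of-frame
#' stop after 24 novel residues. These are designed structural anchors; the
#' remaining sequence (UTRs, introns, non-anchored codons) is random and
#' controlled by `seed`, so every anchored quantity is invariant to the
#' seed. Deletion boundary bases are patched to make the call unambiguous
#' (zero equivalent left shifts).
#'
#' @param seed Seed for the random background.
#' @return A `locus_fixture` (see [make_locus_fixture()]).
#' @examples
#' fx <- replica_locus_fixture()
#' nchar(splice(fx$genes$Fam83g_like, fx$genome))  # 2939-nt transcript
#' @export
replica_locus_fixture <- function(seed = 1) {
  # gene B transcript: 950 + 164 + 125 + 700 + 1000 = 2939 nt,
  # 5' UTR 300 nt, CDS 2439 nt (codon 272 spans the exon 2/3 junction),
  # 3' UTR 200 nt
  tx <- withr::with_seed(seed, {
    utr5 <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
    cds <- strsplit(paste0(c("ATG", random_sense_codons(811), "TAA"),
                           collapse = ""), "")[[1]]
    utr3 <- sample(c("A", "C", "G", "T"), 200, replace = TRUE)
    acg <- sample(c("A", "C", "G"), 71, replace = TRUE)
    list(utr5 = utr5, cds = cds, utr3 = utr3, acg = acg)
  })
  cds <- tx$cds
  # exon 4 holds CDS nt 940..1639; keep its first 71 nt T-free so the
  # shifted (exon-3-skipped) frame meets no stop before the planted TGA
  cds[940:1010] <- tx$acg
  cds[1011:1013] <- c("T", "G", "A")
  # mutant codon 272 = CDS nt 814 (exon 2's last base) + exon 4 nt 1-2;
  # force it to a sense codon encoding a different residue than wild type
  wt_aa272 <- CODON_TABLE[paste0(cds[814:816], collapse = "")]
  patched <- FALSE
  for (b1 in c("C", "G", "A")) {
    for (b2 in c("C", "G", "A")) {
      aa <- CODON_TABLE[paste0(c(cds[814], b1, b2), collapse = "")]
      if (aa != "*" && aa != wt_aa272) {
        cds[940] <- b1
        cds[941] <- b2
        patched <- TRUE
        break
      }
    }
    if (patched) break
  }
  gene_b_tx <- paste0(c(tx$utr5, cds, tx$utr3), collapse = "")

  gene_b <- gene_spec(
    name = "Fam83g_like", strand = "+", genomic_start = 1000,
    exon_lengths = c(950, 164, 125, 700, 1000),
    intron_lengths = c(800, 1200, 800, 800),
    cds_start = 300, cds_end = 2739,
    transcript_seq = gene_b_tx,
    domains = tibble(name = c("DUF1669-like", "PLD-like-N", "proline-rich"),
                     aa_start = c(21, 97, 470), aa_end = c(288, 97 + 184, 511))
  )

  # gene A: 13 x 150-bp exons, minus strand, spanning [200, 9500); its
  # transcription-order intron 10-11 covers genomic [2550, 4500)
  gene_a_tx <- withr::with_seed(seed + 1, paste0(c(
    sample(c("A", "C", "G", "T"), 75, replace = TRUE),
    "ATG", random_sense_codons(598), "TAA",
    sample(c("A", "C", "G", "T"), 75, replace = TRUE)), collapse = ""))
  gene_a <- gene_spec(
    name = "Slc5a10_like", strand = "-", genomic_start = 200,
    exon_lengths = rep(150L, 13),
    intron_lengths = c(rep(100L, 7), 1350L, 1450L, 1950L, 1650L, 250L),
    cds_start = 75, cds_end = 1875,
    transcript_seq = gene_a_tx
  )

  spec <- locus_fixture_spec(
    genes = list(gene_b, gene_a),
    seq_length = 10000,
    deletion = c(3284, 955),
    primers = list(
      fam_outer = list(gene = "Fam83g_like",
                       pair = primer_pair(c(1, 700, 28), c(4, 150, 28))),
      fam_nested = list(gene = "Fam83g_like",
                        pair = primer_pair(c(1, 850, 28), c(4, 67, 28))),
      slc_nested = list(gene = "Slc5a10_like",
                        pair = primer_pair(c(10, 20, 28), c(11, 60, 28)))
    ),
    chrom = "replica_locus",
    seed = seed
  )
  fx <- make_locus_fixture(spec)

  # disambiguate the deletion boundaries: block single-base left/right
  # shifts so the left-aligned call is exact (both patched positions are
  # interior intron bases of both genes)
  g <- strsplit(fx$genome, "")[[1]]
  d0 <- 3284
  d1 <- d0 + 955
  if (g[d0] == g[d1]) {                   # wild[d0-1] vs wild[d1-1], 1-based
    g[d0] <- setdiff(c("A", "C", "G", "T"), g[d1])[1]
  }
  if (g[d0 + 1] == g[d1 + 1]) {
    g[d0 + 1] <- setdiff(c("A", "C", "G", "T"), g[d1 + 1])[1]
  }
  fx$genome <- paste0(g, collapse = "")
  fx$mutant_genome <- apply_deletion(fx$genome, d0, 955)
  fx
}

#' Write / read a locus fixture as FASTA + GFF3 + JSON
#'
#' `write_locus_fixture()` emits `<prefix>_wild.fa` and
#' `<prefix>_mutant.fa` (via Biostrings), `<prefix>.gff3` with
#' gene/mRNA/exon/CDS features (via rtracklayer, 1-based inclusive), and
#' `<prefix>.json` with the deletion descriptor and primer placements.
#' `read_locus_fixture()` parses them back into an equivalent fixture; the
#' round trip reproduces coordinates, strands, ordinals and CDS bounds.
#'
#' @param fixture A `locus_fixture`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return `write_locus_fixture()` returns the written paths invisibly;
#'   `read_locus_fixture()` returns a `locus_fixture`.
#' @export
write_locus_fixture <- function(fixture, dir, prefix = "locus") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    wild = file.path(dir, paste0(prefix, "_wild.fa")),
    mutant = file.path(dir, paste0(prefix, "_mutant.fa")),
    gff3 = file.path(dir, paste0(prefix, ".gff3")),
    json = file.path(dir, paste0(prefix, ".json"))
  )
  wild <- Biostrings::DNAStringSet(setNames(fixture$genome, fixture$chrom))
  mut <- Biostrings::DNAStringSet(setNames(fixture$mutant_genome,
                                           paste0(fixture$chrom, "_mutant")))
  Biostrings::writeXStringSet(wild, paths$wild)
  Biostrings::writeXStringSet(mut, paths$mutant)
  rtracklayer::export(gene_models_to_granges(fixture$genes, fixture$chrom),
                      paths$gff3, format = "gff3")
  jsonlite::write_json(fixture$descriptor, paths$json, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}

#' @rdname write_locus_fixture
#' @export
read_locus_fixture <- function(dir, prefix = "locus") {
  wild <- Biostrings::readDNAStringSet(
    file.path(dir, paste0(prefix, "_wild.fa")))
  mut <- Biostrings::readDNAStringSet(
    file.path(dir, paste0(prefix, "_mutant.fa")))
  gr <- rtracklayer::import(file.path(dir, paste0(prefix, ".gff3")))
  desc <- jsonlite::read_json(file.path(dir, paste0(prefix, ".json")),
                              simplifyVector = TRUE)
  genes <- granges_to_gene_models(gr)
  primers <- purrr::map(
    if (length(desc$primers) > 0) desc$primers else list(),
    function(p) list(gene = p$gene,
                     pair = primer_pair(unname(unlist(p$forward)),
                                        unname(unlist(p$reverse)))))
  structure(list(genome = as.character(wild[[1]]),
                 mutant_genome = as.character(mut[[1]]),
                 genes = genes,
                 deletion = list(start = desc$deletion$start,
                                 length = desc$deletion$length),
                 primers = primers, chrom = desc$chrom,
                 descriptor = desc),
            class = "locus_fixture")
}

# gene models -> GFF3-ready GRanges (1-based inclusive)
gene_models_to_granges <- function(models, chrom) {
  rows <- purrr::imap_dfr(models, function(m, nm) {
    span <- tibble(type = c("gene", "mRNA"),
                   start = min(m$exons$start) + 1, end = max(m$exons$end),
                   ID = c(m$name, paste0(m$name, ".t1")),
                   Parent = c(NA_character_, m$name),
                   exon_number = NA_integer_, cds_start = NA_integer_,
                   cds_end = NA_integer_)
    exons <- tibble(type = "exon", start = m$exons$start + 1,
                    end = m$exons$end,
                    ID = sprintf("%s.exon%d", m$name, m$exons$ordinal),
                    Parent = paste0(m$name, ".t1"),
                    exon_number = m$exons$ordinal,
                    cds_start = NA_integer_, cds_end = NA_integer_)
    cds_g <- transcript_interval_to_genomic(m, m$cds_start, m$cds_end)
    cds_g <- cds_g[order(cds_g$ordinal), ]          # transcription order
    cum_before <- c(0, cumsum(cds_g$end - cds_g$start))[seq_len(nrow(cds_g))]
    cds <- tibble(type = "CDS", start = cds_g$start + 1, end = cds_g$end,
                  ID = paste0(m$name, ".cds"),
                  Parent = paste0(m$name, ".t1"),
                  exon_number = cds_g$ordinal,
                  cds_start = m$cds_start, cds_end = m$cds_end,
                  phase = as.integer((3 - cum_before %% 3) %% 3))
    dplyr::mutate(dplyr::bind_rows(span, exons, cds), strand = m$strand,
                  gene = m$name)
  })
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = rows$start, end = rows$end),
    strand = rows$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = rows$type, ID = rows$ID, Parent = rows$Parent,
    exon_number = rows$exon_number, cds_start = rows$cds_start,
    cds_end = rows$cds_end, phase = rows$phase, gene = rows$gene)
  gr
}

# GFF3 GRanges -> named list of gene models
granges_to_gene_models <- function(gr) {
  df <- as.data.frame(gr)
  df$Parent <- vapply(df$Parent, function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  }, character(1))
  gene_names <- df$ID[df$type == "gene"]
  out <- list()
  for (nm in gene_names) {
    tx_id <- df$ID[df$type == "mRNA" & df$Parent == nm][1]
    ex <- df[df$type == "exon" & df$Parent == tx_id, ]
    strand <- as.character(ex$strand[1])
    ord <- as.integer(ex$exon_number)
    exons <- tibble(ordinal = ord, start = ex$start - 1, end = ex$end)
    exons <- exons[order(exons$ordinal), ]
    cds <- df[df$type == "CDS" & df$Parent == tx_id, ]
    out[[nm]] <- gene_model(nm, strand, exons,
                            cds_start = as.integer(cds$cds_start[1]),
                            cds_end = as.integer(cds$cds_end[1]))
  }
  out
}
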