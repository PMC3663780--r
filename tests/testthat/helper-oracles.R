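# Independent oracles used across the suite. Each deliberately takes a
# different route than the package implementation it checks.

# Translation oracle: Biostrings' translator, truncated at the first stop.
oracle_translate <- function(transcript, cds_start = 0) {
  cds <- substring(transcript, cds_start + 1, nchar(transcript))
  cds <- substring(cds, 1, 3 * (nchar(cds) %/% 3))
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           no.init.codon = TRUE))
  sub("\\*.*$", "", aa)
}

# Random DNA string.
random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force per-base deletion annotation oracle: classify every deleted
# base by membership in per-base feature maps built by enumeration.
oracle_annotate <- function(d0, d1, model) {
  n_ex <- nrow(model$exons)
  exon_bases <- lapply(seq_len(n_ex), function(i) {
    seq(model$exons$start[i], model$exons$end[i] - 1)
  })
  gene_lo <- min(model$exons$start)
  gene_hi <- max(model$exons$end)
  all_gene <- seq(gene_lo, gene_hi - 1)
  intron_bases <- setdiff(all_gene, unlist(exon_bases))
  del <- seq(d0, d1 - 1)
  hit_exon <- vapply(exon_bases, function(b) length(intersect(del, b)) > 0,
                     logical(1))
  classification <- if (any(hit_exon)) {
    "removes_exonic_sequence"
  } else if (length(intersect(del, intron_bases)) > 0) {
    "intronic_only"
  } else {
    NA_character_
  }
  # splice-site base sets by enumeration, strand aware
  sites <- list()
  for (i in seq_len(n_ex)) {
    s <- model$exons$start[i]
    e <- model$exons$end[i]
    if (model$strand == "+") {
      acc <- (s - 2):s
      don <- (e - 1):(e + 1)
    } else {
      acc <- (e - 1):(e + 1)
      don <- (s - 2):s
    }
    if (i > 1 && length(intersect(del, acc)) > 0) {
      sites[[length(sites) + 1]] <- c(model$exons$ordinal[i], "acceptor")
    }
    if (i < n_ex && length(intersect(del, don)) > 0) {
      sites[[length(sites) + 1]] <- c(model$exons$ordinal[i], "donor")
    }
  }
  list(classification = classification,
       sites = if (length(sites) == 0) character(0) else
         sort(vapply(sites, paste, character(1), collapse = ":")))
}

# Small map + trait used by several simulation tests.
toy_map <- function(n = 5, span = 5e6, rate = 0.5) {
  make_marker_map(n, span_bp = span, cm_per_mb = rate)
}
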