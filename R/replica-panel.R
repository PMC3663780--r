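# The replica mapping panel encodes the totals stated for the large
# testcross: 1,679 progeny, 840 mutant : 839 normal, 11 crossovers between
# the proximal flank and the trait, 19 between the trait and the distal
# flank, and an interior marker never separated from the trait. Physical
# positions use a local 0-based frame (proximal flank to distal flank =
# 4.8 Mb; SNP2 to SNP6 = 0.75 Mb).

replica_marker_positions <- tibble::tribble(
  ~name,        ~pos_bp,
  "D11Mit313",        0,
  "D11Mit208",  1.00e6,
  "D11Mit260",  3.25e6,
  "D11Mit242",  5.80e6,
  "D11Mit261",  5.90e6,
  "D11Mit216",  6.50e6
)

replica_snp_positions <- tibble::tribble(
  ~name,  ~pos_bp,
  "SNP1", 2.60e6,
  "SNP2", 3.00e6,
  "SNP3", 3.35e6,
  "SNP4", 3.45e6,
  "SNP5", 3.55e6,
  "SNP6", 3.75e6
)

#' The replica chromosome 11 marker map
#'
#' Six microsatellite markers on a local 0-based physical frame, converted
#' at 0.5 cM/Mb. The span between `D11Mit208` and `D11Mit242` is 4.8 Mb.
#'
#' @return A [genetic_map()].
#' @export
replica_map <- function() {
  m <- replica_marker_positions
  genetic_map(tibble(name = m$name, chrom = "chr11",
                     pos_bp = m$pos_bp, pos_cM = m$pos_bp * 0.5 / 1e6),
              cm_per_mb = 0.5)
}

#' @rdname replica_map
#' @export
replica_trait <- function() trait_locus("wly", pos_bp = 3.30e6)

#' The SNP panel used for interval refinement
#'
#' Six SNP markers strictly inside the `D11Mit208`-`D11Mit242` interval;
#' `SNP2`-`SNP6` span 0.75 Mb.
#'
#' @return A tibble: `name`, `pos_bp`, `pos_cM`.
#' @export
replica_snp_map <- function() {
  dplyr::mutate(replica_snp_positions, pos_cM = .data$pos_bp * 0.5 / 1e6)
}

replica_panel_layout <- function() {
  # per-class: phenotype, crossover location (defines marker + SNP alleles)
  tibble::tribble(
    ~n,   ~phenotype, ~crossover,
    824,  "mutant",   "none",
    825,  "normal",   "none",
    2,    "mutant",   "208-SNP1",
    3,    "mutant",   "SNP1-SNP2",
    1,    "mutant",   "SNP2-wly",
    2,    "normal",   "208-SNP1",
    2,    "normal",   "SNP1-SNP2",
    1,    "normal",   "SNP2-wly",
    1,    "mutant",   "wly-SNP6",
    9,    "mutant",   "SNP6-242",
    9,    "normal",   "SNP6-242"
  )
}

#' The replica 1,679-progeny backcross panel
#'
#' A deterministic panel reproducing the stated totals of the large
#' testcross: 840 mutant / 839 normal; 11 recombinants with a crossover
#' between `D11Mit208` and the trait and 19 between the trait and
#' `D11Mit242` (all between `D11Mit208` and `D11Mit260` or between `SNP6`'s
#' position and `D11Mit242`, so `D11Mit260` never recombines with the
#' trait); all remaining progeny parental. Sub-splits of the crossovers
#' among the SNP intervals encode the refinement outcome: two recombinants
#' carry a crossover between `SNP2` and the trait and one between the trait
#' and `SNP6`.
#'
#' @return A [backcross_panel()]; the companion SNP genotypes for its
#'   recombinant progeny come from [replica_snp_genotypes()].
#' @export
replica_backcross_panel <- function() {
  layout <- replica_panel_layout()
  map <- replica_map()
  # dam allele per marker: trait-side allele Y, opposite side X
  rows <- purrr::pmap_dfr(layout, function(n, phenotype, crossover) {
    y <- if (phenotype == "mutant") "N" else "A"
    x <- if (y == "N") "A" else "N"
    proximal_cross <- crossover %in% c("208-SNP1", "SNP1-SNP2", "SNP2-wly")
    distal_cross <- crossover %in% c("wly-SNP6", "SNP6-242")
    allele <- c(
      D11Mit313 = if (proximal_cross) x else y,
      D11Mit208 = if (proximal_cross) x else y,
      D11Mit260 = y,
      D11Mit242 = if (distal_cross) x else y,
      D11Mit261 = if (distal_cross) x else y,
      D11Mit216 = if (distal_cross) x else y
    )
    geno <- ifelse(allele == "A", "H", "N")
    dplyr::bind_cols(tibble(phenotype = rep(phenotype, n)),
                     as_tibble(t(geno))[rep(1, n), ])
  })
  rows <- dplyr::mutate(rows,
                        id = sprintf("N2-%04d", dplyr::row_number()),
                        .before = 1)
  backcross_panel(rows, map = replica_map(), trait = replica_trait())
}

#' SNP genotypes typed on the replica panel's recombinant progeny
#'
#' Stage-two genotyping covers only the 30 progeny recombinant between the
#' flanking microsatellites, exactly as recombinant-only refinement
#' prescribes.
#'
#' @return A tibble: `id` plus `SNP1`..`SNP6` genotype codes (`H`/`N`).
#' @export
replica_snp_genotypes <- function() {
  layout <- replica_panel_layout()
  snps <- replica_snp_positions$name
  start_id <- cumsum(c(0, layout$n[-nrow(layout)]))
  purrr::pmap_dfr(
    cbind(layout, start = start_id),
    function(n, phenotype, crossover, start) {
      if (crossover == "none") return(NULL)
      y <- if (phenotype == "mutant") "N" else "A"
      x <- if (y == "N") "A" else "N"
      allele <- switch(crossover,
        "208-SNP1" = rep(y, 6),
        "SNP1-SNP2" = c(x, rep(y, 5)),
        "SNP2-wly" = c(x, x, rep(y, 4)),
        "wly-SNP6" = c(rep(y, 5), x),
        "SNP6-242" = rep(y, 6))
      geno <- ifelse(allele == "A", "H", "N")
      out <- as_tibble(setNames(as.list(geno), snps))[rep(1, n), ]
      dplyr::mutate(out, id = sprintf("N2-%04d", start + seq_len(n)),
                    .before = 1)
    })
}

#' The packaged critical-interval gene table
#'
#' Annotated genes in and around the refined critical interval, encoding
#' the published triage evidence: six genes whose engineered null alleles
#' leave the coat normal; predicted genes and genes without any skin
#' expression evidence; and the two overlapping skin-cDNA-library genes.
#' Gene coordinates are synthetic (local frame); genes the source describes
#' only collectively carry generic names.
#'
#' @return A tibble: `name`, `start_bp`, `end_bp`, `null_allele_coat_normal`
#'   (logical, `NA` = unknown), `skin_expression_evidence`
#'   (`cdna_library`/`other`/`none`/`unknown`).
#' @export
replica_interval_genes <- function() {
  tibble::tribble(
    ~name,              ~start_bp, ~end_bp,  ~null_allele_coat_normal, ~skin_expression_evidence,
    "flanking_gene_1",  2.90e6,    2.95e6,   NA,                       "cdna_library",
    "Slc47a1",          3.02e6,    3.05e6,   TRUE,                     "other",
    "Epn2",             3.06e6,    3.12e6,   TRUE,                     "other",
    "Grap",             3.13e6,    3.16e6,   TRUE,                     "other",
    "predicted_gene_1", 3.17e6,    3.18e6,   NA,                       "none",
    "predicted_gene_2", 3.19e6,    3.20e6,   NA,                       "none",
    "skin_silent_1",    3.21e6,    3.24e6,   NA,                       "none",
    "skin_silent_2",    3.25e6,    3.28e6,   NA,                       "none",
    "Slc5a10",          3.30e6,    3.335e6,  NA,                       "cdna_library",
    "Fam83g",           3.31e6,    3.325e6,  NA,                       "cdna_library",
    "predicted_gene_3", 3.36e6,    3.38e6,   NA,                       "none",
    "skin_silent_3",    3.39e6,    3.395e6,  NA,                       "none",
    "Ulk2",             3.40e6,    3.46e6,   TRUE,                     "other",
    "Mapk7",            3.47e6,    3.49e6,   TRUE,                     "other",
    "predicted_gene_4", 3.50e6,    3.52e6,   NA,                       "none",
    "Akap10",           3.60e6,    3.67e6,   TRUE,                     "other"
  )
}

#' The refined critical interval of the replica analysis
#'
#' @return `c(start_bp, end_bp)` of the `SNP2`-`SNP6` span, half-open.
#' @export
replica_critical_interval <- function() {
  snps <- replica_snp_positions
  c(snps$pos_bp[snps$name == "SNP2"], snps$pos_bp[snps$name == "SNP6"])
}
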