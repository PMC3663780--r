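test_that("splicing concatenates exons strand-aware", {
  genome <- "TTTACGGCATTT"
  single <- gene_model("s", "+", tibble::tibble(start = 3, end = 9),
                       cds_start = 0, cds_end = 6)
  expect_identical(splice(single, genome), "ACGGCA")
  # minus-strand 2-exon toy, worked by hand:
  # exons (transcription order) [8,11) then [2,5); plus-strand pieces are
  # "TAC" and "GCA" -> ascending concat "TACGCA" -> revcomp "TGCGTA"
  minus <- gene_model("m", "-", tibble::tibble(start = c(8, 2),
                                               end = c(11, 5)),
                      cds_start = 0, cds_end = 6)
  expect_identical(splice(minus, "ATTACTTCGCAT"),
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString("TACGCA"))))
  expect_error(splice(single, "ACGT"), "exceed")
  # conservation: replica transcript length = sum of exon lengths
  fx <- replica_locus_fixture(seed = 1)
  b <- fx$genes$Fam83g_like
  expect_equal(nchar(splice(b, fx$genome)), sum(exon_lengths(b)))
})

test_that("translation follows the standard table and stops at the first stop", {
  expect_identical(translate_cds("ATGAAATAG", 0), "MK")
  expect_identical(translate_cds("GGATGAAATAG", 2), "MK")
  out <- translate_cds("ATGAAAGCT", 0)
  expect_identical(as.character(out), "MKA")
  expect_true(attr(out, "no_in_frame_stop"))
  expect_error(translate_cds("AT", 0), "too short")
  expect_error(translate_cds("ATGAAA", 5), "too short")
})

test_that("translation agrees with an independent oracle on random CDSs", {
  withr::with_seed(512, {
    for (i in 1:150) {
      tx <- random_dna(3 * sample(5:60, 1))
      expect_identical(as.character(translate_cds(tx, 0)),
                       oracle_translate(tx, 0), info = tx)
    }
  })
})

test_that("the exon-skipping rule reproduces the replica's mutant transcript", {
  fx <- replica_locus_fixture(seed = 1)
  call <- find_deletion(fx$genome, fx$mutant_genome, chrom = fx$chrom)
  ann <- annotate_deletion(call, fx$genes)
  b <- fx$genes$Fam83g_like
  mut_b <- predict_mutant_model(b, call, ann)
  expect_equal(mut_b$exons$ordinal, c(1L, 2L, 4L, 5L))
  # exon 2 is joined to exon 4 across a gap shortened by the whole deletion
  expect_equal(mut_b$exons$start[3] - mut_b$exons$end[2],
               b$exons$start[4] - b$exons$end[2] - 955)
  # the overlapping gene is spliced normally after coordinate lift
  a <- fx$genes$Slc5a10_like
  mut_a <- predict_mutant_model(a, call, ann)
  expect_identical(splice(mut_a, fx$mutant_genome), splice(a, fx$genome))
  expect_equal(mut_a$exons$ordinal, a$exons$ordinal)
})

test_that("donor loss triggers skipping symmetrically", {
  # delete the donor of exon 2 (not its acceptor): exons [10,22) [30,42) [50,62)
  m <- gene_model("g", "+", tibble::tibble(start = c(10, 30, 50),
                                           end = c(22, 42, 62)),
                  cds_start = 0, cds_end = 36)
  call <- list(chrom = "c", start_bp = 41, length_bp = 4, ambiguity_span = 0L)
  mut <- predict_mutant_model(m, call)
  expect_equal(mut$exons$ordinal, c(1L, 3L))
})

test_that("a deletion internal to an exon truncates without skipping", {
  m <- gene_model("g", "+", tibble::tibble(start = c(10, 30), end = c(22, 42)),
                  cds_start = 0, cds_end = 24)
  call <- list(chrom = "c", start_bp = 33, length_bp = 3, ambiguity_span = 0L)
  mut <- predict_mutant_model(m, call)
  expect_equal(mut$exons$ordinal, c(1L, 2L))
  expect_equal(unname(exon_lengths(mut)), c(12, 9))
})

test_that("removing the CDS start codon is outside the skipping rule", {
  fx <- replica_locus_fixture(seed = 1)
  b <- fx$genes$Fam83g_like
  # start codon sits at genomic 1300..1302 (transcript 300 on exon 1)
  call <- list(chrom = "c", start_bp = 1295, length_bp = 20,
               ambiguity_span = 0L)
  expect_error(predict_mutant_model(b, call), "start lost")
})

test_that("amplicon arithmetic matches the single-exon closed form", {
  m <- gene_model("g", "+", tibble::tibble(start = 0, end = 300),
                  cds_start = 0, cds_end = 300)
  of <- 10; or <- 200; lf <- 20; lr <- 25
  expect_equal(predict_amplicon(m, primer_pair(c(1, of, lf), c(1, or, lr))),
               (or + lr) - of)
  expect_error(predict_amplicon(m, primer_pair(c(1, 200, 25), c(1, 10, 20))),
               "upstream")
  expect_error(predict_amplicon(m, primer_pair(c(2, 0, 10), c(1, 200, 20))),
               "primer site lost")
})

test_that("amplicon difference equals skipped length when primers flank the skip", {
  withr::with_seed(99, {
    for (i in 1:20) {
      n_ex <- sample(3:6, 1)
      ex_len <- sample(60:200, n_ex, replace = TRUE)
      in_len <- sample(40:120, n_ex - 1, replace = TRUE)
      gs <- gene_spec("g", sample(c("+", "-"), 1), 20, ex_len, in_len,
                      0, 3 * ((sum(ex_len)) %/% 3))
      skip <- (2:(n_ex - 1))[sample.int(n_ex - 2, 1)]
      fx <- make_locus_fixture(locus_fixture_spec(
        list(gs), 20 + sum(ex_len) + sum(in_len) + 40,
        deletion = c(25, 1), seed = i))  # placeholder deletion, unused below
      model <- fx$genes$g
      primers <- primer_pair(c(1, 5, 15), c(n_ex, 10, 15))
      wt <- predict_amplicon(model, primers)
      mut_exons <- model$exons[model$exons$ordinal != skip, ]
      mut <- gene_model("g", model$strand, mut_exons, 0, 3,
                        check_frame = FALSE)
      expect_equal(wt - predict_amplicon(mut, primers), ex_len[skip])
    }
  })
})

test_that("protein comparison and frameshift reporting follow the prefix rule", {
  cmp <- compare_proteins("MKLV", "MKQ")
  expect_equal(cmp$last_identical_residue, 2L)
  expect_equal(cmp$novel_residues, 1L)
  expect_equal(cmp$frameshift, "after codon 2")
  same <- compare_proteins("MKLV", "MKLV")
  expect_equal(same$novel_residues, 0L)
  expect_equal(same$frameshift, "none")
  trunc <- compare_proteins("MKLV", "MK")
  expect_equal(trunc$frameshift, "none")  # clean truncation, no divergence
  expect_equal(trunc$novel_residues, 0L)
})

test_that("domain retention is the identical-prefix fraction", {
  doms <- tibble::tibble(name = c("inside", "beyond", "straddle"),
                         aa_start = c(10, 470, 380), aa_end = c(90, 511, 419))
  cmp <- list(last_identical_residue = 400L)
  d <- domain_overlap(cmp, doms)
  expect_equal(d$fraction_retained[d$domain == "inside"], 1)
  expect_false(d$truncated[d$domain == "inside"])
  expect_equal(d$fraction_retained[d$domain == "beyond"], 0)
  expect_equal(d$fraction_retained[d$domain == "straddle"],
               (400 - 380 + 1) / (419 - 380 + 1))
  expect_true(all(d$truncated[d$domain != "inside"]))
})

test_that("the frame rule depends on skipped length mod 3", {
  # gene with exon 2 of varying length; skipping it shifts frame iff
  # its length is not a multiple of 3
  for (len2 in c(125, 126, 3)) {
    ex <- c(90, len2, 120)
    gs <- gene_spec("g", "+", 10, ex, c(50, 60), 0, 3 * (sum(ex) %/% 3))
    glen <- 10 + sum(ex) + 110 + 20
    fx <- make_locus_fixture(locus_fixture_spec(list(gs), glen,
                                                deletion = c(15, 1), seed = 8))
    model <- fx$genes$g
    # deletion knocking out exon 2's acceptor only
    acc_start <- model$exons$start[2] - 2
    call <- list(chrom = "c", start_bp = acc_start - 3, length_bp = 6,
                 ambiguity_span = 0L)
    rep <- predict_consequence(model, fx$genome, call,
                               primer_pair(c(1, 0, 10), c(3, 100, 10)))
    expect_equal(rep$skipped_exons, 2L)
    if (len2 %% 3 == 0) {
      expect_equal(rep$frameshift, "none")
    } else {
      expect_match(rep$frameshift, "^after codon")
    }
    expect_equal(rep$wt_amplicon_bp - rep$mut_amplicon_bp, len2)
  }
})

test_that("transcript-length conservation holds through mutation", {
  fx <- replica_locus_fixture(seed = 6)
  call <- find_deletion(fx$genome, fx$mutant_genome)
  b <- fx$genes$Fam83g_like
  mut_b <- predict_mutant_model(b, call)
  skipped <- setdiff(b$exons$ordinal, mut_b$exons$ordinal)
  skipped_len <- sum(exon_lengths(b)[as.character(skipped)])
  # exonic bases directly deleted but not part of a skipped exon
  direct <- 0
  expect_equal(nchar(splice(mut_b, fx$mutant_genome)),
               nchar(splice(b, fx$genome)) - skipped_len - direct)
})
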