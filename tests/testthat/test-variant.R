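test_that("find_deletion recovers hand-worked and degenerate cases", {
  call <- find_deletion("AACGTTT", "AATTT")
  expect_equal(call$start_bp, 2L)
  expect_equal(call$length_bp, 2L)

  # left-alignment through a homopolymer: any placement normalizes the same;
  # the A-run at 2..5 absorbs 2 equivalent left shifts
  wild <- "CCAAAAGG"
  for (cut in 2:4) {
    call <- find_deletion(wild, apply_deletion(wild, cut, 2))
    expect_equal(call$start_bp, 2L)
    expect_equal(call$length_bp, 2L)
    expect_equal(call$ambiguity_span, 2L)
  }

  expect_error(find_deletion("ACGT", "ACCT"), "position 3")
  expect_error(find_deletion("ACGT", "ACGTA"), "shorter")
  expect_error(find_deletion("ACGTACGT", "ACTTAC"), "not a simple deletion")
  expect_error(find_deletion("", "A"), "non-empty")
})

test_that("random injected deletions are recovered exactly", {
  withr::with_seed(424, {
    for (i in 1:250) {
      n <- sample(50:400, 1)
      wild <- random_dna(n)
      len <- sample(1:20, 1)
      start <- sample(0:(n - len), 1)
      call <- find_deletion(wild, apply_deletion(wild, start, len))
      expect_equal(call$length_bp, len)
      # the call must be an equivalent placement, normalized left
      expect_lte(call$start_bp, start)
      expect_identical(apply_deletion(wild, call$start_bp, call$length_bp),
                       apply_deletion(wild, start, len))
      # left-alignment: shifting one base further left changes the result
      if (call$start_bp > 0) {
        expect_false(identical(
          apply_deletion(wild, call$start_bp - 1, call$length_bp),
          apply_deletion(wild, start, len)))
      }
    }
  })
})

test_that("deletion annotation matches the replica's published geometry", {
  fx <- replica_locus_fixture(seed = 1)
  call <- find_deletion(fx$genome, fx$mutant_genome, chrom = fx$chrom)
  ann <- annotate_deletion(call, fx$genes)
  cls <- setNames(ann$genes$classification, ann$genes$gene)
  expect_equal(cls[["Slc5a10_like"]], "intronic_only")
  expect_equal(cls[["Fam83g_like"]], "removes_exonic_sequence")
  # the deletion sits in intron 10-11 of the minus-strand gene
  slc_introns <- ann$features_hit[ann$features_hit$gene == "Slc5a10_like", ]
  expect_equal(slc_introns$feature, "intron")
  expect_equal(slc_introns$ordinal, 10L)
  # and removes all of exon 3 plus part of intron 2-3 of the plus-strand gene
  fam <- ann$features_hit[ann$features_hit$gene == "Fam83g_like", ]
  expect_equal(fam$fraction_removed[fam$feature == "exon"], 1)
  expect_equal(fam$ordinal[fam$feature == "exon"], 3L)
  expect_equal(fam$ordinal[fam$feature == "intron"], 2L)
  expect_lt(fam$fraction_removed[fam$feature == "intron"], 1)
  lost <- ann$splice_sites_lost
  expect_true(any(lost$gene == "Fam83g_like" & lost$exon_ordinal == 3 &
                  lost$site == "acceptor"))
  expect_false(any(lost$gene == "Slc5a10_like"))
})

test_that("annotation agrees with a per-base brute-force oracle", {
  fx <- replica_locus_fixture(seed = 2)
  withr::with_seed(77, {
    for (i in 1:40) {
      len <- sample(c(1:5, 50, 200, 955, 2000), 1)
      d0 <- sample(0:(10000 - len), 1)
      call <- list(start_bp = d0, length_bp = len)
      ann <- suppressWarnings(annotate_deletion(call, fx$genes))
      for (model in fx$genes) {
        oracle <- oracle_annotate(d0, d0 + len, model)
        got_cls <- ann$genes$classification[ann$genes$gene == model$name]
        expect_equal(if (length(got_cls) == 0) NA_character_ else got_cls,
                     oracle$classification,
                     info = sprintf("%s del %d+%d", model$name, d0, len))
        got_sites <- ann$splice_sites_lost[
          ann$splice_sites_lost$gene == model$name, ]
        expect_equal(sort(paste(got_sites$exon_ordinal, got_sites$site,
                                sep = ":")),
                     oracle$sites,
                     info = sprintf("%s del %d+%d", model$name, d0, len))
      }
    }
  })
})

test_that("a deletion spanning two exons loses all four surrounding sites", {
  # plus-strand toy: exons [10,20) [30,40) [50,60); delete [28,61) to
  # remove exons 2 and 3 entirely with the intervening intron
  m <- gene_model("g", "+", tibble::tibble(start = c(10, 30, 50),
                                           end = c(20, 40, 60)),
                  cds_start = 0, cds_end = 30)
  call <- list(start_bp = 28, length_bp = 33, chrom = "c")
  ann <- annotate_deletion(call, list(m))
  lost <- ann$splice_sites_lost
  expect_setequal(paste(lost$exon_ordinal, lost$site),
                  c("2 acceptor", "2 donor", "3 acceptor"))
  # a deletion strictly inside an exon removes sequence but no splice site
  ann2 <- annotate_deletion(list(start_bp = 33, length_bp = 3, chrom = "c"),
                            list(m))
  expect_equal(ann2$genes$classification, "removes_exonic_sequence")
  expect_equal(nrow(ann2$splice_sites_lost), 0)
})

test_that("VCF output uses the anchor-base convention", {
  fx <- replica_locus_fixture(seed = 1)
  call <- find_deletion(fx$genome, fx$mutant_genome, chrom = fx$chrom)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_deletion_vcf(call, fx$genome, path)
  lines <- readLines(path)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  rec <- strsplit(lines[length(lines)], "\t")[[1]]
  expect_equal(as.integer(rec[2]), call$start_bp)       # 1-based anchor base
  expect_equal(nchar(rec[4]) - nchar(rec[5]), call$length_bp)
  expect_identical(substring(rec[4], 1, 1), rec[5])
  # REF must match the wild-type sequence at POS
  expect_identical(rec[4], substring(fx$genome, call$start_bp,
                                     call$start_bp + call$length_bp))
})
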