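test_that("segregation chi-square matches closed form", {
  mk_panel <- function(n_mut, n_norm) {
    structure(tibble::tibble(
      phenotype = c(rep("mutant", n_mut), rep("normal", n_norm))),
      class = c("backcross_panel", "tbl_df", "tbl", "data.frame"))
  }
  s <- test_segregation(mk_panel(840, 839))
  expect_equal(s$chi2, (840 - 839.5)^2 / 839.5 + (839 - 839.5)^2 / 839.5)
  expect_equal(s$chi2, 1 / 1679, tolerance = 1e-12)
  expect_gt(s$p_value, 0.98)

  expect_identical(test_segregation(mk_panel(50, 50))$chi2, 0)

  s2 <- test_segregation(mk_panel(100, 0))
  expect_equal(s2$chi2, 100)
  expect_lt(s2$p_value, 1e-22)

  expect_error(test_segregation(mk_panel(0, 0)), "zero progeny")
})

test_that("null chi-square p-values are uniform", {
  # 2,000 null testcrosses of n = 1679; KS test at alpha = 0.01
  pvals <- withr::with_seed(20130509, {
    n_mut <- rbinom(2000, 1679, 0.5)
    vapply(n_mut, function(m) {
      test_segregation(structure(tibble::tibble(
        phenotype = c(rep("mutant", m), rep("normal", 1679 - m))),
        class = c("backcross_panel", "tbl_df", "tbl", "data.frame")))$p_value
    }, numeric(1))
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))  # discrete ties
  expect_gt(ks$p.value, 0.01)
})

test_that("dam haplotypes follow the genotype and phenotype rules", {
  map <- toy_map(6, span = 6e6)
  tr <- trait_locus("wly", pos_bp = 3e6)
  panel <- backcross_panel(tibble::tibble(
    id = c("p1", "p2", "p3"),
    phenotype = c("mutant", "normal", "mutant"),
    M1 = c("H", "N", "-"), M2 = c("H", "N", "-"), M3 = c("H", "N", "-"),
    M4 = c("H", "N", "-"), M5 = c("H", "N", "-"), M6 = c("H", "N", "-")),
    map, tr)
  haps <- infer_transmitted_haplotypes(panel)
  # mutant with all-H markers: A alleles everywhere, trait allele N
  expect_equal(unlist(haps[1, map$name]), setNames(rep("A", 6), map$name))
  expect_equal(haps$wly[1], "N")
  # normal with all-N markers: N alleles, trait allele A
  expect_equal(unname(unlist(haps[2, map$name])), rep("N", 6))
  expect_equal(haps$wly[2], "A")
  # fully missing progeny: unknown everywhere, excluded from interval counts
  expect_true(all(is.na(haps[3, map$name])))
  est <- estimate_recombination(haps, "M1", "M2")
  expect_equal(est$n_informative, 2L)
})

test_that("haplotype classes partition the panel", {
  map <- toy_map()
  tr <- trait_locus("t", pos_bp = 2.5e6)
  panel <- simulate_backcross(map, tr, n = 500, seed = 9)
  classes <- count_haplotype_classes(infer_transmitted_haplotypes(panel))
  expect_equal(sum(classes$count), 500)
  # zero-span map: only the two parental classes can occur
  map0 <- genetic_map(tibble::tibble(
    name = c("a", "b"), chrom = "c", pos_bp = c(0, 10),
    pos_cM = c(0, 1e-9)))
  p0 <- simulate_backcross(map0, trait_locus("t", 5, pos_cM = 5e-10),
                           n = 300, seed = 1)
  c0 <- count_haplotype_classes(infer_transmitted_haplotypes(p0))
  expect_lte(nrow(c0), 2)
})

test_that("recombination estimates match the recombinant-count formulas", {
  haps <- infer_transmitted_haplotypes(replica_backcross_panel())
  prox <- estimate_recombination(haps, "D11Mit208", "wly")
  expect_equal(prox$n_recombinant, 11L)
  expect_equal(prox$r, 11 / 1679)
  expect_equal(prox$se, sqrt((11 / 1679) * (1 - 11 / 1679) / 1679))
  expect_equal(prox$r, 0.00655, tolerance = 1e-3)
  dist <- estimate_recombination(haps, "D11Mit242", "wly")
  expect_equal(dist$r, 19 / 1679)
  expect_equal(dist$r, 0.01132, tolerance = 1e-3)
  zero <- estimate_recombination(haps, "D11Mit260", "wly")
  expect_identical(zero$n_recombinant, 0L)
  expect_identical(zero$se, 0)
})

test_that("se formula matches the binomial bootstrap", {
  map <- make_marker_map(2, span_bp = 10e6, cm_per_mb = 0.5)
  haps <- infer_transmitted_haplotypes(
    simulate_backcross(map, trait_locus("t", 0), n = 800, seed = 4))
  est <- estimate_recombination(haps, "M1", "M2")
  boot <- withr::with_seed(1, {
    reps <- rbinom(4000, est$n_informative, est$r) / est$n_informative
    stats::sd(reps)
  })
  expect_lt(abs(est$se - boot) / est$se, 0.1)
})

test_that("the replica panel localizes the trait to the stated flanks", {
  panel <- replica_backcross_panel()
  haps <- infer_transmitted_haplotypes(panel)
  loc <- localize_trait(haps)
  expect_equal(loc$proximal_flank, "D11Mit208")
  expect_equal(loc$distal_flank, "D11Mit242")
  expect_equal(loc$n_proximal_recombinants, 11L)
  expect_equal(loc$n_distal_recombinants, 19L)
  expect_equal(loc$interval_bp, 4.8e6)
  # the marker that never recombined with the trait sits inside the interval
  expect_true("D11Mit260" %in% loc$inside_markers)
})

test_that("SNP refinement narrows the replica interval to SNP2-SNP6", {
  panel <- replica_backcross_panel()
  loc <- localize_trait(infer_transmitted_haplotypes(panel))
  ref <- refine_interval(loc, panel, replica_snp_genotypes(), replica_snp_map())
  expect_equal(ref$proximal_flank, "SNP2")
  expect_equal(ref$distal_flank, "SNP6")
  expect_equal(ref$n_proximal_recombinants, 2L)
  expect_equal(ref$n_distal_recombinants, 1L)
  expect_setequal(ref$inside_markers, c("D11Mit260", "SNP3", "SNP4", "SNP5"))
  expect_equal(ref$interval_bp, 0.75e6)
  # refinement with no extra markers is the identity
  expect_identical(refine_interval(loc, panel, NULL), loc)
  # extra markers outside the current interval are rejected
  expect_error(
    refine_interval(loc, panel, replica_snp_genotypes(),
                    tibble::tibble(name = paste0("SNP", 1:6),
                                   pos_bp = seq(6e6, 6.5e6, length.out = 6))),
    "inside the current interval")
})

test_that("simulated intervals contain the true locus and never widen on refinement", {
  map <- replica_map()
  wly <- replica_trait()
  pos <- setNames(map$pos_bp, map$name)
  for (s in 1:25) {
    panel <- simulate_backcross(map, wly, n = 1679, seed = 100 + s)
    loc <- localize_trait(infer_transmitted_haplotypes(panel))
    expect_lte(pos[loc$proximal_flank], wly$pos_bp)
    expect_gte(pos[loc$distal_flank], wly$pos_bp)
  }
})

test_that("expected interval width shrinks as the panel grows", {
  map <- replica_map()
  wly <- replica_trait()
  width <- function(n) {
    mean(vapply(1:12, function(s) {
      panel <- simulate_backcross(map, wly, n = n, seed = 1000 * n + s)
      localize_trait(infer_transmitted_haplotypes(panel))$interval_bp
    }, numeric(1)))
  }
  w <- c(width(100), width(400), width(1600))
  expect_true(w[3] <= w[2] && w[2] <= w[1])
})
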