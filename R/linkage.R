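#' Test the 1:1 segregation ratio of a testcross
#'
#' In a testcross a fully penetrant recessive trait segregates 1 mutant : 1
#' normal. The chi-square goodness-of-fit statistic (df = 1, no continuity
#' correction) against the equal split is
#' `(n_mutant - E)^2/E + (n_normal - E)^2/E` with `E = n/2`.
#'
#' @param panel A [backcross_panel()] (or anything with a `phenotype`
#'   column of `mutant`/`normal` values).
#' @return A list of class `segregation_test` with fields `n_mutant`,
#'   `n_normal`, `chi2`, `df`, `p_value`; see [glance.segregation_test()].
#' @examples
#' map <- make_marker_map(3, 3e6)
#' panel <- simulate_backcross(map, trait_locus("t", 1.5e6), n = 400, seed = 2)
#' glance(test_segregation(panel))
#' @export
test_segregation <- function(panel) {
  if (nrow(panel) == 0) abort("panel has zero progeny")
  n_mutant <- sum(panel$phenotype == "mutant")
  n_normal <- sum(panel$phenotype == "normal")
  e <- (n_mutant + n_normal) / 2
  chi2 <- (n_mutant - e)^2 / e + (n_normal - e)^2 / e
  structure(list(n_mutant = n_mutant, n_normal = n_normal, chi2 = chi2,
                 df = 1L, p_value = pchisq(chi2, df = 1, lower.tail = FALSE)),
            class = "segregation_test")
}

#' @export
print.segregation_test <- function(x, ...) {
  cat(sprintf(
    "<segregation_test> %d mutant : %d normal, chi2 = %.4g (df = 1), P = %.3g\n",
    x$n_mutant, x$n_normal, x$chi2, x$p_value))
  invisible(x)
}

#' @rdname test_segregation
#' @param x A `segregation_test`.
#' @param ... Unused.
#' @export
glance.segregation_test <- function(x, ...) {
  tibble(n_mutant = x$n_mutant, n_normal = x$n_normal,
         chi2 = x$chi2, df = x$df, p_value = x$p_value)
}

#' Infer the dam-transmitted haplotype of each progeny
#'
#' In a testcross the sire is homozygous, so each progeny's genotype reads
#' out the gamete transmitted by the heterozygous F1 dam directly: genotype
#' `H` means she transmitted the A-derived allele, `N` the N-derived allele,
#' missing stays unknown. The trait is carried as a pseudo-locus: a mutant
#' phenotype implies the dam transmitted the mutant (N-derived) allele, a
#' normal phenotype the wild-type (A-derived) allele.
#'
#' @param panel A [backcross_panel()].
#' @return A tibble of class `haplotype_set`: `id`, one column per marker
#'   and a trait column, values `A`, `N` or `NA`. Attributes `map` and
#'   `trait_name`.
#' @export
infer_transmitted_haplotypes <- function(panel) {
  map <- attr(panel, "map")
  trait <- attr(panel, "trait")
  trait_name <- if (inherits(trait, "trait_locus")) trait$name else trait
  marker_cols <- intersect(map$name, names(panel))
  geno <- as_tibble(panel)[marker_cols]
  bad <- purrr::map_lgl(geno, ~ any(!is.na(.x) & !.x %in% c("H", "N")))
  if (any(bad)) {
    abort(paste0("unknown genotype code in marker column(s): ",
                 paste(marker_cols[bad], collapse = ", ")))
  }
  alleles <- dplyr::mutate(geno, dplyr::across(
    dplyr::everything(), ~ dplyr::case_match(.x, "H" ~ "A", "N" ~ "N")))
  haps <- dplyr::bind_cols(
    tibble(id = panel$id),
    alleles,
    tibble(!!trait_name := dplyr::case_match(panel$phenotype,
                                             "mutant" ~ "N",
                                             "normal" ~ "A"))
  )
  structure(haps, map = map, trait_name = trait_name,
            class = c("haplotype_set", class(haps)))
}

#' Tally transmitted-haplotype classes
#'
#' Partitions progeny by their full dam-transmitted allele pattern over all
#' loci (markers in map order, then the trait pseudo-locus); unknown alleles
#' (`?`) make a pattern its own class. Counts sum to the panel size.
#'
#' @param haplotypes A `haplotype_set` from [infer_transmitted_haplotypes()].
#' @return A tibble with columns `pattern` (e.g. `"AAANNN|N"`, trait allele
#'   after the bar) and `count`, sorted by decreasing count.
#' @export
count_haplotype_classes <- function(haplotypes) {
  map <- attr(haplotypes, "map")
  trait_name <- attr(haplotypes, "trait_name")
  cols <- c(intersect(map$name, names(haplotypes)), trait_name)
  m <- as.matrix(as_tibble(haplotypes)[cols])
  m[is.na(m)] <- "?"
  k <- length(cols)
  pattern <- paste0(
    apply(m[, -k, drop = FALSE], 1, paste0, collapse = ""), "|", m[, k])
  dplyr::arrange(dplyr::count(tibble(pattern = pattern), .data$pattern,
                              name = "count"),
                 dplyr::desc(.data$count))
}

#' Estimate the recombination fraction between two loci
#'
#' Informative progeny are those with a known dam-derived allele at both
#' loci; recombinants are those whose alleles differ. The estimate is
#' `r = n_recombinant / n_informative` with binomial standard error
#' `sqrt(r (1 - r) / n_informative)`.
#'
#' @param haplotypes A `haplotype_set`.
#' @param locus_a,locus_b Column names (markers or the trait pseudo-locus).
#' @return A one-row tibble: `locus_a`, `locus_b`, `n_recombinant`,
#'   `n_informative`, `r`, `se`.
#' @export
estimate_recombination <- function(haplotypes, locus_a, locus_b) {
  for (loc in c(locus_a, locus_b)) {
    if (!loc %in% names(haplotypes)) {
      abort(paste0("locus '", loc, "' not typed in this haplotype set"))
    }
  }
  a <- haplotypes[[locus_a]]
  b <- haplotypes[[locus_b]]
  informative <- !is.na(a) & !is.na(b)
  n_inf <- sum(informative)
  if (n_inf == 0) {
    abort("no progeny informative for both loci")
  }
  n_rec <- sum(a[informative] != b[informative])
  r <- n_rec / n_inf
  tibble(locus_a = locus_a, locus_b = locus_b,
         n_recombinant = n_rec, n_informative = n_inf,
         r = r, se = sqrt(r * (1 - r) / n_inf))
}

#' Recombination fraction in every adjacent marker interval
#'
#' @param haplotypes A `haplotype_set`.
#' @return A tibble with one row per adjacent marker pair (map order).
#' @export
interval_estimates <- function(haplotypes) {
  map <- attr(haplotypes, "map")
  markers <- intersect(map$name, names(haplotypes))
  purrr::map_dfr(seq_len(length(markers) - 1), function(i) {
    estimate_recombination(haplotypes, markers[i], markers[i + 1])
  })
}

# Crossovers required for one progeny if the trait allele is inserted at
# each slot (0 = proximal of all markers .. K = distal of all). NA-tolerant:
# switches are counted between consecutive *known* alleles.
slot_penalties_one <- function(m, t) {
  k <- length(m)
  vapply(0:k, function(s) {
    seqv <- append(m, t, after = s)
    known <- seqv[!is.na(seqv)]
    if (length(known) < 2) 0L else sum(known[-1] != known[-length(known)])
  }, integer(1))
}

# Column sums of slot penalties over all progeny. Fast vectorized path for
# complete rows; generic path for rows with missing alleles.
slot_penalty_totals <- function(M, t) {
  k <- ncol(M)
  total <- numeric(k + 1)
  complete <- !is.na(t) & rowSums(is.na(M)) == 0
  if (any(complete)) {
    Mc <- M[complete, , drop = FALSE]
    tc <- t[complete]
    D <- Mc != tc                          # mismatch vs trait allele
    S <- Mc[, -1, drop = FALSE] != Mc[, -k, drop = FALSE]
    base <- rowSums(S)
    delta <- cbind(D[, 1],
                   if (k > 1) D[, -k, drop = FALSE] + D[, -1, drop = FALSE] - S,
                   D[, k])
    total <- total + colSums(base + delta)
  }
  partial <- which(!complete & !is.na(t))
  for (i in partial) {
    total <- total + slot_penalties_one(M[i, ], t[i])
  }
  total
}

#' Localize the trait between flanking markers by recombinant counting
#'
#' Places the trait pseudo-locus in the inter-marker slot (or terminal
#' position) minimizing the total number of crossovers required across all
#' progeny; slots tied at the minimum — which arise around interior markers
#' showing zero recombination with the trait — are merged into a single
#' critical interval. The reported flanks are the markers bounding that
#' interval, i.e. the nearest markers whose trait-marker recombinants place
#' the trait on the other side. When a side shows no recombinant at all the
#' outermost typed marker is used and a warning is recorded.
#'
#' @param haplotypes A `haplotype_set` from [infer_transmitted_haplotypes()].
#' @param map Optional [genetic_map()] (defaults to the set's own map).
#' @return A list of class `trait_localization`: `proximal_flank`,
#'   `distal_flank`, `n_proximal_recombinants`, `n_distal_recombinants`,
#'   `proximal_recombinant_ids`, `distal_recombinant_ids`,
#'   `inside_markers` (markers not separable from the trait),
#'   `double_recombinant_ids` (flagged, retained), `interval_bp`, and
#'   `warnings`. [tidy.trait_localization()] returns the per-interval
#'   recombination estimates.
#' @export
localize_trait <- function(haplotypes, map = NULL) {
  map <- map %||% attr(haplotypes, "map")
  trait_name <- attr(haplotypes, "trait_name")
  if (is.null(trait_name) || !trait_name %in% names(haplotypes)) {
    abort("trait pseudo-locus absent from the haplotype set")
  }
  markers <- intersect(map$name, names(haplotypes))
  if (length(markers) < 2) abort("need at least two typed markers")
  M <- as.matrix(as_tibble(haplotypes)[markers])
  t_allele <- haplotypes[[trait_name]]
  k <- length(markers)

  total <- slot_penalty_totals(M, t_allele)
  best <- which(total == min(total)) - 1L   # slots 0..k
  lo <- min(best)
  hi <- max(best)

  warnings <- character(0)
  if (any(diff(sort(best)) > 1)) {
    warnings <- c(warnings,
                  "tied localization slots are non-contiguous; reporting their span")
  }
  if (lo == 0) {
    proximal_flank <- markers[1]
    warnings <- c(warnings,
                  "no recombinant bounds the proximal side; using outermost marker")
  } else {
    proximal_flank <- markers[lo]
  }
  if (hi == k) {
    distal_flank <- markers[k]
    warnings <- c(warnings,
                  "no recombinant bounds the distal side; using outermost marker")
  } else {
    distal_flank <- markers[hi + 1]
  }
  inside <- if (hi > lo) markers[seq(lo + 1, hi)] else character(0)

  pa <- haplotypes[[proximal_flank]]
  da <- haplotypes[[distal_flank]]
  prox_rec <- !is.na(t_allele) & !is.na(pa) & pa != t_allele &
    !is.na(da) & da == t_allele
  dist_rec <- !is.na(t_allele) & !is.na(da) & da != t_allele &
    !is.na(pa) & pa == t_allele
  double_rec <- !is.na(t_allele) & !is.na(pa) & !is.na(da) &
    pa != t_allele & da != t_allele

  pos <- setNames(map$pos_bp, map$name)
  structure(list(
    proximal_flank = proximal_flank,
    distal_flank = distal_flank,
    n_proximal_recombinants = sum(prox_rec),
    n_distal_recombinants = sum(dist_rec),
    proximal_recombinant_ids = haplotypes$id[prox_rec],
    distal_recombinant_ids = haplotypes$id[dist_rec],
    double_recombinant_ids = haplotypes$id[double_rec],
    inside_markers = inside,
    interval_bp = unname(pos[distal_flank] - pos[proximal_flank]),
    trait_name = trait_name,
    map = map,
    haplotypes = haplotypes,
    warnings = warnings
  ), class = "trait_localization")
}

#' @export
print.trait_localization <- function(x, ...) {
  cat(sprintf(
    "<trait_localization> %s in (%s, %s): %d proximal + %d distal recombinants, %s bp\n",
    x$trait_name, x$proximal_flank, x$distal_flank,
    x$n_proximal_recombinants, x$n_distal_recombinants,
    format(x$interval_bp, big.mark = ",")))
  if (length(x$inside_markers) > 0) {
    cat("  not separated from the trait:",
        paste(x$inside_markers, collapse = ", "), "\n")
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' @rdname localize_trait
#' @param x A `trait_localization`.
#' @param ... Unused.
#' @export
tidy.trait_localization <- function(x, ...) {
  interval_estimates(x$haplotypes)
}

#' @rdname localize_trait
#' @export
glance.trait_localization <- function(x, ...) {
  tibble(trait = x$trait_name,
         proximal_flank = x$proximal_flank, distal_flank = x$distal_flank,
         n_proximal_recombinants = x$n_proximal_recombinants,
         n_distal_recombinants = x$n_distal_recombinants,
         interval_bp = x$interval_bp,
         n_warnings = length(x$warnings))
}

#' Refine a critical interval with markers typed on recombinants only
#'
#' The second mapping stage types additional markers (here SNPs inside the
#' current critical interval) only on the progeny recombinant within that
#' interval; all other progeny are implicitly parental across the interval,
#' so their alleles at the new markers are imputed from their (identical)
#' flanking-marker alleles. Localization is re-run over the union of loci.
#' The refined interval is never wider than the input interval.
#'
#' @param localization A [localize_trait()] result.
#' @param panel The original [backcross_panel()].
#' @param extra_genotypes A data frame: `id` plus one column per extra
#'   marker with codes `H`/`N`/`-`, covering every recombinant listed in
#'   `localization`.
#' @param extra_map A data frame (`name`, `pos_bp`, optional `pos_cM`) with
#'   the extra markers' positions, all strictly inside the current interval.
#' @return A new `trait_localization` over the combined marker set.
#' @export
refine_interval <- function(localization, panel, extra_genotypes,
                            extra_map = NULL) {
  stopifnot(inherits(localization, "trait_localization"))
  map <- localization$map
  haps <- localization$haplotypes

  if (is.null(extra_genotypes) || ncol(extra_genotypes) <= 1) {
    return(localization)
  }
  extra_genotypes <- as_tibble(extra_genotypes)
  extra_markers <- setdiff(names(extra_genotypes), "id")
  if (is.null(extra_map)) abort("`extra_map` with marker positions is required")
  extra_map <- as_tibble(extra_map)
  if (!all(extra_markers %in% extra_map$name)) {
    abort("every extra marker needs a position in `extra_map`")
  }
  pos <- setNames(map$pos_bp, map$name)
  lo <- pos[localization$proximal_flank]
  hi <- pos[localization$distal_flank]
  em <- extra_map[match(extra_markers, extra_map$name), ]
  if (any(em$pos_bp <= lo | em$pos_bp >= hi)) {
    abort("extra markers must lie strictly inside the current interval")
  }

  rec_ids <- c(localization$proximal_recombinant_ids,
               localization$distal_recombinant_ids,
               localization$double_recombinant_ids)
  missing_rec <- setdiff(rec_ids, extra_genotypes$id)
  if (length(missing_rec) > 0) {
    abort(paste0("extra genotypes missing for recombinant progeny: ",
                 paste(missing_rec, collapse = ", ")))
  }

  if (!"pos_cM" %in% names(em)) {
    em$pos_cM <- vapply(em$pos_bp, function(p) interpolate_cM(map, p),
                        numeric(1))
  }
  combined_map <- genetic_map(
    dplyr::bind_rows(
      as_tibble(map),
      tibble(name = em$name, chrom = attr(map, "chrom"),
             pos_bp = em$pos_bp, pos_cM = em$pos_cM)),
    cm_per_mb = attr(map, "cm_per_mb"))

  # typed alleles for recombinants; imputed parental alleles elsewhere
  extra_alleles <- dplyr::mutate(
    extra_genotypes,
    dplyr::across(dplyr::all_of(extra_markers), ~ {
      x <- as.character(.x)
      x[x == "-"] <- NA_character_
      bad <- !is.na(x) & !x %in% c("H", "N")
      if (any(bad)) abort("unknown genotype code in extra genotypes")
      dplyr::case_match(x, "H" ~ "A", "N" ~ "N")
    }))
  aug <- dplyr::left_join(as_tibble(haps), extra_alleles, by = "id")
  flank_allele <- aug[[localization$proximal_flank]]
  parental <- !aug$id %in% rec_ids
  for (mname in extra_markers) {
    impute <- parental & is.na(aug[[mname]])
    aug[[mname]][impute] <- flank_allele[impute]
  }

  aug <- structure(aug, map = combined_map,
                   trait_name = localization$trait_name,
                   class = c("haplotype_set", class(as_tibble(aug))))
  refined <- localize_trait(aug, combined_map)

  cpos <- setNames(combined_map$pos_bp, combined_map$name)
  if (cpos[refined$proximal_flank] < lo || cpos[refined$distal_flank] > hi) {
    abort("internal error: refinement widened the interval")
  }
  refined
}
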