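#' Haldane map function and its inverse
#'
#' Under a no-interference (Poisson) crossover model the recombination
#' fraction between loci separated by `d` Morgans is
#' `r = (1 - exp(-2 d)) / 2`.
#'
#' @param d_morgan Genetic distance in Morgans.
#' @param r Recombination fraction in `[0, 0.5)`.
#' @return A numeric vector.
#' @export
haldane <- function(d_morgan) (1 - exp(-2 * d_morgan)) / 2

#' @rdname haldane
#' @export
haldane_inverse <- function(r) {
  if (any(r < 0 | r >= 0.5)) abort("`r` must lie in [0, 0.5)")
  -log(1 - 2 * r) / 2
}

#' Simulate a backcross (testcross) panel
#'
#' Emulates an (A x N)F1 female, heterozygous for a recessive mutation
#' carried on the N haplotype, bred back to homozygous-mutant N males. Only
#' the dam's meiosis is informative: her transmitted chromatid is generated
#' by a Haldane (no-interference) crossover process along the genetic map,
#' the sire always contributing the N haplotype with the mutant allele.
#' A progeny is phenotypically mutant iff the dam transmitted the mutant
#' (N-derived) allele at the trait locus, thinned by `penetrance`. Marker
#' genotypes are `H` (heterozygous A/N) when the dam transmitted the
#' A-derived allele, `N` (homozygous) otherwise; `genotyping_error` flips
#' each genotype call independently.
#'
#' The crossover process is simulated as a Markov chain over the ordered
#' loci (markers plus the trait): the transmitted parental origin switches
#' across each interval with probability equal to the Haldane recombination
#' fraction of the interval's genetic length, which is exact for a Poisson
#' crossover process without interference.
#'
#' @param map A [genetic_map()].
#' @param trait A [trait_locus()] lying within the map span (its genetic
#'   position is interpolated from the map when not given).
#' @param n Number of progeny (>= 1).
#' @param genotyping_error Per-genotype flip probability, in `[0, 1)`.
#' @param seed Integer seed; identical seeds give identical panels. Seeds
#'   are explicit: the global RNG state is left untouched.
#'
#' @return A tibble of class `backcross_panel`: columns `id`, `phenotype`
#'   (`mutant`/`normal`) and one genotype column per marker with codes
#'   `H`, `N` or `NA` (missing). Attributes: `map`, `trait`, `seed`, and
#'   `truth`, a tibble with the simulated dam allele (`A`/`N`) at the trait
#'   locus per progeny (simulation truth, not observable in a real cross).
#' @examples
#' map <- make_marker_map(6, span_bp = 6e6, cm_per_mb = 0.5)
#' wly <- trait_locus("wly", pos_bp = 3.3e6)
#' panel <- simulate_backcross(map, wly, n = 200, seed = 1)
#' table(panel$phenotype)
#' @export
simulate_backcross <- function(map, trait, n, genotyping_error = 0,
                               seed = NULL) {
  stopifnot(inherits(map, "genetic_map"), inherits(trait, "trait_locus"))
  if (!is.numeric(n) || n < 1) abort("`n` must be >= 1")
  n <- as.integer(n)
  if (genotyping_error < 0 || genotyping_error >= 1) {
    abort("`genotyping_error` must lie in [0, 1)")
  }
  if (trait$pos_bp < min(map$pos_bp) || trait$pos_bp > max(map$pos_bp)) {
    abort("trait position must lie within the map span")
  }
  trait_cM <- trait$pos_cM %||% interpolate_cM(map, trait$pos_bp)

  loci <- tibble(
    name = c(map$name, trait$name),
    pos_cM = c(map$pos_cM, trait_cM),
    is_trait = c(rep(FALSE, nrow(map)), TRUE)
  )
  loci <- dplyr::arrange(loci, .data$pos_cM, .data$is_trait)
  L <- nrow(loci)

  sim <- function() {
    # dam-transmitted parental origin: TRUE = A-derived, FALSE = N-derived
    origin <- matrix(NA, nrow = n, ncol = L)
    origin[, 1] <- runif(n) < 0.5
    if (L > 1) {
      r_int <- haldane(diff(loci$pos_cM) / 100)
      for (j in 2:L) {
        switch <- runif(n) < r_int[j - 1]
        origin[, j] <- xor(origin[, j - 1], switch)
      }
    }
    trait_col <- which(loci$is_trait)
    carries_mutant <- !origin[, trait_col]  # N-derived chromatid carries wly
    expressed <- carries_mutant & (runif(n) < trait$penetrance)
    geno <- ifelse(origin[, -trait_col, drop = FALSE], "H", "N")
    if (genotyping_error > 0) {
      flip <- matrix(runif(length(geno)) < genotyping_error, nrow = n)
      geno[flip] <- ifelse(geno[flip] == "H", "N", "H")
    }
    list(geno = geno, expressed = expressed, carries_mutant = carries_mutant)
  }
  res <- if (is.null(seed)) sim() else withr::with_seed(seed, sim())

  marker_names <- loci$name[!loci$is_trait]
  panel <- tibble(
    id = sprintf("N2-%04d", seq_len(n)),
    phenotype = ifelse(res$expressed, "mutant", "normal")
  )
  geno_tbl <- as_tibble(res$geno, .name_repair = "minimal")
  names(geno_tbl) <- marker_names
  panel <- dplyr::bind_cols(panel, geno_tbl[map$name])

  new_backcross_panel(
    panel, map = map, trait = trait, seed = seed,
    truth = tibble(id = panel$id,
                   trait_allele = ifelse(res$carries_mutant, "N", "A"))
  )
}

new_backcross_panel <- function(tbl, map, trait, seed = NULL, truth = NULL) {
  trait_name <- if (inherits(trait, "trait_locus")) trait$name else trait
  missing_markers <- setdiff(setdiff(names(tbl), c("id", "phenotype")),
                             map$name)
  if (length(missing_markers) > 0) {
    abort(paste0("panel genotypes reference markers absent from the map: ",
                 paste(missing_markers, collapse = ", ")))
  }
  structure(as_tibble(tbl), map = map, trait = trait, seed = seed,
            truth = truth,
            class = c("backcross_panel", class(as_tibble(tbl))))
}

#' Assemble a backcross panel from a genotype table
#'
#' @param genotypes A data frame with columns `id`, `phenotype` and one
#'   column per marker (codes `H`, `N`, `-` or `NA`).
#' @param map The [genetic_map()] the marker columns refer to.
#' @param trait A [trait_locus()] or trait name.
#' @return A `backcross_panel` tibble.
#' @export
backcross_panel <- function(genotypes, map, trait) {
  genotypes <- as_tibble(genotypes)
  marker_cols <- setdiff(names(genotypes), c("id", "phenotype"))
  genotypes <- dplyr::mutate(
    genotypes,
    dplyr::across(dplyr::all_of(marker_cols), ~ {
      x <- as.character(.x)
      x[x == "-"] <- NA_character_
      bad <- !is.na(x) & !x %in% c("H", "N")
      if (any(bad)) {
        abort(paste0("unknown genotype code(s): ",
                     paste(unique(x[bad]), collapse = ", ")))
      }
      x
    })
  )
  if (!all(genotypes$phenotype %in% c("mutant", "normal"))) {
    abort("`phenotype` must be 'mutant' or 'normal'")
  }
  new_backcross_panel(genotypes, map = map, trait = trait)
}

#' Read / write a backcross genotype table as TSV
#'
#' Columns: `id`, `phenotype`, then one column per marker with codes
#' `H` (heterozygous), `N` (homozygous) or `-` (missing).
#'
#' @param path File path.
#' @param map,trait Passed to [backcross_panel()] on read.
#' @return `read_backcross_panel()` returns a `backcross_panel`;
#'   `write_backcross_panel()` returns `path` invisibly.
#' @export
read_backcross_panel <- function(path, map, trait) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()))
  backcross_panel(tab, map = map, trait = trait)
}

#' @param panel A `backcross_panel`.
#' @rdname read_backcross_panel
#' @export
write_backcross_panel <- function(panel, path) {
  out <- as_tibble(panel)
  marker_cols <- setdiff(names(out), c("id", "phenotype"))
  out <- dplyr::mutate(out, dplyr::across(dplyr::all_of(marker_cols),
                                          ~ dplyr::coalesce(.x, "-")))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @export
print.backcross_panel <- function(x, ...) {
  map <- attr(x, "map")
  trait <- attr(x, "trait")
  trait_name <- if (inherits(trait, "trait_locus")) trait$name else trait
  cat(sprintf("<backcross_panel> %d progeny, %d markers on %s, trait '%s'\n",
              nrow(x), nrow(map), attr(map, "chrom"), trait_name))
  NextMethod()
}
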