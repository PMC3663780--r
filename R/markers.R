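#' Construct a genetic marker map
#'
#' A genetic map is a tibble of ordered marker loci on one chromosome, each
#' with a physical position (`pos_bp`, 0-based) and a genetic position
#' (`pos_cM`). Both coordinates must be strictly increasing (monotone
#' co-linear); multi-chromosome maps are rejected.
#'
#' @param markers A data frame with columns `name`, `chrom`, `pos_bp`,
#'   `pos_cM` (one row per marker).
#' @param cm_per_mb Default linear conversion rate used by helpers that
#'   derive genetic from physical positions, in cM per Mb.
#'
#' @return A tibble of class `genetic_map` with attributes `chrom` and
#'   `cm_per_mb`.
#' @seealso [make_marker_map()] to build a map from positions alone.
#' @export
genetic_map <- function(markers, cm_per_mb = 0.5) {
  markers <- as_tibble(markers)
  required <- c("name", "chrom", "pos_bp", "pos_cM")
  missing_cols <- setdiff(required, names(markers))
  if (length(missing_cols) > 0) {
    abort(paste0("marker table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(markers) < 2) abort("a genetic map needs at least 2 markers")
  if (anyDuplicated(markers$name)) abort("marker names must be unique")
  if (length(unique(markers$chrom)) != 1) {
    abort("all markers must lie on a single chromosome")
  }
  if (any(markers$pos_bp < 0) || any(markers$pos_cM < 0)) {
    abort("marker positions must be non-negative")
  }
  if (!is.numeric(cm_per_mb) || cm_per_mb <= 0) {
    abort("`cm_per_mb` must be a positive number")
  }
  markers <- dplyr::arrange(markers, .data$pos_bp)
  if (any(diff(markers$pos_bp) <= 0)) {
    abort("marker physical positions must be strictly increasing")
  }
  if (any(diff(markers$pos_cM) <= 0)) {
    abort("marker genetic positions must be strictly increasing (co-linear)")
  }
  structure(markers[required],
            chrom = unique(markers$chrom),
            cm_per_mb = cm_per_mb,
            class = c("genetic_map", class(markers)))
}

#' Build an evenly spaced (or user-positioned) marker map
#'
#' Physical positions are converted to genetic positions linearly:
#' `pos_cM = pos_bp * cm_per_mb / 1e6`.
#'
#' @param n_markers Number of markers (>= 2).
#' @param span_bp Chromosome span in bp; default placement spreads markers
#'   evenly from 0 to `span_bp`.
#' @param cm_per_mb Conversion rate, cM per Mb.
#' @param positions_bp Optional explicit physical positions (strictly
#'   increasing, within `[0, span_bp]`); overrides even placement.
#' @param chrom Chromosome label.
#' @param names Optional marker names (default `M1..Mn`).
#'
#' @return A `genetic_map` tibble.
#' @examples
#' make_marker_map(2, span_bp = 1e6, cm_per_mb = 0.5)
#' @export
make_marker_map <- function(n_markers, span_bp, cm_per_mb = 0.5,
                            positions_bp = NULL, chrom = "chr1",
                            names = NULL) {
  if (n_markers < 2) abort("`n_markers` must be >= 2")
  if (span_bp <= 0) abort("`span_bp` must be positive")
  if (is.null(positions_bp)) {
    positions_bp <- round(seq(0, span_bp, length.out = n_markers))
  }
  if (length(positions_bp) != n_markers) {
    abort("`positions_bp` length must equal `n_markers`")
  }
  if (any(diff(positions_bp) <= 0)) {
    abort("`positions_bp` must be strictly increasing")
  }
  if (min(positions_bp) < 0 || max(positions_bp) > span_bp) {
    abort("`positions_bp` must lie within [0, span_bp]")
  }
  if (is.null(names)) names <- paste0("M", seq_len(n_markers))
  genetic_map(
    tibble(name = names, chrom = chrom,
           pos_bp = as.numeric(positions_bp),
           pos_cM = positions_bp * cm_per_mb / 1e6),
    cm_per_mb = cm_per_mb
  )
}

#' Define the trait locus segregating in a backcross
#'
#' @param name Locus name (used as the trait pseudo-locus label).
#' @param pos_bp Physical position, 0-based bp.
#' @param pos_cM Genetic position in cM; if `NULL`, interpolated linearly
#'   from the map when the locus is used in simulation.
#' @param mode Inheritance mode; only `"recessive"` is supported.
#' @param penetrance Probability that a homozygous-mutant genotype shows the
#'   mutant phenotype, in (0, 1].
#'
#' @return A list of class `trait_locus`.
#' @export
trait_locus <- function(name, pos_bp, pos_cM = NULL,
                        mode = "recessive", penetrance = 1) {
  mode <- match.arg(mode, "recessive")
  if (!is.numeric(penetrance) || penetrance <= 0 || penetrance > 1) {
    abort("`penetrance` must lie in (0, 1]")
  }
  structure(list(name = name, pos_bp = pos_bp, pos_cM = pos_cM,
                 mode = mode, penetrance = penetrance),
            class = "trait_locus")
}

#' Read / write a marker map as TSV
#'
#' The TSV has columns `name`, `chrom`, `pos_bp`, `pos_cM`.
#'
#' @param path File path.
#' @param cm_per_mb Conversion rate recorded on the returned map.
#' @return `read_marker_map()` returns a `genetic_map`;
#'   `write_marker_map()` returns `path` invisibly.
#' @export
read_marker_map <- function(path, cm_per_mb = 0.5) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    name = readr::col_character(), chrom = readr::col_character(),
    pos_bp = readr::col_double(), pos_cM = readr::col_double()
  ))
  genetic_map(tab, cm_per_mb = cm_per_mb)
}

#' @param map A `genetic_map`.
#' @rdname read_marker_map
#' @export
write_marker_map <- function(map, path) {
  stopifnot(inherits(map, "genetic_map"))
  readr::write_tsv(as_tibble(map), path)
  invisible(path)
}

# Interpolate a genetic position for a physical position, linearly between
# the flanking markers (extrapolates with the map's cm_per_mb at the ends).
interpolate_cM <- function(map, pos_bp) {
  x <- map$pos_bp
  y <- map$pos_cM
  rate <- attr(map, "cm_per_mb") / 1e6
  if (pos_bp <= x[1]) return(y[1] - (x[1] - pos_bp) * rate)
  n <- length(x)
  if (pos_bp >= x[n]) return(y[n] + (pos_bp - x[n]) * rate)
  stats::approx(x, y, xout = pos_bp)$y
}
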