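#' Triage candidate genes in a critical interval
#'
#' Applies the published rule set to an annotated gene list. Exclusion
#' reasons use the fixed precedence `outside_interval` >
#' `knockout_normal_coat` > `no_skin_role`, so input order never affects
#' membership:
#'
#' * genes not overlapping the interval (any-overlap, half-open
#'   coordinates) are excluded as `outside_interval`;
#' * genes whose engineered null-allele homozygotes show a normal coat are
#'   excluded as `knockout_normal_coat`;
#' * genes with no skin expression evidence (`"none"`) are excluded as
#'   `no_skin_role`;
#' * genes isolated from skin cDNA libraries become primary candidates;
#' * genes with `other`/`unknown` evidence and no positive exclusion are
#'   retained as primary candidates flagged `weak_evidence` — exclusion
#'   requires positive evidence, not absence of annotation.
#'
#' @param genes A data frame: `name`, `start_bp`, `end_bp`,
#'   `null_allele_coat_normal` (logical, `NA` = unknown),
#'   `skin_expression_evidence` (`cdna_library`/`other`/`none`/`unknown`).
#' @param interval `c(start_bp, end_bp)`, half-open.
#' @return A list of class `triage_result`: `table` (the annotated input
#'   with `status`, `reason`, `weak_evidence`), `primary` (character vector)
#'   and `excluded` (tibble `gene`, `reason`).
#' @examples
#' triage(replica_interval_genes(), replica_critical_interval())
#' @export
triage <- function(genes, interval) {
  if (length(interval) != 2 || interval[2] <= interval[1]) {
    abort("`interval` must be c(start, end) with start < end")
  }
  genes <- as_tibble(genes)
  if (nrow(genes) == 0) {
    warn("empty gene list; nothing to triage")
  } else if (any(genes$end_bp <= genes$start_bp)) {
    abort("gene coordinates must satisfy start < end")
  }
  evidence_levels <- c("cdna_library", "other", "none", "unknown")
  bad <- !genes$skin_expression_evidence %in% evidence_levels
  if (any(bad)) {
    abort(paste0("unknown skin_expression_evidence value(s): ",
                 paste(unique(genes$skin_expression_evidence[bad]),
                       collapse = ", ")))
  }
  inside <- genes$start_bp < interval[2] & genes$end_bp > interval[1]
  tab <- dplyr::mutate(
    genes,
    reason = dplyr::case_when(
      !inside ~ "outside_interval",
      isTRUE_vec(.data$null_allele_coat_normal) ~ "knockout_normal_coat",
      .data$skin_expression_evidence == "none" ~ "no_skin_role",
      TRUE ~ NA_character_
    ),
    status = ifelse(is.na(.data$reason), "primary", "excluded"),
    weak_evidence = .data$status == "primary" &
      .data$skin_expression_evidence != "cdna_library"
  )
  structure(list(
    table = tab,
    primary = tab$name[tab$status == "primary"],
    excluded = tibble(gene = tab$name[tab$status == "excluded"],
                      reason = tab$reason[tab$status == "excluded"])
  ), class = "triage_result")
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.triage_result <- function(x, ...) {
  cat(sprintf("<triage_result> %d gene(s): %d primary, %d excluded\n",
              nrow(x$table), length(x$primary), nrow(x$excluded)))
  if (length(x$primary) > 0) {
    cat("  primary:", paste(x$primary, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname triage
#' @param x A `triage_result`.
#' @param ... Unused.
#' @export
tidy.triage_result <- function(x, ...) x$table

#' @rdname triage
#' @export
glance.triage_result <- function(x, ...) {
  tibble(n_genes = nrow(x$table),
         n_primary = length(x$primary),
         n_excluded = nrow(x$excluded),
         n_weak = sum(x$table$weak_evidence))
}
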