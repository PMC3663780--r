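#' Plot dam-transmitted haplotype classes
#'
#' A tile diagram of the distinct transmitted haplotypes (markers in map
#' order plus the trait pseudo-locus), one column per class with its
#' progeny count below — the standard way a testcross panel is summarized.
#'
#' @param object A `backcross_panel`.
#' @param max_classes Show at most this many classes (by decreasing count).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.backcross_panel <- function(object, max_classes = 12, ...) {
  haps <- infer_transmitted_haplotypes(object)
  classes <- utils::head(count_haplotype_classes(haps), max_classes)
  map <- attr(haps, "map")
  loci <- c(map$name, attr(haps, "trait_name"))
  long <- purrr::imap_dfr(classes$pattern, function(p, i) {
    alleles <- strsplit(sub("\\|", "", p), "")[[1]]
    tibble(class = i, count = classes$count[i], locus = loci,
           allele = alleles)
  })
  long$locus <- factor(long$locus, levels = rev(loci))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$class),
                                     y = .data$locus,
                                     fill = .data$allele)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_fill_manual(
      values = c(A = "white", N = "grey20", `?` = "grey70"),
      name = "dam allele") +
    ggplot2::geom_text(
      data = dplyr::distinct(long, .data$class, .data$count),
      ggplot2::aes(x = factor(.data$class), y = 0.4,
                   label = .data$count),
      inherit.aes = FALSE, size = 3) +
    ggplot2::labs(x = "haplotype class", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a trait localization on the physical map
#'
#' Markers along the chromosome with the critical interval shaded and the
#' flanking recombinant counts annotated.
#'
#' @param object A `trait_localization`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trait_localization <- function(object, ...) {
  map <- object$map
  mk <- tibble(name = map$name, pos_mb = map$pos_bp / 1e6,
               role = dplyr::case_when(
                 map$name %in% c(object$proximal_flank,
                                 object$distal_flank) ~ "flank",
                 map$name %in% object$inside_markers ~ "inside",
                 TRUE ~ "outside"))
  pos <- setNames(mk$pos_mb, mk$name)
  ggplot2::ggplot(mk, ggplot2::aes(x = .data$pos_mb, y = 0)) +
    ggplot2::annotate("rect",
                      xmin = pos[object$proximal_flank],
                      xmax = pos[object$distal_flank],
                      ymin = -0.2, ymax = 0.2, fill = "indianred",
                      alpha = 0.25) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$pos_mb, y = -0.1, yend = 0.1)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$role), size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$name), angle = 45,
                       hjust = 0, nudge_y = 0.15, size = 3) +
    ggplot2::scale_color_manual(values = c(flank = "steelblue",
                                           inside = "forestgreen",
                                           outside = "grey40")) +
    ggplot2::annotate(
      "text", x = mean(c(pos[object$proximal_flank],
                         pos[object$distal_flank])), y = -0.35,
      label = sprintf("%d + %d flanking recombinants",
                      object$n_proximal_recombinants,
                      object$n_distal_recombinants), size = 3) +
    ggplot2::ylim(-0.5, 0.8) +
    ggplot2::labs(x = "position (Mb)", y = NULL,
                  title = sprintf("%s critical interval", object$trait_name)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank(),
                   panel.grid.minor.y = ggplot2::element_blank())
}

#' Plot wild-type and mutant gene structure for a consequence report
#'
#' Exon boxes on transcript coordinates for both alleles; skipped exons
#' appear only on the wild-type track.
#'
#' @param object A `consequence_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.consequence_report <- function(object, ...) {
  track <- function(model, label) {
    lens <- exon_lengths(model)
    ends <- cumsum(lens)
    tibble(allele = label, ordinal = model$exons$ordinal,
           xmin = c(0, ends[-length(ends)]), xmax = ends)
  }
  df <- dplyr::bind_rows(track(object$wt_model, "wild type"),
                         track(object$mutant_model, "mutant"))
  df$skipped <- df$allele == "wild type" &
    df$ordinal %in% object$skipped_exons
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = -0.3, ymax = 0.3,
                                    fill = .data$skipped),
                       color = "grey20") +
    ggplot2::geom_text(ggplot2::aes(
      x = (.data$xmin + .data$xmax) / 2, y = 0,
      label = .data$ordinal), size = 3) +
    ggplot2::facet_wrap(~ .data$allele, ncol = 1) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "palegreen3",
                                          `TRUE` = "indianred"),
                               guide = "none") +
    ggplot2::labs(x = "spliced transcript position (nt)", y = NULL,
                  title = sprintf("%s: exon structure", object$gene)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
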