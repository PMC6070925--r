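#' Plot a MAL cluster map
#'
#' Gene-arrow map of the detected clusters, one facet per cluster, in the
#' style of comparative MAL locus figures: genes drawn as arrows along the
#' contig, colored by role.
#'
#' @param object A `mal_scan` from [run_scan()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mal_scan <- function(object, ...) {
  df <- tidy(object)
  if (nrow(df) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "no clusters") +
             ggplot2::theme_void())
  }
  members <- bind_rows(purrr::map(seq_len(nrow(object$clusters)), function(k) {
    mutate(object$clusters$members[[k]],
           cluster_id = object$clusters$cluster_id[k])
  }))
  members <- mutate(members,
                    role = ifelse(is.na(.data$role), "ambiguous", .data$role),
                    x = ifelse(.data$strand == "+", .data$start, .data$end),
                    xend = ifelse(.data$strand == "+", .data$end, .data$start))
  ggplot2::ggplot(members) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x, xend = .data$xend, y = 0, yend = 0,
                   color = .data$role),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"), type = "closed"),
      linewidth = 2
    ) +
    ggplot2::facet_wrap(~cluster_id, ncol = 1, scales = "free_x") +
    ggplot2::scale_y_continuous(NULL, breaks = NULL) +
    ggplot2::labs(x = "contig position (bp)", color = "role") +
    ggplot2::theme_minimal()
}

#' Plot signature residues of classified proteins
#'
#' Tile plot of the nine signature positions per protein, annotated with the
#' predicted substrate specificity.
#'
#' @param object A `mal_classification` from [classify_signature()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mal_classification <- function(object, ...) {
  anchors <- signature_anchors()
  df <- bind_rows(purrr::map(seq_len(nrow(object)), function(k) {
    tibble(id = object$id[k], label = object$label[k],
           position = factor(anchors, levels = anchors),
           residue = chars(object$signature[k]))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$id)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$label), alpha = 0.4) +
    ggplot2::geom_text(ggplot2::aes(label = .data$residue), size = 3) +
    ggplot2::labs(x = "position (Sc IMA1 numbering)", y = NULL,
                  fill = "prediction") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a bootstrapped phylogram
#'
#' Base-graphics phylogram (ape) with bootstrap supports on internal nodes.
#'
#' @param tree A `phylo`, e.g. from [run_tree()] or [bootstrap_support()].
#' @param ... Passed to [ape::plot.phylo()].
#' @return The tree, invisibly.
#' @export
plot_phylogram <- function(tree, ...) {
  ape::plot.phylo(tree, ...)
  if (!is.null(tree$node.label)) {
    ape::nodelabels(tree$node.label, frame = "none", adj = c(1.1, -0.3), cex = 0.7)
  }
  invisible(tree)
}
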