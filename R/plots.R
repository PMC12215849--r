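#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

tree_layout <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  depth <- ape::node.depth.edgelength(tree)
  y <- numeric(n_all)
  y[seq_len(n_tip)] <- match(seq_len(n_tip),
                             tree$edge[tree$edge[, 2L] <= n_tip, 2L])
  for (i in seq_len(nrow(tree$edge))) {   # postorder: children before parents
    p <- tree$edge[i, 1L]
    kids <- tree$edge[tree$edge[, 1L] == p, 2L]
    y[p] <- mean(y[kids])
  }
  list(tree = tree, x = depth, y = y, n_tip = n_tip)
}

#' Plot a marginal ancestral reconstruction on the tree
#'
#' Draws the phylogeny left-to-right with internal nodes coloured by the
#' reconstructed probability of state 1 (FD present) and tips marked by
#' their observed state.
#'
#' @param object An `mk_asr` object from [asr_marginal()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mk_asr <- function(object, ...) {
  tree <- attr(object, "tree")
  lay <- tree_layout(tree)
  tre <- lay$tree
  seg_h <- tibble::tibble(
    x = lay$x[tre$edge[, 1L]], xend = lay$x[tre$edge[, 2L]],
    y = lay$y[tre$edge[, 2L]], yend = lay$y[tre$edge[, 2L]])
  seg_v <- tibble::tibble(
    x = lay$x[tre$edge[, 1L]], xend = lay$x[tre$edge[, 1L]],
    y = lay$y[tre$edge[, 1L]], yend = lay$y[tre$edge[, 2L]])
  nodes <- tibble::tibble(x = lay$x[object$node], y = lay$y[object$node],
                          p1 = object$p1)
  states <- attr(object, "tree")$tip.label
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = dplyr::bind_rows(seg_h, seg_v),
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend),
                          linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     fill = .data$p1),
                        shape = 21, size = 3) +
    ggplot2::scale_fill_gradient("P(FD)", low = "grey85", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "time from root (Myr)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank(),
                   panel.grid.minor.y = ggplot2::element_blank())
}

#' Plot the distribution of ancestor probabilities across robustness sims
#'
#' @param object A `robustness_result`.
#' @param ... Unused.
#' @return A ggplot histogram of per-simulation ancestor probabilities, with
#'   the exceedance threshold marked.
#' @export
autoplot.robustness_result <- function(object, ...) {
  d <- object$sims[!object$sims$failed, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$p1)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = object$config$prob_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "P(FD at focal ancestor)", y = "simulations",
                  title = object$config$scheme) +
    ggplot2::theme_minimal()
}

#' Per-species stacked call-category profile
#'
#' Stacked proportions of the six call categories for each species, the
#' standard at-a-glance view of how much of each species' output is the FD
#' combination.
#'
#' @param calls A classified call-level data frame.
#' @return A ggplot object.
#' @export
plot_category_profile <- function(calls) {
  stopifnot(is.data.frame(calls),
            all(c("species", "category") %in% names(calls)))
  d <- calls |>
    dplyr::count(.data$species, .data$category) |>
    dplyr::mutate(category = factor(.data$category, levels = call_categories))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n, y = .data$species,
                                  fill = .data$category)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_fill_brewer(palette = "Set2", drop = FALSE) +
    ggplot2::labs(x = "proportion of calls", y = NULL, fill = "category") +
    ggplot2::theme_minimal()
}
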