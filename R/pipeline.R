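#' Identify significantly enriched subpathways and pathways
#'
#' Runs the full analysis over one or more pathways: locate DEG-dense
#' subpathways (grow node sets under `n_s`, weighted Kruskal minimal
#' spanning tree, non-signature leaf trimming), score each subpathway by
#' combining hypergeometric enrichment with bootstrap perturbation
#' analysis, adjust all combined p-values as a single Benjamini-Hochberg
#' family, and call a pathway significant when at least one of its
#' subpathways falls below `alpha` after adjustment.
#'
#' @param pathways A [gene_graph()] or a list of them.
#' @param deg A [deg_input()].
#' @param n_s Maximum permitted non-signature nodes on an admitting
#'   shortest path (default 4).
#' @param alpha FDR level for pathway calls (default 0.01).
#' @param n_boot Bootstrap replicates for the perturbation p-value.
#' @param seed Optional integer master seed for reproducible bootstraps.
#' @inheritParams grow_node_sets
#' @inheritParams build_weighted_subgraph
#' @inheritParams locate_subpathways
#' @inheritParams score_subpathways
#' @return An object of class `subspia_result`: list with `subpathways`
#'   (located subpathways, see [locate_subpathways()]), `scores` (see
#'   [score_subpathways()]), `calls` (see [call_pathways()]) and `config`.
#' @export
#' @examples
#' g <- generate_pathway(30, seed = 1)
#' sim <- plant_de_module(g, module_size = 5, seed = 2)
#' fit <- subspia(g, sim$deg, n_boot = 200, seed = 3)
#' fit$calls
subspia <- function(pathways, deg, n_s = 4, alpha = 0.01, n_boot = 2000,
                    seed = NULL,
                    distance_rule = c("intermediates", "edges"),
                    k_zero_penalty = 2, min_signature_nodes = 1,
                    universe_mode = c("platform", "genome"),
                    genome_size = 25000) {
  distance_rule <- match.arg(distance_rule)
  universe_mode <- match.arg(universe_mode)
  if (inherits(pathways, "gene_graph")) pathways <- list(pathways)
  stopifnot(all(map_chr(pathways, class) == "gene_graph"))
  subpathways <- bind_rows(map(
    pathways, locate_subpathways,
    deg = deg, n_s = n_s, distance_rule = distance_rule,
    k_zero_penalty = k_zero_penalty,
    min_signature_nodes = min_signature_nodes
  ))
  if (nrow(subpathways) == 0L) {
    warn("no subpathways were located in any pathway")
  }
  scores <- score_subpathways(
    subpathways, pathways, deg,
    n_boot = n_boot, seed = seed,
    universe_mode = universe_mode, genome_size = genome_size
  )
  calls <- if (nrow(scores) > 0L) {
    call_pathways(scores, alpha = alpha)
  } else {
    tibble(
      pathway_id = character(), n_subpathways = integer(),
      p_g_fdr = numeric(), significant = logical()
    )
  }
  structure(
    list(
      subpathways = subpathways, scores = scores, calls = calls,
      config = list(
        n_s = n_s, alpha = alpha, n_boot = n_boot, seed = seed,
        distance_rule = distance_rule, k_zero_penalty = k_zero_penalty,
        min_signature_nodes = min_signature_nodes,
        universe_mode = universe_mode, genome_size = genome_size,
        n_pathways = length(pathways)
      )
    ),
    class = "subspia_result"
  )
}

#' @export
print.subspia_result <- function(x, ...) {
  cat(
    "<subspia_result> ", x$config$n_pathways, " pathway(s), ",
    nrow(x$scores), " subpathway(s) scored, ",
    sum(x$calls$significant), " pathway(s) significant at FDR ",
    x$config$alpha, "\n",
    sep = ""
  )
  if (nrow(x$calls) > 0L) print(head(x$calls, 10))
  invisible(x)
}

#' Tidy subpathway scores of a fitted result
#'
#' @param x A `subspia_result`.
#' @param ... Unused.
#' @return The per-subpathway score tibble (one row per subpathway).
#' @method tidy subspia_result
#' @export
tidy.subspia_result <- function(x, ...) {
  x$scores
}

#' One-row summary of a fitted result
#'
#' @param x A `subspia_result`.
#' @param ... Unused.
#' @return A one-row tibble: pathway/subpathway counts, number significant,
#'   the smallest adjusted p-value, and the main tuning parameters.
#' @method glance subspia_result
#' @export
glance.subspia_result <- function(x, ...) {
  tibble(
    n_pathways = x$config$n_pathways,
    n_subpathways = nrow(x$scores),
    n_significant = sum(x$calls$significant),
    min_p_g_fdr = if (nrow(x$calls) > 0L) min(x$calls$p_g_fdr) else NA_real_,
    alpha = x$config$alpha,
    n_s = x$config$n_s,
    n_boot = x$config$n_boot
  )
}

#' Plot pathway-level evidence
#'
#' Bar chart of `-log10` of the minimum FDR-adjusted combined p-value per
#' pathway, colored by the significance call; the dashed line marks
#' `alpha`.
#'
#' @param object A `subspia_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot subspia_result
#' @export
autoplot.subspia_result <- function(object, ...) {
  calls <- object$calls
  if (nrow(calls) == 0L) {
    abort("nothing to plot: no subpathways were located")
  }
  calls |>
    mutate(pathway_id = stats::reorder(.data$pathway_id, -.data$p_g_fdr)) |>
    ggplot(aes(
      x = .data$pathway_id, y = -log10(pmax(.data$p_g_fdr, 1e-300)),
      fill = .data$significant
    )) +
    geom_col() +
    geom_hline(
      yintercept = -log10(object$config$alpha),
      linetype = "dashed", linewidth = 0.3
    ) +
    coord_flip() +
    labs(
      x = NULL, y = expression(-log[10] ~ "FDR-adjusted" ~ P[G]),
      fill = paste0("FDR < ", object$config$alpha)
    ) +
    theme_minimal()
}

#' Plot a located subpathway tree
#'
#' Draws the trimmed spanning tree of one located subpathway with
#' signature genes highlighted.
#'
#' @param result A `subspia_result`.
#' @param index Row of `result$subpathways` to draw.
#' @return A ggplot object.
#' @export
plot_subpathway <- function(result, index = 1) {
  stopifnot(inherits(result, "subspia_result"))
  sp <- result$subpathways[index, ]
  edges <- sp$tree_edges[[1]]
  members <- sp$members[[1]]
  g <- igraph::graph_from_data_frame(
    edges[, c("u", "v")],
    directed = FALSE, vertices = data.frame(name = members)
  )
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble(
    gene = members, x = xy[, 1], y = xy[, 2],
    signature = members %in% sp$signature_members[[1]]
  )
  seg <- tibble(
    x = nodes$x[match(edges$u, nodes$gene)],
    y = nodes$y[match(edges$u, nodes$gene)],
    xend = nodes$x[match(edges$v, nodes$gene)],
    yend = nodes$y[match(edges$v, nodes$gene)]
  )
  ggplot() +
    geom_segment(
      data = seg,
      aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      color = "grey60"
    ) +
    geom_point(
      data = nodes,
      aes(x = .data$x, y = .data$y, color = .data$signature), size = 4
    ) +
    geom_text(
      data = nodes,
      aes(x = .data$x, y = .data$y, label = .data$gene),
      vjust = -1.1, size = 3
    ) +
    labs(
      color = "signature",
      title = paste0(sp$pathway_id, " subpathway ", sp$subpathway_index)
    ) +
    theme_void()
}
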