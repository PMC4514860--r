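#' Interaction-type to signed-weight lookup
#'
#' KGML relation subtypes are mapped to the signed unit weight \eqn{\beta}
#' used by the perturbation model: activating/expressing interactions
#' propagate perturbation with sign +1, inhibiting/repressing ones with -1,
#' and interactions with no defined regulatory direction (binding,
#' unsigned phosphorylation, indirect effects, ...) with 0.
#'
#' @return A named numeric vector mapping relation subtype to beta.
#' @export
#' @examples
#' kgml_beta_table()[c("activation", "inhibition", "binding/association")]
kgml_beta_table <- function() {
  c(
    "activation"          = 1,
    "expression"          = 1,
    "inhibition"          = -1,
    "repression"          = -1,
    "binding/association" = 0,
    "dissociation"        = 0,
    "phosphorylation"     = 0,
    "dephosphorylation"   = 0,
    "glycosylation"       = 0,
    "ubiquitination"      = 0,
    "methylation"         = 0,
    "indirect effect"     = 0,
    "state change"        = 0,
    "missing interaction" = 0,
    "compound"            = 0,
    "hidden compound"     = 0,
    "unknown"             = 0
  )
}

relation_beta <- function(relation, beta_table = kgml_beta_table()) {
  beta <- unname(beta_table[relation])
  # unseen vocabulary carries no regulatory sign
  beta[is.na(beta)] <- 0
  beta
}

#' Directed gene network of one pathway
#'
#' Container for a pathway's gene-level network: a set of gene identifiers
#' (one gene per node) and directed, typed edges each carrying a signed unit
#' weight `beta` in \{-1, 0, +1\}. Self-loops are dropped and parallel edges
#' between the same ordered gene pair are collapsed into one edge whose beta
#' is the clipped sum, because the perturbation model indexes beta by gene
#' pair.
#'
#' @param edges Data frame with columns `from`, `to`, `relation` and
#'   optionally `beta`; when `beta` is absent it is looked up from
#'   `beta_table`.
#' @param nodes Character vector of gene identifiers; defaults to the genes
#'   appearing in `edges`. Isolated genes may be added here.
#' @param pathway_id,pathway_name Pathway identifier and display name.
#' @param beta_table Named lookup used to derive beta from `relation`.
#'
#' @return An object of class `gene_graph`: a list with elements
#'   `pathway_id`, `pathway_name`, `nodes` (sorted character) and `edges`
#'   (a tibble with columns `from`, `to`, `relation`, `beta`).
#' @export
#' @examples
#' gene_graph(data.frame(from = "A", to = "B", relation = "activation"))
gene_graph <- function(edges = NULL, nodes = NULL, pathway_id = "pathway",
                       pathway_name = pathway_id,
                       beta_table = kgml_beta_table()) {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- tibble(
      from = character(), to = character(),
      relation = character(), beta = numeric()
    )
  } else {
    edges <- as_tibble(edges)
    stopifnot(all(c("from", "to", "relation") %in% names(edges)))
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    edges$relation <- as.character(edges$relation)
    if (!"beta" %in% names(edges)) {
      edges$beta <- relation_beta(edges$relation, beta_table)
    }
    edges <- collapse_parallel_edges(edges[edges$from != edges$to, ])
  }
  nodes <- sort(unique(c(as.character(nodes), edges$from, edges$to)))
  bad <- setdiff(c(edges$from, edges$to), nodes)
  if (length(bad) > 0L) {
    abort(paste0("edge endpoint(s) not in node set: ", toString(bad)))
  }
  structure(
    list(
      pathway_id = pathway_id, pathway_name = pathway_name,
      nodes = nodes, edges = edges[, c("from", "to", "relation", "beta")]
    ),
    class = "gene_graph"
  )
}

# Parallel edges between the same ordered pair collapse to one edge;
# beta is the sum clipped to {-1, 0, +1}, relation types are joined.
collapse_parallel_edges <- function(edges) {
  if (nrow(edges) <= 1L) {
    return(as_tibble(edges))
  }
  edges |>
    group_by(.data$from, .data$to) |>
    summarise(
      relation = paste(sort(unique(.data$relation)), collapse = "+"),
      beta = pmax(-1, pmin(1, sum(.data$beta))),
      .groups = "drop"
    ) |>
    arrange(.data$from, .data$to)
}

#' @export
print.gene_graph <- function(x, ...) {
  cat(
    "<gene_graph> ", x$pathway_id,
    if (nzchar(x$pathway_name) && !identical(x$pathway_name, x$pathway_id)) {
      paste0(" (", x$pathway_name, ")")
    } else {
      ""
    },
    ": ", length(x$nodes), " genes, ", nrow(x$edges), " edges\n",
    sep = ""
  )
  invisible(x)
}

#' Convert a gene graph to an igraph object
#'
#' @param graph A [gene_graph()].
#' @param directed Keep edge direction (`TRUE`) or take the undirected,
#'   simplified view used for node-set growth and spanning trees.
#' @return An `igraph` graph with vertex names equal to gene identifiers.
#' @export
as_igraph <- function(graph, directed = TRUE) {
  stopifnot(inherits(graph, "gene_graph"))
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("from", "to")],
    directed = directed,
    vertices = data.frame(name = graph$nodes)
  )
  if (!directed) g <- igraph::simplify(g)
  g
}
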