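#' Pathway-level crosstalk network
#'
#' A simple undirected graph whose nodes are pathways and whose edges
#' record crosstalk between them.
#'
#' @param edges Data frame with columns `from`, `to` (pathway ids).
#' @param nodes Pathway ids; defaults to those appearing in `edges`.
#' @param rule Label recording how the edges were derived.
#' @return An object of class `pathway_network`: list with `nodes`
#'   (sorted character), `edges` (tibble `from`, `to` with `from < to`)
#'   and `rule`.
#' @export
pathway_network <- function(edges = NULL, nodes = NULL, rule = "supplied") {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- tibble(from = character(), to = character())
  } else {
    edges <- as_tibble(edges)
    stopifnot(all(c("from", "to") %in% names(edges)))
    edges <- tibble(
      from = pmin(as.character(edges$from), as.character(edges$to)),
      to = pmax(as.character(edges$from), as.character(edges$to))
    ) |>
      filter(.data$from != .data$to) |>
      distinct() |>
      arrange(.data$from, .data$to)
  }
  nodes <- sort(unique(c(as.character(nodes), edges$from, edges$to)))
  structure(
    list(nodes = nodes, edges = edges, rule = rule),
    class = "pathway_network"
  )
}

#' @export
print.pathway_network <- function(x, ...) {
  cat(
    "<pathway_network> ", length(x$nodes), " pathways, ", nrow(x$edges),
    " edges (rule: ", x$rule, ")\n",
    sep = ""
  )
  invisible(x)
}

as_igraph_pathway_network <- function(net) {
  igraph::graph_from_data_frame(
    net$edges,
    directed = FALSE,
    vertices = data.frame(name = net$nodes)
  )
}

#' Build the pathway network from KGML documents
#'
#' Under the default `"maplink"` rule, pathways A and B are connected when
#' A's KGML contains a `map`-type entry referencing B, or vice versa
#' (cross-pathway links in KEGG are written as map entries / maplink
#' relations). The alternative `"shared_genes"` rule connects pathways that
#' share at least `min_shared_genes` genes, for probing sensitivity to the
#' edge definition. Only the supplied pathways become nodes.
#'
#' @param kgml_paths Character vector of KGML file paths (or XML strings).
#' @param rule Edge rule, `"maplink"` (default) or `"shared_genes"`.
#' @param min_shared_genes Minimum shared genes under `"shared_genes"`.
#' @return A [pathway_network()].
#' @export
build_pathway_network <- function(kgml_paths,
                                  rule = c("maplink", "shared_genes"),
                                  min_shared_genes = 1) {
  rule <- match.arg(rule)
  docs <- map(kgml_paths, xml2::read_xml)
  ids <- map_chr(docs, ~ sub("^path:", "", xml2::xml_attr(xml2::xml_root(.x), "name")))
  if (rule == "maplink") {
    refs <- map(docs, function(doc) {
      ent <- xml2::xml_find_all(doc, ".//entry[@type='map']")
      nm <- unlist(strsplit(xml2::xml_attr(ent, "name"), "\\s+"))
      unique(sub("^path:", "", nm[grepl("^path:", nm)]))
    })
    rows <- map2(ids, refs, function(a, b) {
      b <- intersect(setdiff(b, a), ids)
      if (length(b) == 0L) {
        return(NULL)
      }
      tibble(from = a, to = b)
    })
    edges <- bind_rows(rows)
  } else {
    genes <- map(kgml_paths, ~ parse_kgml(.x)$nodes)
    rows <- list()
    if (length(ids) > 1L) {
      for (i in seq_len(length(ids) - 1L)) {
        for (j in seq((i + 1L), length(ids))) {
          if (length(intersect(genes[[i]], genes[[j]])) >= min_shared_genes) {
            rows <- c(rows, list(tibble(from = ids[[i]], to = ids[[j]])))
          }
        }
      }
    }
    edges <- bind_rows(rows)
  }
  pathway_network(edges, nodes = ids, rule = rule)
}

#' Topology summary of an identified pathway set
#'
#' Computes, for a subset of pathways in the crosstalk network, the average
#' degree and average (unnormalized shortest-path) betweenness taken from
#' the whole network, and the average Watts-Strogatz local clustering
#' coefficient computed on the subgraph induced by the subset plus its
#' directly connected neighbors (set `include_neighbors = FALSE` for the
#' subset-only subgraph). The significance of the average degree is the
#' fraction of `n_perm` uniformly random same-size pathway subsets whose
#' average degree is at least the observed one, with +1 smoothing in
#' numerator and denominator.
#'
#' @param net A [pathway_network()].
#' @param subset Character vector of pathway ids (non-empty, all present
#'   in the network).
#' @param n_perm Number of random subsets (default 10000).
#' @param seed Optional integer seed; the global RNG state is preserved.
#' @param include_neighbors Include direct neighbors in the clustering
#'   subgraph (default TRUE).
#' @return A one-row tibble: `subset_size`, `avg_degree`,
#'   `degree_p_value`, `avg_clustering`, `avg_betweenness`, `n_perm`.
#' @export
topology_summary <- function(net, subset, n_perm = 10000, seed = NULL,
                             include_neighbors = TRUE) {
  stopifnot(inherits(net, "pathway_network"), n_perm >= 100)
  subset <- unique(as.character(subset))
  if (length(subset) == 0L) {
    abort("`subset` must be non-empty")
  }
  if (!all(subset %in% net$nodes)) {
    abort(paste0(
      "pathway id(s) absent from the network: ",
      toString(head(setdiff(subset, net$nodes), 5))
    ))
  }
  g <- as_igraph_pathway_network(net)
  deg <- igraph::degree(g)
  bet <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  avg_degree <- mean(deg[subset])
  avg_betweenness <- mean(bet[subset])

  cl_nodes <- subset
  if (include_neighbors) {
    nb <- unique(unlist(map(subset, ~ igraph::as_ids(igraph::neighbors(g, .x)))))
    cl_nodes <- unique(c(subset, nb))
  }
  gs <- igraph::induced_subgraph(g, cl_nodes)
  local_cc <- igraph::transitivity(gs, type = "local", vids = subset)
  local_cc[is.nan(local_cc)] <- 0 # degree < 2: no triangle possible
  avg_clustering <- mean(local_cc)

  k <- length(subset)
  draw_means <- function() {
    vapply(
      seq_len(n_perm),
      function(b) mean(deg[sample.int(length(deg), k)]),
      numeric(1)
    )
  }
  means <- if (is.null(seed)) draw_means() else withr::with_seed(seed, draw_means())
  degree_p_value <- (1 + sum(means >= avg_degree)) / (n_perm + 1)

  tibble(
    subset_size = k,
    avg_degree = avg_degree,
    degree_p_value = degree_p_value,
    avg_clustering = avg_clustering,
    avg_betweenness = avg_betweenness,
    n_perm = as.integer(n_perm)
  )
}
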