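#' Grow signature-connected node sets
#'
#' Partitions the signature (DEG) nodes of a pathway into groups that are
#' mutually reachable under the admission rule, and attaches the
#' non-signature genes lying on the admitting shortest paths. Two signature
#' genes u, v are *admissible* when the canonical shortest path between
#' them on the undirected view of the graph carries at most `n_s`
#' non-signature intermediate nodes (`distance_rule = "intermediates"`,
#' the default) or at most `n_s + 1` edges (`distance_rule = "edges"`).
#' A node set is one connected component of the admissibility relation
#' together with the canonical-path intermediates of every admissible pair
#' in the component, which makes the result independent of any choice of
#' start node. Redundant non-signature nodes picked up here are pruned
#' later by the spanning-tree trimming step.
#'
#' The canonical shortest path between two genes is the lexicographically
#' smallest node sequence among the minimum-length paths, read from the
#' lexicographically smaller endpoint.
#'
#' @param graph A [gene_graph()].
#' @param signature Character vector of signature (DEG) gene identifiers.
#'   Genes absent from the graph are skipped with a message.
#' @param n_s Maximum number of permitted non-signature nodes on the
#'   admitting shortest path (default 4).
#' @param distance_rule `"intermediates"` counts non-signature intermediate
#'   nodes on the canonical shortest path; `"edges"` bounds the path length
#'   in edges by `n_s + 1`.
#' @return A tibble with one row per node set: `pathway_id`, `members`
#'   (list of sorted gene ids), `signature_members` (list), `n_signature`,
#'   `n_total`. Zero rows when the graph holds no signature gene.
#' @export
grow_node_sets <- function(graph, signature, n_s = 4,
                           distance_rule = c("intermediates", "edges")) {
  stopifnot(inherits(graph, "gene_graph"), n_s >= 0)
  distance_rule <- match.arg(distance_rule)
  signature <- unique(as.character(signature))
  absent <- setdiff(signature, graph$nodes)
  if (length(absent) > 0L) {
    inform(paste0(
      length(absent), " signature gene(s) absent from pathway ",
      graph$pathway_id, " were skipped"
    ))
  }
  sig <- sort(intersect(signature, graph$nodes))
  empty <- tibble(
    pathway_id = character(), members = list(), signature_members = list(),
    n_signature = integer(), n_total = integer()
  )
  if (length(sig) == 0L) {
    return(empty)
  }
  gu <- as_igraph(graph, directed = FALSE)
  d <- igraph::distances(gu, v = sig, to = sig)

  # admissible pairs and their canonical-path intermediates
  pairs_from <- character()
  pairs_to <- character()
  intermediates <- list()
  if (length(sig) > 1L) {
    for (i in seq_len(length(sig) - 1L)) {
      for (j in seq((i + 1L), length(sig))) {
        du <- d[i, j]
        if (!is.finite(du)) next
        if (distance_rule == "edges" && du > n_s + 1) next
        path <- canonical_shortest_path(gu, sig[[i]], sig[[j]])
        inner <- path[-c(1L, length(path))]
        nonsig <- inner[!inner %in% sig]
        if (distance_rule == "intermediates" && length(nonsig) > n_s) next
        pairs_from <- c(pairs_from, sig[[i]])
        pairs_to <- c(pairs_to, sig[[j]])
        intermediates <- c(intermediates, list(nonsig))
      }
    }
  }

  adm <- igraph::graph_from_data_frame(
    data.frame(from = pairs_from, to = pairs_to),
    directed = FALSE, vertices = data.frame(name = sig)
  )
  comp <- igraph::components(adm)$membership
  sets <- split(names(comp), comp)
  # deterministic order: by smallest signature member
  sets <- sets[order(map_chr(sets, min))]

  out <- map(sets, function(s) {
    in_comp <- pairs_from %in% s # both endpoints share a component
    mem <- sort(unique(c(s, unlist(intermediates[in_comp], use.names = FALSE))))
    tibble(
      pathway_id = graph$pathway_id,
      members = list(mem),
      signature_members = list(sort(s)),
      n_signature = length(s),
      n_total = length(mem)
    )
  })
  bind_rows(out)
}

# Lexicographically smallest among the minimum-length undirected paths,
# read from the lexicographically smaller endpoint.
canonical_shortest_path <- function(gu, u, v) {
  ends <- sort(c(u, v))
  res <- igraph::all_shortest_paths(gu, from = ends[[1]], to = ends[[2]])
  paths <- res$vpaths %||% res$res
  seqs <- map(paths, ~ igraph::as_ids(.x))
  if (length(seqs) == 1L) {
    return(seqs[[1]])
  }
  mat <- do.call(rbind, seqs)
  seqs[[do.call(order, as.data.frame(mat))[[1]]]]
}

#' Build the weighted undirected subgraph of a node set
#'
#' Converts the subgraph induced by a node set into the undirected weighted
#' graph whose minimal spanning tree favours signature genes. With
#' \eqn{k_x} the number of signature genes adjacent to x inside the induced
#' subgraph, an edge (u, v) weighs 1 when both endpoints are signature
#' genes, \eqn{1 + 1/k_v} when only u is, and \eqn{1 + 1/k_u + 1/k_v} when
#' neither is. A non-signature endpoint with \eqn{k = 0} (possible for
#' larger `n_s`) contributes the finite penalty `k_zero_penalty` in place
#' of \eqn{1/k}, keeping such nodes strictly less attractive than any
#' signature-adjacent node.
#'
#' @param graph A [gene_graph()].
#' @param members Gene identifiers of the node set; must induce a connected
#'   undirected subgraph.
#' @param signature Character vector of signature genes.
#' @param k_zero_penalty Finite stand-in for `1/k` at `k = 0` (default 2).
#' @return An object of class `weighted_subgraph`: list with `members`,
#'   `signature_members`, `edges` (tibble `u`, `v`, `w`, with `u < v`) and
#'   `k` (named count of signature neighbours).
#' @export
build_weighted_subgraph <- function(graph, members, signature,
                                    k_zero_penalty = 2) {
  stopifnot(inherits(graph, "gene_graph"))
  members <- sort(unique(as.character(members)))
  stopifnot(all(members %in% graph$nodes))
  sig <- intersect(members, signature)
  e <- graph$edges[graph$edges$from %in% members & graph$edges$to %in% members, ]
  und <- tibble(u = pmin(e$from, e$to), v = pmax(e$from, e$to)) |> distinct()
  if (length(members) > 1L) {
    gi <- igraph::graph_from_data_frame(
      und,
      directed = FALSE, vertices = data.frame(name = members)
    )
    if (igraph::components(gi)$no != 1L) {
      abort("`members` do not induce a connected subgraph")
    }
  }
  nbr_sig <- function(x) {
    length(unique(c(und$v[und$u == x], und$u[und$v == x])) |> intersect(sig))
  }
  k <- stats::setNames(vapply(members, nbr_sig, integer(1)), members)
  inv_k <- ifelse(k > 0, 1 / k, k_zero_penalty)
  u_sig <- und$u %in% sig
  v_sig <- und$v %in% sig
  w <- 1 +
    ifelse(u_sig, 0, inv_k[und$u]) +
    ifelse(v_sig, 0, inv_k[und$v])
  structure(
    list(
      members = members, signature_members = sort(sig),
      edges = tibble(u = und$u, v = und$v, w = unname(w)), k = k
    ),
    class = "weighted_subgraph"
  )
}

#' Kruskal minimal spanning tree
#'
#' Deterministic Kruskal: edges are sorted by (weight, u, v) with `u < v`
#' lexicographically, then greedily added unless they close a cycle, until
#' `|members| - 1` edges are selected.
#'
#' @param wg A [build_weighted_subgraph()] result; must be connected.
#' @return An object of class `subpathway`: list with `members`,
#'   `signature_members`, `tree_edges` (tibble `u`, `v`, `w`) and
#'   `total_weight`.
#' @export
kruskal_mst <- function(wg) {
  stopifnot(inherits(wg, "weighted_subgraph"))
  n <- length(wg$members)
  e <- wg$edges[order(wg$edges$w, wg$edges$u, wg$edges$v), ]
  parent <- stats::setNames(seq_len(n), wg$members)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  keep <- logical(nrow(e))
  taken <- 0L
  ui <- match(e$u, wg$members)
  vi <- match(e$v, wg$members)
  for (i in seq_len(nrow(e))) {
    if (taken == n - 1L) break
    ru <- find(ui[[i]])
    rv <- find(vi[[i]])
    if (ru != rv) {
      parent[[ru]] <- rv
      keep[[i]] <- TRUE
      taken <- taken + 1L
    }
  }
  if (taken != n - 1L) {
    abort("input subgraph is disconnected; cannot span it")
  }
  tree <- e[keep, ]
  structure(
    list(
      members = wg$members, signature_members = wg$signature_members,
      tree_edges = tree, total_weight = sum(tree$w)
    ),
    class = "subpathway"
  )
}

#' Trim non-signature leaves off a spanning tree
#'
#' Iteratively removes tree leaves that are not signature genes until every
#' leaf is a signature gene. Redundant non-signature genes admitted during
#' growth end up as leaves of the minimal spanning tree, so trimming leaves
#' the tree that holds the maximum number of signature genes with the
#' minimum number of non-signature genes. Signature genes are never
#' removed; the operation is idempotent.
#'
#' @param sp A `subpathway` (see [kruskal_mst()]).
#' @return A trimmed `subpathway`.
#' @export
trim_mst <- function(sp) {
  stopifnot(inherits(sp, "subpathway"))
  members <- sp$members
  edges <- sp$tree_edges
  repeat {
    if (length(members) <= 1L) break
    degree <- table(factor(c(edges$u, edges$v), levels = members))
    drop <- members[degree <= 1L & !members %in% sp$signature_members]
    if (length(drop) == 0L) break
    members <- setdiff(members, drop)
    edges <- edges[!(edges$u %in% drop | edges$v %in% drop), ]
  }
  structure(
    list(
      members = members,
      signature_members = sp$signature_members,
      tree_edges = edges, total_weight = sum(edges$w)
    ),
    class = "subpathway"
  )
}

#' @export
print.subpathway <- function(x, ...) {
  cat(
    "<subpathway> ", length(x$members), " genes (",
    length(x$signature_members), " signature), ",
    nrow(x$tree_edges), " tree edges, total weight ",
    format(x$total_weight), "\n",
    sep = ""
  )
  invisible(x)
}

#' Locate DEG-dense subpathways in a pathway
#'
#' Full subpathway location: grow signature-connected node sets under
#' `n_s`, convert each to the signature-weighted undirected subgraph,
#' extract its Kruskal minimal spanning tree, and trim non-signature
#' leaves. Node sets holding a single signature gene become singleton
#' subpathways (no edges); `min_signature_nodes` can filter those out.
#'
#' @inheritParams grow_node_sets
#' @param deg A [deg_input()]; the signature is `names(deg$delta_e)`.
#' @inheritParams build_weighted_subgraph
#' @param min_signature_nodes Keep only subpathways with at least this many
#'   signature genes (default 1).
#' @return A tibble with one row per subpathway: `pathway_id`,
#'   `subpathway_index`, `members` (list), `signature_members` (list),
#'   `tree_edges` (list of tibbles), `n_signature`, `n_total`.
#' @export
locate_subpathways <- function(graph, deg, n_s = 4,
                               distance_rule = c("intermediates", "edges"),
                               k_zero_penalty = 2, min_signature_nodes = 1) {
  stopifnot(inherits(graph, "gene_graph"), inherits(deg, "deg_input"))
  distance_rule <- match.arg(distance_rule)
  sets <- grow_node_sets(graph, names(deg$delta_e),
    n_s = n_s,
    distance_rule = distance_rule
  )
  empty <- tibble(
    pathway_id = character(), subpathway_index = integer(),
    members = list(), signature_members = list(), tree_edges = list(),
    n_signature = integer(), n_total = integer()
  )
  if (nrow(sets) == 0L) {
    return(empty)
  }
  rows <- map(seq_len(nrow(sets)), function(i) {
    mem <- sets$members[[i]]
    sig <- sets$signature_members[[i]]
    if (length(mem) == 1L) {
      tree <- tibble(u = character(), v = character(), w = numeric())
      final <- list(members = mem, signature_members = sig, tree_edges = tree)
    } else {
      wg <- build_weighted_subgraph(graph, mem, sig, k_zero_penalty = k_zero_penalty)
      final <- trim_mst(kruskal_mst(wg))
    }
    tibble(
      pathway_id = graph$pathway_id,
      subpathway_index = i,
      members = list(sort(final$members)),
      signature_members = list(sort(final$signature_members)),
      tree_edges = list(final$tree_edges),
      n_signature = length(final$signature_members),
      n_total = length(final$members)
    )
  })
  out <- bind_rows(rows)
  out[out$n_signature >= min_signature_nodes, ]
}
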