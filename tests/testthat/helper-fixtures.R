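# Shared fixtures and independent oracles used across the suite.

# Worked-example fixture: seven-gene region whose grown node set at n_s = 2
# is {16,17,19,20,21,22,24} with signature {16,17,20,22,24}; the minimal
# spanning tree keeps non-signature 21 as an interior node and leaves
# non-signature 19 as a leaf, so trimming removes exactly 19. A pendant
# non-signature chain (28,29,30) checks that growth does not pick up genes
# beyond the signature region.
fig4_graph <- function() {
  parse_edge_list(
    c(
      "16\tactivation\t17",
      "17\tactivation\t20",
      "16\tactivation\t19",
      "19\tactivation\t22",
      "17\tactivation\t21",
      "21\tactivation\t22",
      "21\tactivation\t24",
      "24\tactivation\t28",
      "28\tactivation\t29",
      "29\tactivation\t30"
    ),
    pathway_id = "fig4"
  )
}

fig4_signature <- function() c("16", "17", "20", "22", "24")

# Sequential transcription of the growth procedure: start one node set from
# `start`, repeatedly admit any not-yet-included signature node whose
# canonical shortest path from a member passes the distance rule (visiting
# candidates in the order given by `shuffle_with`), then restart on leftover
# signature genes. Returns the list of signature-member sets. Independent
# traversal-order oracle for grow_node_sets().
seq_grow_signature_sets <- function(graph, signature, n_s,
                                    distance_rule = "intermediates",
                                    start = NULL, shuffle_with = NULL) {
  sig <- sort(intersect(signature, graph$nodes))
  if (length(sig) == 0L) {
    return(list())
  }
  gu <- igraph::simplify(igraph::graph_from_data_frame(
    graph$edges[, c("from", "to")],
    directed = FALSE, vertices = data.frame(name = graph$nodes)
  ))
  d <- igraph::distances(gu, v = sig, to = sig)
  canon <- function(u, v) {
    ends <- sort(c(u, v))
    res <- igraph::all_shortest_paths(gu, from = ends[[1]], to = ends[[2]])
    paths <- res$vpaths
    if (is.null(paths)) paths <- res$res
    seqs <- lapply(paths, igraph::as_ids)
    keys <- vapply(seqs, paste, character(1), collapse = "\r")
    seqs[[order(keys)[[1]]]]
  }
  admissible <- function(u, v) {
    du <- d[u, v]
    if (!is.finite(du)) {
      return(FALSE)
    }
    if (distance_rule == "edges") {
      return(du <= n_s + 1)
    }
    path <- canon(u, v)
    inner <- path[-c(1L, length(path))]
    sum(!inner %in% sig) <= n_s
  }
  if (!is.null(shuffle_with)) {
    sig_order <- withr::with_seed(shuffle_with, sample(sig))
  } else {
    sig_order <- sig
  }
  if (!is.null(start)) sig_order <- c(start, setdiff(sig_order, start))
  left <- sig_order
  sets <- list()
  while (length(left) > 0L) {
    s <- left[[1]]
    left <- left[-1]
    repeat {
      added <- FALSE
      for (v in left) {
        if (any(vapply(s, admissible, logical(1), v = v))) {
          s <- c(s, v)
          left <- setdiff(left, v)
          added <- TRUE
          break
        }
      }
      if (!added) break
    }
    sets <- c(sets, list(sort(s)))
  }
  sets[order(vapply(sets, min, character(1)))]
}

# Brute-force minimum spanning weight: enumerate all (n-1)-edge subsets and
# keep the lightest one that spans the graph.
brute_force_mst_weight <- function(members, edges) {
  n <- length(members)
  if (n == 1L) {
    return(0)
  }
  combos <- utils::combn(nrow(edges), n - 1L)
  best <- Inf
  for (j in seq_len(ncol(combos))) {
    sub <- edges[combos[, j], ]
    # spanning + acyclic on n-1 edges == connected on all n vertices
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[[i]] != i) i <- parent[[i]]
      i
    }
    ok <- TRUE
    for (k in seq_len(nrow(sub))) {
      a <- find(match(sub$u[[k]], members))
      b <- find(match(sub$v[[k]], members))
      if (a == b) {
        ok <- FALSE
        break
      }
      parent[[a]] <- b
    }
    if (ok) best <- min(best, sum(sub$w))
  }
  best
}

# Random connected weighted graph wrapped as a weighted_subgraph so it can
# be fed straight to kruskal_mst(); weights are arbitrary positive reals.
random_weighted_graph <- function(n, extra_edges = 3) {
  members <- sprintf("n%02d", seq_len(n))
  ord <- sample(members)
  u <- ord[-n]
  v <- ord[-1]
  pairs <- paste(pmin(u, v), pmax(u, v))
  extra_edges <- min(extra_edges, choose(n, 2) - (n - 1L))
  while (extra_edges > 0L) {
    cand <- sample(members, 2)
    key <- paste(min(cand), max(cand))
    if (!key %in% pairs) {
      u <- c(u, cand[[1]])
      v <- c(v, cand[[2]])
      pairs <- c(pairs, key)
      extra_edges <- extra_edges - 1L
    }
  }
  uu <- pmin(u, v)
  vv <- pmax(u, v)
  edges <- tibble::tibble(
    u = uu, v = vv,
    w = round(stats::runif(length(uu), 0.5, 5), 3)
  )
  structure(
    list(
      members = sort(members), signature_members = character(),
      edges = edges, k = NULL
    ),
    class = "weighted_subgraph"
  )
}

# Direct summation of the upper-tail hypergeometric formula with exact
# binomial coefficients; oracle for p_nde().
p_nde_oracle <- function(m, t, n, r) {
  if (r == 0) {
    return(1)
  }
  x <- 0:(r - 1)
  1 - sum(choose(t, x) * choose(m - t, n - x)) / choose(m, n)
}

# Exhaustive tail probability of the average degree over all k-subsets.
exact_degree_tail <- function(degrees, k, observed) {
  combos <- utils::combn(length(degrees), k)
  means <- colMeans(matrix(degrees[combos], nrow = k))
  mean(means >= observed - 1e-12)
}

# A fresh multi-pathway synthetic study: `n_pathways` disjoint-gene graphs
# sharing one universe (padded to `universe_size`), with an optional planted
# module in the first pathway and background DEGs everywhere else.
synth_study <- function(seed, n_pathways = 3, n_genes = 50,
                        universe_size = 2000, module_size = 0, effect = 3,
                        background_de_rate = 0.05, edge_density = 0.05) {
  withr::with_seed(seed, {
    graphs <- lapply(seq_len(n_pathways), function(i) {
      g <- generate_pathway(n_genes,
        edge_density = edge_density,
        pathway_id = sprintf("pw%02d", i)
      )
      # disjoint gene namespaces per pathway
      relabel <- function(x) sprintf("p%02d_%s", i, x)
      gene_graph(
        edges = tibble::tibble(
          from = relabel(g$edges$from), to = relabel(g$edges$to),
          relation = g$edges$relation, beta = g$edges$beta
        ),
        nodes = relabel(g$nodes), pathway_id = g$pathway_id
      )
    })
    pathway_genes <- unlist(lapply(graphs, `[[`, "nodes"))
    extra <- max(0L, universe_size - length(pathway_genes))
    universe <- c(pathway_genes, sprintf("bg%05d", seq_len(extra)))
    planted <- character()
    de <- numeric(0)
    if (module_size > 0L) {
      sim <- plant_de_module(graphs[[1]],
        module_size = module_size,
        effect = effect, background_de_rate = 0
      )
      planted <- sim$truth$planted_module
      de <- sim$deg$delta_e
    }
    background <- setdiff(universe, planted)
    hit <- background[stats::runif(length(background)) < background_de_rate]
    de <- c(de, stats::setNames(stats::rnorm(length(hit)), hit))
    list(
      graphs = graphs,
      deg = deg_input(universe = universe, delta_e = de),
      planted = planted
    )
  })
}
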