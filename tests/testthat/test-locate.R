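path_graph <- function(...) {
  genes <- c(...)
  parse_edge_list(sprintf(
    "%s\tactivation\t%s", genes[-length(genes)], genes[-1]
  ))
}

test_that("growth admits one intermediate under n_s = 1 and none under n_s = 0", {
  g <- path_graph("s1", "x", "s2")
  one <- grow_node_sets(g, c("s1", "s2"), n_s = 1)
  expect_equal(nrow(one), 1L)
  expect_equal(one$members[[1]], c("s1", "s2", "x"))
  expect_equal(one$signature_members[[1]], c("s1", "s2"))

  two <- grow_node_sets(g, c("s1", "s2"), n_s = 0)
  expect_equal(nrow(two), 2L)
  expect_equal(two$members, list("s1", "s2"))
})

test_that("disconnected signature genes form separate singleton sets", {
  g <- gene_graph(
    tibble::tibble(
      from = c("s1", "s2"), to = c("a", "b"),
      relation = "activation"
    )
  )
  for (ns in c(0, 2, 5)) {
    sets <- grow_node_sets(g, c("s1", "s2"), n_s = ns)
    expect_equal(nrow(sets), 2L)
    expect_equal(sets$signature_members, list("s1", "s2"))
  }
})

test_that("signature genes absent from the graph are skipped with a message", {
  g <- path_graph("a", "b")
  expect_message(sets <- grow_node_sets(g, c("a", "zz"), n_s = 1), "skipped")
  expect_equal(sets$members[[1]], "a")
  expect_equal(nrow(grow_node_sets(g, character(), n_s = 1)), 0L)
})

test_that("the distance-rule readings differ exactly when signature genes sit on the path", {
  # s1 - s2 - s3 chain: s1..s3 path has a signature intermediate
  g <- path_graph("s1", "s2", "s3")
  sig <- c("s1", "s3") # s2 not signature here
  # 1 non-signature intermediate (s2): admitted under intermediates, n_s = 1
  expect_equal(nrow(grow_node_sets(g, sig, n_s = 1)), 1L)
  # edges rule bounds path length by n_s + 1 = 2: also admitted
  expect_equal(nrow(grow_node_sets(g, sig, n_s = 1, distance_rule = "edges")), 1L)
  # with s2 in the signature the path s1..s3 has 0 non-signature intermediates
  g4 <- path_graph("s1", "s2", "s3", "s4")
  sig4 <- c("s1", "s2", "s4")
  # s2..s4 has 1 non-signature intermediate -> single set even at n_s = 1
  expect_equal(nrow(grow_node_sets(g4, sig4, n_s = 1)), 1L)
  # edges rule, n_s = 0: any pair farther than 1 edge is inadmissible
  sets <- grow_node_sets(g4, sig4, n_s = 0, distance_rule = "edges")
  expect_equal(sets$signature_members, list(c("s1", "s2"), "s4"))
})

test_that("edge weights follow the signature-count formula", {
  # s1 - x - s2 and s3 - x: x adjacent to three signature nodes
  g <- gene_graph(tibble::tibble(
    from = c("s1", "x", "s3", "s1"),
    to = c("x", "s2", "x", "s2"),
    relation = "activation"
  ))
  wg <- build_weighted_subgraph(g, c("s1", "s2", "s3", "x"), c("s1", "s2", "s3"))
  w_of <- function(a, b) wg$edges$w[wg$edges$u == min(a, b) & wg$edges$v == max(a, b)]
  expect_equal(w_of("s1", "s2"), 1) # both signature
  expect_equal(w_of("s1", "x"), 1 + 1 / 3) # k_x = 3
  expect_equal(wg$k[["x"]], 3L)

  # two non-signature endpoints with k = 1 each: w = 1 + 1 + 1 = 3
  g2 <- path_graph("s1", "u", "v", "s2")
  wg2 <- build_weighted_subgraph(g2, c("s1", "u", "v", "s2"), c("s1", "s2"))
  expect_equal(wg2$edges$w[wg2$edges$u == "u" & wg2$edges$v == "v"], 3)
  expect_equal(wg2$edges$w[wg2$edges$u == "s1" & wg2$edges$v == "u"], 2) # 1 + 1/1
})

test_that("a signature-orphan non-signature node gets the finite k = 0 penalty", {
  g <- path_graph("s1", "a", "b", "c", "s2")
  wg <- build_weighted_subgraph(g, c("s1", "a", "b", "c", "s2"), c("s1", "s2"))
  # b is adjacent to no signature node: 1/k term is the penalty (default 2)
  expect_equal(wg$k[["b"]], 0L)
  w_ab <- wg$edges$w[wg$edges$u == "a" & wg$edges$v == "b"]
  expect_equal(w_ab, 1 + 1 / 1 + 2)
  expect_true(all(is.finite(wg$edges$w)))
  wg5 <- build_weighted_subgraph(g, c("s1", "a", "b", "c", "s2"), c("s1", "s2"),
    k_zero_penalty = 5
  )
  expect_equal(wg5$edges$w[wg5$edges$u == "a" & wg5$edges$v == "b"], 7)
})

test_that("weights are at least 1, and exactly 1 only between signature genes", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      g <- generate_pathway(20, edge_density = 0.12)
      sig <- sample(g$nodes, 6)
      sets <- grow_node_sets(g, sig, n_s = 3)
      for (i in seq_len(nrow(sets))) {
        if (sets$n_total[[i]] < 2) next
        wg <- build_weighted_subgraph(g, sets$members[[i]], sig)
        expect_true(all(wg$edges$w >= 1))
        both_sig <- wg$edges$u %in% sig & wg$edges$v %in% sig
        expect_equal(wg$edges$w == 1, both_sig)
      }
    }
  })
})

test_that("kruskal picks the forced tree on a weighted triangle and fixes trees", {
  tri <- structure(
    list(
      members = c("a", "b", "c"), signature_members = character(),
      edges = tibble::tibble(u = c("a", "a", "b"), v = c("b", "c", "c"), w = c(1, 1, 2))
    ),
    class = "weighted_subgraph"
  )
  mst <- kruskal_mst(tri)
  expect_equal(mst$total_weight, 2)
  expect_equal(nrow(mst$tree_edges), 2L)

  # acyclic input is returned unchanged
  chain <- structure(
    list(
      members = c("a", "b", "c"), signature_members = character(),
      edges = tibble::tibble(u = c("a", "b"), v = c("b", "c"), w = c(2, 3))
    ),
    class = "weighted_subgraph"
  )
  expect_equal(kruskal_mst(chain)$tree_edges, chain$edges)

  disc <- structure(
    list(
      members = c("a", "b", "c"), signature_members = character(),
      edges = tibble::tibble(u = "a", v = "b", w = 1)
    ),
    class = "weighted_subgraph"
  )
  expect_error(kruskal_mst(disc), "disconnected")
})

test_that("kruskal matches brute-force enumeration and igraph on random graphs", {
  withr::with_seed(21, {
    for (rep in 1:25) {
      n <- sample(4:8, 1)
      wg <- random_weighted_graph(n, extra_edges = sample(2:4, 1))
      got <- kruskal_mst(wg)$total_weight
      expect_equal(got, brute_force_mst_weight(wg$members, wg$edges))
      ig <- igraph::graph_from_data_frame(wg$edges, directed = FALSE)
      expect_equal(got, sum(igraph::E(igraph::mst(ig, weights = igraph::E(ig)$w))$w))
    }
  })
})

test_that("kruskal tie-breaking is deterministic under edge shuffling", {
  withr::with_seed(31, {
    wg <- random_weighted_graph(7, extra_edges = 5)
    wg$edges$w <- sample(c(1, 1.5, 2), nrow(wg$edges), replace = TRUE)
    ref <- kruskal_mst(wg)$tree_edges
    for (rep in 1:5) {
      shuffled <- wg
      shuffled$edges <- shuffled$edges[sample(nrow(shuffled$edges)), ]
      expect_equal(kruskal_mst(shuffled)$tree_edges, ref)
    }
  })
})

test_that("trimming removes non-signature leaves only, and is idempotent", {
  g <- fig4_graph()
  sig <- fig4_signature()
  sets <- grow_node_sets(g, sig, n_s = 2)
  wg <- build_weighted_subgraph(g, sets$members[[1]], sig)
  mst <- kruskal_mst(wg)
  trimmed <- trim_mst(mst)
  expect_equal(setdiff(mst$members, trimmed$members), "19")
  expect_true(all(sig %in% trimmed$members))
  expect_true("21" %in% trimmed$members) # interior non-signature survives
  expect_equal(trim_mst(trimmed), trimmed) # idempotent

  # chain sig - nonsig - nonsig collapses to the signature singleton
  chain <- structure(
    list(
      members = c("s", "x", "y"), signature_members = "s",
      edges = tibble::tibble(u = c("s", "x"), v = c("x", "y"), w = c(2, 3))
    ),
    class = "weighted_subgraph"
  )
  out <- trim_mst(kruskal_mst(chain))
  expect_equal(out$members, "s")
  expect_equal(nrow(out$tree_edges), 0L)

  # all-signature leaves: fixpoint
  all_sig <- kruskal_mst(structure(
    list(
      members = c("a", "b", "c"), signature_members = c("a", "b", "c"),
      edges = tibble::tibble(u = c("a", "b"), v = c("b", "c"), w = c(1, 1))
    ),
    class = "weighted_subgraph"
  ))
  expect_equal(trim_mst(all_sig)$members, all_sig$members)
})

test_that("every leaf of a located subpathway is a signature gene", {
  withr::with_seed(41, {
    for (rep in 1:15) {
      g <- generate_pathway(30, edge_density = 0.08)
      sig <- sample(g$nodes, 8)
      deg <- deg_input(g$nodes, stats::setNames(stats::rnorm(8, 2), sig))
      sp <- locate_subpathways(g, deg, n_s = 3)
      for (i in seq_len(nrow(sp))) {
        edges <- sp$tree_edges[[i]]
        members <- sp$members[[i]]
        expect_equal(nrow(edges), length(members) - 1L) # tree
        if (nrow(edges) == 0L) next
        degree <- table(factor(c(edges$u, edges$v), levels = members))
        leaves <- members[degree == 1L]
        expect_true(all(leaves %in% sp$signature_members[[i]]))
      }
    }
  })
})

test_that("total MST weight is bounded below by |S| - 1 with equality iff all-signature", {
  withr::with_seed(51, {
    for (rep in 1:15) {
      g <- generate_pathway(25, edge_density = 0.1)
      sig <- sample(g$nodes, 7)
      sets <- grow_node_sets(g, sig, n_s = 3)
      for (i in seq_len(nrow(sets))) {
        if (sets$n_total[[i]] < 2) next
        wg <- build_weighted_subgraph(g, sets$members[[i]], sig)
        mst <- kruskal_mst(wg)
        n_s_members <- length(mst$members)
        expect_gte(mst$total_weight, n_s_members - 1)
        if (all(mst$members %in% sig)) {
          expect_equal(mst$total_weight, n_s_members - 1)
        } else {
          expect_gt(mst$total_weight, n_s_members - 1)
        }
      }
    }
  })
})

test_that("located subpathways split and merge with signature geography", {
  g <- path_graph("s1", "s2", "a", "b", "c", "d", "e", "f", "s3", "s4")
  deg <- deg_input(g$nodes, stats::setNames(rep(2, 4), c("s1", "s2", "s3", "s4")))
  # 6 intermediates > n_s = 4: two subpathways
  two <- locate_subpathways(g, deg, n_s = 4)
  expect_equal(nrow(two), 2L)
  expect_equal(two$signature_members, list(c("s1", "s2"), c("s3", "s4")))
  # n_s = 6 bridges them into one
  one <- locate_subpathways(g, deg, n_s = 6)
  expect_equal(nrow(one), 1L)
  expect_equal(one$n_signature, 4L)

  empty_deg <- deg_input(g$nodes, stats::setNames(numeric(0), character(0)))
  expect_equal(nrow(locate_subpathways(g, empty_deg)), 0L)
})

test_that("growth is independent of the start node and traversal order", {
  withr::with_seed(61, {
    for (rep in 1:30) {
      g <- generate_pathway(sample(10:16, 1), edge_density = 0.12)
      sig <- sample(g$nodes, sample(3:5, 1))
      ns <- sample(0:3, 1)
      got <- grow_node_sets(g, sig, n_s = ns)$signature_members
      for (start in sig) {
        ref <- seq_grow_signature_sets(g, sig, ns,
          start = start,
          shuffle_with = rep * 101 + match(start, sig)
        )
        expect_equal(got, ref)
      }
    }
  })
})

test_that("node sets grow monotonically in n_s", {
  withr::with_seed(71, {
    for (rep in 1:30) {
      g <- generate_pathway(15, edge_density = 0.1)
      sig <- sample(g$nodes, 4)
      ns <- sample(0:2, 1)
      small <- grow_node_sets(g, sig, n_s = ns)$members
      big <- grow_node_sets(g, sig, n_s = ns + sample(1:3, 1))$members
      for (s in small) {
        expect_true(any(vapply(big, function(b) all(s %in% b), logical(1))))
      }
    }
  })
})

test_that("min_signature_nodes filters singleton subpathways", {
  g <- gene_graph(tibble::tibble(
    from = c("s1", "x"), to = c("x", "y"), relation = "activation"
  ), nodes = c("s1", "x", "y", "s2"))
  deg <- deg_input(g$nodes, c(s1 = 2, s2 = -2))
  all_sp <- locate_subpathways(g, deg, n_s = 2)
  expect_equal(nrow(all_sp), 2L) # two singletons (s2 is isolated)
  expect_equal(nrow(locate_subpathways(g, deg, n_s = 2, min_signature_nodes = 2)), 0L)
})
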