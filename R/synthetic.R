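#' Generate a synthetic sparse signaling pathway
#'
#' Emulates the structure of signaling pathways that the subpathway model
#' assumes: sparsely connected directed gene networks made of linear chain
#' backbones with a sprinkling of shortcut edges. A random chain over all
#' genes guarantees connectivity; further directed edges are added at
#' random until roughly `edge_density * n * (n - 1)` edges exist. A
#' fraction `signed_fraction` of edges carry a regulatory sign (activation
#' or inhibition, equally likely); the rest are unsigned
#' binding/association edges.
#'
#' @param n_genes Number of genes (>= 2).
#' @param edge_density Target fraction of possible directed edges
#'   (0 < density <= 1); densities below the spanning chain are augmented
#'   to keep the graph connected.
#' @param signed_fraction Fraction of edges given beta = +/-1.
#' @param seed Optional integer seed; the global RNG state is preserved.
#' @param pathway_id Identifier of the generated pathway.
#' @return A [gene_graph()] with genes named `g001`, `g002`, ...
#' @export
generate_pathway <- function(n_genes, edge_density = 0.05,
                             signed_fraction = 0.8, seed = NULL,
                             pathway_id = "synth01") {
  stopifnot(n_genes >= 2, edge_density > 0, edge_density <= 1)
  build <- function() {
    genes <- sprintf("g%03d", seq_len(n_genes))
    ord <- sample(genes)
    from <- ord[-n_genes]
    to <- ord[-1]
    n_target <- max(n_genes - 1L, round(edge_density * n_genes * (n_genes - 1L)))
    have <- paste(from, to)
    while (length(have) < n_target) {
      cand_f <- sample(genes, 1)
      cand_t <- sample(setdiff(genes, cand_f), 1)
      key <- paste(cand_f, cand_t)
      if (!key %in% have) {
        from <- c(from, cand_f)
        to <- c(to, cand_t)
        have <- c(have, key)
      }
    }
    n_e <- length(from)
    signed <- runif(n_e) < signed_fraction
    relation <- ifelse(
      signed,
      ifelse(runif(n_e) < 0.5, "activation", "inhibition"),
      "binding/association"
    )
    gene_graph(
      edges = tibble(from = from, to = to, relation = relation),
      nodes = genes, pathway_id = pathway_id
    )
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Plant a coherent differentially-expressed module
#'
#' Selects a connected module by random-walk growth on the undirected view
#' of the pathway (so the plant matches the model's locality assumption),
#' gives its genes a coherent signed expression change
#' `sign * effect + Normal(0, noise_sd)` with one sign drawn per module,
#' and lets every other universe gene become a background DEG independently
#' with probability `background_de_rate` and `Delta E ~ Normal(0, 1)`.
#'
#' @param graph A [gene_graph()].
#' @param module_size Number of genes to plant (0 plants nothing).
#' @param effect Absolute planted log fold-change (> 0 when planting).
#' @param background_de_rate Per-gene probability of a background DEG.
#' @param noise_sd Standard deviation of the planted-effect noise.
#' @param seed Optional integer seed.
#' @param universe Background gene universe; defaults to the graph's genes
#'   and may be a superset (off-pathway genes can then become background
#'   DEGs).
#' @return A list with elements `deg` (a [deg_input()]) and `truth`
#'   (class `synthetic_truth`: `pathway_id`, `planted_module`,
#'   `effect_size`, `noise_sd`, `seed`).
#' @export
plant_de_module <- function(graph, module_size = 6, effect = 3,
                            background_de_rate = 0.02, noise_sd = 0.3,
                            seed = NULL, universe = graph$nodes) {
  stopifnot(inherits(graph, "gene_graph"), module_size >= 0)
  universe <- unique(c(as.character(universe), graph$nodes))
  build <- function() {
    module <- character()
    if (module_size > 0L) {
      stopifnot(effect > 0, module_size <= length(graph$nodes))
      gu <- as_igraph(graph, directed = FALSE)
      start <- sample(graph$nodes, 1)
      module <- start
      while (length(module) < module_size) {
        frontier <- setdiff(
          unique(unlist(map(
            module,
            ~ igraph::as_ids(igraph::neighbors(gu, .x))
          ))),
          module
        )
        if (length(frontier) == 0L) {
          abort("module_size exceeds the reachable component of the start gene")
        }
        module <- c(module, sample(frontier, 1))
      }
      module <- sort(module)
    }
    de <- numeric(0)
    if (length(module) > 0L) {
      sgn <- sample(c(-1, 1), 1)
      de <- stats::setNames(
        sgn * effect + rnorm(length(module), 0, noise_sd), module
      )
    }
    background <- setdiff(universe, module)
    hit <- background[runif(length(background)) < background_de_rate]
    de <- c(de, stats::setNames(rnorm(length(hit)), hit))
    list(
      deg = deg_input(universe = universe, delta_e = de),
      truth = structure(
        list(
          pathway_id = graph$pathway_id, planted_module = module,
          effect_size = effect, noise_sd = noise_sd, seed = seed
        ),
        class = "synthetic_truth"
      )
    )
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(
    "<synthetic_truth>", x$pathway_id, "-", length(x$planted_module),
    "planted genes, |effect| =", x$effect_size, "\n"
  )
  invisible(x)
}

#' Write a synthetic truth record as JSON
#'
#' @param truth A `synthetic_truth` (see [plant_de_module()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, null = "null")
  invisible(path)
}
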